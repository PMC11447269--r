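# ABBA-BABA D-statistics over population quartets with weighted
# block-jackknife significance. Site patterns are frequency-weighted
# (population mode); the outgroup polarizes derived alleles, so sites with
# a heterozygous, missing or polymorphic outgroup are skipped.

#' Frequency-weighted ABBA/BABA site-pattern weights
#'
#' For derived-allele frequencies (p1, p2, p3, pO) of the quartet
#' (((P1, P2), P3), O): `abba = (1 - p1) p2 p3 (1 - pO)` and
#' `baba = p1 (1 - p2) p3 (1 - pO)`.
#'
#' @param p1,p2,p3,pO derived-allele frequency vectors in [0, 1].
#' @return list of numeric vectors `abba`, `baba`.
#' @export
site_pattern_weights <- function(p1, p2, p3, pO) {
  stopifnot(all(c(p1, p2, p3, pO) >= 0 & c(p1, p2, p3, pO) <= 1, na.rm = TRUE))
  list(abba = (1 - p1) * p2 * p3 * (1 - pO),
       baba = p1 * (1 - p2) * p3 * (1 - pO))
}

#' D statistic from pattern sums
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; undefined (`NA`, flagged) when the
#' denominator is zero.
#'
#' @param abba,baba summed pattern weights.
#' @return D in [-1, 1] or `NA`.
#' @export
d_statistic <- function(abba, baba) {
  if (abba + baba == 0) {
    warning("D undefined: abba + baba == 0")
    return(NA_real_)
  }
  (abba - baba) / (abba + baba)
}

#' Weighted block jackknife for the D statistic
#'
#' Delete-one-genomic-block resampling with block weights proportional to
#' informative-site counts (Busing-style weighted jackknife), giving a
#' standard error robust to linkage and `Z = D / se`. With identical
#' pattern sums in every block the se is 0 and Z is flagged infinite.
#'
#' @param blocks `data.table`/data.frame with per-block partial sums:
#'   columns `abba`, `baba`, `n` (informative sites).
#' @return list: `D`, `se`, `Z`, `n_blocks`.
#' @export
block_jackknife <- function(blocks) {
  blocks <- as.data.table(blocks)[n > 0]
  g <- nrow(blocks)
  if (g < 10L)
    stop("only ", g, " non-empty blocks; use a smaller block size (>= 10 required)")
  A <- sum(blocks$abba); B <- sum(blocks$baba)
  D <- d_statistic(A, B)
  n_tot <- sum(blocks$n)
  theta_j <- (A - blocks$abba - (B - blocks$baba)) /
    (A - blocks$abba + (B - blocks$baba))
  h <- n_tot / blocks$n
  theta_dot <- g * D - sum((1 - 1 / h) * theta_j)
  tau <- h * D - (h - 1) * theta_j
  var_j <- sum((tau - theta_dot)^2 / (h - 1)) / g
  if (var_j < .Machine$double.eps) var_j <- 0  # identical blocks, fp residue
  se <- sqrt(var_j)
  Z <- if (se == 0) {
    warning("jackknife se is 0; Z flagged infinite")
    sign(D) * Inf
  } else D / se
  list(D = D, se = se, Z = Z, n_blocks = g)
}

#' ABBA-BABA D statistic for a population quartet
#'
#' Computes per-population derived-allele frequencies (outgroup-polarized),
#' frequency-weighted pattern sums per genomic block and the weighted
#' block-jackknife Z score. Sites where any quartet population has no
#' called alleles, or where the outgroup does not define an ancestral
#' allele, are skipped.
#'
#' @param geno a `genotype_matrix`.
#' @param table matching `variant_table`.
#' @param popmap popmap.
#' @param quartet character vector (P1, P2, P3, O) of population labels.
#' @param block_size_bp jackknife block size (default 5 Mb).
#' @return list: `D`, `se`, `Z`, `n_blocks`, `n_informative_sites`,
#'   `abba`, `baba`, `blocks`.
#' @export
dstat_quartet <- function(geno, table, popmap, quartet,
                          block_size_bp = 5e6) {
  stopifnot(length(quartet) == 4L, all(quartet %in% popmap$population))
  g <- unclass(geno)
  pops <- lapply(quartet, function(p) popmap$individual[popmap$population == p])

  out_g <- g[, pops[[4]], drop = FALSE]
  anc_ref <- rowSums(out_g == 0L, na.rm = TRUE) > 0 &
    rowSums(out_g != 0L, na.rm = TRUE) == 0
  anc_alt <- rowSums(out_g == 2L, na.rm = TRUE) > 0 &
    rowSums(out_g != 2L, na.rm = TRUE) == 0
  polarizable <- anc_ref | anc_alt

  freqs <- lapply(pops[1:3], function(ind) {
    gi <- g[, ind, drop = FALSE]
    n <- 2 * rowSums(!is.na(gi))
    p_alt <- rowSums(gi, na.rm = TRUE) / n
    list(p_alt = p_alt, n = n)
  })
  ok <- polarizable & freqs[[1]]$n > 0 & freqs[[2]]$n > 0 & freqs[[3]]$n > 0
  # derived frequency: alt where the outgroup is hom ref, ref otherwise
  pd <- lapply(freqs, function(fr) ifelse(anc_ref, fr$p_alt, 1 - fr$p_alt))
  pO <- rep(0, nrow(table))  # outgroup is ancestral by construction
  w <- site_pattern_weights(pd[[1]][ok], pd[[2]][ok], pd[[3]][ok], pO[ok])

  blk <- data.table(chrom = table$chrom[ok],
                    block = (table$pos[ok] - 1L) %/% as.integer(block_size_bp),
                    abba = w$abba, baba = w$baba)
  blocks <- blk[, .(abba = sum(abba), baba = sum(baba), n = .N),
                by = .(chrom, block)]
  jk <- block_jackknife(blocks)
  c(jk, list(n_informative_sites = sum(ok), abba = sum(w$abba),
             baba = sum(w$baba), blocks = blocks[]))
}
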