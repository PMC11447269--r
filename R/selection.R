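# Selection scans: theta-pi log-ratio windows, XP-EHH, gene-level Ka/Ks,
# the >= 2-method consensus, and private non-synonymous variant screens.

#' Extended haplotype homozygosity decay curve
#'
#' EHH at distance x from the core SNP is the fraction of haplotype pairs
#' identical at all SNPs beyond the core up to x (each direction
#' separately); EHH(core) = 1 by definition. Non-increasing with distance
#' in each direction.
#'
#' @param haps 0/1 matrix, sites x haplotypes (>= 2 haplotypes), phased.
#' @param positions bp positions, strictly increasing.
#' @param core_index 1-based row index of the core SNP.
#' @return `data.frame`: pos, ehh, side (-1 left, 0 core, +1 right).
#' @export
ehh <- function(haps, positions, core_index) {
  stopifnot(ncol(haps) >= 2L, !is.unsorted(positions, strictly = TRUE),
            core_index >= 1L, core_index <= nrow(haps))
  .ehh_curve_cpp(haps, as.numeric(positions), as.integer(core_index) - 1L)
}

#' Integrated EHH (iHH)
#'
#' Trapezoid integral of the EHH decay over bp in each direction, summed;
#' integration stops after the first point below `cutoff` (that bounding
#' trapezoid is included).
#'
#' @param haps,positions,core_index as in [ehh()].
#' @param cutoff EHH truncation level (default 0.05).
#' @return iHH in bp.
#' @export
ihh <- function(haps, positions, core_index, cutoff = 0.05) {
  stopifnot(ncol(haps) >= 2L)
  .ihh_core(haps, as.numeric(positions), as.integer(core_index) - 1L, cutoff)
}

#' Cross-population EHH scores at every SNP core
#'
#' `raw = ln(iHH_A / iHH_B)` per core; positive when haplotype
#' homozygosity is extended in population A. Cores where either iHH is 0
#' are undefined (`NA`) and excluded from standardization.
#'
#' @param haps_a,haps_b 0/1 haplotype matrices on the same SNP grid.
#' @param positions shared bp positions.
#' @param cutoff EHH truncation level.
#' @return numeric vector of raw scores (one per SNP).
#' @export
xpehh <- function(haps_a, haps_b, positions, cutoff = 0.05) {
  stopifnot(nrow(haps_a) == nrow(haps_b))
  ia <- .ihh_all_cores(haps_a, as.numeric(positions), cutoff)
  ib <- .ihh_all_cores(haps_b, as.numeric(positions), cutoff)
  out <- rep(NA_real_, length(ia))
  ok <- ia > 0 & ib > 0
  out[ok] <- log(ia[ok] / ib[ok])
  out
}

#' Z-transform scores and take the top outlier tail
#'
#' Standardizes by the genome-wide mean and standard deviation of the
#' defined scores and flags the top `outlier_quantile` tail (inclusive at
#' the threshold, so ties all enter the outlier set).
#'
#' @param scores raw scores (`NA` allowed).
#' @param outlier_quantile tail mass (default 0.05).
#' @return list: `z`, `threshold`, `outlier` (logical).
#' @export
standardize_scores <- function(scores, outlier_quantile = 0.05) {
  mu <- mean(scores, na.rm = TRUE)
  sdev <- sd(scores, na.rm = TRUE)
  z <- (scores - mu) / sdev
  thr <- quantile(z, 1 - outlier_quantile, na.rm = TRUE, names = FALSE)
  list(z = z, threshold = thr, outlier = !is.na(z) & z >= thr)
}

#' Sliding-window theta-pi log-ratio scan
#'
#' Per sliding window, `value = ln(pi_A / pi_B)`; with the candidate
#' population as B, selective sweeps in the candidate give large positive
#' values. Windows with fewer than `min_variable` variable sites (union of
#' both populations) are excluded. `pi_B = 0` in a retained window yields
#' `Inf`, which lands in the outlier set. Outliers are the top
#' `outlier_quantile` of retained windows, threshold inclusive.
#'
#' @param geno a `genotype_matrix`.
#' @param table matching `variant_table`.
#' @param popmap popmap.
#' @param pop_a,pop_b population labels (numerator / denominator-candidate).
#' @param chrom_lengths named chromosome lengths.
#' @param window_bp,step_bp window geometry (default 40 kb / 20 kb).
#' @param min_variable minimum variable sites per retained window.
#' @param outlier_quantile outlier tail (default 0.05).
#' @return `data.table`: chrom, start, end, n_variable_sites, pi_a, pi_b,
#'   value, retained, outlier.
#' @export
pi_ratio_windows <- function(geno, table, popmap, pop_a, pop_b,
                             chrom_lengths, window_bp = 40000L,
                             step_bp = 20000L, min_variable = 20L,
                             outlier_quantile = 0.05) {
  ind_a <- popmap$individual[popmap$population == pop_a]
  ind_b <- popmap$individual[popmap$population == pop_b]
  pi_a <- pop_site_pi(geno, ind_a)
  pi_b <- pop_site_pi(geno, ind_b)
  variable <- (pi_a > 0 & !is.na(pi_a)) | (pi_b > 0 & !is.na(pi_b))
  win <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    starts <- seq(1L, max(1L, chrom_lengths[[cn]] - window_bp + 1L), by = step_bp)
    data.table(chrom = cn, start = as.integer(starts),
               end = as.integer(pmin(starts + window_bp - 1L,
                                     chrom_lengths[[cn]])))
  }))
  stat <- lapply(seq_len(nrow(win)), function(i) {
    idx <- table$chrom == win$chrom[i] & table$pos >= win$start[i] &
      table$pos <= win$end[i]
    c(nv = sum(variable & idx),
      sa = sum(pi_a[idx], na.rm = TRUE), sb = sum(pi_b[idx], na.rm = TRUE))
  })
  m <- do.call(rbind, stat)
  win[, `:=`(n_variable_sites = as.integer(m[, "nv"]),
             pi_a = m[, "sa"] / window_bp, pi_b = m[, "sb"] / window_bp)]
  win[, value := log(pi_a / pi_b)]
  win[, retained := n_variable_sites >= min_variable & !is.nan(value)]
  fin <- win$retained & is.finite(win$value)
  thr <- if (any(fin))
    quantile(win$value[fin], 1 - outlier_quantile, names = FALSE) else Inf
  win[, outlier := retained & value >= thr]
  win[]
}

#' Map flagged windows or SNPs to genes
#'
#' A gene is flagged when any flagged interval overlaps it by at least one
#' bp (the overlap rule is a parameter of the consensus, not of the
#' underlying scans).
#'
#' @param flagged `data.frame` with chrom, start, end of flagged intervals
#'   (points allowed: start == end).
#' @param model a `gene_model`.
#' @return character vector of flagged gene ids.
#' @export
genes_hit <- function(flagged, model) {
  if (is.null(flagged) || nrow(flagged) == 0L) return(character())
  gr <- GenomicRanges::GRanges(flagged$chrom,
                               IRanges::IRanges(flagged$start, flagged$end))
  hit <- GenomicRanges::findOverlaps(model$genes, gr, ignore.strand = TRUE)
  unique(model$genes$gene_id[S4Vectors::queryHits(hit)])
}

#' Combine per-method gene flags into sweep calls
#'
#' A gene is called a consensus sweep iff at least two of the three
#' methods flag it.
#'
#' @param pi_ratio_genes,xpehh_genes,kaks_genes character vectors of
#'   flagged gene ids per method.
#' @param model a `gene_model` providing the gene universe.
#' @return `data.table`: gene_id, pi_ratio, xpehh, kaks, consensus.
#' @export
consensus_sweep <- function(pi_ratio_genes, xpehh_genes, kaks_genes, model) {
  out <- data.table(gene_id = model$genes$gene_id)
  out[, `:=`(pi_ratio = gene_id %in% pi_ratio_genes,
             xpehh = gene_id %in% xpehh_genes,
             kaks = gene_id %in% kaks_genes)]
  out[, consensus := (pi_ratio + xpehh + kaks) >= 2L]
  out[]
}

#' Gene-level Ka/Ks flags from a simulated dataset
#'
#' Builds per-population pseudo-CDS codon sequences over each gene's
#' variant coding sites (majority allele per population, codon context
#' from the simulator) and flags genes with Ka/Ks > `ratio_threshold`.
#' Real-data Ka/Ks requires externally supplied CDS alignments; this
#' helper exists so the three-method consensus is exercised end to end on
#' synthetic bundles.
#'
#' @param sim a `karst_sim`.
#' @param pop_a,pop_b population labels.
#' @param ratio_threshold flag genes above this Ka/Ks (default 1).
#' @return character vector of flagged gene ids.
#' @export
kaks_gene_flags <- function(sim, pop_a, pop_b, ratio_threshold = 1) {
  tab <- sim$table
  cp <- sim$codon_pos
  rc <- sim$ref_codon
  use <- !is.na(cp) & !is.na(tab$gene_id) & tab$gene_id != "-"
  if (!any(use)) return(character())
  g <- unclass(sim$geno)
  maj_base <- function(pop, idx) {
    ind <- sim$popmap$individual[sim$popmap$population == pop]
    gi <- g[, ind, drop = FALSE][idx, , drop = FALSE]
    freq <- rowSums(gi, na.rm = TRUE) / (2 * rowSums(!is.na(gi)))
    ifelse(!is.na(freq) & freq > 0.5, tab$alt[idx], tab$ref[idx])
  }
  flagged <- character()
  for (gene in unique(tab$gene_id[use])) {
    idx <- which(use & tab$gene_id == gene)
    ba <- maj_base(pop_a, idx); bb <- maj_base(pop_b, idx)
    codon_at <- function(base, i) {
      codon <- rc[idx[i]]
      substr(codon, cp[idx[i]] + 1L, cp[idx[i]] + 1L) <- base[i]
      codon
    }
    ca <- paste(vapply(seq_along(idx), function(i) codon_at(ba, i), ""),
                collapse = "")
    cb <- paste(vapply(seq_along(idx), function(i) codon_at(bb, i), ""),
                collapse = "")
    res <- tryCatch(suppressWarnings(kaks_ng86(ca, cb)),
                    error = function(e) NULL)
    if (!is.null(res) && !is.na(res$ratio) && res$ratio > ratio_threshold)
      flagged <- c(flagged, gene)
  }
  flagged
}

#' Three-method selective-sweep consensus scan
#'
#' Runs the theta-pi log-ratio windows (candidate in the denominator) and
#' the per-SNP XP-EHH scan (candidate in the numerator), maps outliers to
#' genes by any-bp overlap, optionally adds gene-level Ka/Ks flags, and
#' applies the >= 2-method consensus rule.
#'
#' @param geno,table,popmap the data model.
#' @param haplotypes list(h1, h2) phased 0/1 matrices (sites x
#'   individuals). Unphased input must be pseudo-phased first (see
#'   [pseudo_phase()]).
#' @param model a `gene_model`.
#' @param chrom_lengths named chromosome lengths.
#' @param candidate_pop,background_pop population labels.
#' @param kaks_genes optional pre-computed Ka/Ks gene flags (e.g. from
#'   [kaks_gene_flags()]).
#' @param window_bp,step_bp,min_variable,outlier_quantile scan parameters.
#' @return list: `calls` (consensus table), `pi_windows`, `xpehh_z`.
#' @export
sweep_consensus_scan <- function(geno, table, popmap, haplotypes, model,
                                 chrom_lengths, candidate_pop,
                                 background_pop, kaks_genes = character(),
                                 window_bp = 40000L, step_bp = 20000L,
                                 min_variable = 20L, outlier_quantile = 0.05) {
  pw <- pi_ratio_windows(geno, table, popmap, pop_a = background_pop,
                         pop_b = candidate_pop, chrom_lengths,
                         window_bp = window_bp, step_bp = step_bp,
                         min_variable = min_variable,
                         outlier_quantile = outlier_quantile)
  pi_genes <- genes_hit(pw[pw$outlier], model)

  hap_cols <- function(pop) {
    ind <- popmap$individual[popmap$population == pop]
    cbind(haplotypes$h1[, ind, drop = FALSE],
          haplotypes$h2[, ind, drop = FALSE])
  }
  ha <- hap_cols(candidate_pop); hb <- hap_cols(background_pop)
  raw <- rep(NA_real_, nrow(table))
  for (cn in unique(table$chrom)) {
    idx <- which(table$chrom == cn)
    raw[idx] <- xpehh(ha[idx, , drop = FALSE], hb[idx, , drop = FALSE],
                      table$pos[idx])
  }
  st <- standardize_scores(raw, outlier_quantile)
  # aggregate per-SNP Z to the window grid by the maximum score, then take
  # the top tail of windows (candidate's tail; threshold inclusive)
  xw <- copy(pw[, .(chrom, start, end)])
  xw[, score := vapply(seq_len(.N), function(i) {
    idx <- table$chrom == chrom[i] & table$pos >= start[i] &
      table$pos <= end[i] & !is.na(st$z)
    if (!any(idx)) NA_real_ else max(st$z[idx])
  }, 0)]
  thr <- quantile(xw$score, 1 - outlier_quantile, na.rm = TRUE, names = FALSE)
  xw[, outlier := !is.na(score) & score >= thr]
  xp_genes <- genes_hit(xw[xw$outlier], model)
  calls <- consensus_sweep(pi_genes, xp_genes, kaks_genes, model)
  list(calls = calls, pi_windows = pw, xpehh_windows = xw, xpehh_z = st$z)
}

#' Pseudo-phase an unphased genotype matrix
#'
#' Assigns heterozygous alleles to haplotypes at random within each
#' individual. This destroys real haplotype structure beyond single sites
#' and is only a fallback for unphased input to haplotype statistics; a
#' loud warning is emitted.
#'
#' @param geno a `genotype_matrix`.
#' @param seed integer seed.
#' @return list(h1, h2) of 0/1 matrices (`NA` where genotypes are missing).
#' @export
pseudo_phase <- function(geno, seed = 1L) {
  warning("pseudo-phasing unphased genotypes: haplotype statistics will be ",
          "attenuated; supply phased data where possible")
  g <- unclass(geno)
  with_seed(seed, {
    flip <- matrix(rbinom(length(g), 1L, 0.5), nrow = nrow(g))
    h1 <- ifelse(g == 2L, 1L, ifelse(g == 1L, flip, 0L))
    h2 <- ifelse(g == 2L, 1L, ifelse(g == 1L, 1L - flip, 0L))
    h1[is.na(g)] <- NA_integer_; h2[is.na(g)] <- NA_integer_
    list(h1 = h1, h2 = h2)
  })
}
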