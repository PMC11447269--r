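# PLINK-style run-of-homozygosity detection and inbreeding coefficients.

#' ROH detection parameters
#'
#' Defaults follow the PLINK invocation `--homozyg --homozyg-density 50
#' --homozyg-gap 100 --homozyg-kb 100 --homozyg-snp 50 --homozyg-window-het
#' 1 --homozyg-window-snp 20 --homozyg-window-threshold 0.05`. The quoted
#' allowance of 50 missing calls per 20-SNP window is internally
#' inconsistent; the effective cap is `min(max_missing_per_window,
#' window_snps)` (so missingness never breaks a window), with the quoted
#' value retained for provenance.
#'
#' @param window_snps sliding-window size in SNPs.
#' @param max_het_per_window maximum heterozygous calls per window.
#' @param max_missing_per_window maximum missing calls per window (capped
#'   at `window_snps`).
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   covering a SNP for it to be in-run.
#' @param min_segment_snps,min_segment_kb minimum segment size.
#' @param min_density_kb_per_snp maximum kb per SNP inside a segment.
#' @param max_gap_kb maximum gap between consecutive in-run SNPs.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 20L, max_het_per_window = 1L,
                       max_missing_per_window = 50L,
                       window_hit_threshold = 0.05,
                       min_segment_snps = 50L, min_segment_kb = 100,
                       min_density_kb_per_snp = 50, max_gap_kb = 100) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) > 0), window_hit_threshold <= 1)
  p$effective_max_missing <- min(p$max_missing_per_window, p$window_snps)
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity in one individual
#'
#' Slides a `window_snps`-SNP window one SNP at a time along each
#' chromosome; a window is homozygous when it contains at most
#' `max_het_per_window` heterozygous and `effective_max_missing` missing
#' calls. Each SNP's hit rate is the fraction of windows containing it
#' that are homozygous; SNPs at or above `window_hit_threshold` are
#' in-run. Maximal stretches of consecutive in-run SNPs are split at gaps
#' larger than `max_gap_kb` and then filtered by the segment minima and
#' density. Segment boundaries are the first/last in-run SNP positions.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix`.
#' @param table matching `variant_table` (sites sorted per chromosome).
#' @param params a [roh_params()].
#' @return `data.table` of segments: chrom, start, end (bp, 1-based
#'   inclusive), n_snps, length_kb.
#' @export
detect_roh <- function(individual, geno, table, params = roh_params()) {
  g <- unclass(geno)[, individual]
  out <- lapply(unique(table$chrom), function(cn) {
    idx <- which(table$chrom == cn)
    detect_roh_chrom(g[idx], table$pos[idx], cn, params)
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric())
  res[]
}

detect_roh_chrom <- function(g, pos, chrom_name, params) {
  n <- length(g)
  w <- params$window_snps
  if (n < w) {
    message("chromosome ", chrom_name, " has fewer than ", w, " SNPs; skipped")
    return(NULL)
  }
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  n_win <- n - w + 1L
  j <- seq_len(n_win)
  hom_win <- (ch[j + w] - ch[j]) <= params$max_het_per_window &
    (cm[j + w] - cm[j]) <= params$effective_max_missing
  # hit rate per SNP: windows j in [i - w + 1, i] clipped to [1, n_win]
  cw <- cumsum(c(0L, as.integer(hom_win)))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L); hi <- pmin(i, n_win)
  n_cover <- hi - lo + 1L
  n_hom <- cw[hi + 1L] - cw[lo]
  in_run <- n_hom / n_cover >= params$window_hit_threshold

  # maximal stretches of in-run SNPs, split at large gaps
  r <- rle(in_run)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    run_pos <- pos[s:e]
    brk <- which(diff(run_pos) > params$max_gap_kb * 1000)
    piece_start <- c(s, s + brk); piece_end <- c(s + brk - 1L, e)
    for (p in seq_along(piece_start)) {
      a <- piece_start[p]; b <- piece_end[p]
      n_snps <- b - a + 1L
      length_kb <- (pos[b] - pos[a] + 1) / 1000
      if (n_snps >= params$min_segment_snps &&
          length_kb >= params$min_segment_kb &&
          length_kb / n_snps <= params$min_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <-
          data.table(chrom = chrom_name, start = pos[a], end = pos[b],
                     n_snps = n_snps, length_kb = length_kb)
      }
    }
  }
  rbindlist(segs)
}

#' Fraction of the genome in runs of homozygosity
#'
#' @param segments segment `data.table` from [detect_roh()] (disjoint).
#' @param genome_length_bp total length of the analyzed chromosomes, or a
#'   named per-chromosome vector when `per_chrom = TRUE`.
#' @param per_chrom report one fraction per chromosome.
#' @return numeric fraction, or named vector per chromosome.
#' @export
f_roh <- function(segments, genome_length_bp, per_chrom = FALSE) {
  if (nrow(segments)) {
    so <- segments[order(chrom, start)]
    ov <- so[, any(start[-1] <= head(end, -1)), by = chrom]$V1
    if (any(ov)) stop("overlapping ROH segments; segments must be disjoint")
  }
  if (!per_chrom) {
    return(sum(segments$end - segments$start + 1) / sum(genome_length_bp))
  }
  stopifnot(!is.null(names(genome_length_bp)))
  len <- segments[, .(bp = sum(end - start + 1)), by = chrom]
  out <- setNames(rep(0, length(genome_length_bp)), names(genome_length_bp))
  out[len$chrom] <- len$bp / genome_length_bp[len$chrom]
  out
}

#' Fraction of genes overlapped by runs of homozygosity
#'
#' A gene counts as "in ROH" when at least `min_overlap` of its length is
#' covered by segments (default 50 percent).
#'
#' @param segments segment `data.table` from [detect_roh()].
#' @param model a `gene_model`.
#' @param min_overlap minimum covered fraction of the gene span.
#' @return fraction of genes in ROH.
#' @export
genes_in_roh_fraction <- function(segments, model, min_overlap = 0.5) {
  genes <- model$genes
  if (length(genes) == 0L) return(NA_real_)
  if (nrow(segments) == 0L) return(0)
  seg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start, segments$end)))
  cov <- GenomicRanges::intersect(
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                           IRanges::IRanges(GenomicRanges::start(genes),
                                            GenomicRanges::end(genes)),
                           gene_id = genes$gene_id), seg,
    ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(genes, cov)
  covered <- tapply(GenomicRanges::width(cov)[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
  frac <- setNames(rep(0, length(genes)), seq_along(genes))
  frac[names(covered)] <- covered
  mean(frac / GenomicRanges::width(genes) >= min_overlap)
}

#' Excess-homozygosity inbreeding coefficient F
#'
#' `F = (O(hom) - E(hom)) / (N - E(hom))` per individual, where the
#' expected homozygous count uses sample allele frequencies with the
#' small-sample correction: `E = sum_sites(1 - 2 p (1 - p) n/(n - 1))`,
#' `n` being the called allele count at the site. Only sites called in the
#' individual contribute.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix`; allele frequencies are estimated from
#'   all individuals in it.
#' @return list: `F`, `O_hom`, `E_hom`, `N`.
#' @export
excess_hom_F <- function(individual, geno) {
  g <- unclass(geno)
  gi <- g[, individual]
  called <- !is.na(gi)
  n_all <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n_all
  use <- called & n_all >= 2
  exp_het <- 2 * p[use] * (1 - p[use]) * n_all[use] / (n_all[use] - 1)
  E <- sum(1 - exp_het)
  O <- sum(gi[use] != 1L)
  N <- sum(use)
  if (isTRUE(all.equal(N, E))) {
    warning("excess_hom_F undefined: expected equals total")
    return(list(F = NA_real_, O_hom = O, E_hom = E, N = N))
  }
  list(F = (O - E) / (N - E), O_hom = O, E_hom = E, N = N)
}
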