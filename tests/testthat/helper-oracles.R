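suppressPackageStartupMessages(library(data.table))

# Independent brute-force oracles. These re-derive expected values from
# first principles (literal rule application, exhaustive enumeration) and
# deliberately avoid the package's vectorized/compiled code paths.

# Mean pairwise difference over all haplotype pairs, by enumeration.
brute_site_pi <- function(n, j) {
  alleles <- c(rep(1L, j), rep(0L, n - j))
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Literal PLINK-rule ROH caller: enumerate every window, score every SNP,
# walk stretches with explicit loops.
brute_roh <- function(g, pos, chrom = "chr1", params = roh_params()) {
  n <- length(g)
  w <- params$window_snps
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric())
  if (n < w) return(empty)
  max_miss <- min(params$max_missing_per_window, w)
  n_win <- n - w + 1L
  hom_win <- logical(n_win)
  for (j in seq_len(n_win)) {
    win <- g[j:(j + w - 1L)]
    hom_win[j] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= max_miss
  }
  in_run <- logical(n)
  for (i in seq_len(n)) {
    js <- seq(max(1L, i - w + 1L), min(i, n_win))
    in_run[i] <- mean(hom_win[js]) >= params$window_hit_threshold
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!in_run[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && in_run[j + 1L]) j <- j + 1L
    # split the stretch [i, j] at gaps
    a <- i
    for (k in i:j) {
      gap_next <- k < j && (pos[k + 1L] - pos[k]) > params$max_gap_kb * 1000
      if (gap_next || k == j) {
        b <- k
        n_snps <- b - a + 1L
        len_kb <- (pos[b] - pos[a] + 1) / 1000
        if (n_snps >= params$min_segment_snps &&
            len_kb >= params$min_segment_kb &&
            len_kb / n_snps <= params$min_density_kb_per_snp) {
          segs[[length(segs) + 1L]] <-
            data.frame(chrom = chrom, start = pos[a], end = pos[b],
                       n_snps = n_snps, length_kb = len_kb)
        }
        a <- k + 1L
      }
    }
    i <- j + 1L
  }
  if (length(segs) == 0L) return(empty)
  do.call(rbind, segs)
}

# Random single-chromosome genotype vector with homozygous tracts, for
# ROH oracle-equivalence tests.
random_roh_genome <- function(n_snps, len_bp = 3e6, p_tract = 0.3) {
  pos <- sort(sample.int(len_bp, n_snps))
  n_tracts <- rpois(1, 3)
  in_tract <- rep(FALSE, n_snps)
  for (k in seq_len(n_tracts)) {
    s <- runif(1, 0, len_bp)
    e <- s + runif(1, 5e4, 8e5)
    in_tract <- in_tract | (pos >= s & pos <= e)
  }
  p_het <- ifelse(in_tract, 0.002, 0.25)
  g <- ifelse(runif(n_snps) < p_het, 1L, sample(c(0L, 2L), n_snps, replace = TRUE))
  g[runif(n_snps) < 0.02] <- NA_integer_
  list(g = g, pos = pos)
}

# Delete-one-block weighted jackknife recomputed from scratch.
brute_jackknife_D <- function(blocks) {
  A <- sum(blocks$abba); B <- sum(blocks$baba)
  D <- (A - B) / (A + B)
  g <- nrow(blocks)
  n <- sum(blocks$n)
  theta <- numeric(g)
  for (j in seq_len(g)) {
    keep <- setdiff(seq_len(g), j)
    a <- sum(blocks$abba[keep]); b <- sum(blocks$baba[keep])
    theta[j] <- (a - b) / (a + b)
  }
  h <- n / blocks$n
  theta_dot <- g * D - sum((1 - 1 / h) * theta)
  tau <- h * D - (h - 1) * theta
  sqrt(sum((tau - theta_dot)^2 / (h - 1)) / g)
}

# EHH by direct pair counting: fraction of haplotype pairs identical at
# every SNP strictly between the core and x (inclusive of x).
brute_ehh_at <- function(haps, core, x) {
  n <- ncol(haps)
  rng <- if (x > core) (core + 1):x else if (x < core) x:(core - 1) else integer()
  same <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (length(rng) == 0 || all(haps[rng, a] == haps[rng, b])) same <- same + 1
    }
  }
  same / (n * (n - 1) / 2)
}

# Small helpers to build fixtures in code --------------------------------

make_table <- function(n, chrom = "chr1", start = 1000, by = 1000,
                       gerp = NA_real_, ...) {
  pos <- seq(start, by = by, length.out = n)
  variant_table(chrom = rep(chrom, n), pos = pos, ref = rep("A", n),
                alt = rep("G", n), gerp = gerp, ...)
}

make_geno <- function(..., callable = NULL) {
  g <- cbind(...)
  if (is.null(callable))
    callable <- setNames(rep(nrow(g), ncol(g)), colnames(g))
  genotype_matrix(g, colnames(g), callable_length = callable)
}

make_popmap <- function(individuals, populations, roles = NULL) {
  if (is.null(roles))
    roles <- ifelse(populations == "outgroup", "outgroup",
                    ifelse(populations == "target", "target", "background"))
  data.frame(individual = individuals, population = populations, role = roles)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
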