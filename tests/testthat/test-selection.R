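test_that("EHH decay: identical, paired and distinct haplotypes", {
  pos <- seq(1000, by = 1000, length.out = 11)
  core <- 6L

  same <- matrix(0L, nrow = 11, ncol = 4)
  curve <- ehh(same, pos, core)
  expect_true(all(curve$ehh == 1))
  expect_equal(ihh(same, pos, core), 10000)  # 5 kb flank each side

  # two identical pairs beyond the core: plateau C(2,2)+C(2,2) over C(4,2)
  paired <- cbind(c(rep(0L, 5), 0L, rep(0L, 5)),
                  c(rep(0L, 5), 1L, rep(0L, 5)),
                  c(rep(1L, 5), 0L, rep(1L, 5)),
                  c(rep(1L, 5), 1L, rep(1L, 5)))
  cp <- ehh(paired, pos, core)
  expect_true(all(cp$ehh[cp$side != 0] == 1 / 3))

  # all haplotypes distinct at the first flanking SNP
  distinct <- matrix(0L, nrow = 3, ncol = 2)
  distinct[1, ] <- c(0L, 1L)  # left flank differs
  distinct[3, ] <- c(1L, 0L)  # right flank differs
  cd <- ehh(distinct, seq(100, 300, by = 100), 2L)
  expect_equal(cd$ehh[cd$side == -1], 0)
  expect_equal(cd$ehh[cd$side == 1], 0)
})

test_that("EHH equals brute-force pair counting and is non-increasing", {
  withr::local_seed(15)
  for (rep in 1:25) {
    n_snp <- sample(10:40, 1)
    n_hap <- sample(c(4L, 6L, 8L), 1)
    haps <- matrix(rbinom(n_snp * n_hap, 1, runif(1, 0.2, 0.8)), ncol = n_hap)
    pos <- sort(sample.int(1e5, n_snp))
    core <- sample(n_snp, 1)
    curve <- ehh(haps, pos, core)
    for (side in c(-1, 1)) {
      sub <- curve[curve$side == side, ]
      if (nrow(sub) == 0) next
      ord <- order(abs(sub$pos - pos[core]))
      vals <- sub$ehh[ord]
      expect_true(all(diff(vals) <= 1e-12))
      x_idx <- match(sub$pos, pos)
      for (k in seq_along(x_idx)) {
        expect_equal(sub$ehh[k], brute_ehh_at(haps, core, x_idx[k]))
      }
    }
  }
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  withr::local_seed(16)
  haps <- matrix(rbinom(30 * 8, 1, 0.5), ncol = 8)
  pos <- sort(sample.int(1e5, 30))
  expect_equal(xpehh(haps, haps, pos), rep(0, 30))
  hb <- matrix(rbinom(30 * 8, 1, 0.5), ncol = 8)
  ab <- xpehh(haps, hb, pos)
  ba <- xpehh(hb, haps, pos)
  ok <- !is.na(ab)
  expect_equal(ab[ok], -ba[ok])
})

test_that("standardized scores have mean 0, sd 1 and inclusive outliers", {
  withr::local_seed(17)
  x <- rnorm(1000)
  st <- standardize_scores(x)
  expect_lt(abs(mean(st$z)), 1e-12)
  expect_lt(abs(sd(st$z) - 1), 1e-12)
  expect_true(all(st$z[st$outlier] >= st$threshold))
  thr_hits <- which(st$z == st$threshold)
  expect_true(all(st$outlier[thr_hits]))
})

test_that("pi_ratio_windows excludes sparse windows and flags Inf", {
  sim <- simulate_dataset(sim_config(seed = 45, genome = c(chr1 = 1e6),
                                     mutation_density = 2, annotate = FALSE,
                                     missing_rate = 0))
  pw <- pi_ratio_windows(sim$geno, sim$table, sim$popmap,
                         "backgroundA", "target", sim$genome)
  expect_true(all(!pw$retained[pw$n_variable_sites < 20]))
  expect_true(all(pw$n_variable_sites[pw$retained] >= 20))
  # equal diversity -> value 0
  tab <- make_table(100, by = 400)
  g <- cbind(a1 = rep(1L, 100), a2 = rep(1L, 100),
             b1 = rep(1L, 100), b2 = rep(1L, 100))
  geno <- quiet(genotype_matrix(g))
  pm <- make_popmap(colnames(g), c("A", "A", "B", "B"))
  pw0 <- pi_ratio_windows(geno, tab, pm, "A", "B", c(chr1 = 40000))
  expect_equal(pw0$value[pw0$retained], rep(0, sum(pw0$retained)))
  # pi_B = 0 in a variable window -> Inf, in the outlier set
  gB <- g; gB[, c("b1", "b2")] <- 0L
  pwi <- pi_ratio_windows(quiet(genotype_matrix(gB)), tab, pm, "A", "B",
                          c(chr1 = 40000))
  expect_true(all(is.infinite(pwi$value[pwi$retained])))
  expect_true(all(pwi$outlier[pwi$retained]))
})

test_that("kaks_ng86 reproduces the hand-counted worked example", {
  res <- kaks_ng86("ATGGCTTTTGGG", "ATGGCATTTGGG")
  expect_equal(res$S, 7 / 3, tolerance = 1e-12)
  expect_equal(res$N, 29 / 3, tolerance = 1e-12)
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$Ka, 0)
  expect_equal(res$Ks, -0.75 * log(1 - 4 * (3 / 7) / 3), tolerance = 1e-12)
  expect_equal(res$Ks, 0.6355, tolerance = 1e-4)
  expect_equal(res$ratio, 0)
})

test_that("kaks_ng86 edge contracts: identical, Ks = 0, stops, saturation", {
  same <- quiet(kaks_ng86("ATGGCTTTT", "ATGGCTTTT"))
  expect_equal(c(same$Ka, same$Ks), c(0, 0))
  expect_true(is.na(same$ratio))
  # one non-synonymous difference, zero synonymous
  expect_warning(ns <- kaks_ng86("ATGGCT", "ATGACT"), "Ks = 0")
  expect_gt(ns$Ka, 0)
  expect_true(is.na(ns$ratio))
  expect_error(kaks_ng86("TAAGCT", "TAAGCA"), "stop")
  expect_error(kaks_ng86("ATGGCT", "ATG"), ".")
})

test_that("kaks_ng86 is symmetric on random codon pairs", {
  withr::local_seed(18)
  codons <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], NULL)
  for (rep in 1:30) {
    a <- paste(sample(codons, 6, replace = TRUE), collapse = "")
    b <- paste(sample(codons, 6, replace = TRUE), collapse = "")
    ra <- quiet(kaks_ng86(a, b))
    rb <- quiet(kaks_ng86(b, a))
    expect_equal(ra[c("Ka", "Ks", "S", "N", "Sd", "Nd")],
                 rb[c("Ka", "Ks", "S", "N", "Sd", "Nd")])
  }
})

test_that("consensus requires at least two methods", {
  model <- gene_model(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1000, 2000),
                                                    width = 500),
                           gene_id = c("G1", "G2", "G3")),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1), gene_id = "G1"))
  calls <- consensus_sweep(pi_ratio_genes = c("G1", "G2"),
                           xpehh_genes = c("G1"),
                           kaks_genes = c("G3"), model)
  expect_equal(calls$consensus, c(TRUE, FALSE, FALSE))
  all3 <- consensus_sweep("G1", "G1", "G1", model)
  expect_true(all3$consensus[1])
})

test_that("private and fixed screens apply the two quoted criteria", {
  n <- 8
  ann <- data.frame(site_id = paste0("chr1:", seq(1000, by = 1000,
                                                  length.out = n)),
                    gene_id = paste0("G", 1:n),
                    effect_term = c(rep("missense_variant", 6),
                                    "synonymous_variant", "stop_gained"),
                    impact = c(rep("MODERATE", 6), "LOW", "HIGH"),
                    coding_class = c(rep("non_synonymous", 6), "synonymous",
                                     "non_synonymous"))
  tab <- make_table(n, ann = ann)
  t1 <- c(2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L)
  t2 <- c(2L, 2L, 2L, 2L, NA, 2L, 2L, 2L)
  # backgrounds: site 1 absent; site 2 freq 2/8; site 4 freq 6/8;
  # site 6 freq 10.53%-ish (1/8); site 7 synonymous; site 8 stop private
  b <- cbind(b1 = c(0L, 1L, 0L, 2L, 0L, 0L, 2L, 0L),
             b2 = c(0L, 1L, 0L, 2L, 0L, 1L, 2L, 0L),
             b3 = c(0L, 0L, 0L, 1L, 0L, 0L, 2L, 0L),
             b4 = c(0L, 0L, 0L, 1L, 0L, 0L, 2L, 0L))
  g <- cbind(t1 = t1, t2 = t2, b, out = rep(0L, n))
  geno <- quiet(genotype_matrix(g))
  pm <- make_popmap(colnames(g), c("target", "target", "bgA", "bgA", "bgB",
                                   "bgB", "outgroup"))
  priv <- private_nonsyn_screen(tab, geno, pm, "target", mode = "private")
  expect_setequal(priv$pos, c(1000, 8000))  # hom in all targets, bg freq 0
  expect_true(all(priv$tier == "private"))
  expect_true(priv$stop_gained[priv$pos == 8000])

  fixed <- private_nonsyn_screen(tab, geno, pm, "target", mode = "fixed",
                                 max_background_freq = 0.2895)
  expect_setequal(fixed$pos, c(1000, 2000, 6000, 8000))
  expect_equal(sort(unique(fixed$tier)),
               c("fixed_with_background", "private"))

  sg <- stop_gained_screen(tab, geno, pm, "target")
  expect_equal(sg$pos, 8000)
  sg_none <- stop_gained_screen(tab, geno, pm, "target",
                                candidate_genes = c("G1", "G2"))
  expect_equal(nrow(sg_none), 0L)
  sg_in <- stop_gained_screen(tab, geno, pm, "target",
                              candidate_genes = "G8")
  expect_equal(sg_in$gene_id, "G8")
})

test_that("the fixed-tier background-frequency ceiling is inclusive", {
  n <- 2
  ann <- data.frame(site_id = paste0("chr1:", c(1000, 2000)),
                    gene_id = c("G1", "G2"),
                    effect_term = "missense_variant", impact = "MODERATE",
                    coding_class = "non_synonymous")
  tab <- make_table(n, ann = ann)
  # background freq exactly at the ceiling (2/8 = 0.25) and just above (3/8)
  g <- cbind(t1 = c(2L, 2L), t2 = c(2L, 2L),
             b1 = c(1L, 2L), b2 = c(1L, 1L),
             b3 = c(0L, 0L), b4 = c(0L, 0L), out = c(0L, 0L))
  geno <- quiet(genotype_matrix(g))
  pm <- make_popmap(colnames(g), c("target", "target", "bg", "bg", "bg", "bg",
                                   "outgroup"))
  hits <- private_nonsyn_screen(tab, geno, pm, "target", mode = "fixed",
                                max_background_freq = 0.25)
  expect_equal(hits$pos, 1000)       # 0.25 included, 0.375 excluded
  # and with the study's 28.95% ceiling, 11/38 = 28.947% passes
  expect_true(11 / 38 <= 0.2895)
  expect_false(12 / 38 <= 0.2895)
})

test_that("pseudo-phasing warns loudly and preserves genotypes", {
  sim <- simulate_dataset(sim_config(seed = 46, genome = c(chr1 = 2e5),
                                     missing_rate = 0))
  expect_warning(ph <- pseudo_phase(sim$geno, seed = 2), "pseudo-phasing")
  expect_equal(ph$h1 + ph$h2, unclass(sim$geno)[, ] + 0L, ignore_attr = TRUE)
})
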