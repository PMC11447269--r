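test_that("site_pi matches the all-pairs oracle exactly for n <= 10", {
  for (n in 2:10) {
    for (j in 0:n) {
      expect_identical(site_pi(n, j), brute_site_pi(n, j),
                       label = sprintf("n=%d j=%d", n, j))
    }
  }
  expect_equal(site_pi(2, 1), 1.0)
  expect_equal(site_pi(8, 0), 0.0)
  expect_equal(site_pi(8, 4), 32 / 56)
})

test_that("site_pi skips sites with fewer than two called alleles", {
  expect_message(out <- site_pi(c(1, 4), c(0, 2)), "skipped")
  expect_true(is.na(out[1]))
  expect_equal(out[2], brute_site_pi(4, 2))
})

test_that("windowed_pi divides by the fixed window size", {
  w <- windowed_pi("chr1", 25000, 0.5, c(chr1 = 1e5))
  expect_equal(nrow(w), 2L)
  expect_equal(w$value[1], 1e-5)       # 0.5 / 50000
  expect_equal(w$value[2], 0)          # empty window
  expect_equal(w$n_variable_sites, c(1L, 0L))
})

test_that("windowed_pi is translation invariant and conserves the total", {
  withr::local_seed(4)
  pos <- sort(sample.int(3e5, 400))
  pi_vals <- runif(400, 0, 1)
  w <- windowed_pi(rep("chr1", 400), pos, pi_vals, c(chr1 = 3e5))
  expect_equal(sum(w$value) * 50000, sum(pi_vals), tolerance = 1e-12)
  # two identical consecutive windows of sites -> identical values
  pos1 <- sort(sample.int(5e4, 60))
  piv <- runif(60)
  w2 <- windowed_pi(rep("chr1", 120), c(pos1, pos1 + 50000), rep(piv, 2),
                    c(chr1 = 1e5))
  expect_equal(w2$value[1], w2$value[2])
  expect_equal(w2$n_variable_sites[1], w2$n_variable_sites[2])
})

test_that("population pi recovers the generator's expected heterozygosity", {
  # planted frequencies: i.i.d. sites, so MC error is binomial-scale
  sim <- simulate_dataset(sim_config(seed = 77, genome = c(chr1 = 2e6),
                                     mutation_density = 2, missing_rate = 0,
                                     annotate = FALSE))
  ind <- sim$popmap$individual[sim$popmap$population == "backgroundA"]
  pv <- pop_site_pi(sim$geno, ind)
  g <- unclass(sim$geno)[, ind]
  p_hat <- rowSums(g) / (2 * length(ind))
  n <- 2 * length(ind)
  expected <- 2 * p_hat * (1 - p_hat) * n / (n - 1)
  expect_equal(mean(pv), mean(expected), tolerance = 1e-12)
})

test_that("heterozygosity_rate uses callable length and strata", {
  g <- matrix(0L, nrow = 500, ncol = 1, dimnames = list(NULL, "i1"))
  g[1:36] <- 1L
  geno <- genotype_matrix(g, "i1", callable_length = c(i1 = 100000))
  tab <- make_table(500)
  hr <- heterozygosity_rate("i1", geno, tab)
  expect_equal(hr$overall, 0.36)
  g2 <- g; g2[] <- 0L
  hr0 <- heterozygosity_rate("i1", genotype_matrix(g2, "i1",
                                                   callable_length = c(i1 = 1e5)),
                             tab)
  expect_equal(hr0$overall, 0)
  # upper edge: all het, callable = site count
  g3 <- matrix(1L, nrow = 500, ncol = 1, dimnames = list(NULL, "i1"))
  hr1 <- heterozygosity_rate("i1", genotype_matrix(g3, "i1",
                                                   callable_length = c(i1 = 500)),
                             tab)
  expect_equal(hr1$overall, 1000)
})

test_that("coding/non-coding stratification splits het counts", {
  tab <- make_table(100)  # pos 1000..100000
  g <- matrix(1L, nrow = 100, ncol = 1, dimnames = list(NULL, "i1"))
  geno <- genotype_matrix(g, "i1", callable_length = c(i1 = 100000))
  model <- gene_model(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000), gene_id = "G1"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000), gene_id = "G1"))
  hr <- heterozygosity_rate("i1", geno, tab, model, genome_length = 100000)
  expect_equal(hr$coding, 1000 * 50 / 50000)
  expect_equal(hr$noncoding, 1000 * 50 / 50000)
})

test_that("ns_s_ratio counts carried variants and flags 0 denominators", {
  n <- 50
  ann <- data.frame(site_id = site_ids <- paste0("chr1:", seq(1000, by = 1000,
                                                              length.out = n)),
                    gene_id = "G1",
                    effect_term = rep(c("missense_variant", "synonymous_variant"),
                                      c(30, 20)),
                    impact = rep(c("MODERATE", "LOW"), c(30, 20)),
                    coding_class = rep(c("non_synonymous", "synonymous"),
                                       c(30, 20)))
  tab <- make_table(n, ann = ann)
  g <- matrix(1L, nrow = n, ncol = 1, dimnames = list(NULL, "i1"))
  geno <- genotype_matrix(g, "i1", callable_length = c(i1 = n))
  expect_equal(ns_s_ratio("i1", geno, tab)$ratio, 1.5)

  g0 <- g; g0[1:30, 1] <- 0L  # no NS carried
  expect_equal(ns_s_ratio("i1", genotype_matrix(g0, "i1",
                                                callable_length = c(i1 = n)),
                          tab)$ratio, 0)
  gS <- g; gS[31:50, 1] <- 0L  # no S carried
  expect_warning(
    r <- ns_s_ratio("i1", genotype_matrix(gS, "i1", callable_length = c(i1 = n)),
                    tab)$ratio, "undefined")
  expect_true(is.na(r))
})

test_that("king_kinship: duplicates, independents, bins, symmetry", {
  withr::local_seed(11)
  g <- matrix(sample(0:2, 2000, replace = TRUE, prob = c(.25, .5, .25)),
              ncol = 2)
  g[, 2] <- g[, 1]
  colnames(g) <- c("a", "b")
  geno <- quiet(genotype_matrix(g))
  k <- king_kinship("a", "b", geno)
  expect_equal(k$phi, 0.5)
  expect_equal(k$degree_class, "duplicate/MZ")

  # independent HWE individuals at p = 0.5
  g2 <- matrix(sample(0:2, 20000, replace = TRUE, prob = c(.25, .5, .25)),
               ncol = 2, dimnames = list(NULL, c("a", "b")))
  k2 <- king_kinship("a", "b", quiet(genotype_matrix(g2)))
  expect_lt(abs(k2$phi), 0.05)
  expect_equal(k2$degree_class, "unrelated/>3rd-degree")

  # symmetry
  g3 <- matrix(sample(c(0:2, NA), 400, replace = TRUE),
               ncol = 2, dimnames = list(NULL, c("a", "b")))
  geno3 <- quiet(genotype_matrix(g3))
  expect_equal(quiet(king_kinship("a", "b", geno3))$phi,
               quiet(king_kinship("b", "a", geno3))$phi)
})

test_that("kinship degree bins are applied exactly as quoted", {
  classify <- karstpop:::phi_degree_class
  expect_equal(classify(0.40), "duplicate/MZ")
  expect_equal(classify(0.354), "1st-degree")
  expect_equal(classify(0.2), "1st-degree")
  expect_equal(classify(0.177), "1st-degree")
  expect_equal(classify(0.1), "2nd-degree")
  expect_equal(classify(0.0884), "2nd-degree")
  expect_equal(classify(0.05), "3rd-degree")
  expect_equal(classify(0.0442), "unrelated/>3rd-degree")
})
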