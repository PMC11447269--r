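load_fixture <- function() {
  # 6 sites: GERP {4.5, 5.0, 6.0, 3.9, 7.0, absent}; popmap with outgroup
  tab <- variant_table(chrom = rep("chr1", 6),
                       pos = c(100, 200, 300, 400, 500, 600),
                       ref = rep("A", 6), alt = rep("G", 6),
                       gerp = c(4.5, 5.0, 6.0, 3.9, 7.0, NA))
  g <- rbind(c(1L, 0L, 0L),   # het deleterious (derived = alt)
             c(1L, 0L, 0L),   # het deleterious
             c(2L, 0L, 0L),   # hom derived deleterious
             c(1L, 0L, 0L),   # GERP 3.9 -> never deleterious
             c(2L, 2L, 2L),   # outgroup hom alt -> derived = ref; i1 ancestral
             c(1L, 0L, 0L))   # no GERP record
  colnames(g) <- c("i1", "i2", "out")
  # pad with neutral called sites so n_called = 100 for i1
  pad <- matrix(0L, nrow = 94, ncol = 3,
                dimnames = list(NULL, colnames(g)))
  tab2 <- variant_table(chrom = rep("chr1", 94),
                        pos = seq(1000, by = 10, length.out = 94),
                        ref = "A", alt = "G", gerp = 0)
  full_tab <- variant_table(c(tab$chrom, tab2$chrom), c(tab$pos, tab2$pos),
                            c(tab$ref, tab2$ref), c(tab$alt, tab2$alt),
                            gerp = c(tab$gerp, tab2$gerp))
  geno <- genotype_matrix(rbind(g, pad), colnames(g),
                          callable_length = c(i1 = 100, i2 = 100, out = 100))
  popmap <- make_popmap(c("i1", "i2", "out"),
                        c("target", "backgroundA", "outgroup"))
  list(tab = full_tab, geno = geno, popmap = popmap)
}

test_that("polarize_derived uses outgroup homozygotes and excludes the rest", {
  tab <- make_table(3)
  g <- cbind(i1 = c(1L, 1L, 1L), out = c(0L, 2L, 1L))
  geno <- genotype_matrix(g, c("i1", "out"),
                          callable_length = c(i1 = 3, out = 3))
  popmap <- make_popmap(c("i1", "out"), c("target", "outgroup"))
  out <- quiet(polarize_derived(tab, geno, popmap))
  expect_equal(out$derived, c("alt", "ref", NA))
  expect_equal(out$ancestral, c("A", "G", NA))
})

test_that("genetic_load reproduces the worked example", {
  fx <- load_fixture()
  tab <- quiet(polarize_derived(fx$tab, fx$geno, fx$popmap))
  gl <- genetic_load("i1", fx$geno, tab)
  expect_equal(gl$n_called, 100L)
  expect_equal(gl$masked, 0.095)     # GERP {4.5, 5.0} het / 100 called
  expect_equal(gl$realized, 0.060)   # GERP 6.0 hom derived / 100 called
  # raising the threshold drops the het contributions first
  gl55 <- genetic_load("i1", fx$geno, tab, gerp_threshold = 5.5)
  expect_equal(gl55$masked, 0)
  expect_equal(gl55$realized, 0.060)
})

test_that("sites below the GERP threshold contribute to neither load", {
  fx <- load_fixture()
  tab <- quiet(polarize_derived(fx$tab, fx$geno, fx$popmap))
  # raise threshold to 8: nothing deleterious
  gl <- genetic_load("i1", fx$geno, tab, gerp_threshold = 8)
  expect_equal(gl$masked, 0)
  expect_equal(gl$realized, 0)
})

test_that("load accounting is disjoint and threshold-monotone", {
  sim <- simulate_dataset(sim_config(seed = 61, genome = c(chr1 = 5e5),
                                     f_roh = c(target = 0.4, backgroundA = 0,
                                               backgroundB = 0)))
  flt <- quiet(shared_site_filter(sim$table, sim$geno, sim$popmap,
                                  c("target", "backgroundA", "backgroundB")))
  tab <- quiet(polarize_derived(flt$table, flt$geno, sim$popmap))
  g <- unclass(flt$geno)[, "target_1"]
  del <- !is.na(tab$gerp) & tab$gerp >= 4 & !is.na(tab$derived)
  het <- del & !is.na(g) & g == 1L
  hom <- del & !is.na(g) &
    ((tab$derived == "alt" & g == 2L) | (tab$derived == "ref" & g == 0L))
  expect_equal(sum(het & hom), 0L)  # site-by-site disjoint
  loads <- sapply(c(2, 4, 6), function(thr)
    unlist(genetic_load("target_1", flt$geno, tab, gerp_threshold = thr)
           [c("masked", "realized")]))
  expect_true(all(diff(loads["masked", ]) <= 0))
  expect_true(all(diff(loads["realized", ]) <= 0))
})

test_that("shared_site_filter removes only cross-species monomorphic homozygotes", {
  tab <- make_table(3)
  g <- cbind(a1 = c(2L, 1L, 0L), a2 = c(2L, 2L, 0L),
             b1 = c(2L, 2L, 0L), c1 = c(2L, 2L, 2L), out = c(0L, 0L, 0L))
  geno <- quiet(genotype_matrix(g))
  popmap <- make_popmap(colnames(g),
                        c("target", "target", "backgroundA", "backgroundB",
                          "outgroup"))
  out <- quiet(shared_site_filter(tab, geno, popmap,
                                  c("target", "backgroundA", "backgroundB")))
  # site 1: all hom-alt in all three species -> removed
  # site 2: polymorphic in target -> retained
  # site 3: hom-ref in target+backgroundA, hom-alt in backgroundB -> retained
  expect_equal(out$table$pos, c(2000, 3000))
})

test_that("effect_category_proportions divides carrier counts by called sites", {
  n <- 1000
  ann <- data.frame(site_id = paste0("chr1:", seq(1000, by = 1000,
                                                  length.out = n)),
                    gene_id = "G1",
                    effect_term = c(rep("stop_gained", 2),
                                    rep("missense_variant", 8),
                                    rep("synonymous_variant", 90),
                                    rep("intergenic_variant", 900)),
                    impact = c(rep("HIGH", 2), rep("MODERATE", 8),
                               rep("LOW", 90), rep("MODIFIER", 900)),
                    coding_class = c(rep("non_synonymous", 10),
                                     rep("synonymous", 90),
                                     rep("other", 900)))
  tab <- make_table(n, ann = ann)
  g <- matrix(0L, nrow = n, ncol = 1, dimnames = list(NULL, "i1"))
  g[1:2, 1] <- 1L   # carries both HIGH sites het
  geno <- genotype_matrix(g, "i1", callable_length = c(i1 = n))
  p_all <- effect_category_proportions("i1", geno, tab, mode = "all")
  expect_equal(unname(p_all["HIGH"]), 0.002)
  p_hom <- effect_category_proportions("i1", geno, tab,
                                       mode = "homozygous_only")
  expect_equal(unname(p_hom["HIGH"]), 0)
  # no alt alleles at all -> all zero
  g0 <- matrix(0L, nrow = n, ncol = 1, dimnames = list(NULL, "i1"))
  p0 <- effect_category_proportions("i1",
                                    genotype_matrix(g0, "i1",
                                                    callable_length = c(i1 = n)),
                                    tab)
  expect_true(all(p0 == 0))
})

test_that("homozygous-only proportions never exceed all-genotype ones", {
  sim <- simulate_dataset(sim_config(seed = 62, genome = c(chr1 = 5e5)))
  for (ind in c("target_1", "backgroundA_3")) {
    pa <- effect_category_proportions(ind, sim$geno, sim$table, "all")
    ph <- effect_category_proportions(ind, sim$geno, sim$table,
                                      "homozygous_only")
    expect_true(all(ph <= pa))
  }
})

test_that("one_way_anova matches stats::oneway.test and hand computation", {
  # hand-computed oracle: {1,2} vs {5,6}: SSB = 16, SSW = 1, F = 32
  res <- one_way_anova(list(a = c(1, 2), b = c(5, 6)))
  expect_equal(res$F, (16 / 1) / (1 / 2))
  ref <- stats::oneway.test(v ~ g,
                            data.frame(v = c(1, 2, 5, 6),
                                       g = c("a", "a", "b", "b")),
                            var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  withr::local_seed(3)
  groups <- list(a = rnorm(5), b = rnorm(7, 1), c = rnorm(6, 2))
  res2 <- one_way_anova(groups)
  ref2 <- stats::oneway.test(v ~ g,
                             data.frame(v = unlist(groups),
                                        g = rep(names(groups),
                                                lengths(groups))),
                             var.equal = TRUE)
  expect_equal(res2$F, unname(ref2$statistic))
  expect_equal(res2$p, ref2$p.value)
})

test_that("one_way_anova edge cases: equal means and degenerate variance", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_warning(deg <- one_way_anova(list(a = c(1, 1), b = c(2, 2))),
                 "degenerate")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})
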