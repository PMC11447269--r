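# GERP-based masked/realized genetic load, effect-category genotype
# proportions and one-way ANOVA comparisons across populations.

#' Polarize sites to derived alleles using outgroup genotypes
#'
#' The ancestral allele is the one carried homozygously by every called
#' outgroup individual; the derived allele is the other one. Sites where
#' the outgroup is heterozygous, entirely missing or polymorphic are
#' excluded (derived = `NA`); exclusions are counted and reported.
#'
#' @param table a `variant_table`.
#' @param geno matching `genotype_matrix`.
#' @param popmap popmap with an `outgroup` role.
#' @return the table with columns `derived` ("ref"/"alt"/`NA`) and
#'   `ancestral` refreshed from the outgroup.
#' @export
polarize_derived <- function(table, geno, popmap) {
  out_ind <- popmap$individual[popmap$role == "outgroup"]
  stopifnot(length(out_ind) >= 1L)
  g <- unclass(geno)[, out_ind, drop = FALSE]
  all_ref <- rowSums(g == 0L, na.rm = TRUE) > 0 &
    rowSums(g != 0L, na.rm = TRUE) == 0
  all_alt <- rowSums(g == 2L, na.rm = TRUE) > 0 &
    rowSums(g != 2L, na.rm = TRUE) == 0
  derived <- rep(NA_character_, nrow(table))
  derived[all_ref] <- "alt"
  derived[all_alt] <- "ref"
  message(sum(is.na(derived)), " site(s) excluded from polarization ",
          "(outgroup heterozygous, missing or polymorphic)")
  tab <- copy(table)
  tab[, derived := derived]
  tab[, ancestral := ifelse(derived == "alt", ref,
                            ifelse(derived == "ref", alt, NA_character_))]
  setattr(tab, "class", class(table))
  setattr(tab, "ann", annotations(table))
  tab
}

#' Remove sites monomorphic across a set of species
#'
#' Drops sites where every called individual of every listed population is
#' homozygous for the same allele (the "identical positions shared by all
#' species" rule applied before load estimation).
#'
#' @param table a `variant_table`.
#' @param geno matching `genotype_matrix`.
#' @param popmap popmap.
#' @param species_set population labels to test across.
#' @return list with filtered `table` and `geno`.
#' @export
shared_site_filter <- function(table, geno, popmap, species_set) {
  stopifnot(all(species_set %in% popmap$population))
  ind <- popmap$individual[popmap$population %in% species_set]
  g <- unclass(geno)[, ind, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  all_ref <- rowSums(g == 0L, na.rm = TRUE) == n_called & n_called > 0
  all_alt <- rowSums(g == 2L, na.rm = TRUE) == n_called & n_called > 0
  keep <- !(all_ref | all_alt)
  message(sprintf("shared_site_filter: removed %d monomorphic shared site(s)",
                  sum(!keep)))
  out_g <- unclass(geno)[keep, , drop = FALSE]
  list(table = vt_subset(table, keep),
       geno = genotype_matrix(out_g, colnames(geno), callable_length(geno)))
}

#' Masked and realized genetic load for one individual
#'
#' Masked load: sum of GERP scores of deleterious (GERP >= threshold)
#' derived alleles carried heterozygously, divided by the individual's
#' called genotypes. Realized load: same sum for genotypes homozygous for
#' the deleterious derived allele. Both denominators are the count of
#' non-missing genotypes over all sites in `table` (`denominator_mode =
#' "identical"`); `"deleterious_only"` restricts the denominator to
#' polarizable deleterious sites.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix`.
#' @param table matching, polarized `variant_table` (see
#'   [polarize_derived()]).
#' @param gerp_threshold deleteriousness threshold (default 4).
#' @param denominator_mode `"identical"` (default) or `"deleterious_only"`.
#' @return list: `masked`, `realized`, `n_called`.
#' @export
genetic_load <- function(individual, geno, table, gerp_threshold = 4,
                         denominator_mode = c("identical", "deleterious_only")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot("derived" %in% names(table))
  g <- unclass(geno)[, individual]
  called <- !is.na(g)
  del <- !is.na(table$gerp) & table$gerp >= gerp_threshold &
    !is.na(table$derived)
  het <- called & del & g == 1L
  hom_der <- called & del &
    ((table$derived == "alt" & g == 2L) | (table$derived == "ref" & g == 0L))
  n_called <- if (denominator_mode == "identical") sum(called)
  else sum(called & del)
  if (n_called == 0L) {
    warning("genetic_load undefined: no called genotypes")
    return(list(masked = NA_real_, realized = NA_real_, n_called = 0L))
  }
  list(masked = sum(table$gerp[het]) / n_called,
       realized = sum(table$gerp[hom_der]) / n_called,
       n_called = n_called)
}

#' Effect-category genotype proportions for one individual
#'
#' For each impact category (HIGH, MODERATE, LOW, MODIFIER): the number of
#' sites where the individual carries the annotated (alternate) allele -
#' het or hom-alt in mode `all`, hom-alt only in mode `homozygous_only` -
#' divided by the individual's called genotypes. Sites are assigned to the
#' category of their most severe annotation.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix`.
#' @param table matching `variant_table` with annotations.
#' @param mode `"all"` or `"homozygous_only"`.
#' @return named numeric vector over the four categories.
#' @export
effect_category_proportions <- function(individual, geno, table,
                                        mode = c("all", "homozygous_only")) {
  mode <- match.arg(mode)
  g <- unclass(geno)[, individual]
  called <- !is.na(g)
  carries <- if (mode == "all") called & g >= 1L else called & g == 2L
  n_called <- sum(called)
  out <- setNames(numeric(length(IMPACT_LEVELS)), IMPACT_LEVELS)
  for (lv in IMPACT_LEVELS) {
    out[lv] <- sum(carries & !is.na(table$impact) & table$impact == lv) /
      n_called
  }
  out
}

#' Classic one-way ANOVA with pairwise contrasts
#'
#' Between/within mean-square F with its F-distribution p value, plus
#' unadjusted pairwise Welch t contrasts (optionally Benjamini-Hochberg
#' adjusted). Zero within-group variance everywhere makes the p value
#' degenerate; it is flagged.
#'
#' @param groups named list: population -> numeric vector of per-individual
#'   values (>= 2 groups of >= 2 values).
#' @param adjust `"none"` (default) or `"BH"` for the pairwise contrasts.
#' @return list: `F`, `p`, `df`, `pairwise` (data.table), `degenerate`.
#' @export
one_way_anova <- function(groups, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  x <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), lengths(groups)))
  k <- nlevels(f); n <- length(x)
  stopifnot(n > k)
  gm <- mean(x)
  means <- tapply(x, f, mean)
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum((x - means[f])^2)
  dfb <- k - 1L; dfw <- n - k
  degenerate <- ssw == 0
  Fstat <- if (degenerate && ssb == 0) 0 else (ssb / dfb) / (ssw / dfw)
  p <- if (degenerate) {
    warning("one_way_anova: zero within-group variance; p value degenerate")
    if (ssb == 0) 1 else 0
  } else pf(Fstat, dfb, dfw, lower.tail = FALSE)
  pairs <- utils::combn(names(groups), 2L)
  pw <- rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
    a <- groups[[pairs[1, i]]]; b <- groups[[pairs[2, i]]]
    pv <- if (sd(a) == 0 && sd(b) == 0) ifelse(mean(a) == mean(b), 1, 0)
    else stats::t.test(a, b)$p.value
    data.table(group1 = pairs[1, i], group2 = pairs[2, i],
               diff = mean(a) - mean(b), p = pv)
  }))
  if (adjust == "BH") pw[, p := stats::p.adjust(p, method = "BH")]
  list(F = Fstat, p = p, df = c(dfb, dfw), pairwise = pw[],
       degenerate = degenerate)
}
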