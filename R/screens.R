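# Private / fixed-tier non-synonymous variant screens and the premature
# stop codon screen.

screen_base <- function(table, geno, popmap, target_population) {
  t_ind <- popmap$individual[popmap$population == target_population]
  stopifnot(length(t_ind) >= 1L)
  b_ind <- popmap$individual[popmap$role != "outgroup" &
                               !popmap$individual %in% t_ind]
  g <- unclass(geno)
  gt <- g[, t_ind, drop = FALSE]
  eligible <- rowSums(is.na(gt)) == 0L
  all_hom_alt <- eligible & rowSums(gt == 2L) == length(t_ind)
  gb <- g[, b_ind, drop = FALSE]
  bg_freq <- rowSums(gb, na.rm = TRUE) / (2 * rowSums(!is.na(gb)))
  bg_freq[is.nan(bg_freq)] <- 0
  list(all_hom_alt = all_hom_alt, bg_freq = bg_freq)
}

#' Screen for non-synonymous variants private to (or fixed in) a population
#'
#' A hit satisfies: (1) the site's most severe annotation has
#' `coding_class == "non_synonymous"`; (2) every target individual is
#' called and homozygous for the alternate allele; and (3) the
#' background (non-outgroup, non-target) alternate-allele frequency is 0
#' in mode `private`, or at most `max_background_freq` (inclusive) in mode
#' `fixed`.
#'
#' @param table a `variant_table` with annotations.
#' @param geno matching `genotype_matrix`.
#' @param popmap popmap.
#' @param target_population population label.
#' @param mode `"private"` or `"fixed"`.
#' @param max_background_freq fixed-tier frequency ceiling (default
#'   0.2895, inclusive).
#' @return `data.table` of hits: gene_id, chrom, pos, ref, alt, tier,
#'   background_max_freq, stop_gained.
#' @export
private_nonsyn_screen <- function(table, geno, popmap, target_population,
                                  mode = c("private", "fixed"),
                                  max_background_freq = 0.2895) {
  mode <- match.arg(mode)
  sb <- screen_base(table, geno, popmap, target_population)
  ns <- !is.na(table$coding_class) & table$coding_class == "non_synonymous"
  hit <- ns & sb$all_hom_alt &
    (if (mode == "private") sb$bg_freq == 0
     else sb$bg_freq <= max_background_freq)
  out <- data.table(gene_id = table$gene_id[hit], chrom = table$chrom[hit],
                    pos = table$pos[hit], ref = table$ref[hit],
                    alt = table$alt[hit],
                    background_max_freq = sb$bg_freq[hit],
                    stop_gained = !is.na(table$effect_term[hit]) &
                      table$effect_term[hit] == "stop_gained")
  out[, tier := ifelse(background_max_freq == 0, "private",
                       "fixed_with_background")]
  out[]
}

#' Screen for premature stop codons homozygous in a population
#'
#' Hits are `stop_gained` variants homozygous (alternate) in every called
#' target individual, optionally restricted to a candidate gene list.
#'
#' @inheritParams private_nonsyn_screen
#' @param candidate_genes optional character vector of gene ids.
#' @return `data.table` of hits (same columns as
#'   [private_nonsyn_screen()]).
#' @export
stop_gained_screen <- function(table, geno, popmap, target_population,
                               candidate_genes = NULL) {
  sb <- screen_base(table, geno, popmap, target_population)
  sg <- !is.na(table$effect_term) & table$effect_term == "stop_gained"
  hit <- sg & sb$all_hom_alt
  if (!is.null(candidate_genes))
    hit <- hit & !is.na(table$gene_id) & table$gene_id %in% candidate_genes
  out <- data.table(gene_id = table$gene_id[hit], chrom = table$chrom[hit],
                    pos = table$pos[hit], ref = table$ref[hit],
                    alt = table$alt[hit],
                    background_max_freq = sb$bg_freq[hit],
                    stop_gained = TRUE)
  out[, tier := ifelse(background_max_freq == 0, "private",
                       "fixed_with_background")]
  out[]
}

#' Read a one-gene-per-line candidate list
#' @param path plain-text file, one gene id per line.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
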