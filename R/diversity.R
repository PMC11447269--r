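# Nucleotide diversity, heterozygosity, NS/S ratios and KING-style kinship.

#' Per-site nucleotide diversity
#'
#' Unbiased per-site pi for `j` alternate alleles among `n` called alleles:
#' `2 j (n - j) / (n (n - 1))`, the mean pairwise difference over all
#' haplotype pairs. Sites with fewer than two called alleles are skipped
#' (`NA`, with a message).
#'
#' @param n_called_alleles called allele count(s) at the site(s).
#' @param n_alt_alleles alternate allele count(s).
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(n_called_alleles, n_alt_alleles) {
  n <- as.numeric(n_called_alleles)
  j <- as.numeric(n_alt_alleles)
  stopifnot(all(j >= 0 & j <= n))
  out <- 2 * j * (n - j) / (n * (n - 1))
  skip <- n < 2
  if (any(skip)) {
    message(sum(skip), " site(s) with fewer than 2 called alleles skipped")
    out[skip] <- NA_real_
  }
  out
}

# Alt-allele and called-allele counts per site for a set of individuals.
allele_counts <- function(geno, individuals) {
  g <- unclass(geno)[, individuals, drop = FALSE]
  list(n = 2L * rowSums(!is.na(g)), j = rowSums(g, na.rm = TRUE))
}

#' Population per-site pi from a genotype matrix
#' @param geno a `genotype_matrix`.
#' @param individuals column names of the population's individuals.
#' @return numeric vector of per-site pi (`NA` where < 2 called alleles).
#' @export
pop_site_pi <- function(geno, individuals) {
  ac <- allele_counts(geno, individuals)
  suppressMessages(site_pi(ac$n, ac$j))
}

#' Nucleotide diversity in non-overlapping windows
#'
#' Tiles each chromosome with fixed windows and reports, per window, the
#' sum of per-site pi divided by the window size (per-bp pi; multiply by
#' 100 for a percentage). Empty windows report 0. The denominator is the
#' fixed window size, matching vcftools' `--window-pi` convention;
#' `denominator = "callable"` divides by callable bp in the window instead.
#'
#' @param chrom,pos site coordinates.
#' @param pi_values per-site pi, e.g. from [pop_site_pi()].
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp window size (default 50 kb).
#' @param denominator `"window"` (default) or `"callable"`.
#' @param callable_bp per-window callable bp when `denominator = "callable"`.
#' @return `data.table`: chrom, start, end (1-based inclusive),
#'   n_variable_sites, value.
#' @export
windowed_pi <- function(chrom, pos, pi_values, chrom_lengths,
                        window_bp = 50000L, denominator = c("window", "callable"),
                        callable_bp = NULL) {
  denominator <- match.arg(denominator)
  win <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    n_w <- ceiling(chrom_lengths[[cn]] / window_bp)
    data.table(chrom = cn,
               start = as.integer((seq_len(n_w) - 1L) * window_bp + 1L),
               end = as.integer(pmin(seq_len(n_w) * window_bp,
                                     chrom_lengths[[cn]])))
  }))
  dt <- data.table(chrom = chrom, pos = pos, pi = pi_values)
  dt <- dt[!is.na(pi)]
  dt[, wstart := as.integer(((pos - 1L) %/% window_bp) * window_bp + 1L)]
  agg <- dt[, .(n_variable_sites = sum(pi > 0), pi_sum = sum(pi)),
            by = .(chrom, wstart)]
  win[, `:=`(n_variable_sites = 0L, pi_sum = 0)]
  idx <- match(paste(agg$chrom, agg$wstart), paste(win$chrom, win$start))
  win[idx, `:=`(n_variable_sites = agg$n_variable_sites, pi_sum = agg$pi_sum)]
  denom <- if (denominator == "window") as.numeric(window_bp) else {
    stopifnot(length(callable_bp) == nrow(win))
    as.numeric(callable_bp)
  }
  win[, value := pi_sum / denom]
  win[, pi_sum := NULL]
  win[]
}

#' Heterozygosity per 1000 bp, overall and by coding stratum
#'
#' Counts heterozygous genotypes and divides by callable length (in kb).
#' With a gene model, sites are stratified into coding (CDS) and
#' non-coding; stratum callable lengths assume uniform callability and
#' split the individual's callable length proportionally to the CDS share
#' of the genome.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix` (with callable lengths).
#' @param table matching `variant_table`.
#' @param model optional `gene_model` for the coding/non-coding split.
#' @param genome_length total genome length (bp); defaults to the
#'   individual's callable length.
#' @return list: `overall`, and with a model `coding`, `noncoding`
#'   (heterozygous sites per 1000 bp; `NA` and a warning when a stratum
#'   has zero callable length).
#' @export
heterozygosity_rate <- function(individual, geno, table, model = NULL,
                                genome_length = NULL) {
  g <- unclass(geno)[, individual]
  cl <- callable_length(geno)[[individual]]
  stopifnot(cl > 0)
  het <- !is.na(g) & g == 1L
  out <- list(overall = 1000 * sum(het) / cl)
  if (!is.null(model)) {
    genome_length <- genome_length %||% cl
    sites <- GenomicRanges::GRanges(table$chrom,
                                    IRanges::IRanges(table$pos, width = 1L))
    in_cds <- IRanges::overlapsAny(sites, GenomicRanges::reduce(model$cds))
    cds_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(model$cds)))
    cl_coding <- cl * cds_bp / genome_length
    cl_noncoding <- cl - cl_coding
    out$coding <- if (cl_coding > 0) 1000 * sum(het & in_cds) / cl_coding else {
      warning("zero callable length in coding stratum"); NA_real_
    }
    out$noncoding <- if (cl_noncoding > 0)
      1000 * sum(het & !in_cds) / cl_noncoding else {
        warning("zero callable length in non-coding stratum"); NA_real_
      }
  }
  out
}

#' Ratio of non-synonymous to synonymous variants carried by an individual
#'
#' A variant is "carried" when the individual has at least one alternate
#' allele (het or hom-alt); sites are classified by the most severe
#' annotation's coding class. Undefined (`NA`, with a warning) when the
#' synonymous count is zero.
#'
#' @param individual individual id.
#' @param geno a `genotype_matrix`.
#' @param table matching `variant_table` with annotations.
#' @return list: `ns`, `s`, `ratio`.
#' @export
ns_s_ratio <- function(individual, geno, table) {
  g <- unclass(geno)[, individual]
  carries <- !is.na(g) & g >= 1L
  ns <- sum(carries & !is.na(table$coding_class) &
              table$coding_class == "non_synonymous")
  s <- sum(carries & !is.na(table$coding_class) &
             table$coding_class == "synonymous")
  ratio <- if (s == 0L) {
    warning("ns_s_ratio undefined: no synonymous variants carried")
    NA_real_
  } else ns / s
  list(ns = ns, s = s, ratio = ratio)
}

KINSHIP_BINS <- c(duplicate_mz = 0.354, first_degree = 0.177,
                  second_degree = 0.0884, third_degree = 0.0442)

#' KING kinship coefficient between two individuals
#'
#' Within-population (homogeneous) estimator over jointly called sites:
#' `phi = (N_het,het - 2 N_opposing_hom) / (N_het(i) + N_het(j))`.
#' Degree classes follow the standard KING bins: phi > 0.354
#' duplicate/monozygotic twin; (0.177, 0.354] 1st degree; (0.0884, 0.177]
#' 2nd degree; (0.0442, 0.0884] 3rd degree; otherwise unrelated/>3rd.
#'
#' @param individual_i,individual_j individual ids.
#' @param geno a `genotype_matrix`.
#' @return list: `phi`, `degree_class`, `n_sites`, `low_confidence` (TRUE
#'   when fewer than 100 jointly called sites).
#' @export
king_kinship <- function(individual_i, individual_j, geno) {
  g <- unclass(geno)
  gi <- g[, individual_i]; gj <- g[, individual_j]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- sum(gi == 1L) + sum(gj == 1L)
  phi <- if (denom == 0L) {
    warning("kinship undefined: no heterozygous genotypes in either individual")
    NA_real_
  } else (n_hh - 2 * n_opp) / denom
  list(phi = phi, degree_class = phi_degree_class(phi), n_sites = sum(ok),
       low_confidence = sum(ok) < 100L)
}

# bins are closed at their lower edge ([0.177, 0.354] is 1st degree);
# phi <= 0.0442 is unrelated
phi_degree_class <- function(phi) {
  if (is.na(phi)) NA_character_
  else if (phi > KINSHIP_BINS[["duplicate_mz"]]) "duplicate/MZ"
  else if (phi >= KINSHIP_BINS[["first_degree"]]) "1st-degree"
  else if (phi >= KINSHIP_BINS[["second_degree"]]) "2nd-degree"
  else if (phi > KINSHIP_BINS[["third_degree"]]) "3rd-degree"
  else "unrelated/>3rd-degree"
}
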