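# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction. Chosen over
# richer codon models because the consensus rule across selection methods
# dominates sweep calls; the estimator is deliberately simple and exact.

ng86_codon_sites <- function(codon) {
  # fraction of possible single-base changes per position that are
  # synonymous, summed over the codon; changes to stop codons count as
  # non-synonymous
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (!is.na(gc[mut]) && gc[[mut]] == aa && gc[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

ng86_path_diffs <- function(ca, cb) {
  # observed synonymous/non-synonymous differences between two codons,
  # averaged over all mutational paths that avoid stop codons (all paths
  # if every one passes through a stop)
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, non = 0))
  perms <- if (d == 1L) list(pos) else all_perms(pos)
  acc <- list()
  for (ord in perms) {
    cur <- ca; syn <- 0; non <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") through_stop <- TRUE
      if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    acc[[length(acc) + 1L]] <- c(syn = syn, non = non, stop = through_stop)
  }
  m <- do.call(rbind, acc)
  ok <- m[, "stop"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(syn = mean(m[ok, "syn"]), non = mean(m[ok, "non"]))
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

jc_correct <- function(p) {
  if (p == 0) return(0)
  if (p >= 0.75) {
    warning("proportion ", signif(p, 4), " saturated; corrected distance undefined")
    return(NA_real_)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Synonymous/non-synonymous site fractions per codon from the standard
#' codon table (averaged over the two sequences), observed differences
#' averaged over shortest mutational paths for multi-difference codons
#' (stop-crossing paths excluded when avoidable), and Jukes-Cantor
#' correction `d = -3/4 ln(1 - 4p/3)`. The ratio is undefined (`NA`) when
#' `Ks = 0`; proportions >= 0.75 are saturated and flagged.
#'
#' @param cds_a,cds_b codon sequences: equal length, multiple of 3, no
#'   internal stop codons.
#' @return list: `Ka`, `Ks`, `ratio`, `S`, `N`, `Sd`, `Nd`.
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  stopifnot(nchar(cds_a) == nchar(cds_b), nchar(cds_a) %% 3 == 0,
            nchar(cds_a) > 0)
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  gc <- Biostrings::GENETIC_CODE
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop("internal stop codon in input sequence")
  S <- (sum(vapply(ca, ng86_codon_sites, 0)) +
          sum(vapply(cb, ng86_codon_sites, 0))) / 2
  N <- nchar(cds_a) - S
  diffs <- mapply(function(a, b) ng86_path_diffs(a, b), ca, cb)
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["non", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) {
    if (!is.na(Ks) && Ks == 0) warning("Ka/Ks undefined: Ks = 0")
    NA_real_
  } else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd)
}
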