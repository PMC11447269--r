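`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's random state, seeds the generator, evaluates `expr`
#' and restores the previous state, so that seeded operations never leak
#' into (or depend on) global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Impact severity, most severe first. Used wherever one annotation must
# represent a site.
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

impact_rank <- function(impact) match(impact, IMPACT_LEVELS)

site_id <- function(chrom, pos) paste0(chrom, ":", pos)
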