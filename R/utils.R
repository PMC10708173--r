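# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without clobbering the
#' session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Geometric mean of strictly positive values.
geo_mean <- function(x) exp(mean(log(x)))

# Single string formatter for error messages.
msg <- function(...) paste0(...)

# Detect field separator from a file extension: tab for .tsv/.txt, comma else.
sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

# Condition group labels: the cross of the varying design factors of a
# sample table (variety, tissue, treatment).  Used by the ratio and ANOVA
# screening filters and by the panel validator.
condition_groups <- function(samples) {
  interaction(samples$variety, samples$tissue, samples$treatment,
              drop = TRUE, lex.order = TRUE)
}
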