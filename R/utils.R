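# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Normalize species names for comparison
#'
#' Species names are compared as exact normalized strings: leading/trailing
#' whitespace trimmed, internal runs of whitespace collapsed to one space,
#' and case folded to lower case. Taxonomic standardization (synonymy,
#' fuzzy matching) is assumed to have happened upstream.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_names(c("  Acacia  dealbata ", "ACACIA DEALBATA"))
normalize_names <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

#' Softplus activation
#'
#' `softplus(x) = log(1 + exp(x))`, evaluated in a numerically stable form.
#' Used as the output activation of the diversity networks so predictions
#' are strictly positive without an upper bound.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with softplus applied elementwise.
#' @export
#' @examples
#' softplus(0)  # log(2)
softplus <- function(x) {
  # log(1+exp(x)) = max(x,0) + log1p(exp(-|x|))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_divnn <- function(...) stop(sprintf(...), call. = FALSE)
warn_divnn <- function(...) warning(sprintf(...), call. = FALSE)
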