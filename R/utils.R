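# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the random number generator seeded to `seed` and restores
#' the caller's RNG state afterwards, so library functions never perturb user
#' random streams.
#'
#' @param seed Integer seed (kept below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' Root-mean-square error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot taken about the mean of `observed`.
#' Can be negative when predictions are worse than the constant mean.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Unitless R^2.
#' @export
rsq <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R^2 undefined: observed values are constant", call. = FALSE)
  1 - sum((predicted - observed)^2) / ss_tot
}

# sprintf-style stop()/warning() without call noise
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Stable short hash of an R object (used for deterministic tie-breaks).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  # polynomial rolling hash over the deparsed text; stable across sessions
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  h
}
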