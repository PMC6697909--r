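# Internal helpers shared across modules.

ct_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their `(spec, seed)` arguments and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Centered moving average with edge shrinkage; w is an odd window in samples.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Round half away from zero to `digits` decimals (printing convention for
# percentage cells; R's round() is half-to-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
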