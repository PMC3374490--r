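# Internal numerical helpers and unit conversions.

# 1 mmHg in Pa (conventional value).
MMHG_PA <- 133.322

mmHg_to_Pa <- function(p) p * MMHG_PA

um_to_mm <- function(x) x / 1000
mm_to_um <- function(x) x * 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate a polynomial with coefficients in increasing powers.
polyval <- function(coef, x) {
  y <- rep(coef[length(coef)], length(x))
  for (j in rev(seq_len(length(coef) - 1L))) y <- y * x + coef[j]
  y
}

# Coefficients of the derivative polynomial (increasing powers).
polyder <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

row_norm <- function(m) sqrt(rowSums(m^2))

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when comparing percent metrics against integers reported at
#' coarser precision (base R's [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
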