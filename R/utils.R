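## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_morph <- function(code, msg) {
  cond <- structure(
    class = c(code, "morphaline_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warn_morph <- function(code, msg) {
  cond <- structure(
    class = c(code, "morphaline_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

## Wrap index into 1..n (x2 periodicity is always handled by index wrapping).
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

## Linear interpolation that tolerates unsorted query points and clamps ends.
interp_clamped <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

## Monotone non-decreasing re-fit (pool-adjacent-violators).
fit_monotone <- function(x, y) {
  o <- order(x)
  yy <- stats::isoreg(x[o], y[o])$yf
  out <- numeric(length(y))
  out[o] <- yy
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
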