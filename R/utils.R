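# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed.
# Keeps results within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

# stop() with a class so callers/tests can distinguish contract violations.
abort_input <- function(msg, class = "adpkdval_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort_input(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Piecewise-linear quantile sampler through (min, q1, median, q3, max).
# Hits the published median and IQR exactly by construction.
sample_piecewise_quantiles <- function(n, knots) {
  stopifnot(length(knots) == 5L, !is.unsorted(knots))
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  u <- runif(n)
  approx(probs, knots, xout = u, rule = 2)$y
}
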