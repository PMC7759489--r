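# Internal helpers shared across modules.

# Fold a master seed and a sequence of indices into a new seed for an
# independent, reproducible substream.  Values stay strictly below 2^31 - 1
# so they are always valid arguments to set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) s <- (s * 69069 + as.double(k) + 12345) %% 2147483629
  as.integer(s)
}

check_positive <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be a positive finite number", name), call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be a nonnegative finite number", name), call. = FALSE)
  invisible(x)
}

# Probability clamp used inside Bernoulli likelihoods so that separated data
# give a finite (if extreme) objective rather than -Inf.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Numerically stable log(1 + exp(x))
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
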