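# Small numerical helpers shared across modules.

# Deterministic derivation of substream seeds from one master seed; kept
# below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 16807) %% 2147483647)
}

# One draw from a normal truncated to (lo, hi); inverse-CDF with a guard for
# intervals far in the tail, where the quantile inversion degenerates.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (!(hi > lo)) stop("rtruncnorm1: empty interval")
  if (sd <= 0) return(min(max(mean, lo), hi))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # all mass numerically outside (lo, hi): return the boundary nearest the
    # mean, nudged inside
    return(if (mean <= lo) lo + 1e-9 * (hi - lo) else hi - 1e-9 * (hi - lo))
  }
  qnorm(runif(1, plo, phi), mean, sd)
}

# Split-chain potential scale reduction factor. `draws` is an iterations x
# chains matrix of post-burn-in samples of one scalar parameter.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W <= 0) {
    # all chains constant at the same value: perfectly converged; constant at
    # different values: not converged
    return(if (isTRUE(all(abs(means - means[1]) < 1e-12))) 1 else Inf)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

sem <- function(x) {
  n <- sum(is.finite(x))
  if (n < 2) return(NA_real_)
  sd(x[is.finite(x)]) / sqrt(n)
}
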