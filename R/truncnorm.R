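## Numerically safe half-line truncated normal draws for the probit
## augmentation.  Z ~ N(mu, 1) truncated to (0, Inf) when y = 1 and to
## (-Inf, 0] when y = 0.  Moderate truncations use the inverse-CDF on the
## upper tail; far tails (standardized bound > 6, where naive rejection would
## stall) use Robert's translated-exponential rejection sampler, which has
## acceptance probability -> 1 as the bound grows.

# Standard normal truncated to (a, Inf), vectorized over a.
.rtnorm_std_lower <- function(a) {
  n <- length(a)
  out <- numeric(n)
  easy <- a <= 6
  if (any(easy)) {
    pa <- pnorm(a[easy], lower.tail = FALSE)
    out[easy] <- qnorm(runif(sum(easy)) * pa, lower.tail = FALSE)
  }
  hard <- which(!easy)
  if (length(hard)) {
    ah <- a[hard]
    lam <- (ah + sqrt(ah^2 + 4)) / 2
    todo <- seq_along(hard)
    z <- numeric(length(hard))
    while (length(todo)) {
      prop <- ah[todo] + rexp(length(todo)) / lam[todo]
      acc <- runif(length(todo)) <= exp(-(prop - lam[todo])^2 / 2)
      z[todo[acc]] <- prop[acc]
      todo <- todo[!acc]
    }
    out[hard] <- z
  }
  out
}

# N(mu, 1) truncated to the positive (positive = TRUE) or non-positive
# half-line, vectorized.
.rtnorm_half <- function(mu, positive) {
  out <- numeric(length(mu))
  if (any(positive))
    out[positive] <- mu[positive] + .rtnorm_std_lower(-mu[positive])
  if (any(!positive))
    out[!positive] <- -(-mu[!positive] + .rtnorm_std_lower(mu[!positive]))
  out
}
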