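# Independent reference implementations used as oracles. These stay naive
# (full sorts, explicit loops) and never share code with the package paths
# they check.

# Kraskov algorithm-2 MI reference: brute-force neighbour search by full
# sort of max-norm joint distances, closed marginal balls, self excluded.
ksg_mi_ref <- function(x, y, k = 4) {
  n <- length(x)
  nx <- integer(n)
  ny <- integer(n)
  for (i in seq_len(n)) {
    dx <- abs(x - x[i])
    dy <- abs(y - y[i])
    dj <- pmax(dx, dy)
    dj[i] <- Inf
    nb <- order(dj)[seq_len(k)]
    ex <- max(dx[nb])
    ey <- max(dy[nb])
    nx[i] <- sum(dx <= ex) - 1L
    ny[i] <- sum(dy <= ey) - 1L
  }
  digamma(k) - 1 / k + digamma(n) - mean(digamma(nx) + digamma(ny))
}

# exact hypergeometric upper tail by direct summation of the pmf
hyper_tail_ref <- function(obs, K, N, n) {
  i <- seq(obs, min(n, K))
  if (length(i) == 0 || obs > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# bivariate Gaussian sample with correlation rho
rbigauss <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}

# small uniform dither so oracle comparisons can run with the package's
# noise stage switched off (noise_amplitude = 0)
dither <- function(v, seed, amp = 1e-8) {
  set.seed(seed)
  v + runif(length(v), -amp, amp)
}
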