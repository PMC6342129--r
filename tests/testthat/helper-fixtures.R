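# Small programmatic fixtures shared across test files.

# a 15 x 15 unit-spaced detector array with 4-du buffer and a simulated
# dataset on it
tiny_dataset <- function(N = 15, seed = 42, p0 = 0.1, sigma = 2,
                         nx = 15, buffer = 4) {
  det <- detector_grid(nx, nx)
  dom <- scr_domain(det, buffer = buffer)
  truth <- sim_population(N, dom, sigma = sigma, p0 = p0, seed = seed)
  captures <- sim_captures(truth, det)
  list(detectors = det, domain = dom, truth = truth, captures = captures)
}

# full detection log-likelihood summed over ALL detectors: the independent
# oracle the local (windowed) evaluation must reproduce when the windows
# cover the whole array
full_loglik_oracle <- function(y_row, s, detectors, sigma, p0) {
  d2 <- (detectors$x - s[1])^2 + (detectors$y - s[2])^2
  p <- p0 * exp(-d2 / (2 * sigma^2))
  sum(ifelse(y_row == 1, log(p), log1p(-p)))
}

# textbook Brooks-Gelman PSRF with the d.f. correction, written out
# longhand as the independent check for gelman_rubin()
psrf_oracle <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  xbar <- sapply(chains, mean)
  s2 <- sapply(chains, var)
  W <- sum(s2) / m
  B <- n / (m - 1) * sum((xbar - mean(xbar))^2)
  sig2 <- (n - 1) / n * W + B / n
  V <- sig2 + B / (m * n)
  var_w <- var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (cov(s2, xbar^2) - 2 * mean(xbar) * cov(s2, xbar))
  var_v <- ((n - 1) / n)^2 * var_w + ((m + 1) / (m * n))^2 * var_b +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * cov_wb
  df <- 2 * V^2 / var_v
  sqrt((V / W) * (df + 3) / (df + 1))
}
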