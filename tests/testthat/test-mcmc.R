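test_that("fits are deterministic under a seed and conserve z constraints", {
  d <- tiny_dataset(N = 12, seed = 17)
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = 4, n_expected = 12)
  f1 <- scr_fit(d$captures, d$detectors, d$domain, li, n_adapt = 200,
                n_iter = 300, n_chains = 2, thin = 3, seed = 31)
  f2 <- scr_fit(d$captures, d$detectors, d$domain, li, n_adapt = 200,
                n_iter = 300, n_chains = 2, thin = 3, seed = 31)
  expect_identical(f1$samples, f2$samples)
  M <- li$n_detected + li$n_augmented
  expect_true(all(f1$samples$N >= li$n_detected & f1$samples$N <= M))
  # detected individuals never leave the population
  for (ch in seq_along(f1$draws)) {
    expect_true(all(f1$draws[[ch]]$z[, seq_len(li$n_detected)] == 1L))
  }
  # activity centers stay inside their AC windows
  w <- li$windows
  for (i in c(1, li$n_detected + 1)) {
    expect_true(all(f1$draws[[1]]$s_x[, i] >= w$x_lo[i] &
                      f1$draws[[1]]$s_x[, i] <= w$x_hi[i]))
    expect_true(all(f1$draws[[1]]$s_y[, i] >= w$y_lo[i] &
                      f1$draws[[1]]$s_y[, i] <= w$y_hi[i]))
  }
  expect_equal(nrow(f1$samples), 2 * (300 %/% 3))
})

test_that("zero-iteration fits return empty samples with valid metadata", {
  d <- tiny_dataset(N = 10, seed = 19)
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = 4, n_expected = 10)
  f <- scr_fit(d$captures, d$detectors, d$domain, li, n_adapt = 10,
               n_iter = 0, n_chains = 1, thin = 3, seed = 1)
  expect_equal(nrow(f$samples), 0)
  expect_equal(f$config$M, li$n_detected + li$n_augmented)
  expect_length(f$seeds$chains, 1)
})

test_that("activity centers never land in non-suitable habitat", {
  det <- detector_grid(10, 10)
  hab <- matrix(1L, 18, 18)
  hab[, 1:9] <- 0L  # left half of the domain is non-habitat
  dom <- scr_domain(det, buffer = 4, habitat = hab)
  tr <- sim_population(12, dom, sigma = 2, p0 = 0.3, seed = 23)
  cp <- sim_captures(tr, det, seed = 24)
  li <- less_index(cp, det, dom, ac_width = 10, extension = 4,
                   n_expected = 12)
  f <- scr_fit(cp, det, dom, li, n_adapt = 200, n_iter = 400, n_chains = 1,
               thin = 2, seed = 25)
  sx <- as.vector(f$draws[[1]]$s_x)
  expect_true(all(sx >= dom$bounds[1] + 9))
  # and individuals with habitat-free windows are permanently excluded
  ph <- li$windows$prop_habitat
  if (any(ph == 0)) {
    dead <- which(ph == 0)
    expect_true(all(f$draws[[1]]$z[, dead] == 0L))
  }
})

test_that("s-chain is uniform over its window under a flat likelihood", {
  det <- detector_grid(5, 5)
  dom <- scr_domain(det, buffer = 2)
  y <- matrix(0L, 0, nrow(det))
  li <- less_index(y, det, dom, ac_width = 4, extension = 1, n_layers = 1)
  f <- scr_fit(y, det, dom, li, n_adapt = 500, n_iter = 5000, n_chains = 1,
               thin = 1, seed = 3,
               updates = list(z = FALSE, sigma = FALSE, p0 = FALSE,
                              psi0 = FALSE),
               init = list(z = rep(1L, li$n_augmented), p0 = 0, sigma = 1))
  w <- li$windows[1, ]
  keep <- seq(1, 5000, by = 3)  # decorrelate the random-walk chain
  sx <- f$draws[[1]]$s_x[keep, 1]
  sy <- f$draws[[1]]$s_y[keep, 1]
  expect_gt(ks.test(sx, "punif", w$x_lo, w$x_hi)$p.value, 0.01)
  expect_gt(ks.test(sy, "punif", w$y_lo, w$y_hi)$p.value, 0.01)
  # reflection keeps every proposal inside the window
  expect_true(all(sx >= w$x_lo & sx <= w$x_hi))
  expect_true(all(sy >= w$y_lo & sy <= w$y_hi))
})

test_that("psi0 marginal matches the conjugate Beta when all prop_habitat = 1", {
  det <- detector_grid(10, 10)
  dom <- scr_domain(det, buffer = 0)
  tr <- sim_population(12, dom, sigma = 2, p0 = 0.2, seed = 8)
  cp <- sim_captures(tr, det)
  M <- 40
  li <- less_index_full(cp, det, dom, M)
  expect_true(all(abs(li$windows$prop_habitat - 1) < 1e-9))
  k <- 25  # freeze z at a known inclusion count
  zfix <- c(rep(1L, k), rep(0L, M - k))
  zfix[seq_len(cp$n_detected)] <- 1L
  f <- scr_fit(cp, det, dom, li, n_adapt = 500, n_iter = 5000, n_chains = 1,
               thin = 1, seed = 2,
               updates = list(s = FALSE, z = FALSE, sigma = FALSE,
                              p0 = FALSE),
               init = list(z = zfix, sigma = 2, p0 = 0.2), save_sz = FALSE)
  draws <- f$samples$psi0[seq(1, 5000, by = 4)]  # decorrelate Metropolis ties
  ks <- suppressWarnings(
    ks.test(draws, function(q) pbeta(q, 1 + k, 1 + M - k))
  )
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(f$samples$psi0), (1 + k) / (2 + M), tolerance = 0.03)
})

test_that("detection-parameter updates mix in the adapted acceptance band", {
  d <- tiny_dataset(N = 15, seed = 29)
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = 4, n_expected = 15)
  f <- scr_fit(d$captures, d$detectors, d$domain, li, n_adapt = 1000,
               n_iter = 1500, n_chains = 1, thin = 3, seed = 7)
  acc <- f$accept[[1]]
  expect_gt(acc$sigma, 0.2); expect_lt(acc$sigma, 0.6)
  expect_gt(acc$p0, 0.2); expect_lt(acc$p0, 0.6)
})

test_that("LESS with domain-spanning windows is bitwise identical to the no-LESS fit", {
  d <- tiny_dataset(N = 15, seed = 42)
  M <- 60
  lf <- less_index_full(d$captures, d$detectors, d$domain, M)
  f1 <- scr_fit(d$captures, d$detectors, d$domain, lf, n_adapt = 200,
                n_iter = 400, n_chains = 2, thin = 2, seed = 9)
  f2 <- scr_fit_full(d$captures, d$detectors, d$domain, M, n_adapt = 200,
                     n_iter = 400, n_chains = 2, thin = 2, seed = 9)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior recovers parameters on a moderate simulated dataset", {
  det <- detector_grid(20, 20)
  dom <- scr_domain(det, buffer = 4)
  tr <- sim_population(30, dom, sigma = 2, p0 = 0.07, seed = 51)
  cp <- sim_captures(tr, det, seed = 52)
  li <- less_index(cp, det, dom, ac_width = 10, extension = 4,
                   n_expected = 30)
  f <- scr_fit(cp, det, dom, li, n_adapt = 1000, n_iter = 2000,
               n_chains = 2, thin = 2, seed = 53)
  td <- tidy(f)
  expect_lt(abs(td$estimate[td$term == "sigma"] - 2) / 2, 0.25)
  nrow_ <- td[td$term == "N", ]
  expect_true(nrow_$conf.low <= 30 && 30 <= nrow_$conf.high)
})
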