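test_that("Gelman-Rubin statistic matches a longhand textbook computation", {
  set.seed(101)
  same <- replicate(3, rnorm(500, 0, 1), simplify = FALSE)
  expect_lte(gelman_rubin(same), 1.1)
  ident <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(gelman_rubin(ident), 1)
  disjoint <- list(rnorm(100, 0, 0.1), rnorm(100, 50, 0.1))
  expect_gt(gelman_rubin(disjoint), 10)
  fixed <- list(c(0.3, 1.2, -0.5, 0.8, 2.0), c(0.9, -0.2, 1.5, 0.1, 0.7),
                c(1.1, 0.4, -0.8, 0.6, 1.3))
  expect_equal(gelman_rubin(fixed), psrf_oracle(fixed), tolerance = 1e-10)
  expect_error(gelman_rubin(list(c(1, 2, 3))), "2 chains")
})

test_that("Gelman-Rubin agrees with coda's implementation", {
  skip_if_not_installed("coda")
  set.seed(7)
  chains <- replicate(3, cumsum(rnorm(200)) / 10 + rnorm(200),
                      simplify = FALSE)
  ours <- gelman_rubin(chains)
  theirs <- unname(coda::gelman.diag(
    coda::mcmc.list(lapply(chains, coda::mcmc)), autoburnin = FALSE
  )$psrf[1, 1])
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("relative bias, CV and coverage reproduce hand-computed values", {
  expect_equal(relative_bias(c(100, 100, 100), 100), 0)
  expect_equal(relative_bias(c(110, 110), 100), 0.1)
  expect_equal(relative_bias(c(102, 98), 100), 0)
  expect_error(relative_bias(c(1, 2), 0), "truth")
  expect_equal(coefficient_of_variation(c(90, 110)),
               100 * sd(c(90, 110)) / 100, tolerance = 1e-12)
  expect_equal(round(coefficient_of_variation(c(90, 110)), 2), 14.14)
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(90, 110)),
               coefficient_of_variation(3.7 * c(90, 110)))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_equal(ci_coverage(c(90, 101), c(110, 120), 100), 0.5)
  expect_equal(ci_coverage(c(1, 2), c(200, 300), 100), 1)
  expect_equal(ci_coverage(c(101, 102), c(110, 120), 100), 0)
  expect_error(ci_coverage(10, 5, 7), "malformed")
})

test_that("density-map MRE is the mean absolute normalized difference", {
  dom <- scr_domain(bounds = c(0, 2, 0, 1), buffer = 0)
  mk <- function(v) {
    localscr:::new_density_map(matrix(v, nrow = 1), dom, normalized = FALSE)
  }
  expect_equal(mre(mk(c(0.5, 0.5)), mk(c(0.6, 0.4))), 0.1)
  expect_equal(mre(mk(c(1, 3)), mk(c(1, 3))), 0)
  # invariant to pre-normalization scaling of either map
  expect_equal(mre(mk(c(0.5, 0.5)), mk(c(6, 4))), 0.1)
  expect_equal(mre(mk(c(5, 5)), mk(c(0.6, 0.4))), 0.1)
  # per-cell relative variant
  expect_equal(mre(mk(c(0.5, 0.5)), mk(c(0.6, 0.4)),
                   per_cell_relative = TRUE), 0.2)
  dom2 <- scr_domain(bounds = c(0, 3, 0, 1), buffer = 0)
  m3 <- localscr:::new_density_map(matrix(c(1, 1, 1), 1), dom2,
                                   normalized = FALSE)
  expect_error(mre(mk(c(1, 1)), m3), "different grids")
})

test_that("normalized maps sum to one over included cells", {
  det <- detector_grid(10, 10)
  dom <- scr_domain(det, buffer = 2)
  tr <- sim_population(8, dom, sigma = 2, p0 = 0.2, seed = 61)
  m <- true_density_map(tr, dom)
  nm <- normalize_density_map(m)
  expect_equal(sum(nm$values, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(nm$values >= 0, na.rm = TRUE))
  expect_true(all(is.na(nm$values[nm$buffer_mask])))
})

test_that("predicted map reduces to the true map for a degenerate posterior", {
  det <- detector_grid(10, 10)
  dom <- scr_domain(det, buffer = 2)
  tr <- sim_population(6, dom, sigma = 2, p0 = 0.2, seed = 71)
  cp <- sim_captures(tr, det, seed = 72)
  li <- less_index_full(cp, det, dom, M = 20)
  # freeze everything: single included individual pinned at a known AC
  M <- 20
  zfix <- integer(M); zfix[1] <- 1L
  sx <- rep(5, M); sy <- rep(5, M)
  sx[1] <- tr$ac$x[1]; sy[1] <- tr$ac$y[1]
  f <- scr_fit(cp, det, dom, li, n_adapt = 0, n_iter = 20, n_chains = 1,
               thin = 1, seed = 3,
               updates = list(s = FALSE, z = FALSE, sigma = FALSE,
                              p0 = FALSE, psi0 = FALSE),
               init = list(z = zfix, s_x = sx, s_y = sy, sigma = 2,
                           p0 = 0.2))
  pm <- predicted_density_map(f, dom)
  tr1 <- tr; tr1$ac <- tr$ac[1, ]
  tm <- true_density_map(tr1, dom)
  expect_equal(pm$values, tm$values, tolerance = 1e-12)
  # averaging identical draws is idempotent
  pm2 <- predicted_density_map(f, dom, draw_step = 5)
  expect_equal(pm$values, pm2$values, tolerance = 1e-12)
  expect_error(
    predicted_density_map(
      scr_fit(cp, det, dom, li, n_adapt = 0, n_iter = 10, n_chains = 1,
              thin = 1, seed = 4, save_sz = FALSE), dom),
    "save_sz"
  )
})

test_that("scenario summaries score each parameter and gate on R-hat", {
  reps <- tibble::tibble(
    replicate = rep(1:3, each = 3),
    param = rep(c("N", "sigma", "p0"), 3),
    estimate = c(100, 2, 0.07, 110, 2.2, 0.08, 90, 1.8, 0.06),
    lo = c(90, 1.5, 0.05, 95, 1.7, 0.06, 80, 1.4, 0.04),
    hi = c(115, 2.5, 0.09, 130, 2.7, 0.10, 105, 2.2, 0.08),
    rhat_max_rep = c(rep(1.0, 3), rep(1.0, 3), rep(1.5, 3)),
    mre = rep(c(0.1, 0.2, 0.9), each = 3)
  )
  s <- summarize_scenario(reps, truth = list(N = 100, sigma = 2, p0 = 0.07))
  expect_equal(nrow(s), 3)
  expect_equal(s$n_excluded, rep(1L, 3))  # the rhat = 1.5 replicate
  expect_equal(s$RB[s$param == "N"], mean(c(100, 110) - 100) / 100)
  expect_equal(s$coverage[s$param == "N"], 1)
  expect_equal(s$MRE, rep(mean(c(0.1, 0.2)), 3))
  # estimates exactly at truth: RB 0, coverage by interval content
  flat <- dplyr::mutate(reps[reps$param == "N", ], estimate = 100,
                        rhat_max_rep = 1)
  s2 <- summarize_scenario(flat, truth = list(N = 100))
  expect_equal(s2$RB, 0)
})
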