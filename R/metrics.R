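#' Gelman-Rubin potential scale reduction factor
#'
#' Brooks-Gelman PSRF with the sampling-variability (d.f.) correction, the
#' form computed by `coda::gelman.diag`. Chains are considered converged
#' when the statistic is at most 1.1 for all monitored parameters.
#'
#' @param chains List of numeric vectors, one per chain, equal lengths.
#' @return The PSRF (scalar).
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("gelman_rubin needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 2) stop("chains must contain at least 2 samples")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (B == 0 || W == 0) {
    # identical chains (or constant chains): no between-chain disagreement
    return(1)
  }
  sig2 <- (n - 1) / n * W + B / n
  Vhat <- sig2 + B / (m * n)
  # variance of Vhat -> degrees of freedom correction (Brooks & Gelman)
  var_w <- stats::var(vars) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(vars, means^2) -
                         2 * mean(means) * stats::cov(vars, means))
  var_v <- ((n - 1) / n)^2 * var_w + ((m + 1) / (m * n))^2 * var_b +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * cov_wb
  df <- 2 * Vhat^2 / var_v
  psrf2 <- Vhat / W
  if (is.finite(df) && df > 2) psrf2 <- psrf2 * (df + 3) / (df + 1)
  sqrt(psrf2)
}

#' Gelman-Rubin diagnostics for a fitted model
#'
#' @param fit An [scr_fit()].
#' @param params Parameters to monitor.
#' @return Tibble with `param`, `rhat`.
#' @export
rhat_scr <- function(fit, params = c("sigma", "p0", "psi0", "N")) {
  stopifnot(inherits(fit, "scr_fit"))
  purrr::map_dfr(params, function(p) {
    ch <- split(as.numeric(fit$samples[[p]]), fit$samples$chain)
    tibble::tibble(param = p, rhat = gelman_rubin(ch))
  })
}

#' Relative bias of a set of point estimates
#'
#' `RB = (1 / (theta * n)) * sum(theta_hat - theta)`: the mean deviation
#' from truth in units of the truth.
#'
#' @param estimates Per-replicate point estimates.
#' @param truth True parameter value (nonzero).
#' @return Relative bias (scalar).
#' @export
relative_bias <- function(estimates, truth) {
  if (length(estimates) < 1) stop("need at least one estimate")
  if (truth == 0) stop("relative bias is undefined for truth = 0")
  mean(estimates - truth) / truth
}

#' Coefficient of variation of point estimates, in percent
#'
#' `CV = 100 * SD(theta_hat) / mean(theta_hat)` across replicates.
#'
#' @param estimates Per-replicate point estimates (n >= 2).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(estimates) {
  if (length(estimates) < 2) stop("CV needs at least 2 estimates")
  m <- mean(estimates)
  if (m == 0) stop("CV is undefined for zero mean")
  100 * stats::sd(estimates) / m
}

#' Credible-interval coverage
#'
#' Fraction of replicates whose interval `[lo, hi]` contains the truth.
#'
#' @param lo,hi Per-replicate interval bounds.
#' @param truth True parameter value.
#' @return Fraction in `[0, 1]`.
#' @export
ci_coverage <- function(lo, hi, truth) {
  stopifnot(length(lo) == length(hi))
  if (any(lo > hi)) stop("malformed interval: lo > hi")
  mean(lo <= truth & truth <= hi)
}

#' Posterior-predicted density surface
#'
#' For each stored posterior draw, sums the half-normal space-use kernels
#' (that draw's sigma) of all individuals included in the population
#' (z = 1) at the habitat cell centers, then averages over draws.
#'
#' @param fit An [scr_fit()] run with `save_sz = TRUE`.
#' @param domain The [scr_domain()] used for the fit.
#' @param draw_step Use every `draw_step`-th kept draw (default 1 = all).
#' @return An `scr_density_map`.
#' @export
predicted_density_map <- function(fit, domain, draw_step = 1) {
  stopifnot(inherits(fit, "scr_fit"))
  if (!isTRUE(fit$config$save_sz) ||
      any(vapply(fit$draws, function(d) nrow(d$s_x) == 0, logical(1)))) {
    stop("fit was run without save_sz = TRUE; activity-center draws are ",
         "not available")
  }
  n_keep <- fit$config$n_iter %/% fit$config$thin
  use <- seq(1, n_keep, by = draw_step)
  maps <- lapply(seq_along(fit$draws), function(ch) {
    dr <- fit$draws[[ch]]
    sig <- fit$samples$sigma[fit$samples$chain == ch][use]
    v <- predicted_density_cpp(
      dr$s_x[use, , drop = FALSE], dr$s_y[use, , drop = FALSE],
      dr$z[use, , drop = FALSE], sig, domain$cell_x, domain$cell_y
    )
    matrix(v, nrow = length(domain$cell_y))
  })
  new_density_map(Reduce(`+`, maps) / length(maps), domain,
                  normalized = FALSE)
}

#' Normalize a density map to unit mass
#'
#' @param map An `scr_density_map`.
#' @param exclude_buffer Restrict to non-buffer cells (others set `NA`).
#' @return A normalized `scr_density_map`.
#' @export
normalize_density_map <- function(map, exclude_buffer = TRUE) {
  v <- map$values
  if (exclude_buffer) v[map$buffer_mask] <- NA_real_
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("density map has no positive mass to normalize")
  map$values <- v / tot
  map$normalized <- TRUE
  map
}

#' Mean relative error between true and predicted density maps
#'
#' Both maps are restricted to non-buffer habitat cells and scaled to sum to
#' one; the MRE is the mean absolute difference of the normalized cell
#' values over the h included cells. A flag switches to a per-cell
#' `|Dhat - D| / D` average instead.
#'
#' @param true_map,pred_map `scr_density_map`s on the same grid.
#' @param per_cell_relative If `TRUE`, average `|Dhat_j - D_j| / D_j` over
#'   cells with `D_j > 0` instead of `|Dhat_j - D_j|`.
#' @return MRE (scalar, >= 0).
#' @export
mre <- function(true_map, pred_map, per_cell_relative = FALSE) {
  if (!identical(dim(true_map$values), dim(pred_map$values))) {
    stop("density maps are on different grids")
  }
  if (!identical(true_map$buffer_mask, pred_map$buffer_mask)) {
    stop("density maps have different buffer masks")
  }
  t_n <- normalize_density_map(true_map, exclude_buffer = TRUE)
  p_n <- normalize_density_map(pred_map, exclude_buffer = TRUE)
  keep <- !t_n$buffer_mask
  D <- t_n$values[keep]
  Dh <- p_n$values[keep]
  if (per_cell_relative) {
    pos <- D > 0
    return(mean(abs(Dh[pos] - D[pos]) / D[pos]))
  }
  mean(abs(Dh - D))
}

#' Summarize replicate fits into scenario-level scores
#'
#' Computes, per parameter, the relative bias of the posterior means, the
#' across-replicate coefficient of variation, and 95% equal-tailed
#' credible-interval coverage; plus the mean density-map MRE when supplied.
#' Replicates with any monitored Gelman-Rubin statistic above `rhat_max`
#' are excluded (and counted).
#'
#' @param replicates Tibble with one row per replicate x parameter:
#'   columns `replicate`, `param`, `estimate`, `lo`, `hi`, optionally
#'   `rhat_max_rep` (max monitored R-hat of that replicate) and `mre`.
#' @param truth Named vector/list of true values, e.g.
#'   `c(N = 100, sigma = 2, p0 = 0.07)`.
#' @param labels Optional named list of scenario labels prepended as columns.
#' @param rhat_max Convergence gate (default 1.1).
#' @return Tibble with one row per parameter: `param`, `RB`, `CV`,
#'   `coverage`, `MRE`, `n_reps`, `n_excluded`, plus label columns.
#' @export
summarize_scenario <- function(replicates, truth, labels = NULL,
                               rhat_max = 1.1) {
  stopifnot(all(c("replicate", "param", "estimate", "lo", "hi") %in%
                  names(replicates)))
  if (!"rhat_max_rep" %in% names(replicates)) {
    replicates$rhat_max_rep <- NA_real_
  }
  conv <- dplyr::distinct(replicates, .data$replicate, .data$rhat_max_rep)
  bad <- conv$replicate[!is.na(conv$rhat_max_rep) &
                          conv$rhat_max_rep > rhat_max]
  kept <- dplyr::filter(replicates, !(.data$replicate %in% bad))
  if (nrow(kept) == 0) stop("no converged replicates to summarize")
  mre_mean <- if ("mre" %in% names(kept)) {
    mean(dplyr::distinct(kept, .data$replicate, .data$mre)$mre)
  } else {
    NA_real_
  }
  out <- kept |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      RB = relative_bias(.data$estimate, truth[[unique(.data$param)]]),
      CV = if (dplyr::n() >= 2) {
        coefficient_of_variation(.data$estimate)
      } else {
        NA_real_
      },
      coverage = ci_coverage(.data$lo, .data$hi,
                             truth[[unique(.data$param)]]),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(MRE = mre_mean, n_excluded = length(bad))
  if (!is.null(labels)) {
    out <- dplyr::bind_cols(tibble::as_tibble(labels), out)
  }
  out
}
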