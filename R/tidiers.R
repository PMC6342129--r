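#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of an SCR fit
#'
#' One row per monitored parameter with the posterior mean, standard
#' deviation, equal-tailed 95% credible interval and Gelman-Rubin statistic.
#'
#' @param x An [scr_fit()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.scr_fit <- function(x, ...) {
  params <- c("sigma", "p0", "psi0", "N", "density")
  rh <- rhat_scr(x, params = c("sigma", "p0", "psi0", "N"))
  purrr::map_dfr(params, function(p) {
    v <- as.numeric(x$samples[[p]])
    tibble::tibble(
      term = p,
      estimate = mean(v),
      std.error = stats::sd(v),
      conf.low = as.numeric(stats::quantile(v, 0.025, names = FALSE)),
      conf.high = as.numeric(stats::quantile(v, 0.975, names = FALSE)),
      rhat = if (p %in% rh$param) rh$rhat[rh$param == p] else NA_real_
    )
  })
}

#' One-row summary of an SCR fit
#'
#' @param x An [scr_fit()].
#' @param ... Unused.
#' @return A one-row tibble: data size, abundance and density posterior
#'   means with 95% interval, worst R-hat, runtime.
#' @export
glance.scr_fit <- function(x, ...) {
  td <- tidy(x)
  n_row <- td[td$term == "N", ]
  tibble::tibble(
    n_detected = x$config$n_detected,
    M = x$config$M,
    n_chains = x$config$n_chains,
    n_samples = nrow(x$samples),
    N_hat = n_row$estimate,
    N_lo = n_row$conf.low,
    N_hi = n_row$conf.high,
    density = td$estimate[td$term == "density"],
    sigma_hat = td$estimate[td$term == "sigma"],
    p0_hat = td$estimate[td$term == "p0"],
    max_rhat = max(td$rhat, na.rm = TRUE),
    runtime_s = x$runtime_s
  )
}

#' Trace and density plots for an SCR fit
#'
#' @param object An [scr_fit()].
#' @param params Parameters to display.
#' @param ... Unused.
#' @return A ggplot object (faceted traces).
#' @export
autoplot.scr_fit <- function(object, params = c("sigma", "p0", "psi0", "N"),
                             ...) {
  long <- object$samples |>
    dplyr::select(dplyr::all_of(c("chain", "iteration", params))) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "param") |>
    dplyr::mutate(chain = factor(.data$chain))
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}

#' Plot a density surface
#'
#' @param object An `scr_density_map`.
#' @param exclude_buffer Blank out buffer cells.
#' @param ... Unused.
#' @return A ggplot raster of the density surface.
#' @export
autoplot.scr_density_map <- function(object, exclude_buffer = FALSE, ...) {
  v <- object$values
  if (exclude_buffer) v[object$buffer_mask] <- NA_real_
  df <- tidyr::expand_grid(
    y = object$domain$cell_y,
    x = object$domain$cell_x
  )
  df$density <- as.vector(t(v))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (du)", y = "y (du)") +
    ggplot2::theme_minimal()
}
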