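#' Half-normal detection probability
#'
#' Probability of detecting an individual at a detector a given distance from
#' its activity center: `p0 * exp(-d^2 / (2 * sigma^2))`. `p0` is the
#' detection probability at the AC itself and `sigma` scales with home-range
#' extent.
#'
#' @param distance Distance(s) from the activity center (du).
#' @param p0 Baseline detection probability at distance 0.
#' @param sigma Half-normal scale parameter (du).
#' @return Detection probability/ies.
#' @examples
#' detection_prob(0, 0.07, 2)    # 0.07
#' detection_prob(4, 0.07, 2)    # 0.07 * exp(-2)
#' @export
detection_prob <- function(distance, p0, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("sigma must be > 0")
  stopifnot(all(distance >= 0), all(p0 >= 0), all(p0 <= 1))
  p0 * exp(-distance^2 / (2 * sigma^2))
}

#' One-dimensional Gaussian mass inside a centered window
#'
#' Fraction of a Gaussian kernel's mass falling within a window of the given
#' width (in units of sigma) centered on the kernel: `erf(w / (2 * sqrt(2)))`.
#' A width of 9 sigma captures 99.9993% of the detection-function range along
#' one axis, which motivates the default window sizes.
#'
#' @param width_in_sigma Window width divided by sigma (>= 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' gaussian_window_mass(9)  # 0.999993
#' @export
gaussian_window_mass <- function(width_in_sigma) {
  stopifnot(all(width_in_sigma >= 0))
  2 * stats::pnorm(width_in_sigma / 2) - 1
}

#' Simulate a population of activity centers
#'
#' Activity centers are drawn i.i.d. uniformly over the *suitable* habitat of
#' the state-space (a continuous uniform point process, realized by rejection
#' from the bounding rectangle).
#'
#' @param N Number of individuals.
#' @param domain An [scr_domain()].
#' @param sigma Half-normal scale (du) carried along for downstream steps.
#' @param p0 Baseline detection probability carried along.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `scr_truth`: list with `ac` (tibble
#'   `individual`, `x`, `y`), `N`, `sigma`, `p0`, `seed`.
#' @export
sim_population <- function(N, domain, sigma = 2, p0 = 0.07, seed = NULL) {
  stopifnot(N >= 1, sigma > 0, p0 > 0, p0 < 1)
  if (sum(domain$habitat) == 0) stop("domain has no suitable habitat")
  if (!is.null(seed)) set.seed(seed)
  b <- domain$bounds
  xs <- numeric(N)
  ys <- numeric(N)
  got <- 0
  while (got < N) {
    m <- max(2L * (N - got), 10L)
    cx <- stats::runif(m, b[1], b[2])
    cy <- stats::runif(m, b[3], b[4])
    ok <- in_habitat(cx, cy, domain)
    keep <- min(sum(ok), N - got)
    if (keep > 0) {
      sel <- which(ok)[seq_len(keep)]
      xs[got + seq_len(keep)] <- cx[sel]
      ys[got + seq_len(keep)] <- cy[sel]
      got <- got + keep
    }
  }
  structure(
    list(
      ac = tibble::tibble(individual = seq_len(N), x = xs, y = ys),
      N = N, sigma = sigma, p0 = p0, seed = seed
    ),
    class = "scr_truth"
  )
}

#' @export
print.scr_truth <- function(x, ...) {
  cat(sprintf("<scr_truth> N = %d, sigma = %.6g, p0 = %.6g\n",
              x$N, x$sigma, x$p0))
  invisible(x)
}

#' Simulate binary detections
#'
#' Independent Bernoulli draws per individual x detector with half-normal
#' probability [detection_prob()]. Individuals never detected are dropped
#' from the capture history (as in real data) but remain in `truth` for
#' scoring; `detected_individual` maps retained rows back to the simulated
#' population.
#'
#' @param truth An [sim_population()] result.
#' @param detectors Detector tibble.
#' @param seed Optional integer seed.
#' @return An object of class `scr_captures`: list with `y` (binary matrix,
#'   detected individuals x detectors), `detected_individual` (integer map to
#'   truth rows), `n_detected`, `detectors_n`, and `detections` (long tibble
#'   `individual_id`, `detector_id`).
#' @export
sim_captures <- function(truth, detectors, seed = NULL) {
  validate_detectors(detectors)
  if (!is.null(seed)) set.seed(seed)
  dx <- outer(truth$ac$x, detectors$x, "-")
  dy <- outer(truth$ac$y, detectors$y, "-")
  p <- truth$p0 * exp(-(dx^2 + dy^2) / (2 * truth$sigma^2))
  y <- matrix(stats::rbinom(length(p), 1L, p), nrow = truth$N)
  det <- which(rowSums(y) > 0)
  ym <- y[det, , drop = FALSE]
  long <- which(ym == 1L, arr.ind = TRUE)
  new_scr_captures(
    y = ym,
    detected_individual = det,
    detector_id = detectors$detector_id,
    detections = tibble::tibble(
      individual_id = det[long[, 1]],
      detector_id = detectors$detector_id[long[, 2]]
    )
  )
}

new_scr_captures <- function(y, detected_individual, detector_id,
                             detections) {
  storage.mode(y) <- "integer"
  structure(
    list(
      y = y,
      detected_individual = as.integer(detected_individual),
      n_detected = nrow(y),
      detector_id = detector_id,
      detections = detections
    ),
    class = "scr_captures"
  )
}

#' @export
print.scr_captures <- function(x, ...) {
  cat(sprintf("<scr_captures> %d individuals, %d detections at %d detectors\n",
              x$n_detected, sum(x$y), ncol(x$y)))
  invisible(x)
}

# binary individuals x detectors matrix from whatever the user passed
capture_matrix <- function(captures) {
  if (inherits(captures, "scr_captures")) {
    return(captures$y)
  }
  if (is.matrix(captures)) {
    storage.mode(captures) <- "integer"
    if (!all(captures %in% c(0L, 1L))) stop("capture history must be binary")
    return(captures)
  }
  stop("captures must be an scr_captures object or a binary matrix")
}

#' True density surface from simulated activity centers
#'
#' Per habitat cell, the summed space use of all simulated individuals: the
#' half-normal kernel (without p0) evaluated at the cell center,
#' `sum_i exp(-d_i^2 / (2 sigma^2))`. Buffer cells stay in the raster but are
#' flagged so that map comparisons can exclude them.
#'
#' @param truth An [sim_population()] result.
#' @param domain An [scr_domain()].
#' @return An object of class `scr_density_map`: list with `values` (matrix,
#'   rows = y from bottom), `buffer_mask` (logical matrix), `domain`,
#'   `normalized` flag.
#' @export
true_density_map <- function(truth, domain) {
  v <- kernel_density_map(truth$ac$x, truth$ac$y, truth$sigma, domain)
  new_density_map(v, domain, normalized = FALSE)
}

kernel_density_map <- function(acx, acy, sigma, domain) {
  nx <- length(domain$cell_x)
  ny <- length(domain$cell_y)
  v <- density_map_cpp(acx, acy, sigma, domain$cell_x, domain$cell_y)
  matrix(v, nrow = ny, ncol = nx)
}

new_density_map <- function(values, domain, normalized) {
  structure(
    list(values = values, buffer_mask = buffer_mask(domain),
         domain = domain, normalized = normalized),
    class = "scr_density_map"
  )
}

#' @export
print.scr_density_map <- function(x, ...) {
  cat(sprintf("<scr_density_map> %d x %d cells, total mass %.6g%s\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}
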