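#' Centroid of an individual's detections
#'
#' The evaluation windows of a detected individual are centered on the
#' arithmetic mean of the coordinates of the detectors at which it was
#' detected (binary data: each detector counts once).
#'
#' @param capture_row Binary vector over detectors (one individual's row of
#'   the capture history).
#' @param detectors Detector tibble (`detector_id`, `x`, `y`), rows aligned
#'   with `capture_row`.
#' @return Numeric `c(x, y)`.
#' @examples
#' det <- detector_grid(3, 1)
#' detection_centroid(c(1, 0, 1), det)
#' @export
detection_centroid <- function(capture_row, detectors) {
  hit <- which(capture_row > 0)
  if (length(hit) == 0) {
    stop("individual has no detections; centroid undefined")
  }
  c(x = mean(detectors$x[hit]), y = mean(detectors$y[hit]))
}

new_window <- function(x_lo, x_hi, y_lo, y_hi, width) {
  tibble::tibble(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi,
                 width = width)
}

#' Build a square activity-center evaluation window
#'
#' A width-`width` square centered on `center`. Windows are half-open:
#' a point (x, y) belongs to the window iff `x_lo <= x < x_hi` and
#' `y_lo <= y < y_hi`. Windows are deliberately *not* clipped to the domain;
#' area falling outside suitable habitat is absorbed by the per-individual
#' inclusion-probability correction (see [psi_individual()]).
#'
#' @param center Numeric `c(x, y)`.
#' @param width Window width (du), e.g. `5 * sigma`.
#' @return A one-row window tibble (`x_lo`, `x_hi`, `y_lo`, `y_hi`, `width`).
#' @export
ac_window <- function(center, width) {
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0")
  new_window(center[1] - width / 2, center[1] + width / 2,
             center[2] - width / 2, center[2] + width / 2, width)
}

#' Build the detector evaluation window around an AC window
#'
#' The detector window is concentric with the AC window and extends
#' `extension` du beyond each edge, so its width is
#' `ac_window$width + 2 * extension`. Only detectors inside this window enter
#' the individual's detection likelihood.
#'
#' @param window A one-row AC window tibble.
#' @param extension Extension beyond the AC window edge (du), e.g.
#'   `2 * sigma`.
#' @return A one-row window tibble.
#' @export
detector_window <- function(window, extension) {
  if (!is.numeric(extension) || extension < 0) {
    stop("detector window extension must be >= 0")
  }
  new_window(window$x_lo - extension, window$x_hi + extension,
             window$y_lo - extension, window$y_hi + extension,
             window$width + 2 * extension)
}

#' Detectors inside a window
#'
#' Half-open membership: detector at (x, y) is inside iff
#' `x_lo <= x < x_hi` and `y_lo <= y < y_hi`. On a unit-spaced lattice a
#' width-w window therefore contains at most `ceiling(w)` detectors per axis
#' (a width-18 window holds at most 18 x 18 = 324 detectors).
#'
#' @param window A one-row window tibble.
#' @param detectors Detector tibble.
#' @return Integer vector of detector row indices, ascending; may be empty.
#' @export
detectors_in_window <- function(window, detectors) {
  which(detectors$x >= window$x_lo & detectors$x < window$x_hi &
          detectors$y >= window$y_lo & detectors$y < window$y_hi)
}

#' Tile the domain with juxtaposed augmentation windows
#'
#' Augmented (never-detected) individuals receive AC windows laid edge to
#' edge from the domain's lower-left corner, so augmented activity centers
#' have constant density across the state-space. The last row/column tile is
#' truncated at the domain boundary so that, within a layer, the half-open
#' tiles partition the bounds exactly. Additional identical layers are
#' superimposed when more augmented individuals are needed.
#'
#' @param domain An [scr_domain()].
#' @param width Nominal tile width (du); the `width` column keeps this
#'   nominal value even for truncated edge tiles (it is the denominator of
#'   the habitat-proportion correction).
#' @param n_layers Number of superimposed identical layers.
#' @return A tibble of windows with columns `layer`, `tile`, `x_lo`, `x_hi`,
#'   `y_lo`, `y_hi`, `width`.
#' @export
tile_windows <- function(domain, width, n_layers = 1) {
  stopifnot(width > 0, n_layers >= 1)
  b <- domain$bounds
  if (width > (b[2] - b[1]) || width > (b[4] - b[3])) {
    warning("tile width exceeds the domain extent; a single truncated tile ",
            "per axis is used")
  }
  n_x <- max(1L, ceiling((b[2] - b[1]) / width - 1e-9))
  n_y <- max(1L, ceiling((b[4] - b[3]) / width - 1e-9))
  xs <- b[1] + width * (seq_len(n_x) - 1)
  ys <- b[3] + width * (seq_len(n_y) - 1)
  g <- expand.grid(x_lo = xs, y_lo = ys)
  one <- new_window(g$x_lo, pmin(g$x_lo + width, b[2]),
                    g$y_lo, pmin(g$y_lo + width, b[4]), width)
  one$tile <- seq_len(nrow(one))
  out <- dplyr::bind_rows(
    lapply(seq_len(n_layers), function(l) dplyr::mutate(one, layer = l))
  )
  dplyr::select(out, "layer", "tile", "x_lo", "x_hi", "y_lo", "y_hi", "width")
}

#' Proportion of suitable habitat within a window
#'
#' Area of suitable habitat cells intersected with the window, divided by the
#' *nominal* window area `width^2`. Area outside the domain bounds counts as
#' non-suitable, so windows protruding past the state-space edge get a
#' proportion < 1 even in all-suitable habitat; the inclusion-probability
#' correction uses this to keep density unbiased.
#'
#' @param window A one-row window tibble.
#' @param domain An [scr_domain()].
#' @return A fraction in `[0, 1]`.
#' @export
prop_habitat <- function(window, domain) {
  b <- domain$bounds
  cs <- domain$cell_size
  hab <- domain$habitat
  c_lo <- max(1L, floor((window$x_lo - b[1]) / cs) + 1L)
  c_hi <- min(ncol(hab), ceiling((window$x_hi - b[1]) / cs))
  r_lo <- max(1L, floor((window$y_lo - b[3]) / cs) + 1L)
  r_hi <- min(nrow(hab), ceiling((window$y_hi - b[3]) / cs))
  if (c_lo > c_hi || r_lo > r_hi) {
    return(0)
  }
  cols <- c_lo:c_hi
  rows <- r_lo:r_hi
  # per-cell overlap widths along each axis
  cx0 <- b[1] + (cols - 1) * cs
  cy0 <- b[3] + (rows - 1) * cs
  wx <- pmax(0, pmin(window$x_hi, cx0 + cs) - pmax(window$x_lo, cx0))
  wy <- pmax(0, pmin(window$y_hi, cy0 + cs) - pmax(window$y_lo, cy0))
  area <- sum((wy %o% wx) * (hab[rows, cols, drop = FALSE] == 1L))
  min(1, area / window$width[1]^2)
}

#' Build the local-evaluation (LESS) index
#'
#' Constructs, for every detected and augmented individual, the AC evaluation
#' window, the detector evaluation window, the list of detectors falling
#' inside the detector window, and the proportion of suitable habitat in the
#' AC window. Detected individuals' windows are centered on their detection
#' centroid; augmented individuals use juxtaposed tiles ([tile_windows()])
#' with the same detector extension.
#'
#' Build-time validation guarantees the central LESS contract: every
#' detection of individual i falls inside its detector window. A violation
#' is an error (advising a wider `ac_width`/`extension`); it is never
#' silently widened.
#'
#' @param captures Capture history: binary matrix (individuals x detectors)
#'   or a [sim_captures()] result.
#' @param detectors Detector tibble.
#' @param domain An [scr_domain()].
#' @param ac_width AC window width (du), typically `5 * sigma`.
#' @param extension Detector window extension beyond the AC window edge (du),
#'   typically `2 * sigma`.
#' @param n_layers Number of augmentation layers; default is the smallest
#'   integer making the augmented count strictly exceed
#'   `augment_factor * n_expected`.
#' @param n_expected Expected population size used to size the augmentation
#'   (defaults to `n_detected`); ignored when `n_layers` is given.
#' @param augment_factor Multiplier for the augmentation target (default 4).
#' @return An object of class `less_index`: list with `windows` (tibble, one
#'   row per individual: `individual`, `kind`, AC bounds `x_lo...y_hi`,
#'   `width`, detector-window bounds `dx_lo...dy_hi`, `n_detectors`,
#'   `prop_habitat`), `detector_index` (padded integer matrix),
#'   `n_detectors`, `n_detected`, `n_augmented`, `ac_width`, `extension`,
#'   `n_layers`.
#' @export
less_index <- function(captures, detectors, domain, ac_width, extension,
                       n_layers = NULL, n_expected = NULL,
                       augment_factor = 4) {
  y <- capture_matrix(captures)
  validate_detectors(detectors)
  stopifnot(ncol(y) == nrow(detectors))
  n_det <- nrow(y)
  if (n_det > 0 && any(rowSums(y) == 0)) {
    stop("every detected individual must have at least one detection")
  }
  if (ac_width <= 0) stop("window width must be > 0")
  if (extension < 0) stop("detector window extension must be >= 0")

  ac <- vector("list", n_det)
  for (i in seq_len(n_det)) {
    ac[[i]] <- ac_window(detection_centroid(y[i, ], detectors), ac_width)
  }
  tiles0 <- tile_windows(domain, ac_width, 1)
  per_layer <- nrow(tiles0)
  if (is.null(n_layers)) {
    if (is.null(n_expected)) n_expected <- n_det
    target <- augment_factor * n_expected
    n_layers <- max(1L, floor(target / per_layer) + 1L)
  }
  tiles <- tile_windows(domain, ac_width, n_layers)
  aug <- new_window(tiles$x_lo, tiles$x_hi, tiles$y_lo, tiles$y_hi,
                    tiles$width)
  win <- dplyr::bind_rows(c(ac, list(aug)))
  n_aug <- nrow(aug)
  M <- n_det + n_aug
  win$individual <- seq_len(M)
  win$kind <- rep(c("detected", "augmented"), c(n_det, n_aug))

  dw <- detector_window(win, extension)
  idx <- lapply(seq_len(M), function(i) detectors_in_window(dw[i, ], detectors))
  counts <- lengths(idx)
  ph <- vapply(seq_len(M), function(i) prop_habitat(win[i, ], domain),
               numeric(1))

  # LESS contract: all detections inside the owner's detector window
  for (i in seq_len(n_det)) {
    hits <- which(y[i, ] > 0)
    out <- setdiff(hits, idx[[i]])
    if (length(out) > 0) {
      stop("detection(s) of individual ", i, " at detector(s) ",
           paste(detectors$detector_id[out], collapse = ", "),
           " fall outside its detector window; increase ac_width and/or ",
           "extension")
    }
  }

  pad <- max(1L, max(counts))
  det_index <- matrix(0L, nrow = M, ncol = pad)
  for (i in seq_len(M)) {
    if (counts[i] > 0) det_index[i, seq_len(counts[i])] <- idx[[i]]
  }

  windows <- tibble::tibble(
    individual = win$individual,
    kind = win$kind,
    x_lo = win$x_lo, x_hi = win$x_hi, y_lo = win$y_lo, y_hi = win$y_hi,
    width = win$width,
    dx_lo = dw$x_lo, dx_hi = dw$x_hi, dy_lo = dw$y_lo, dy_hi = dw$y_hi,
    n_detectors = counts,
    prop_habitat = ph
  )
  structure(
    list(
      windows = windows,
      detector_index = det_index,
      n_detectors = counts,
      n_detected = n_det,
      n_augmented = n_aug,
      ac_width = ac_width,
      extension = extension,
      n_layers = n_layers
    ),
    class = "less_index"
  )
}

#' @export
print.less_index <- function(x, ...) {
  cat(sprintf(
    paste0("<less_index> %d detected + %d augmented (%d layers); AC width ",
           "%.6g du, extension %.6g du; max %d detectors/individual\n"),
    x$n_detected, x$n_augmented, x$n_layers, x$ac_width, x$extension,
    max(x$n_detectors)
  ))
  invisible(x)
}

#' Domain-spanning LESS index (no local evaluation)
#'
#' Windows covering the whole state-space and every detector: the resulting
#' model is the classical SCR formulation without local evaluation, run
#' through the identical code path. Used as the reference ("without LESS")
#' fit and in equivalence tests.
#'
#' @inheritParams less_index
#' @param M Total number of individuals (detected + augmented).
#' @return A `less_index`.
#' @export
less_index_full <- function(captures, detectors, domain, M) {
  y <- capture_matrix(captures)
  b <- domain$bounds
  width <- max(b[2] - b[1], b[4] - b[3])
  n_det <- nrow(y)
  stopifnot(M > n_det)
  cen <- c(mean(b[1:2]), mean(b[3:4]))
  full <- ac_window(cen, width)
  # widen so every detector and the whole domain are strictly inside
  full <- new_window(b[1], b[1] + width + 1e-9, b[3], b[3] + width + 1e-9,
                     width + 1e-9)
  win <- dplyr::bind_rows(rep(list(full), M))
  idx_all <- seq_len(nrow(detectors))
  counts <- rep(length(idx_all), M)
  det_index <- matrix(rep(idx_all, each = M), nrow = M)
  windows <- tibble::tibble(
    individual = seq_len(M),
    kind = rep(c("detected", "augmented"), c(n_det, M - n_det)),
    x_lo = win$x_lo, x_hi = win$x_hi, y_lo = win$y_lo, y_hi = win$y_hi,
    width = win$width,
    dx_lo = win$x_lo, dx_hi = win$x_hi, dy_lo = win$y_lo, dy_hi = win$y_hi,
    n_detectors = counts,
    prop_habitat = vapply(seq_len(M), function(i) {
      prop_habitat(win[i, ], domain)
    }, numeric(1))
  )
  structure(
    list(windows = windows, detector_index = det_index,
         n_detectors = counts, n_detected = n_det, n_augmented = M - n_det,
         ac_width = width, extension = 0, n_layers = 1),
    class = "less_index"
  )
}

#' Export a LESS index to JSON
#'
#' Writes per-individual AC window bounds, detector counts, detector index
#' lists and habitat proportions.
#'
#' @param less A [less_index()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_less_index <- function(less, path) {
  M <- nrow(less$windows)
  obj <- list(
    n_detected = less$n_detected,
    n_augmented = less$n_augmented,
    ac_width = less$ac_width,
    extension = less$extension,
    n_layers = less$n_layers,
    xy_bounds = lapply(seq_len(M), function(i) {
      as.list(less$windows[i, c("x_lo", "x_hi", "y_lo", "y_hi")])
    }),
    n_detectors = less$n_detectors,
    detector_index = lapply(seq_len(M), function(i) {
      k <- less$n_detectors[i]
      if (k == 0) integer(0) else less$detector_index[i, seq_len(k)]
    }),
    prop_habitat = less$windows$prop_habitat
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
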