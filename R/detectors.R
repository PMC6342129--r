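#' Build a regular detector grid
#'
#' Detectors are laid out on a regular lattice, one row per detector, with
#' integer-multiples-of-`spacing` coordinates starting at `origin`. This is
#' the layout used throughout the simulation study: a `nx` by `ny` array of
#' detectors one distance unit (du) apart.
#'
#' @param nx,ny Number of detector columns / rows.
#' @param spacing Distance between neighbouring detectors (du).
#' @param origin Coordinate of the lower-left detector, `c(x, y)`.
#' @return A tibble with columns `detector_id`, `x`, `y`.
#' @examples
#' detector_grid(5, 5)
#' @export
detector_grid <- function(nx, ny = nx, spacing = 1, origin = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  g <- expand.grid(
    x = origin[1] + (seq_len(nx) - 1) * spacing,
    y = origin[2] + (seq_len(ny) - 1) * spacing
  )
  tibble::tibble(
    detector_id = seq_len(nrow(g)),
    x = g$x,
    y = g$y
  )
}

# spacing recovered from coordinates; regular grids only need it for the
# domain footprint (each detector is taken to sit at the centre of a
# spacing-sized cell).
detector_spacing <- function(detectors) {
  ux <- sort(unique(detectors$x))
  uy <- sort(unique(detectors$y))
  gaps <- c(diff(ux), diff(uy))
  if (length(gaps) == 0) {
    return(1)
  }
  min(gaps)
}

validate_detectors <- function(detectors) {
  stopifnot(is.data.frame(detectors))
  need <- c("detector_id", "x", "y")
  miss <- setdiff(need, names(detectors))
  if (length(miss) > 0) {
    stop("detector table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(detectors$detector_id) > 0) {
    stop("duplicated detector_id values")
  }
  if (anyDuplicated(detectors[, c("x", "y")]) > 0) {
    stop("detectors must have distinct coordinates")
  }
  invisible(detectors)
}
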