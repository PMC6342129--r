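#' Construct the spatial domain (state-space) of an SCR model
#'
#' The state-space S is the rectangle in which latent activity centers may
#' occur: the detector array footprint expanded by a buffer, overlaid with a
#' binary habitat raster (1 = suitable). Each detector is treated as the
#' centre of a `spacing`-sized cell, so a 50 x 50 unit-spaced array with a
#' 4-du buffer yields a 58 x 58-du domain.
#'
#' @param detectors Detector tibble (`detector_id`, `x`, `y`), or `NULL` if
#'   `bounds` is given directly.
#' @param buffer Buffer width (du) added on every side of the detector
#'   footprint. Cells within `buffer` of the domain edge are flagged as
#'   buffer cells and excluded from density-map comparisons.
#' @param cell_size Habitat raster resolution (du).
#' @param bounds Optional explicit bounds `c(x_min, x_max, y_min, y_max)`;
#'   overrides the detector-derived footprint.
#' @param habitat Optional binary matrix (rows = y from bottom, cols = x) that
#'   must tile `bounds` exactly; defaults to all-suitable.
#' @return An object of class `scr_domain`: a list with `bounds`, `buffer`,
#'   `cell_size`, `habitat` (binary matrix), and cell-center coordinate
#'   vectors `cell_x`, `cell_y`.
#' @export
scr_domain <- function(detectors = NULL, buffer = 4, cell_size = 1,
                       bounds = NULL, habitat = NULL) {
  if (is.null(bounds)) {
    if (is.null(detectors)) stop("supply either detectors or bounds")
    validate_detectors(detectors)
    sp <- detector_spacing(detectors)
    bounds <- c(
      min(detectors$x) - sp / 2 - buffer, max(detectors$x) + sp / 2 + buffer,
      min(detectors$y) - sp / 2 - buffer, max(detectors$y) + sp / 2 + buffer
    )
  }
  stopifnot(length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3])
  nx <- (bounds[2] - bounds[1]) / cell_size
  ny <- (bounds[4] - bounds[3]) / cell_size
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    stop("habitat raster of the given cell_size does not tile the bounds")
  }
  nx <- round(nx); ny <- round(ny)
  if (is.null(habitat)) {
    habitat <- matrix(1L, nrow = ny, ncol = nx)
  }
  stopifnot(is.matrix(habitat), nrow(habitat) == ny, ncol(habitat) == nx)
  storage.mode(habitat) <- "integer"
  if (!all(habitat %in% c(0L, 1L))) stop("habitat must be binary (0/1)")
  structure(
    list(
      bounds = as.numeric(bounds),
      buffer = buffer,
      cell_size = cell_size,
      habitat = habitat,
      cell_x = bounds[1] + (seq_len(nx) - 0.5) * cell_size,
      cell_y = bounds[3] + (seq_len(ny) - 0.5) * cell_size
    ),
    class = "scr_domain"
  )
}

#' @export
print.scr_domain <- function(x, ...) {
  b <- x$bounds
  cat(sprintf(
    "<scr_domain> %.6g x %.6g du, cell %.6g du, buffer %.6g du, %d/%d cells suitable\n",
    b[2] - b[1], b[4] - b[3], x$cell_size, x$buffer, sum(x$habitat), length(x$habitat)
  ))
  invisible(x)
}

#' Area of the suitable state-space
#'
#' @param domain An [scr_domain()].
#' @return Suitable area in du^2 (count of suitable cells times cell area).
#' @export
domain_area <- function(domain) {
  sum(domain$habitat) * domain$cell_size^2
}

# TRUE for cells whose center is within `buffer` of the domain edge
buffer_mask <- function(domain) {
  b <- domain$bounds
  inner <- c(b[1] + domain$buffer, b[2] - domain$buffer,
             b[3] + domain$buffer, b[4] - domain$buffer)
  cx <- matrix(domain$cell_x, nrow = nrow(domain$habitat),
               ncol = ncol(domain$habitat), byrow = TRUE)
  cy <- matrix(domain$cell_y, nrow = nrow(domain$habitat),
               ncol = ncol(domain$habitat))
  !(cx > inner[1] & cx < inner[2] & cy > inner[3] & cy < inner[4])
}

# is each point inside suitable habitat? points outside bounds -> FALSE
in_habitat <- function(x, y, domain) {
  b <- domain$bounds
  col <- floor((x - b[1]) / domain$cell_size) + 1
  row <- floor((y - b[3]) / domain$cell_size) + 1
  ok <- col >= 1 & col <= ncol(domain$habitat) &
    row >= 1 & row <= nrow(domain$habitat)
  out <- logical(length(x))
  idx <- which(ok)
  out[idx] <- domain$habitat[cbind(row[idx], col[idx])] == 1L
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ncols/nrows/xllcorner/yllcorner/cellsize header and
#' returns the values as a matrix with row 1 at the *bottom* (south), matching
#' the internal habitat convention.
#'
#' @param path Path to an `.asc` file.
#' @return A list with `values` (matrix, rows = y from bottom), `xll`, `yll`,
#'   `cell_size`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("malformed ESRI ASCII header at line ", i, ": ", lines[i])
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) {
    stop("ESRI ASCII header missing: ", paste(miss, collapse = ", "))
  }
  body <- lines[i:length(lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  if (anyNA(vals) || length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII body malformed starting at line ", i,
         ": expected ", hdr$ncols * hdr$nrows, " numeric values")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file is north-up
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cell_size = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values Matrix with row 1 at the bottom (south).
#' @param path Output path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cell_size Cell size.
#' @param nodata NODATA sentinel written in the header.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, xll, yll, cell_size,
                             nodata = -9999) {
  stopifnot(is.matrix(values))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a habitat mask into a spatial domain
#'
#' Reads a 0/1 ESRI ASCII grid and builds the corresponding [scr_domain()].
#' NODATA cells are treated as non-suitable.
#'
#' @param path Path to the `.asc` habitat mask.
#' @param buffer Buffer width (du) recorded on the domain (used for density
#'   map comparisons; the raster itself must already cover the buffer).
#' @return An [scr_domain()].
#' @export
read_habitat <- function(path, buffer = 0) {
  g <- read_ascii_grid(path)
  m <- g$values
  m[is.na(m)] <- 0
  if (!all(m %in% c(0, 1))) stop("habitat mask must contain only 0/1 values")
  bounds <- c(g$xll, g$xll + ncol(m) * g$cell_size,
              g$yll, g$yll + nrow(m) * g$cell_size)
  scr_domain(bounds = bounds, habitat = matrix(as.integer(m), nrow(m)),
             cell_size = g$cell_size, buffer = buffer)
}
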