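#' Read a detector table
#'
#' CSV with header `detector_id,x,y`; coordinates are point locations of
#' detector centers in the declared distance unit.
#'
#' @param path CSV path.
#' @return Detector tibble.
#' @export
read_detectors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("detector_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("detector file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0) {
    stop("detector file ", path, ": non-numeric coordinates at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  validate_detectors(tibble::as_tibble(df[, need]))
}

#' Write a detector table
#'
#' @param detectors Detector tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_detectors <- function(detectors, path) {
  validate_detectors(detectors)
  utils::write.csv(detectors[, c("detector_id", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read binary detections into a capture history
#'
#' CSV with header `individual_id,detector_id`, one row per detection
#' record. Duplicate (individual, detector) pairs collapse to a single
#' binary detection. Detector ids absent from the detector table are an
#' error.
#'
#' @param path CSV path.
#' @param detectors Detector tibble defining the detector order.
#' @return An `scr_captures` (binary matrix over all detectors, plus the
#'   long detection tibble).
#' @export
read_detections <- function(path, detectors) {
  validate_detectors(detectors)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "detector_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("detections file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no detected individuals in ", path)
  unknown <- setdiff(unique(df$detector_id), detectors$detector_id)
  if (length(unknown) > 0) {
    stop("unknown detector_id(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  df <- dplyr::distinct(df, .data$individual_id, .data$detector_id)
  ids <- sort(unique(df$individual_id))
  row <- match(df$individual_id, ids)
  col <- match(df$detector_id, detectors$detector_id)
  y <- matrix(0L, nrow = length(ids), ncol = nrow(detectors))
  y[cbind(row, col)] <- 1L
  new_scr_captures(
    y = y, detected_individual = ids, detector_id = detectors$detector_id,
    detections = tibble::tibble(individual_id = df$individual_id,
                                detector_id = df$detector_id)
  )
}

#' Write detections as a long CSV
#'
#' @param captures An `scr_captures`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(captures, path) {
  stopifnot(inherits(captures, "scr_captures"))
  utils::write.csv(captures$detections, path, row.names = FALSE)
  invisible(path)
}

#' Write a habitat mask or density map as an ESRI ASCII grid
#'
#' @param x An [scr_domain()] (writes the 0/1 habitat raster) or an
#'   `scr_density_map` (writes the density values).
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "scr_domain")) {
    write_ascii_grid(x$habitat, path, x$bounds[1], x$bounds[3], x$cell_size)
  } else if (inherits(x, "scr_density_map")) {
    d <- x$domain
    write_ascii_grid(x$values, path, d$bounds[1], d$bounds[3], d$cell_size)
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Write simulation truth to JSON
#'
#' @param truth An [sim_population()] result.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, N = truth$N, sigma = truth$sigma, p0 = truth$p0,
         ac = truth$ac),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write posterior samples, one CSV per chain
#'
#' Files are named `<stem>_chain<k>.csv` with columns `iteration`, `sigma`,
#' `p0`, `psi0`, `N`, `density`.
#'
#' @param fit An [scr_fit()].
#' @param stem Path stem (directory + file prefix).
#' @return Character vector of paths, invisibly.
#' @export
write_samples <- function(fit, stem) {
  stopifnot(inherits(fit, "scr_fit"))
  paths <- vapply(sort(unique(fit$samples$chain)), function(ch) {
    p <- paste0(stem, "_chain", ch, ".csv")
    utils::write.csv(
      dplyr::filter(fit$samples, .data$chain == ch)[
        , c("iteration", "sigma", "p0", "psi0", "N", "density")],
      p, row.names = FALSE
    )
    p
  }, character(1))
  invisible(paths)
}

#' Read a scenario configuration file
#'
#' YAML with the factorial design keys: detector grid (`nx`, `ny`,
#' `spacing`), `buffer`, `N_true` (list), `sigma`, `p0`,
#' `ac_width_sigma` (list), `extension_sigma` (list), `n_replicates`,
#' chain settings (`chains`, `iter`, `adapt`, `thin`), `seed`,
#' `augment_factor`, optional `include_full` (no-LESS reference).
#'
#' @param path YAML path.
#' @return Named list with defaults filled in.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    nx = 50, ny = 50, spacing = 1, buffer = 4, N_true = list(100),
    sigma = 2, p0 = 0.07, ac_width_sigma = list(5),
    extension_sigma = list(2), n_replicates = 1, chains = 3, iter = 3000,
    adapt = 1000, thin = 3, seed = 1, augment_factor = 4,
    include_full = FALSE, rhat_max = 1.1
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  num <- c("nx", "ny", "spacing", "buffer", "sigma", "p0", "n_replicates",
           "chains", "iter", "adapt", "thin", "seed", "augment_factor")
  bad <- num[vapply(num, function(k) !is.numeric(cfg[[k]]) || cfg[[k]] < 0,
                    logical(1))]
  if (length(bad) > 0) {
    stop("config ", path, ": non-numeric or negative value for ",
         paste(bad, collapse = ", "))
  }
  cfg
}
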