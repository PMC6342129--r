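#' Run one simulation replicate end to end
#'
#' Simulates a population and its binary detections, builds the LESS index,
#' fits the model, and returns per-parameter posterior summaries plus the
#' density-map error. The replicate is the unit of the factorial simulation
#' experiment.
#'
#' @param N_true True population size.
#' @param detectors Detector tibble.
#' @param domain An [scr_domain()].
#' @param sigma,p0 True detection parameters.
#' @param ac_width_sigma AC window width in units of sigma (e.g. 5).
#' @param extension_sigma Detector-window extension in units of sigma
#'   (e.g. 2).
#' @param seed Replicate seed (drives simulation and chain seeds).
#' @param full Fit the no-LESS reference model (domain-spanning windows)
#'   instead of the windowed one.
#' @param augment_factor Augmentation target multiplier (augmented count
#'   strictly exceeds `augment_factor * N_true`).
#' @param n_adapt,n_iter,n_chains,thin Chain protocol (defaults 1000 / 3000
#'   / 3 / 3).
#' @param compute_mre Also compute the true-vs-predicted density-map MRE.
#' @param draw_step Posterior-draw subsampling for the predicted map.
#' @return Tibble with one row per parameter (`N`, `sigma`, `p0`):
#'   `replicate`, `param`, `estimate`, `lo`, `hi`, `rhat_max_rep`, `mre`,
#'   `n_detected`, `detection_rate`, `runtime_s`.
#' @export
run_replicate <- function(N_true, detectors, domain, sigma = 2, p0 = 0.07,
                          ac_width_sigma = 5, extension_sigma = 2,
                          seed = 1, full = FALSE, augment_factor = 4,
                          n_adapt = 1000, n_iter = 3000, n_chains = 3,
                          thin = 3, compute_mre = TRUE, draw_step = 10) {
  truth <- sim_population(N_true, domain, sigma = sigma, p0 = p0,
                          seed = seed)
  captures <- sim_captures(truth, detectors)
  if (captures$n_detected == 0) stop("replicate produced no detections")
  if (full) {
    tiles <- tile_windows(domain, ac_width_sigma * sigma, 1)
    layers <- max(1L, floor(augment_factor * N_true / nrow(tiles)) + 1L)
    M <- captures$n_detected + nrow(tiles) * layers
    less <- less_index_full(captures, detectors, domain, M)
  } else {
    less <- less_index(captures, detectors, domain,
                       ac_width = ac_width_sigma * sigma,
                       extension = extension_sigma * sigma,
                       n_expected = N_true,
                       augment_factor = augment_factor)
  }
  fit <- scr_fit(captures, detectors, domain, less,
                 n_adapt = n_adapt, n_iter = n_iter, n_chains = n_chains,
                 thin = thin, seed = seed, save_sz = compute_mre)
  td <- tidy(fit)
  rh_max <- max(td$rhat, na.rm = TRUE)
  m <- NA_real_
  if (compute_mre) {
    m <- mre(true_density_map(truth, domain),
             predicted_density_map(fit, domain, draw_step = draw_step))
  }
  td |>
    dplyr::filter(.data$term %in% c("N", "sigma", "p0")) |>
    dplyr::transmute(
      replicate = seed,
      param = .data$term,
      estimate = .data$estimate,
      lo = .data$conf.low,
      hi = .data$conf.high,
      rhat_max_rep = rh_max,
      mre = m,
      n_detected = captures$n_detected,
      detection_rate = captures$n_detected / N_true,
      runtime_s = fit$runtime_s
    )
}

#' Run the factorial scenario grid
#'
#' Executes every scenario (AC width x detector extension x population
#' size, plus the optional no-LESS reference) for the configured number of
#' replicates, and reduces each scenario to relative bias, coefficient of
#' variation, coverage and mean MRE via [summarize_scenario()]. Replicate
#' `k` of a scenario uses seed `seed + k`; failures are logged and skipped
#' without aborting the grid. With `out_dir` set, per-replicate results are
#' checkpointed as CSV and re-used on rerun.
#'
#' @param config Config list (see [read_scenario_config()]) or a YAML path.
#' @param out_dir Optional checkpoint directory.
#' @param progress Print one line per replicate.
#' @return A list with `summary` (scenario x parameter tibble) and
#'   `replicates` (all per-replicate rows).
#' @export
run_scenario_grid <- function(config, out_dir = NULL, progress = FALSE) {
  if (is.character(config)) config <- read_scenario_config(config)
  if (is.null(config$rhat_max)) config$rhat_max <- 1.1
  detectors <- detector_grid(config$nx, config$ny, config$spacing)
  domain <- scr_domain(detectors, buffer = config$buffer,
                       cell_size = config$spacing)
  design <- tidyr::expand_grid(
    N_true = unlist(config$N_true),
    ac_width_sigma = unlist(config$ac_width_sigma),
    extension_sigma = unlist(config$extension_sigma),
    full = FALSE
  )
  if (isTRUE(config$include_full)) {
    design <- dplyr::bind_rows(
      design,
      tidyr::expand_grid(N_true = unlist(config$N_true),
                         ac_width_sigma = unlist(config$ac_width_sigma)[1],
                         extension_sigma = 0, full = TRUE)
    )
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  all_reps <- list()
  summaries <- list()
  for (srow in seq_len(nrow(design))) {
    sc <- design[srow, ]
    label <- sprintf("N%g_ac%g_ext%g%s", sc$N_true, sc$ac_width_sigma,
                     sc$extension_sigma, if (sc$full) "_full" else "")
    reps <- list()
    for (k in seq_len(config$n_replicates)) {
      rep_seed <- config$seed + k
      ck <- if (!is.null(out_dir)) {
        file.path(out_dir, paste0(label, "_rep", k, ".csv"))
      }
      if (!is.null(ck) && file.exists(ck)) {
        reps[[k]] <- tibble::as_tibble(utils::read.csv(ck))
        next
      }
      res <- tryCatch(
        run_replicate(
          N_true = sc$N_true, detectors = detectors, domain = domain,
          sigma = config$sigma, p0 = config$p0,
          ac_width_sigma = sc$ac_width_sigma,
          extension_sigma = sc$extension_sigma, seed = rep_seed,
          full = sc$full, augment_factor = config$augment_factor,
          n_adapt = config$adapt, n_iter = config$iter,
          n_chains = config$chains, thin = config$thin
        ),
        error = function(e) {
          warning("scenario ", label, " replicate ", k, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      if (is.null(res)) next
      if (!is.null(ck)) utils::write.csv(res, ck, row.names = FALSE)
      if (progress) {
        message(label, " rep ", k, ": N_hat = ",
                round(res$estimate[res$param == "N"], 1))
      }
      reps[[k]] <- res
    }
    reps <- dplyr::bind_rows(reps)
    all_reps[[label]] <- dplyr::mutate(reps, scenario = label)
    if (nrow(reps) > 0) {
      summaries[[label]] <- tryCatch(
        summarize_scenario(
          reps,
          truth = list(N = sc$N_true, sigma = config$sigma, p0 = config$p0),
          labels = list(scenario = label, N_true = sc$N_true,
                        ac_width_sigma = sc$ac_width_sigma,
                        extension_sigma = sc$extension_sigma,
                        full = sc$full),
          rhat_max = config$rhat_max
        ),
        error = function(e) {
          warning("scenario ", label, " could not be summarized: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
    }
    if (nrow(reps) == 0 || is.null(summaries[[label]])) {
      summaries[[label]] <- tibble::tibble(
        scenario = label, N_true = sc$N_true,
        ac_width_sigma = sc$ac_width_sigma,
        extension_sigma = sc$extension_sigma, full = sc$full,
        param = NA_character_, RB = NA_real_, CV = NA_real_,
        coverage = NA_real_, n_reps = 0L, MRE = NA_real_,
        n_excluded = 0L
      )
    }
  }
  list(summary = dplyr::bind_rows(summaries),
       replicates = dplyr::bind_rows(all_reps))
}
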