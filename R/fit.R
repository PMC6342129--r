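#' Fit a Bayesian SCR model with local evaluation of the state-space
#'
#' Metropolis-within-Gibbs sampler for the data-augmented SCR model: binary
#' detections follow a half-normal detection function of the distance to a
#' latent activity center; activity centers are uniform over suitable
#' habitat; augmented individuals carry inclusion flags
#' `z_i ~ Bernoulli(psi_i)` with the habitat-proportion correction
#' [psi_individual()]; abundance is `N = sum(z)` and density `N / area(S)`.
#' Each individual's likelihood is evaluated only over the detectors in its
#' LESS detector window, and its activity center is confined to its AC
#' window (reflected random-walk proposals) and to suitable habitat
#' (proposal rejection). A classical no-LESS fit is the same sampler run
#' with domain-spanning windows ([scr_fit_full()]).
#'
#' Priors: `p0 ~ Uniform(0, 1)`, `sigma ~ Uniform(0, sigma_max)` (default
#' `sigma_max` = AC window width), `psi0 ~ Uniform(0, 1)`. Proposal scales
#' adapt toward 0.35 acceptance during the adaptive phase only, so the
#' recorded chains satisfy detailed balance.
#'
#' @param captures An [sim_captures()] result or binary individuals x
#'   detectors matrix.
#' @param detectors Detector tibble (`detector_id`, `x`, `y`).
#' @param domain An [scr_domain()].
#' @param less A [less_index()] whose first `n_detected` rows align with
#'   `captures`.
#' @param n_adapt Adaptive-phase iterations (default 1000).
#' @param n_iter Post-adaptation iterations per chain (default 3000).
#' @param n_chains Number of independent chains (default 3).
#' @param thin Thinning interval (default 3); `floor(n_iter / thin)` samples
#'   are kept per chain.
#' @param seed Master seed; chain `c` uses
#'   `(seed + 7919 * (c - 1)) %% 2^31` so chains are independent but the
#'   whole fit is reproducible.
#' @param sigma_max Upper bound of the uniform prior on sigma (du); defaults
#'   to the AC window width.
#' @param save_sz Keep thinned draws of activity centers and inclusion flags
#'   (needed for [predicted_density_map()]).
#' @param updates Named logical list enabling/disabling parameter blocks
#'   (`s`, `z`, `sigma`, `p0`, `psi0`); used to freeze parameters in
#'   validation runs.
#' @param init Optional named list overriding initial values (`sigma`, `p0`,
#'   `psi0`, `s_x`, `s_y`, `z`), applied to every chain.
#' @return An object of class `scr_fit` with elements `samples` (tibble:
#'   `chain`, `iteration`, `sigma`, `p0`, `psi0`, `N`, `density`), `draws`
#'   (per chain: `s_x`, `s_y`, `z` matrices of thinned draws), `accept`,
#'   `proposal_sd`, `seeds`, `config`, `runtime_s`.
#' @export
scr_fit <- function(captures, detectors, domain, less,
                    n_adapt = 1000, n_iter = 3000, n_chains = 3, thin = 3,
                    seed = 1, sigma_max = NULL, save_sz = TRUE,
                    updates = NULL, init = NULL) {
  t0 <- proc.time()[["elapsed"]]
  y <- capture_matrix(captures)
  validate_detectors(detectors)
  stopifnot(inherits(less, "less_index"), inherits(domain, "scr_domain"))
  if (nrow(y) != less$n_detected) {
    stop("capture history has ", nrow(y), " rows but the LESS index was ",
         "built for ", less$n_detected, " detected individuals")
  }
  M <- less$n_detected + less$n_augmented
  n_detected <- less$n_detected
  if (is.null(sigma_max)) sigma_max <- less$ac_width
  stopifnot(sigma_max > 0, n_adapt >= 0, n_iter >= 0, thin >= 1,
            n_chains >= 1)

  up <- list(s = TRUE, z = TRUE, sigma = TRUE, p0 = TRUE, psi0 = TRUE)
  if (!is.null(updates)) up[names(updates)] <- updates

  # per-individual detections aligned to the detector index
  pad <- ncol(less$detector_index)
  y_local <- matrix(0L, nrow = M, ncol = pad)
  for (i in seq_len(n_detected)) {
    k <- less$n_detectors[i]
    if (k > 0) y_local[i, seq_len(k)] <- y[i, less$detector_index[i, seq_len(k)]]
  }
  miss <- rowSums(y) - rowSums(y_local[seq_len(n_detected), , drop = FALSE])
  if (n_detected > 0 && any(miss > 0)) {
    stop("detections outside the detector window for individual(s) ",
         paste(which(miss > 0), collapse = ", "))
  }

  ac_bounds <- as.matrix(less$windows[, c("x_lo", "x_hi", "y_lo", "y_hi")])
  crude <- crude_start_values(y, detectors, less)
  chain_seeds <- (seed + 7919 * (seq_len(n_chains) - 1)) %% 2147483647

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    ini <- initial_state(less, domain, crude, sigma_max)
    if (!is.null(init)) ini[names(init)] <- init
    chains[[ch]] <- scr_mcmc_cpp(
      y = y_local, det_index = less$detector_index,
      n_det = as.integer(less$n_detectors),
      det_x = detectors$x, det_y = detectors$y,
      ac_bounds = ac_bounds, prop_hab = less$windows$prop_habitat,
      n_detected = as.integer(n_detected),
      habitat = domain$habitat, hab_x0 = domain$bounds[1],
      hab_y0 = domain$bounds[3], cell_size = domain$cell_size,
      init = ini[c("s_x", "s_y", "z", "sigma", "p0", "psi0")],
      sigma_max = sigma_max, n_adapt = as.integer(n_adapt),
      n_iter = as.integer(n_iter), thin = as.integer(thin),
      updates = up, save_sz = save_sz,
      s_sd_init = crude$sigma / 2
    )
  }

  area_s <- domain_area(domain)
  n_keep <- n_iter %/% thin
  samples <- purrr::map_dfr(seq_len(n_chains), function(ch) {
    r <- chains[[ch]]
    tibble::tibble(
      chain = ch,
      iteration = seq_len(n_keep),
      sigma = as.numeric(r$sigma),
      p0 = as.numeric(r$p0),
      psi0 = as.numeric(r$psi0),
      N = as.integer(r$N),
      density = as.integer(r$N) / area_s
    )
  })

  structure(
    list(
      samples = samples,
      draws = lapply(chains, function(r) {
        list(s_x = r$s_x, s_y = r$s_y, z = r$z)
      }),
      accept = lapply(chains, `[[`, "accept"),
      proposal_sd = lapply(chains, `[[`, "proposal_sd"),
      seeds = list(master = seed, chains = chain_seeds),
      config = list(
        M = M, n_detected = n_detected, n_augmented = less$n_augmented,
        ac_width = less$ac_width, extension = less$extension,
        n_layers = less$n_layers, sigma_max = sigma_max,
        n_adapt = n_adapt, n_iter = n_iter, n_chains = n_chains,
        thin = thin, area_s = area_s, save_sz = save_sz
      ),
      runtime_s = proc.time()[["elapsed"]] - t0
    ),
    class = "scr_fit"
  )
}

#' Fit the classical SCR model without local evaluation
#'
#' Runs the identical sampler with AC and detector windows spanning the
#' whole state-space, i.e. every detector enters every individual's
#' likelihood and activity centers roam the full domain. Serves as the
#' reference ("without LESS") model.
#'
#' @inheritParams scr_fit
#' @param M Total number of individuals after augmentation.
#' @param ... Passed to [scr_fit()].
#' @return An `scr_fit`.
#' @export
scr_fit_full <- function(captures, detectors, domain, M, ...) {
  less <- less_index_full(captures, detectors, domain, M)
  scr_fit(captures, detectors, domain, less, ...)
}

crude_start_values <- function(y, detectors, less) {
  n_detected <- nrow(y)
  sig <- NA_real_
  if (n_detected > 0) {
    sp <- numeric(0)
    for (i in seq_len(n_detected)) {
      hit <- which(y[i, ] > 0)
      if (length(hit) >= 2) {
        cx <- mean(detectors$x[hit]); cy <- mean(detectors$y[hit])
        sp <- c(sp, mean((detectors$x[hit] - cx)^2 +
                           (detectors$y[hit] - cy)^2) / 2)
      }
    }
    if (length(sp) > 0) sig <- sqrt(mean(sp))
  }
  if (!is.finite(sig) || sig <= 0) sig <- less$ac_width / 5
  p0 <- if (n_detected > 0) {
    min(0.5, max(0.01, sum(y) / (n_detected * 2 * pi * sig^2)))
  } else {
    0.1
  }
  list(sigma = sig, p0 = p0)
}

initial_state <- function(less, domain, crude, sigma_max) {
  M <- less$n_detected + less$n_augmented
  w <- less$windows
  s_x <- numeric(M)
  s_y <- numeric(M)
  z <- integer(M)
  for (i in seq_len(M)) {
    detected <- i <= less$n_detected
    cx <- (w$x_lo[i] + w$x_hi[i]) / 2
    cy <- (w$y_lo[i] + w$y_hi[i]) / 2
    if (w$prop_habitat[i] <= 0) {
      if (detected) {
        stop("AC window of detected individual ", i,
             " contains no suitable habitat")
      }
      s_x[i] <- cx; s_y[i] <- cy; z[i] <- 0L
      next
    }
    pt <- place_in_habitat(cx, cy, w$x_lo[i], w$x_hi[i], w$y_lo[i],
                           w$y_hi[i], domain)
    s_x[i] <- pt[1]; s_y[i] <- pt[2]
    z[i] <- if (detected) 1L else stats::rbinom(1, 1, 0.5)
  }
  sigma <- min(crude$sigma * exp(stats::runif(1, -0.4, 0.4)),
               0.95 * sigma_max)
  p0 <- min(0.95, max(1e-3, crude$p0 * exp(stats::runif(1, -0.5, 0.5))))
  psi0 <- min(0.9, max(0.05,
                       (2 * less$n_detected + 1) / (M + 2) *
                         exp(stats::runif(1, -0.3, 0.3))))
  list(s_x = s_x, s_y = s_y, z = z, sigma = sigma, p0 = p0, psi0 = psi0)
}

# start near `center`, fall back to rejection sampling, then to the nearest
# suitable cell center inside the window
place_in_habitat <- function(cx, cy, x_lo, x_hi, y_lo, y_hi, domain) {
  if (in_habitat(cx, cy, domain)) {
    return(c(cx, cy))
  }
  for (t in seq_len(200)) {
    px <- stats::runif(1, x_lo, x_hi)
    py <- stats::runif(1, y_lo, y_hi)
    if (in_habitat(px, py, domain)) {
      return(c(px, py))
    }
  }
  gx <- rep(domain$cell_x, each = length(domain$cell_y))
  gy <- rep(domain$cell_y, times = length(domain$cell_x))
  ok <- which(as.vector(domain$habitat) == 1L & gx >= x_lo & gx < x_hi &
                gy >= y_lo & gy < y_hi)
  if (length(ok) == 0) stop("no suitable habitat inside the AC window")
  d2 <- (gx[ok] - cx)^2 + (gy[ok] - cy)^2
  best <- ok[which.min(d2)]
  c(gx[best], gy[best])
}

#' @export
print.scr_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<scr_fit> %d chains x %d kept iterations; M = %d (%d detected)\n",
    cfg$n_chains, cfg$n_iter %/% cfg$thin, cfg$M, cfg$n_detected
  ))
  if (nrow(x$samples) > 0) {
    s <- dplyr::summarise(
      x$samples,
      N = mean(.data$N), sigma = mean(.data$sigma), p0 = mean(.data$p0)
    )
    cat(sprintf("  posterior means: N = %.1f, sigma = %.3f, p0 = %.4f\n",
                s$N, s$sigma, s$p0))
  }
  invisible(x)
}
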