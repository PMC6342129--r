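#' Per-individual inclusion probability under the habitat correction
#'
#' Individuals whose AC window contains little suitable habitat are less
#' likely to be part of the population: `psi_i = 1 - (1 - psi0)^prop`, where
#' `prop` is the proportion of suitable habitat in the individual's AC
#' window. With `prop = 1` this reduces to `psi0`; with `prop = 0` inclusion
#' is impossible. The correction keeps the augmented activity-center density
#' constant per unit of *suitable* area, which is what makes density
#' estimates unbiased when windows overlap non-habitat or protrude past the
#' state-space edge.
#'
#' @param psi0 Baseline inclusion probability in `[0, 1]`.
#' @param prop Proportion of suitable habitat in the AC window, in `[0, 1]`.
#' @return Inclusion probability/ies.
#' @export
psi_individual <- function(psi0, prop) {
  if (any(psi0 < 0 | psi0 > 1)) stop("psi0 must be in [0, 1]")
  if (any(prop < 0 | prop > 1)) stop("prop must be in [0, 1]")
  1 - (1 - psi0)^prop
}

#' Local detection log-likelihood of one individual
#'
#' Bernoulli log-likelihood of individual `i`'s detections/non-detections,
#' summed over the detectors in its LESS detector index only; detectors
#' outside the detector window contribute nothing (this truncation is the
#' LESS approximation). With `z = 0` detections are impossible and the
#' all-zero history has log-probability 0.
#'
#' This is the plain-R reference implementation; the MCMC sampler evaluates
#' the same quantity in compiled code.
#'
#' @param i Individual index (1-based row of the LESS index).
#' @param s Activity-center coordinates `c(x, y)`.
#' @param z Inclusion indicator (0/1).
#' @param y_local Binary detection vector aligned with the individual's
#'   detector index (length `less$n_detectors[i]`).
#' @param less A [less_index()].
#' @param detectors Detector tibble.
#' @param sigma,p0 Detection parameters.
#' @return Log-likelihood (scalar).
#' @export
loglik_individual <- function(i, s, z, y_local, less, detectors, sigma, p0) {
  k <- less$n_detectors[i]
  stopifnot(length(y_local) == k)
  if (z == 0) {
    if (any(y_local > 0)) {
      stop("individual ", i, " has detections but z = 0")
    }
    return(0)
  }
  if (k == 0) {
    return(0)
  }
  j <- less$detector_index[i, seq_len(k)]
  d2 <- (detectors$x[j] - s[1])^2 + (detectors$y[j] - s[2])^2
  p <- p0 * exp(-d2 / (2 * sigma^2))
  sum(ifelse(y_local == 1, log(p), log1p(-p)))
}

#' Full conditional probability that an augmented individual is included
#'
#' For an augmented (all-zero history) individual,
#' `P(z = 1 | .) = psi_i * q_i / (psi_i * q_i + 1 - psi_i)` with
#' `q_i = prod_j (1 - p_ij)` over the detectors in its index: the inclusion
#' prior weighted by the probability of having been missed everywhere. The
#' sampler draws `z` exactly from this two-point distribution.
#'
#' @param psi_i Inclusion probability of the individual ([psi_individual()]).
#' @param q_i Probability of no detection at any indexed detector.
#' @return `P(z = 1 | .)`.
#' @export
z_full_conditional <- function(psi_i, q_i) {
  stopifnot(all(psi_i >= 0 & psi_i <= 1), all(q_i >= 0 & q_i <= 1))
  a <- psi_i * q_i
  ifelse(psi_i == 0, 0, a / (a + 1 - psi_i))
}
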