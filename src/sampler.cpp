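#include <Rcpp.h>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for Bayesian SCR with data augmentation
// and local evaluation of the individual state-space. Each individual's
// detection likelihood is summed over its own detector index list only, and
// its activity center is confined to its AC window (reflected random walk)
// and to suitable habitat (proposal rejection). Distances are computed
// lazily per individual per proposal; no full distance matrix is ever
// formed.

static inline double reflect_into(double x, double lo, double hi) {
  // fold a real onto [lo, hi] by repeated reflection at the boundaries
  double w = hi - lo;
  double period = 2.0 * w;
  double u = x - lo;
  double t = u - period * std::floor(u / period);
  if (t > w) t = period - t;
  return lo + t;
}

struct ScrData {
  const IntegerMatrix &y;          // M x pad, aligned to det_index
  const IntegerMatrix &det_index;  // M x pad, 1-based, 0 = padding
  const IntegerVector &n_det;      // detectors per individual
  const NumericVector &det_x, &det_y;
  int M, n_detected;
};

static inline double loglik_one(const ScrData &d, int i, double sx, double sy,
                                double sigma, double p0) {
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double ll = 0.0;
  const int k = d.n_det[i];
  for (int t = 0; t < k; ++t) {
    const int j = d.det_index(i, t) - 1;
    const double dx = d.det_x[j] - sx;
    const double dy = d.det_y[j] - sy;
    const double p = p0 * std::exp(-(dx * dx + dy * dy) * inv2s2);
    if (d.y(i, t) == 1) {
      ll += std::log(p);
    } else {
      ll += std::log1p(-p);
    }
  }
  return ll;
}

static inline bool habitat_ok(double x, double y, const IntegerMatrix &hab,
                              double x0, double y0, double cs) {
  const int col = (int)std::floor((x - x0) / cs);
  const int row = (int)std::floor((y - y0) / cs);
  if (row < 0 || row >= hab.nrow() || col < 0 || col >= hab.ncol())
    return false;
  return hab(row, col) == 1;
}

// [[Rcpp::export]]
List scr_mcmc_cpp(IntegerMatrix y, IntegerMatrix det_index,
                  IntegerVector n_det, NumericVector det_x,
                  NumericVector det_y, NumericMatrix ac_bounds,
                  NumericVector prop_hab, int n_detected,
                  IntegerMatrix habitat, double hab_x0, double hab_y0,
                  double cell_size, List init, double sigma_max,
                  int n_adapt, int n_iter, int thin, List updates,
                  bool save_sz, double s_sd_init) {
  const int M = det_index.nrow();
  ScrData d{y, det_index, n_det, det_x, det_y, M, n_detected};

  NumericVector s_x = clone(as<NumericVector>(init["s_x"]));
  NumericVector s_y = clone(as<NumericVector>(init["s_y"]));
  IntegerVector z = clone(as<IntegerVector>(init["z"]));
  double sigma = as<double>(init["sigma"]);
  double p0 = as<double>(init["p0"]);
  double psi0 = as<double>(init["psi0"]);

  const bool up_s = as<bool>(updates["s"]);
  const bool up_z = as<bool>(updates["z"]);
  const bool up_sigma = as<bool>(updates["sigma"]);
  const bool up_p0 = as<bool>(updates["p0"]);
  const bool up_psi0 = as<bool>(updates["psi0"]);

  // individuals whose AC window holds no suitable habitat never enter the
  // population (psi_i = 0 forces z = 0)
  std::vector<bool> dead(M);
  for (int i = 0; i < M; ++i) {
    dead[i] = (prop_hab[i] <= 0.0);
    if (dead[i] && i >= n_detected) z[i] = 0;
    if (dead[i] && i < n_detected)
      stop("detected individual %d has an AC window without suitable habitat",
           i + 1);
  }

  std::vector<double> L(M);  // detection loglik at current s given z_i = 1
  std::vector<bool> Lvalid(M, false);
  for (int i = 0; i < M; ++i) {
    if (dead[i]) continue;
    L[i] = loglik_one(d, i, s_x[i], s_y[i], sigma, p0);
    Lvalid[i] = true;
    if (i < n_detected && !std::isfinite(L[i]))
      stop("non-finite detection log-likelihood at initialization "
           "(individual %d); check initial sigma/p0 and windows", i + 1);
  }

  // proposal scales, Robbins-Monro adapted toward 0.35 acceptance
  std::vector<double> sd_s(M, s_sd_init);
  double sd_sigma = 0.1, sd_p0 = 0.2, sd_psi0 = 0.2;
  const double target = 0.35;
  const int batch = 50;
  std::vector<int> acc_s(M, 0);
  int try_count = 0, acc_sigma = 0, acc_p0 = 0, acc_psi0 = 0;
  // post-adaptation tallies
  long post_s_acc = 0, post_s_try = 0;
  long post_acc_sigma = 0, post_acc_p0 = 0, post_acc_psi0 = 0, post_try = 0;

  const int n_keep = (thin > 0) ? n_iter / thin : 0;
  NumericVector out_sigma(n_keep), out_p0(n_keep), out_psi0(n_keep);
  IntegerVector out_N(n_keep);
  NumericMatrix out_sx(save_sz ? n_keep : 0, save_sz ? M : 0);
  NumericMatrix out_sy(save_sz ? n_keep : 0, save_sz ? M : 0);
  IntegerMatrix out_z(save_sz ? n_keep : 0, save_sz ? M : 0);

  int keep = 0;
  const int total_iter = n_adapt + n_iter;
  for (int iter = 0; iter < total_iter; ++iter) {
    const bool adapting = iter < n_adapt;
    if (!adapting) ++post_try;

    if (up_s) {
      for (int i = 0; i < M; ++i) {
        if (dead[i]) continue;
        const double xl = ac_bounds(i, 0), xh = ac_bounds(i, 1);
        const double yl = ac_bounds(i, 2), yh = ac_bounds(i, 3);
        double px = reflect_into(s_x[i] + norm_rand() * sd_s[i], xl, xh);
        double py = reflect_into(s_y[i] + norm_rand() * sd_s[i], yl, yh);
        bool accept = false;
        if (habitat_ok(px, py, habitat, hab_x0, hab_y0, cell_size)) {
          if (z[i] == 1) {
            const double Lp = loglik_one(d, i, px, py, sigma, p0);
            if (std::log(unif_rand()) < Lp - L[i]) {
              L[i] = Lp;
              accept = true;
            }
          } else {
            // flat target over the window when excluded from the population
            accept = true;
            Lvalid[i] = false;
          }
        }
        if (accept) {
          s_x[i] = px;
          s_y[i] = py;
          if (!adapting) ++post_s_acc;
          if (adapting) ++acc_s[i];
        }
        if (!adapting) ++post_s_try;
      }
    }

    if (up_sigma) {
      const double sp = sigma * std::exp(norm_rand() * sd_sigma);
      if (sp < sigma_max) {
        double lr = std::log(sp) - std::log(sigma);  // log-scale Jacobian
        std::vector<double> Lp(M);
        bool finite = true;
        for (int i = 0; i < M && finite; ++i) {
          if (z[i] != 1) continue;
          Lp[i] = loglik_one(d, i, s_x[i], s_y[i], sp, p0);
          lr += Lp[i] - L[i];
          if (!std::isfinite(Lp[i])) finite = false;
        }
        if (finite && std::log(unif_rand()) < lr) {
          sigma = sp;
          for (int i = 0; i < M; ++i) {
            if (z[i] == 1) {
              L[i] = Lp[i];
            } else {
              Lvalid[i] = false;
            }
          }
          if (adapting) ++acc_sigma; else ++post_acc_sigma;
        }
      }
    }

    if (up_p0) {
      const double lg = std::log(p0 / (1.0 - p0)) + norm_rand() * sd_p0;
      const double pp = 1.0 / (1.0 + std::exp(-lg));
      double lr = std::log(pp * (1.0 - pp)) - std::log(p0 * (1.0 - p0));
      std::vector<double> Lp(M);
      bool finite = true;
      for (int i = 0; i < M && finite; ++i) {
        if (z[i] != 1) continue;
        Lp[i] = loglik_one(d, i, s_x[i], s_y[i], sigma, pp);
        lr += Lp[i] - L[i];
        if (!std::isfinite(Lp[i])) finite = false;
      }
      if (finite && std::log(unif_rand()) < lr) {
        p0 = pp;
        for (int i = 0; i < M; ++i) {
          if (z[i] == 1) {
            L[i] = Lp[i];
          } else {
            Lvalid[i] = false;
          }
        }
        if (adapting) ++acc_p0; else ++post_acc_p0;
      }
    }

    if (up_z) {
      // exact Gibbs draw from the full conditional of each augmented z_i
      for (int i = n_detected; i < M; ++i) {
        if (dead[i]) continue;
        if (!Lvalid[i]) {
          L[i] = loglik_one(d, i, s_x[i], s_y[i], sigma, p0);
          Lvalid[i] = true;
        }
        const double psi_i = 1.0 - std::pow(1.0 - psi0, prop_hab[i]);
        const double a = psi_i * std::exp(L[i]);
        const double pz1 = a / (a + 1.0 - psi_i);
        z[i] = (unif_rand() < pz1) ? 1 : 0;
      }
    }

    if (up_psi0) {
      const double lg =
          std::log(psi0 / (1.0 - psi0)) + norm_rand() * sd_psi0;
      const double pp = 1.0 / (1.0 + std::exp(-lg));
      double lr =
          std::log(pp * (1.0 - pp)) - std::log(psi0 * (1.0 - psi0));
      for (int i = 0; i < M; ++i) {
        if (dead[i]) continue;
        if (z[i] == 1) {
          lr += std::log(1.0 - std::pow(1.0 - pp, prop_hab[i])) -
                std::log(1.0 - std::pow(1.0 - psi0, prop_hab[i]));
        } else {
          lr += prop_hab[i] * (std::log1p(-pp) - std::log1p(-psi0));
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        psi0 = pp;
        if (adapting) ++acc_psi0; else ++post_acc_psi0;
      }
    }

    if (adapting) {
      ++try_count;
      if (try_count == batch) {
        for (int i = 0; i < M; ++i) {
          const double rate = (double)acc_s[i] / batch;
          sd_s[i] *= std::exp(rate - target);
          const double wmax =
              std::max(ac_bounds(i, 1) - ac_bounds(i, 0), cell_size);
          if (sd_s[i] < 1e-3) sd_s[i] = 1e-3;
          if (sd_s[i] > 2.0 * wmax) sd_s[i] = 2.0 * wmax;
          acc_s[i] = 0;
        }
        sd_sigma *= std::exp((double)acc_sigma / batch - target);
        sd_p0 *= std::exp((double)acc_p0 / batch - target);
        sd_psi0 *= std::exp((double)acc_psi0 / batch - target);
        sd_sigma = std::min(std::max(sd_sigma, 1e-3), 5.0);
        sd_p0 = std::min(std::max(sd_p0, 1e-3), 5.0);
        sd_psi0 = std::min(std::max(sd_psi0, 1e-3), 5.0);
        acc_sigma = acc_p0 = acc_psi0 = 0;
        try_count = 0;
      }
    } else {
      const int it1 = iter - n_adapt + 1;
      if (thin > 0 && it1 % thin == 0 && keep < n_keep) {
        out_sigma[keep] = sigma;
        out_p0[keep] = p0;
        out_psi0[keep] = psi0;
        int N = 0;
        for (int i = 0; i < M; ++i) N += z[i];
        out_N[keep] = N;
        if (save_sz) {
          for (int i = 0; i < M; ++i) {
            out_sx(keep, i) = s_x[i];
            out_sy(keep, i) = s_y[i];
            out_z(keep, i) = z[i];
          }
        }
        ++keep;
      }
    }
  }

  return List::create(
      _["sigma"] = out_sigma, _["p0"] = out_p0, _["psi0"] = out_psi0,
      _["N"] = out_N, _["s_x"] = out_sx, _["s_y"] = out_sy, _["z"] = out_z,
      _["accept"] = List::create(
          _["s"] = post_s_try > 0 ? (double)post_s_acc / post_s_try
                                  : NA_REAL,
          _["sigma"] = post_try > 0 ? (double)post_acc_sigma / post_try
                                    : NA_REAL,
          _["p0"] = post_try > 0 ? (double)post_acc_p0 / post_try : NA_REAL,
          _["psi0"] = post_try > 0 ? (double)post_acc_psi0 / post_try
                                   : NA_REAL),
      _["proposal_sd"] = List::create(
          _["s_mean"] = std::accumulate(sd_s.begin(), sd_s.end(), 0.0) / M,
          _["sigma"] = sd_sigma, _["p0"] = sd_p0, _["psi0"] = sd_psi0));
}

// Total detection log-likelihood over included individuals, using the same
// local detector indexing as the sampler. Exposed for cross-checks against
// the R reference implementation.
// [[Rcpp::export]]
double loglik_total_cpp(IntegerMatrix y, IntegerMatrix det_index,
                        IntegerVector n_det, NumericVector det_x,
                        NumericVector det_y, NumericVector s_x,
                        NumericVector s_y, IntegerVector z, double sigma,
                        double p0, int n_detected) {
  const int M = det_index.nrow();
  ScrData d{y, det_index, n_det, det_x, det_y, M, n_detected};
  double ll = 0.0;
  for (int i = 0; i < M; ++i) {
    if (z[i] == 1) ll += loglik_one(d, i, s_x[i], s_y[i], sigma, p0);
  }
  return ll;
}

// Half-normal kernel surface summed over activity centers, evaluated at the
// habitat cell centers. Returns values column-major (rows = y from bottom).
// [[Rcpp::export]]
NumericVector density_map_cpp(NumericVector acx, NumericVector acy,
                              double sigma, NumericVector cell_x,
                              NumericVector cell_y) {
  const int nx = cell_x.size(), ny = cell_y.size(), n = acx.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericVector out(nx * ny);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      double v = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dx = cell_x[c] - acx[i];
        const double dy = cell_y[r] - acy[i];
        v += std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
      out[c * ny + r] = v;
    }
  }
  return out;
}

// Posterior-averaged density surface: per draw, kernels of z = 1
// individuals with that draw's sigma, averaged over draws.
// [[Rcpp::export]]
NumericVector predicted_density_cpp(NumericMatrix s_x, NumericMatrix s_y,
                                    IntegerMatrix z, NumericVector sigma,
                                    NumericVector cell_x,
                                    NumericVector cell_y) {
  const int ndraw = s_x.nrow(), M = s_x.ncol();
  const int nx = cell_x.size(), ny = cell_y.size();
  NumericVector out(nx * ny);
  if (ndraw == 0) return out;
  for (int t = 0; t < ndraw; ++t) {
    const double inv2s2 = 1.0 / (2.0 * sigma[t] * sigma[t]);
    for (int i = 0; i < M; ++i) {
      if (z(t, i) != 1) continue;
      const double sx = s_x(t, i), sy = s_y(t, i);
      for (int c = 0; c < nx; ++c) {
        const double dx = cell_x[c] - sx;
        const double dx2 = dx * dx;
        for (int r = 0; r < ny; ++r) {
          const double dy = cell_y[r] - sy;
          out[c * ny + r] += std::exp(-(dx2 + dy * dy) * inv2s2);
        }
      }
    }
  }
  for (int k = 0; k < nx * ny; ++k) out[k] /= ndraw;
  return out;
}
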