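#include <Rcpp.h>
using namespace Rcpp;

// Renewal bookkeeping for the cyton family of models on a uniform time grid.
// All fluxes are rates (cells/hour); integrals use the trapezoid rule so that
// halving dt changes reported counts only at O(dt^2).

static void cumtrap(const std::vector<double>& f, std::vector<double>& out,
                    double dt) {
  const int n = (int)f.size();
  out[0] = 0.0;
  for (int k = 1; k < n; ++k)
    out[k] = out[k - 1] + 0.5 * dt * (f[k - 1] + f[k]);
}

// (src * ker)(t_k) with trapezoid end-weights; both defined on the same grid.
static void conv_trap(const std::vector<double>& src,
                      const std::vector<double>& ker,
                      std::vector<double>& out, double dt) {
  const int n = (int)src.size();
  out[0] = 0.0;
  for (int k = 1; k < n; ++k) {
    double acc = 0.5 * (src[0] * ker[k] + src[k] * ker[0]);
    for (int j = 1; j < k; ++j) acc += src[j] * ker[k - j];
    out[k] = acc * dt;
  }
}

// [[Rcpp::export(name = ".sim_grid_cpp")]]
List sim_grid_cpp(double N, double F0, NumericVector Fg, NumericVector phi0,
                  NumericVector phi1, NumericVector psi0, NumericVector psi1,
                  NumericVector Phi1, NumericVector Psi0, NumericVector Psi1,
                  NumericVector Phi0, double dt, int g_max, bool competing) {
  const int n = phi0.size();
  NumericMatrix counts(g_max, n);
  NumericVector cum_div(n), cum_die(n);

  const std::vector<double> vphi1(phi1.begin(), phi1.end());
  const std::vector<double> vpsi1(psi1.begin(), psi1.end());

  std::vector<double> ndiv_prev(n), ndiv(n), ndie(n), born(n);
  std::vector<double> tmp(n), cum1(n), cum2(n), ker(n);

  // generation 0: founders leave by responding (division) or not (death)
  for (int k = 0; k < n; ++k) {
    if (competing) {
      ndiv_prev[k] = N * F0 * phi0[k] * (1.0 - Psi0[k]);
      ndie[k] = N * psi0[k] * (1.0 - F0 * Phi0[k]);
    } else {
      ndiv_prev[k] = N * F0 * phi0[k];
      ndie[k] = N * (1.0 - F0) * psi0[k];
    }
  }
  for (int k = 0; k < n; ++k) tmp[k] = ndiv_prev[k] + ndie[k];
  cumtrap(tmp, cum1, dt);
  for (int k = 0; k < n; ++k) counts(0, k) = N - cum1[k];
  cumtrap(ndiv_prev, cum1, dt);
  cumtrap(ndie, cum2, dt);
  for (int k = 0; k < n; ++k) {
    cum_div[k] += cum1[k];
    cum_die[k] += cum2[k];
  }

  for (int g = 1; g < g_max; ++g) {
    const double F = Fg[g - 1];
    for (int k = 0; k < n; ++k) born[k] = 2.0 * ndiv_prev[k];

    const bool terminal = (g == g_max - 1);
    if (terminal) {
      std::fill(ndiv.begin(), ndiv.end(), 0.0);
    } else if (competing) {
      for (int k = 0; k < n; ++k) ker[k] = vphi1[k] * (1.0 - Psi1[k]);
      conv_trap(born, ker, ndiv, dt);
      for (int k = 0; k < n; ++k) ndiv[k] *= F;
    } else {
      conv_trap(born, vphi1, ndiv, dt);
      for (int k = 0; k < n; ++k) ndiv[k] *= F;
    }

    if (competing) {
      for (int k = 0; k < n; ++k) ker[k] = vpsi1[k] * (1.0 - F * Phi1[k]);
      conv_trap(born, ker, ndie, dt);
    } else {
      conv_trap(born, vpsi1, ndie, dt);
      for (int k = 0; k < n; ++k) ndie[k] *= (1.0 - F);
    }

    cumtrap(born, cum1, dt);
    for (int k = 0; k < n; ++k) tmp[k] = ndiv[k] + ndie[k];
    cumtrap(tmp, cum2, dt);
    for (int k = 0; k < n; ++k) counts(g, k) = cum1[k] - cum2[k];

    cumtrap(ndiv, cum1, dt);
    cumtrap(ndie, cum2, dt);
    for (int k = 0; k < n; ++k) {
      cum_div[k] += cum1[k];
      cum_die[k] += cum2[k];
    }
    std::swap(ndiv_prev, ndiv);
  }

  return List::create(_["counts"] = counts, _["cum_divisions"] = cum_div,
                      _["cum_deaths"] = cum_die);
}
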