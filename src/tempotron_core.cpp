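#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Double-exponential PSP kernel K(t) = v0 * (exp(-t/taum) - exp(-t/taus)),
// t > 0, with v0 chosen so that max_t K(t) = 1.

static inline double kernel_tpeak(double taum, double taus) {
  return taum * taus / (taum - taus) * std::log(taum / taus);
}

static inline double kernel_v0(double taum, double taus) {
  double tp = kernel_tpeak(taum, taus);
  return 1.0 / (std::exp(-tp / taum) - std::exp(-tp / taus));
}

// [[Rcpp::export]]
double cpp_kernel_v0(double taum, double taus) { return kernel_v0(taum, taus); }

// [[Rcpp::export]]
NumericVector cpp_kernel(NumericVector t, double taum, double taus) {
  double v0 = kernel_v0(taum, taus);
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = t[i] > 0.0 ? v0 * (std::exp(-t[i] / taum) - std::exp(-t[i] / taus)) : 0.0;
  return out;
}

// Event-driven exact maximization of
//   V(t) = v0 * sum_j amp_j * (exp(-(t - t_j)/taum) - exp(-(t - t_j)/taus))
// over (0, tend]. Between spikes V is a two-exponential whose interior
// critical point has a closed form; the running sums are kept re-based to the
// current spike time so no exponential ever overflows.
struct VmaxRes { double vmax; double tmax; };

static VmaxRes vmax_core(const double* t, const double* amp, int n,
                         double taum, double taus, double tend, double v0) {
  VmaxRes res; res.vmax = 0.0; res.tmax = NA_REAL;
  double a = 0.0, b = 0.0;
  double rate = 1.0 / taus - 1.0 / taum; // > 0 since taum > taus
  for (int k = 0; k < n; ++k) {
    if (t[k] > tend) break;
    if (k > 0) {
      double d = t[k] - t[k - 1];
      a *= std::exp(-d / taum);
      b *= std::exp(-d / taus);
    }
    a += amp[k];
    b += amp[k];
    double upper = (k + 1 < n && t[k + 1] <= tend) ? t[k + 1] : tend;
    double L = upper - t[k];
    if (L <= 0.0) continue;
    // interior critical point of a*exp(-s/taum) - b*exp(-s/taus)
    if (a * b > 0.0) {
      double ratio = (b * taum) / (a * taus);
      if (ratio > 0.0) {
        double sc = std::log(ratio) / rate;
        if (sc > 0.0 && sc < L) {
          double v = v0 * (a * std::exp(-sc / taum) - b * std::exp(-sc / taus));
          if (v > res.vmax) { res.vmax = v; res.tmax = t[k] + sc; }
        }
      }
    }
    double vend = v0 * (a * std::exp(-L / taum) - b * std::exp(-L / taus));
    if (vend > res.vmax) { res.vmax = vend; res.tmax = t[k] + L; }
  }
  return res;
}

// Earliest t in (0, tend] with V(t) = theta (first threshold crossing);
// NA when the voltage never reaches theta. Each inter-spike interval is split
// at its critical point into monotone pieces and bisected.
static double cross_core(const double* t, const double* amp, int n,
                         double taum, double taus, double tend, double v0,
                         double theta) {
  double a = 0.0, b = 0.0;
  double rate = 1.0 / taus - 1.0 / taum;
  for (int k = 0; k < n; ++k) {
    if (t[k] > tend) break;
    if (k > 0) {
      double d = t[k] - t[k - 1];
      a *= std::exp(-d / taum);
      b *= std::exp(-d / taus);
    }
    a += amp[k];
    b += amp[k];
    double upper = (k + 1 < n && t[k + 1] <= tend) ? t[k + 1] : tend;
    double L = upper - t[k];
    if (L <= 0.0) continue;
    double split = L;
    if (a * b > 0.0) {
      double ratio = (b * taum) / (a * taus);
      if (ratio > 0.0) {
        double sc = std::log(ratio) / rate;
        if (sc > 0.0 && sc < L) split = sc;
      }
    }
    double pieces[2][2] = { {0.0, split}, {split, L} };
    double aa = a, bb = b;
    double f0 = v0 * (aa - bb) - theta; // V at interval start
    for (int p = 0; p < 2; ++p) {
      double s1 = pieces[p][0], s2 = pieces[p][1];
      if (s2 <= s1) continue;
      double f2 = v0 * (aa * std::exp(-s2 / taum) - bb * std::exp(-s2 / taus)) - theta;
      if (f0 < 0.0 && f2 >= 0.0) {
        double lo = s1, hi = s2;
        for (int it = 0; it < 80; ++it) {
          double mid = 0.5 * (lo + hi);
          double fm = v0 * (aa * std::exp(-mid / taum) - bb * std::exp(-mid / taus)) - theta;
          if (fm >= 0.0) hi = mid; else lo = mid;
        }
        return t[k] + 0.5 * (lo + hi);
      }
      if (f0 >= 0.0) return t[k] + s1; // already above at piece start
      f0 = f2;
    }
  }
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_peak_voltage(NumericVector times, NumericVector amp,
                               double taum, double taus, double tend) {
  double v0 = kernel_v0(taum, taus);
  VmaxRes r = vmax_core(times.begin(), amp.begin(), times.size(), taum, taus, tend, v0);
  return NumericVector::create(r.vmax, r.tmax);
}

// [[Rcpp::export]]
double cpp_first_crossing(NumericVector times, NumericVector amp,
                          double taum, double taus, double tend, double theta) {
  double v0 = kernel_v0(taum, taus);
  return cross_core(times.begin(), amp.begin(), times.size(), taum, taus, tend, v0, theta);
}

// Batch evaluation over a flattened dataset. ptr is 0-based offsets of length
// ntrials+1; aff is 0-based afferent index per spike. Returns a matrix with
// columns vmax, tmax, tcross.
// [[Rcpp::export]]
NumericMatrix cpp_eval_batch(NumericVector tim, IntegerVector aff, NumericVector rfac,
                             IntegerVector ptr, NumericVector w, double theta,
                             double taum, double taus, double tend) {
  int ntr = ptr.size() - 1;
  double v0 = kernel_v0(taum, taus);
  NumericMatrix out(ntr, 3);
  std::vector<double> amp;
  for (int i = 0; i < ntr; ++i) {
    int s = ptr[i], e = ptr[i + 1], n = e - s;
    amp.resize(n);
    for (int j = 0; j < n; ++j) amp[j] = w[aff[s + j]] * rfac[s + j];
    VmaxRes r = vmax_core(&tim[s], amp.data(), n, taum, taus, tend, v0);
    out(i, 0) = r.vmax;
    out(i, 1) = r.tmax;
    out(i, 2) = (r.vmax >= theta)
      ? cross_core(&tim[s], amp.data(), n, taum, taus, tend, v0, theta)
      : NA_REAL;
  }
  return out;
}

// Tempotron training. Presentation order is fixed across cycles. On an error
// trial the update is dw_i = sign * lambda * sum_{t_ij < tmax} R_ij K(tmax - t_ij)
// with momentum on a velocity term. decay_scale > 0 switches on the step-size
// schedule lambda_n = lambda0 / (1 + n / decay_scale), n counting presentations.
// margins: per-trial margin m; a target errs unless vmax >= theta*(1+m),
// a null unless vmax <= theta*(1-m). check_every > 0 evaluates the margin-free
// error on all trials every check_every cycles and stops at zero.
// [[Rcpp::export]]
List cpp_train(NumericVector tim, IntegerVector aff, NumericVector rfac,
               IntegerVector ptr, IntegerVector labels, IntegerVector order,
               NumericVector w_init, double theta, double taum, double taus,
               double tend, double lambda0, double decay_scale, double momentum,
               int cycles, NumericVector margins, bool record_snapshots,
               int check_every) {
  int ntr = ptr.size() - 1, nw = w_init.size();
  double v0 = kernel_v0(taum, taus);
  NumericVector w = clone(w_init);
  std::vector<double> vel(nw, 0.0), dw(nw), amp;
  NumericVector errcurve(cycles, NA_REAL);
  NumericMatrix snaps = record_snapshots ? NumericMatrix(cycles, nw) : NumericMatrix(0, 0);
  std::vector<double> checks;
  bool converged = false;
  long npres = 0;
  int cyc = 0;
  for (cyc = 0; cyc < cycles; ++cyc) {
    int nerr = 0;
    for (int oi = 0; oi < ntr; ++oi) {
      int i = order[oi];
      int s = ptr[i], e = ptr[i + 1], n = e - s;
      amp.resize(n);
      for (int j = 0; j < n; ++j) amp[j] = w[aff[s + j]] * rfac[s + j];
      VmaxRes r = vmax_core(&tim[s], amp.data(), n, taum, taus, tend, v0);
      double m = margins[i];
      bool err = labels[i] == 1 ? (r.vmax < theta * (1.0 + m))
                                : (r.vmax > theta * (1.0 - m));
      ++npres;
      if (err) {
        ++nerr;
        if (R_finite(r.tmax)) { // all-empty target patterns: no defined tmax
          double lam = decay_scale > 0.0
            ? lambda0 / (1.0 + (double)npres / decay_scale) : lambda0;
          double sign = labels[i] == 1 ? 1.0 : -1.0;
          std::fill(dw.begin(), dw.end(), 0.0);
          for (int j = 0; j < n; ++j) {
            double dt = r.tmax - tim[s + j];
            if (dt <= 0.0) continue;
            dw[aff[s + j]] += rfac[s + j] *
              v0 * (std::exp(-dt / taum) - std::exp(-dt / taus));
          }
          for (int q = 0; q < nw; ++q) {
            vel[q] = momentum * vel[q] + sign * lam * dw[q];
            w[q] += vel[q];
          }
        }
      }
    }
    errcurve[cyc] = (double)nerr / ntr;
    if (record_snapshots)
      for (int q = 0; q < nw; ++q) snaps(cyc, q) = w[q];
    if (check_every > 0 && ((cyc + 1) % check_every == 0 || cyc + 1 == cycles)) {
      int bad = 0;
      for (int i = 0; i < ntr; ++i) {
        int s = ptr[i], e = ptr[i + 1], n = e - s;
        amp.resize(n);
        for (int j = 0; j < n; ++j) amp[j] = w[aff[s + j]] * rfac[s + j];
        VmaxRes r = vmax_core(&tim[s], amp.data(), n, taum, taus, tend, v0);
        bool fired = r.vmax >= theta;
        if ((labels[i] == 1) != fired) ++bad;
      }
      checks.push_back((double)bad / ntr);
      if (bad == 0) { converged = true; ++cyc; break; }
    }
  }
  return List::create(_["weights"] = w,
                      _["error_curve"] = errcurve,
                      _["snapshots"] = record_snapshots ? (SEXP)snaps : R_NilValue,
                      _["converged"] = converged,
                      _["cycles_run"] = cyc,
                      _["grid_error_history"] = wrap(checks));
}

// Fast path for the two-afferent analytics: peak voltage of
// w1*K(t) + w2*K(t - dt) as a function of the relative latency dt = t2 - t1.
// [[Rcpp::export]]
NumericVector cpp_vmax_pair(NumericVector dt, double w1, double w2,
                            double taum, double taus) {
  double v0 = kernel_v0(taum, taus);
  int n = dt.size();
  NumericVector out(n);
  double t[2], amp[2];
  for (int i = 0; i < n; ++i) {
    double d = dt[i];
    if (d >= 0.0) { t[0] = 0.0; t[1] = d; amp[0] = w1; amp[1] = w2; }
    else          { t[0] = 0.0; t[1] = -d; amp[0] = w2; amp[1] = w1; }
    double tend = t[1] + 20.0 * taum;
    out[i] = vmax_core(t, amp, 2, taum, taus, tend, v0).vmax;
  }
  return out;
}

// Expected error of a two-afferent tempotron under Gaussian relative-latency
// input and Gaussian threshold noise, evaluated on a grid of weight pairs.
// mu, sd, lab describe one Gaussian per stimulus; quadrature uses nq
// trapezoid nodes over mu +- 5 sd. noise_sd = frac * mean(|w1|, |w2|).
// [[Rcpp::export]]
NumericMatrix cpp_pair_grid_error(NumericVector w1g, NumericVector w2g,
                                  NumericVector mu, NumericVector sd,
                                  IntegerVector lab, double theta,
                                  double taum, double taus,
                                  double noise_frac, int nq) {
  double v0 = kernel_v0(taum, taus);
  int n1 = w1g.size(), n2 = w2g.size(), ns = mu.size();
  NumericMatrix err(n1, n2);
  std::vector<double> z(nq), pw(nq);
  double span = 10.0 / (nq - 1); // nodes over +-5 sd
  double psum = 0.0;
  for (int q = 0; q < nq; ++q) {
    z[q] = -5.0 + q * span;
    pw[q] = std::exp(-0.5 * z[q] * z[q]);
    psum += pw[q];
  }
  for (int q = 0; q < nq; ++q) pw[q] /= psum;
  double t[2], amp[2];
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double w1 = w1g[i], w2 = w2g[j];
      if (w1 + w2 <= 0.0 || std::max(w1, w2) <= 0.0) { err(i, j) = NA_REAL; continue; }
      double nsd = noise_frac * 0.5 * (std::fabs(w1) + std::fabs(w2));
      double etot = 0.0;
      for (int s = 0; s < ns; ++s) {
        double es = 0.0;
        for (int q = 0; q < nq; ++q) {
          double d = mu[s] + sd[s] * z[q];
          if (d >= 0.0) { t[0] = 0.0; t[1] = d; amp[0] = w1; amp[1] = w2; }
          else          { t[0] = 0.0; t[1] = -d; amp[0] = w2; amp[1] = w1; }
          double v = vmax_core(t, amp, 2, taum, taus, t[1] + 20.0 * taum, v0).vmax;
          double pfire = nsd > 0.0
            ? R::pnorm(v - theta, 0.0, nsd, 1, 0)
            : (v >= theta ? 1.0 : 0.0);
          es += pw[q] * (lab[s] == 1 ? 1.0 - pfire : pfire);
        }
        etot += es;
      }
      err(i, j) = etot / ns;
    }
  }
  return err;
}
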