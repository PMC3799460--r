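// Levenberg-Marquardt least-squares fit of the box-convolved-with-Gaussian
// (erf-difference) edge profile
//   m(x) = b + A * (Phi(z1) - Phi(z2)),  z1 = (x-c+w/2)/s, z2 = (x-c-w/2)/s
// to 1D intensity profiles. One call fits many profiles (rows of a matrix)
// so per-frame kymograph fitting stays cheap at population scale.
// Parameters p = (c, w, A, b, s) in pixel units; box bounds are enforced by
// projection and a solution resting on a bound is reported via `at_bound`.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double ncdf(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }
static inline double npdf(double z) {
  return 0.39894228040143267794 * std::exp(-0.5 * z * z);
}

static void model_jac(const arma::vec &x, const arma::vec &p, arma::vec &m,
                      arma::mat &J) {
  const double c = p(0), w = p(1), A = p(2), b = p(3), s = p(4);
  const int n = x.n_elem;
  for (int i = 0; i < n; ++i) {
    double z1 = (x(i) - c + 0.5 * w) / s;
    double z2 = (x(i) - c - 0.5 * w) / s;
    double F1 = ncdf(z1), F2 = ncdf(z2);
    double f1 = npdf(z1), f2 = npdf(z2);
    m(i) = b + A * (F1 - F2);
    J(i, 0) = A * (f2 - f1) / s;            // d/dc
    J(i, 1) = A * (f1 + f2) / (2.0 * s);    // d/dw
    J(i, 2) = F1 - F2;                      // d/dA
    J(i, 3) = 1.0;                          // d/db
    J(i, 4) = A * (z2 * f2 - z1 * f1) / s;  // d/ds
  }
}

static arma::vec clamp_p(arma::vec p, const arma::vec &lo,
                         const arma::vec &hi) {
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    if (p(k) < lo(k)) p(k) = lo(k);
    if (p(k) > hi(k)) p(k) = hi(k);
  }
  return p;
}

// [[Rcpp::export(name = ".fit_box_erf_cpp")]]
NumericMatrix fit_box_erf_cpp(NumericMatrix profiles, NumericMatrix inits,
                              NumericVector lower, NumericVector upper,
                              int max_iter = 60) {
  const int nprof = profiles.nrow();
  const int L = profiles.ncol();
  arma::vec x(L);
  for (int i = 0; i < L; ++i) x(i) = i + 0.5;  // pixel centres, 0-based index
  arma::vec lo(lower.begin(), 5), hi(upper.begin(), 5);

  NumericMatrix out(nprof, 9);
  colnames(out) = CharacterVector::create("center_px", "width_px", "plateau",
                                          "background", "sigma_px", "rss",
                                          "converged", "at_bound", "n_iter");
  arma::vec m(L), r(L), mt(L), rt(L);
  arma::mat J(L, 5), Jt(L, 5);

  for (int k = 0; k < nprof; ++k) {
    arma::vec y(L);
    for (int i = 0; i < L; ++i) y(i) = profiles(k, i);
    arma::vec p(5);
    for (int j = 0; j < 5; ++j) p(j) = inits(k, j);
    p = clamp_p(p, lo, hi);

    model_jac(x, p, m, J);
    r = m - y;
    double rss = arma::dot(r, r);
    double lambda = 1e-3;
    bool converged = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      arma::mat JtJ = J.t() * J;
      arma::vec g = J.t() * r;
      bool accepted = false;
      for (int tries = 0; tries < 40; ++tries) {
        arma::mat Aug = JtJ;
        Aug.diag() += lambda * (JtJ.diag() + 1e-12);
        arma::vec step;
        bool ok = arma::solve(step, Aug, -g, arma::solve_opts::no_approx);
        if (ok) {
          arma::vec pt = clamp_p(p + step, lo, hi);
          model_jac(x, pt, mt, Jt);
          rt = mt - y;
          double rss_t = arma::dot(rt, rt);
          if (rss_t <= rss) {
            double drop = rss - rss_t;
            double rel_step = 0.0;
            for (int j = 0; j < 5; ++j)
              rel_step = std::max(rel_step, std::fabs(pt(j) - p(j)) /
                                                (1.0 + std::fabs(p(j))));
            p = pt;
            m = mt;
            J = Jt;
            r = rt;
            rss = rss_t;
            lambda = std::max(lambda * 0.3, 1e-12);
            accepted = true;
            if (drop <= 1e-14 * (rss + 1e-30) || rel_step < 1e-8)
              converged = true;
            break;
          }
        }
        lambda *= 10.0;
        if (lambda > 1e12) break;
      }
      if (!accepted || converged) {
        if (!accepted) converged = true;  // no improving step exists
        break;
      }
    }

    bool at_bound = false;
    const double tol = 1e-8;
    for (int j = 0; j < 5; ++j) {
      if (j == 3) continue;  // background unbounded in practice
      if (p(j) <= lo(j) + tol || p(j) >= hi(j) - tol) at_bound = true;
    }
    out(k, 0) = p(0); out(k, 1) = p(1); out(k, 2) = p(2);
    out(k, 3) = p(3); out(k, 4) = p(4); out(k, 5) = rss;
    out(k, 6) = converged ? 1.0 : 0.0;
    out(k, 7) = at_bound ? 1.0 : 0.0;
    out(k, 8) = it;
  }
  return out;
}

// Data-driven starting values for each profile (row): background from the
// median of the outer 10% of pixels, noise from the MAD (x1.4826) of the
// outer 20%, amplitude from the peak, centre/width from the half-maximum
// crossings, sigma fixed at 2 px. Matches the documented initialization
// rule of fit_frame().
static double med(std::vector<double> v) {
  size_t n = v.size(), h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// [[Rcpp::export(name = ".init_box_cpp")]]
NumericMatrix init_box_cpp(NumericMatrix profiles) {
  const int nprof = profiles.nrow(), L = profiles.ncol();
  const int n_edge = std::max(2, (int)std::ceil(0.05 * L));
  NumericMatrix out(nprof, 6);
  colnames(out) = CharacterVector::create("center", "width", "plateau",
                                          "background", "sigma", "noise");
  for (int k = 0; k < nprof; ++k) {
    std::vector<double> outer1, outer2;
    outer1.reserve(2 * n_edge);
    outer2.reserve(4 * n_edge);
    for (int i = 0; i < n_edge; ++i) {
      outer1.push_back(profiles(k, i));
      outer1.push_back(profiles(k, L - 1 - i));
    }
    for (int i = 0; i < 2 * n_edge; ++i) {
      outer2.push_back(profiles(k, i));
      outer2.push_back(profiles(k, L - 1 - i));
    }
    double b0 = med(outer1);
    double m2 = med(outer2);
    std::vector<double> dev(outer2.size());
    for (size_t i = 0; i < outer2.size(); ++i)
      dev[i] = std::fabs(outer2[i] - m2);
    double noise = 1.4826 * med(dev);
    double ymax = profiles(k, 0);
    for (int i = 1; i < L; ++i) ymax = std::max(ymax, profiles(k, i));
    double a0 = ymax - b0;
    double half = b0 + 0.5 * a0;
    int first = -1, last = -1;
    for (int i = 0; i < L; ++i)
      if (profiles(k, i) >= half) { if (first < 0) first = i; last = i; }
    double c0, w0;
    if (a0 > 0 && first >= 0) {
      c0 = 0.5 * (first + last) + 0.5;  // pixel centres at index + 0.5
      w0 = last - first + 1;
    } else {
      c0 = L / 2.0;
      w0 = L / 4.0;
    }
    w0 = std::min(std::max(w0, 2.5), L - 1.0);
    out(k, 0) = c0; out(k, 1) = w0; out(k, 2) = std::max(a0, 1e-6);
    out(k, 3) = b0; out(k, 4) = 2.0; out(k, 5) = noise;
  }
  return out;
}
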