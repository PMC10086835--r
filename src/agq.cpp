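// Marginal likelihood machinery for the cumulative logistic random-intercept
// model: per-subject posterior modes, adaptive Gauss-Hermite quadrature, the
// analytic gradient of the quadrature approximation, and the fixed-effect
// Hessian (posterior-expectation identities with the quadrature rule treated
// as fixed; the residual inconsistency is of the order of the quadrature
// error itself).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Observation-level log-probability and derivatives under the latent-logistic
// mechanism: with shift c = -eta - u the category probability is
// F(theta_y + c) - F(theta_{y-1} + c), F the logistic CDF.  Derivative
// identities (p the probability, a/b the upper/lower cut arguments):
//   d lp/du = d lp/d eta = f(b)/p - f(a)/p = rb - ra
//   d lp/d theta_y = ra,  d lp/d theta_{y-1} = -rb
//   d2 lp/du2 = e_a - e_b - (rb - ra)^2,  e_a = f'(a)/p = ra (1 - 2 F(a))
// `what` bits: 1 = first derivatives (d1, ra, rb), 2 = second derivatives
// (d2 and e_a, e_b, from which all cross second derivatives follow).
static inline void cellv(int y, int My, const double* theta, double c, int what,
                         double& lp, double& d1, double& d2, double& ra,
                         double& rb, double& ea, double& eb) {
  if (y == 1) {
    double hi = theta[0] + c;
    double L = log1pexp_(-hi);
    lp = -L;
    if (!what) return;
    ra = std::exp(-hi - L); // = 1 - F(hi)
    rb = 0.0;
    d1 = -ra;
    if (what & 2) {
      double pa = std::exp(-L);
      ea = ra * (1.0 - 2.0 * pa);
      eb = 0.0;
      d2 = ea - ra * ra;
    }
  } else if (y == My) {
    double lo = theta[My - 2] + c;
    double L = log1pexp_(-lo);
    lp = -lo - L; // log(1 - F(lo))
    if (!what) return;
    rb = std::exp(-L); // = F(lo)
    ra = 0.0;
    d1 = rb;
    if (what & 2) {
      ea = 0.0;
      eb = rb * (1.0 - 2.0 * rb);
      d2 = -eb - rb * rb;
    }
  } else {
    double hi = theta[y - 1] + c, lo = theta[y - 2] + c;
    double Lh = log1pexp_(-hi), Ll = log1pexp_(-lo);
    double d = Lh - Ll; // = lF(lo) - lF(hi) < 0
    double l1m = (d > -0.6931471805599453) ? std::log(-std::expm1(d))
                                           : std::log1p(-std::exp(d));
    lp = -Lh + l1m;
    if (!std::isfinite(lp)) lp = -745.0;
    if (!what) return;
    ra = std::exp(-hi - 2.0 * Lh - lp);
    rb = std::exp(-lo - 2.0 * Ll - lp);
    d1 = rb - ra;
    if (what & 2) {
      double pa = std::exp(-Lh), pb = std::exp(-Ll);
      ea = ra * (1.0 - 2.0 * pa);
      eb = rb * (1.0 - 2.0 * pb);
      d2 = ea - eb - d1 * d1;
    }
  }
}

// sums of lp, d lp/du, d2 lp/du2 over one subject's observations at given u
static inline void subject_sums(const int* y, const double* eta, int My,
                                const double* theta, int i0, int i1, double u,
                                double& s0, double& s1, double& s2) {
  s0 = s1 = s2 = 0.0;
  double lp, d1, d2, ra, rb, ea, eb;
  for (int j = i0; j <= i1; ++j) {
    cellv(y[j], My, theta, -eta[j] - u, 3, lp, d1, d2, ra, rb, ea, eb);
    s0 += lp;
    s1 += d1;
    s2 += d2;
  }
}

// [[Rcpp::export]]
List agq_core(const arma::ivec& y, const arma::vec& eta, const arma::ivec& sub_start,
              const arma::ivec& sub_end, int My, const arma::vec& theta, double sigma,
              const arma::vec& ght, const arma::vec& ghw, const arma::vec& u_init,
              bool want_grad, bool want_hess = false,
              Rcpp::Nullable<Rcpp::NumericMatrix> Xr = R_NilValue) {
  const int nsub = sub_start.n_elem, K = ght.n_elem, n = y.n_elem;
  const double isig2 = 1.0 / (sigma * sigma);
  const int* yp = y.memptr();
  const double* ep = eta.memptr();
  const double* tp = theta.memptr();
  arma::vec u_hat(nsub), s_hat(nsub), lli(nsub);
  arma::vec grad_eta(want_grad ? n : 0, arma::fill::zeros);
  arma::vec grad_theta(want_grad ? (My - 1) : 0, arma::fill::zeros);
  double grad_logsig = 0.0, loglik = 0.0;

  // Full-Hessian mode: second derivatives of the marginal log-likelihood
  // with respect to psi = (zeta, theta_1..theta_{My-1}, log sigma), via
  //   d2 l_i = sum_k w_k (G_k'' + G_k' G_k'^T) - m m^T,  m = sum_k w_k G_k',
  // where G_k is the joint log-density at node k. The G'' part is returned
  // as per-observation scalar weights (a for eta-eta, c_hi/c_lo for the
  // eta-theta cross, t_aa/t_bb/t_ab for theta-theta) to be scattered in R;
  // the covariance part is accumulated densely over psi.
  arma::mat X;
  int p = 0, q = 0;
  arma::vec hess_a, c_hi, c_lo, t_aa, t_bb, t_ab;
  arma::mat hess_cov;
  double sig2nd = 0.0; // sum of w_k * d2 G_k / d(log sigma)^2
  if (want_hess) {
    if (Xr.isNull()) stop("want_hess requires the design matrix X");
    X = Rcpp::as<arma::mat>(Xr);
    p = X.n_cols;
    q = p + (My - 1) + 1;
    hess_a.zeros(n);
    c_hi.zeros(n);
    c_lo.zeros(n);
    t_aa.zeros(n);
    t_bb.zeros(n);
    t_ab.zeros(n);
    hess_cov.zeros(q, q);
  }

  int Jmax = 0;
  for (int i = 0; i < nsub; ++i)
    Jmax = std::max(Jmax, (int)(sub_end[i] - sub_start[i] + 1));
  const int what = (want_grad ? 1 : 0) | (want_hess ? 3 : 0);
  arma::mat B_d1(Jmax, K), B_ra(Jmax, K), B_rb(Jmax, K), B_d2(Jmax, K),
      B_ea(Jmax, K), B_eb(Jmax, K);
  arma::vec lZ(K), om(K), psik(q > 0 ? q : 1), M1(q > 0 ? q : 1);
  arma::mat M2(q > 0 ? q : 1, q > 0 ? q : 1);

  for (int i = 0; i < nsub; ++i) {
    const int i0 = sub_start[i], i1 = sub_end[i], J = i1 - i0 + 1;
    // posterior mode by safeguarded Newton
    double u = u_init[i], s0, s1, s2;
    subject_sums(yp, ep, My, tp, i0, i1, u, s0, s1, s2);
    double h = s0 - 0.5 * u * u * isig2;
    for (int it = 0; it < 100; ++it) {
      double g = s1 - u * isig2;
      double Hn = s2 - isig2; // < 0
      double step = -g / Hn;
      if (!std::isfinite(step)) step = (g > 0) ? 1.0 : -1.0;
      double un = u + step, hn = h;
      int halvings = 0;
      while (halvings < 40) {
        subject_sums(yp, ep, My, tp, i0, i1, un, s0, s1, s2);
        hn = s0 - 0.5 * un * un * isig2;
        if (hn >= h - 1e-14 * (1.0 + std::fabs(h))) break;
        step *= 0.5;
        un = u + step;
        ++halvings;
      }
      double moved = std::fabs(un - u);
      u = un;
      h = hn;
      if (moved < 1e-10 * (1.0 + std::fabs(u))) break;
    }
    double curv = isig2 - s2; // -h''(u) > 0
    double ss = 1.0 / std::sqrt(curv);
    u_hat[i] = u;
    s_hat[i] = ss;

    // adaptive GH nodes u_k = u + sqrt(2) s t_k; derivative quantities are
    // buffered per (observation, node) so weights need only one pass
    double lmax = -HUGE_VAL;
    double lp, d1, d2, ra, rb, ea, eb;
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * ss * ght[k];
      double t0 = 0.0;
      for (int j = i0; j <= i1; ++j) {
        cellv(yp[j], My, tp, -ep[j] - uk, what, lp, d1, d2, ra, rb, ea, eb);
        t0 += lp;
        if (what & 1) {
          B_d1(j - i0, k) = d1;
          B_ra(j - i0, k) = ra;
          B_rb(j - i0, k) = rb;
        }
        if (what & 2) {
          B_d2(j - i0, k) = d2;
          B_ea(j - i0, k) = ea;
          B_eb(j - i0, k) = eb;
        }
      }
      lZ[k] = t0 - 0.5 * uk * uk * isig2 - std::log(sigma) - 0.5 * LOG2PI +
              std::log(ghw[k]) + ght[k] * ght[k];
      if (lZ[k] > lmax) lmax = lZ[k];
    }
    double sz = 0.0;
    for (int k = 0; k < K; ++k) {
      om[k] = std::exp(lZ[k] - lmax);
      sz += om[k];
    }
    lli[i] = std::log(M_SQRT2 * ss) + lmax + std::log(sz);
    loglik += lli[i];
    if (what) for (int k = 0; k < K; ++k) om[k] /= sz;

    if (want_grad) {
      for (int k = 0; k < K; ++k) {
        double w = om[k];
        if (w < 1e-300) continue;
        double uk = u + M_SQRT2 * ss * ght[k];
        for (int j = i0; j <= i1; ++j) {
          grad_eta[j] += w * B_d1(j - i0, k);
          if (yp[j] < My) grad_theta[yp[j] - 1] += w * B_ra(j - i0, k);
          if (yp[j] > 1) grad_theta[yp[j] - 2] -= w * B_rb(j - i0, k);
        }
        grad_logsig += w * (uk * uk * isig2 - 1.0);
      }
    }

    if (want_hess) {
      M1.zeros();
      M2.zeros();
      for (int k = 0; k < K; ++k) {
        double w = om[k];
        if (w < 1e-300) continue;
        double uk = u + M_SQRT2 * ss * ght[k];
        psik.zeros();
        for (int j = i0; j <= i1; ++j) {
          const int jj = j - i0;
          const double d1j = B_d1(jj, k), raj = B_ra(jj, k), rbj = B_rb(jj, k);
          const double eaj = B_ea(jj, k), ebj = B_eb(jj, k);
          // G'' scatter weights (second derivatives of lp):
          //   eta-eta: d2; eta-theta_y: -e_a - ra d1 (note d lp/d eta and
          //   d lp/du coincide); eta-theta_{y-1}: e_b + rb d1;
          //   theta_y^2: e_a - ra^2; theta_{y-1}^2: -e_b - rb^2;
          //   theta_y theta_{y-1}: ra rb
          hess_a[j] += w * B_d2(jj, k);
          c_hi[j] += w * (-eaj - raj * d1j);
          c_lo[j] += w * (ebj + rbj * d1j);
          t_aa[j] += w * (eaj - raj * raj);
          t_bb[j] += w * (-ebj - rbj * rbj);
          t_ab[j] += w * (raj * rbj);
          // G' over psi
          psik.subvec(0, p - 1) += d1j * X.row(j).t();
          if (yp[j] < My) psik[p + yp[j] - 1] += raj;
          if (yp[j] > 1) psik[p + yp[j] - 2] -= rbj;
        }
        psik[q - 1] = uk * uk * isig2 - 1.0;
        sig2nd += w * (-2.0 * uk * uk * isig2);
        M1 += w * psik;
        M2 += w * (psik * psik.t());
      }
      hess_cov += M2 - M1 * M1.t();
    }
  }

  List out = List::create(_["loglik"] = loglik, _["loglik_i"] = lli, _["u_hat"] = u_hat,
                          _["s_hat"] = s_hat);
  if (want_grad) {
    out["grad_eta"] = grad_eta;
    out["grad_theta"] = grad_theta;
    out["grad_logsigma"] = grad_logsig;
  }
  if (want_hess) {
    out["hess_a"] = hess_a;
    out["c_hi"] = c_hi;
    out["c_lo"] = c_lo;
    out["t_aa"] = t_aa;
    out["t_bb"] = t_bb;
    out["t_ab"] = t_ab;
    out["sig2nd"] = sig2nd;
    out["hess_cov"] = hess_cov;
  }
  return out;
}
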