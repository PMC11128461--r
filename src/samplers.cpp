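// Gradient-based MCMC for the two Bayesian models:
//  * Dirichlet regression (alternative parameterization, logit link,
//    herd random intercepts per non-reference category, scalar precision)
//  * Bernoulli mixed model (session random intercept)
// Sampler: Hamiltonian Monte Carlo preconditioned with a Laplace-
// approximation mass matrix, step size adapted during warmup.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double T_SCALE = 2.5;  // Student-t(3, 0, 2.5) prior scale

// log density of t(df=3, 0, scale) up to nothing (exact, with constants)
static inline double lt3(double x) {
  // lgamma(2) - lgamma(1.5) - 0.5*log(3*pi*s^2) - 2*log1p(x^2/(3 s^2))
  static const double cst = -std::lgamma(1.5) -
    0.5 * std::log(3.0 * M_PI * T_SCALE * T_SCALE);
  return cst - 2.0 * std::log1p(x * x / (3.0 * T_SCALE * T_SCALE));
}
static inline double dlt3(double x) {
  return -4.0 * x / (3.0 * T_SCALE * T_SCALE + x * x);
}


// 1D slice sampler (stepping out, Neal 2003) for log-scale full
// conditionals; f must be a unimodal-ish log density.
template <class F>
static double slice_sample_1d(double x0, F f, double width = 1.0,
                              int max_steps = 20) {
  double ly = f(x0) - R::exp_rand();
  double L = x0 - width * R::unif_rand();
  double Rr = L + width;
  int k = max_steps;
  while (k-- > 0 && f(L) > ly) L -= width;
  k = max_steps;
  while (k-- > 0 && f(Rr) > ly) Rr += width;
  for (int it = 0; it < 50; ++it) {
    double x1 = L + (Rr - L) * R::unif_rand();
    if (f(x1) > ly) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// log full conditional of w = log(scale) given n_eff centered effects with
// sum of squares ssq: prior N(0, e^{2w}) per effect + half-t(3,0,2.5) on
// e^w with log Jacobian.
static double scale_conditional(double w, int n_eff, double ssq) {
  double s2 = std::exp(2.0 * w);
  return -n_eff * w - 0.5 * ssq / s2 -
    2.0 * std::log1p(s2 / (3.0 * T_SCALE * T_SCALE)) + w;
}

// ---------------------------------------------------------------------------
// Dirichlet regression log posterior.
// theta packing: beta (p x (C-1), column-major), u = log(phi),
//                [w = log(sigma), z (H x (C-1))] when H > 0.
// Reference category is the LAST column of logY; its linear predictor is 0.
// ---------------------------------------------------------------------------
struct DirModel {
  arma::mat X;       // n x p
  arma::mat logY;    // n x C
  arma::ivec herd;   // n, 0-based; -1 allowed when H == 0
  int H;
  bool prior_only;
  bool centered;     // random effects raw N(0, sigma^2) vs sigma * N(0, 1)
  double a0 = 0.01, b0 = 0.01;  // gamma prior on phi

  int n() const { return X.n_rows; }
  int p() const { return X.n_cols; }
  int C() const { return logY.n_cols; }
  int dim() const {
    return p() * (C() - 1) + 1 + (H > 0 ? 1 + H * (C() - 1) : 0);
  }

  double lp_grad(const arma::vec& th, arma::vec& grad,
                 arma::vec* ll_out = nullptr) const {
    const int nn = n(), pp = p(), CC = C(), K = CC - 1;
    arma::mat beta(const_cast<double*>(th.memptr()), pp, K, false, true);
    double u = th(pp * K);
    double phi = std::exp(u);
    double w = 0.0, sigma = 0.0;
    const double* zptr = nullptr;
    if (H > 0) {
      w = th(pp * K + 1);
      sigma = std::exp(w);
      zptr = th.memptr() + pp * K + 2;
    }
    grad.zeros(th.n_elem);
    arma::mat gbeta(grad.memptr(), pp, K, false, true);
    double lp = 0.0;

    // priors ----------------------------------------------------------------
    for (int c = 0; c < K; ++c) {           // intercepts ~ t(3, 0, 2.5)
      lp += lt3(beta(0, c));
      gbeta(0, c) += dlt3(beta(0, c));
    }
    lp += a0 * u - b0 * phi;                // gamma(a0, b0) on phi + Jacobian
    grad(pp * K) += a0 - b0 * phi;
    if (H > 0) {
      lp += -2.0 * std::log1p(sigma * sigma / (3.0 * T_SCALE * T_SCALE)) + w;
      grad(pp * K + 1) += dlt3(sigma) * sigma + 1.0;
      if (centered) {                       // effects ~ N(0, sigma^2)
        double s2 = sigma * sigma;
        for (int j = 0; j < H * K; ++j) {
          lp += -0.5 * zptr[j] * zptr[j] / s2 - w;
          grad(pp * K + 2 + j) += -zptr[j] / s2;
          grad(pp * K + 1) += zptr[j] * zptr[j] / s2 - 1.0;
        }
      } else {                              // standardized effects ~ N(0,1)
        for (int j = 0; j < H * K; ++j) {
          lp += -0.5 * zptr[j] * zptr[j];
          grad(pp * K + 2 + j) += -zptr[j];
        }
      }
    }
    if (prior_only) return lp;

    // likelihood ------------------------------------------------------------
    if (ll_out) ll_out->set_size(nn);
    arma::mat eta = X * beta;               // n x K
    arma::rowvec mu(CC), tvec(CC);
    double du_acc = 0.0, dw_acc = 0.0;
    arma::mat gz;
    if (H > 0) gz.zeros(H, K);
    const double lgphi = std::lgamma(phi);
    const double digphi = R::digamma(phi);
    for (int i = 0; i < nn; ++i) {
      int h = (H > 0) ? herd(i) : -1;
      double re_scale = centered ? 1.0 : sigma;
      double mx = 0.0;
      for (int c = 0; c < K; ++c) {
        double e = eta(i, c);
        if (h >= 0) e += re_scale * zptr[h + H * c];
        eta(i, c) = e;
        if (e > mx) mx = e;
      }
      double sum = std::exp(-mx);           // reference category (eta = 0)
      for (int c = 0; c < K; ++c) {
        mu(c) = std::exp(eta(i, c) - mx);
        sum += mu(c);
      }
      mu(K) = std::exp(-mx);
      double ll = lgphi, dphi = digphi, mt = 0.0;
      for (int c = 0; c < CC; ++c) {
        mu(c) /= sum;
        double a = mu(c) * phi;
        ll += -std::lgamma(a) + (a - 1.0) * logY(i, c);
        tvec(c) = logY(i, c) - R::digamma(a);
        dphi += mu(c) * tvec(c);
        mt += mu(c) * tvec(c);
      }
      lp += ll;
      if (ll_out) (*ll_out)(i) = ll;
      du_acc += dphi;
      for (int c = 0; c < K; ++c) {
        double g = phi * mu(c) * (tvec(c) - mt);
        for (int j = 0; j < pp; ++j) gbeta(j, c) += g * X(i, j);
        if (h >= 0) {
          gz(h, c) += g * (centered ? 1.0 : sigma);
          dw_acc += g * zptr[h + H * c];
        }
      }
    }
    grad(pp * K) += phi * du_acc;
    if (H > 0) {
      if (!centered) grad(pp * K + 1) += sigma * dw_acc;
      for (int c = 0; c < K; ++c)
        for (int h = 0; h < H; ++h)
          grad(pp * K + 2 + h + H * c) += gz(h, c);
    }
    return lp;
  }

  // Interweaved scale refresh: in the centered parameterization the scale
  // has a cheap full conditional given the raw effects; in the non-centered
  // one the same update is applied through the centered representation
  // (effects rescaled to keep b = sigma * z fixed).
  bool gibbs_scale(arma::vec& th) const {
    if (H == 0 || prior_only) return false;
    const int n_eff = H * (C() - 1), off = p() * (C() - 1) + 2;
    double w = th(off - 1);
    double ssq = 0.0;
    if (centered) {
      for (int j = 0; j < n_eff; ++j) ssq += th(off + j) * th(off + j);
      th(off - 1) = slice_sample_1d(
        w, [&](double x) { return scale_conditional(x, n_eff, ssq); });
    } else {
      double sigma = std::exp(w);
      for (int j = 0; j < n_eff; ++j) {
        double b = sigma * th(off + j);
        ssq += b * b;
      }
      double w_new = slice_sample_1d(
        w, [&](double x) { return scale_conditional(x, n_eff, ssq); });
      double r = std::exp(w - w_new);
      for (int j = 0; j < n_eff; ++j) th(off + j) *= r;
      th(off - 1) = w_new;
    }
    return true;
  }
};

// ---------------------------------------------------------------------------
// Bernoulli mixed model log posterior.
// theta packing: gamma (q), [w = log(tau), v (S)] when S > 0.
// ---------------------------------------------------------------------------
struct BernModel {
  arma::mat W;      // m x q
  arma::vec y;      // m, 0/1
  arma::ivec sess;  // m, 0-based
  int S;
  bool prior_only;
  bool centered;

  int dim() const { return W.n_cols + (S > 0 ? 1 + S : 0); }

  double lp_grad(const arma::vec& th, arma::vec& grad,
                 arma::vec* ll_out = nullptr) const {
    const int m = W.n_rows, q = W.n_cols;
    arma::vec gamma = th.head(q);
    double w = 0.0, tau = 0.0;
    const double* vptr = nullptr;
    if (S > 0) {
      w = th(q);
      tau = std::exp(w);
      vptr = th.memptr() + q + 1;
    }
    grad.zeros(th.n_elem);
    double lp = lt3(gamma(0));
    grad(0) += dlt3(gamma(0));
    if (S > 0) {
      lp += -2.0 * std::log1p(tau * tau / (3.0 * T_SCALE * T_SCALE)) + w;
      grad(q) += dlt3(tau) * tau + 1.0;
      if (centered) {
        double t2 = tau * tau;
        for (int s = 0; s < S; ++s) {
          lp += -0.5 * vptr[s] * vptr[s] / t2 - w;
          grad(q + 1 + s) += -vptr[s] / t2;
          grad(q) += vptr[s] * vptr[s] / t2 - 1.0;
        }
      } else {
        for (int s = 0; s < S; ++s) {
          lp += -0.5 * vptr[s] * vptr[s];
          grad(q + 1 + s) += -vptr[s];
        }
      }
    }
    if (prior_only) return lp;

    if (ll_out) ll_out->set_size(m);
    arma::vec eta = W * gamma;
    double dw_acc = 0.0;
    double re_scale = centered ? 1.0 : tau;
    for (int j = 0; j < m; ++j) {
      int s = (S > 0) ? sess(j) : -1;
      double e = eta(j);
      if (s >= 0) e += re_scale * vptr[s];
      double ll = y(j) * e - R::log1pexp(e);
      lp += ll;
      if (ll_out) (*ll_out)(j) = ll;
      double r = y(j) - 1.0 / (1.0 + std::exp(-e));
      for (int k = 0; k < q; ++k) grad(k) += r * W(j, k);
      if (s >= 0) {
        grad(q + 1 + s) += r * re_scale;
        dw_acc += r * vptr[s];
      }
    }
    if (S > 0 && !centered) grad(q) += tau * dw_acc;
    return lp;
  }

  bool gibbs_scale(arma::vec& th) const {
    if (S == 0 || prior_only) return false;
    const int q = W.n_cols;
    double w = th(q);
    double ssq = 0.0;
    if (centered) {
      for (int s = 0; s < S; ++s) ssq += th(q + 1 + s) * th(q + 1 + s);
      th(q) = slice_sample_1d(
        w, [&](double x) { return scale_conditional(x, S, ssq); });
    } else {
      double tau = std::exp(w);
      for (int s = 0; s < S; ++s) {
        double b = tau * th(q + 1 + s);
        ssq += b * b;
      }
      double w_new = slice_sample_1d(
        w, [&](double x) { return scale_conditional(x, S, ssq); });
      double r = std::exp(w - w_new);
      for (int s = 0; s < S; ++s) th(q + 1 + s) *= r;
      th(q) = w_new;
    }
    return true;
  }
};

// ---------------------------------------------------------------------------
// Preconditioned Hamiltonian Monte Carlo.  The chain runs in the whitened
// space phi = L^{-1} theta (L from the Laplace approximation), where the
// posterior is approximately standard normal; leapfrog path lengths are
// jittered and the step size is adapted toward 0.8 acceptance in warmup.
// ---------------------------------------------------------------------------
template <class Model>
List run_hmc(const Model& mod, const arma::vec& start, const arma::mat& L,
             int n_chains, int n_warmup, int n_iter, double eps0,
             double jitter, int thin_ll, int n_leapfrog) {
  const int d = start.n_elem;
  arma::mat draws(n_iter * n_chains, d);
  arma::mat ll_store;
  arma::vec accept(n_chains, arma::fill::zeros);
  arma::vec eps_final(n_chains, arma::fill::zeros);
  IntegerVector chain_id(n_iter * n_chains);
  RNGScope scope;
  const int per_ll = thin_ll > 0 ? n_iter / thin_ll : 0;

  for (int ch = 0; ch < n_chains; ++ch) {
    arma::mat Lc = L;                     // per-chain (re-scaled in warmup)
    arma::vec xi(d);
    for (int j = 0; j < d; ++j) xi(j) = R::norm_rand();
    arma::vec th = start + jitter * (Lc * xi);
    arma::vec phi = arma::solve(arma::trimatl(Lc), th);
    arma::vec g(d), llvec;
    double lp = mod.lp_grad(th, g, nullptr);
    arma::vec gw = Lc.t() * g;            // gradient in whitened space
    double leps = std::log(eps0);
    double acc_sum = 0.0;
    int ll_row = 0;
    // windowed scale adaptation: collect whitened draws mid-warmup and
    // rescale the mass matrix columns by their empirical SDs
    int win_lo = (int)(0.3 * n_warmup), win_hi = (int)(0.7 * n_warmup);
    bool do_window = n_warmup >= 100;
    arma::vec m1(d, arma::fill::zeros), m2(d, arma::fill::zeros);
    int win_n = 0;
    for (int it = 0; it < n_warmup + n_iter; ++it) {
      double eps = std::exp(leps);
      int steps = 1 + (int)std::floor(R::unif_rand() * n_leapfrog);
      arma::vec p(d);
      for (int j = 0; j < d; ++j) p(j) = R::norm_rand();
      double H0 = -lp + 0.5 * arma::dot(p, p);
      arma::vec phi_p = phi, gw_p = gw, g_p = g;
      double lp_p = lp;
      bool ok = true;
      for (int s = 0; s < steps; ++s) {
        p += 0.5 * eps * gw_p;
        phi_p += eps * p;
        arma::vec th_p = Lc * phi_p;
        lp_p = mod.lp_grad(th_p, g_p, nullptr);
        if (!std::isfinite(lp_p)) { ok = false; break; }
        gw_p = Lc.t() * g_p;
        p += 0.5 * eps * gw_p;
      }
      double log_acc = -HUGE_VAL;
      if (ok) log_acc = -(-lp_p + 0.5 * arma::dot(p, p)) + H0;
      bool acc = std::log(R::unif_rand()) < log_acc;
      if (acc) { phi = phi_p; gw = gw_p; g = g_p; lp = lp_p; }
      double a = ok ? std::min(1.0, std::exp(log_acc)) : 0.0;
      {                                   // Gibbs refresh of the RE scale
        arma::vec th_cur = Lc * phi;
        if (mod.gibbs_scale(th_cur)) {
          phi = arma::solve(arma::trimatl(Lc), th_cur);
          lp = mod.lp_grad(th_cur, g, nullptr);
          gw = Lc.t() * g;
        }
      }
      if (it < n_warmup) {
        leps += (a - 0.8) * 1.0 / std::pow(it + 10.0, 0.6);
        if (do_window && it >= win_lo && it < win_hi) {
          m1 += phi; m2 += phi % phi; ++win_n;
        }
        if (do_window && it == win_hi && win_n > 10) {
          arma::vec sd = arma::sqrt(arma::clamp(
            m2 / win_n - arma::square(m1 / win_n), 1e-12, arma::datum::inf));
          sd = arma::clamp(sd, 0.2, 10.0);
          arma::vec th_cur = Lc * phi;     // current position, theta scale
          Lc = Lc * arma::diagmat(sd);
          phi = arma::solve(arma::trimatl(Lc), th_cur);
          gw = Lc.t() * g;
          leps = std::log(eps0);           // re-tune step size
        }
      } else {
        int k = it - n_warmup;
        arma::vec th_cur = Lc * phi;
        draws.row(ch * n_iter + k) = th_cur.t();
        chain_id[ch * n_iter + k] = ch + 1;
        acc_sum += a;
        if (thin_ll > 0 && (k + 1) % thin_ll == 0) {
          arma::vec dummy(d);
          mod.lp_grad(th_cur, dummy, &llvec);
          if (ll_store.n_rows == 0) {
            ll_store.set_size(per_ll * n_chains, llvec.n_elem);
          }
          ll_store.row(ch * per_ll + ll_row) = llvec.t();
          ++ll_row;
        }
      }
      if (it % 64 == 0) Rcpp::checkUserInterrupt();
    }
    accept(ch) = acc_sum / n_iter;
    eps_final(ch) = std::exp(leps);
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept"] = accept, _["loglik"] = ll_store,
                      _["eps"] = eps_final);
}

// ---------------------------------------------------------------------------
// Exported interfaces
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dirichlet_lp_cpp(arma::vec theta, arma::mat X, arma::mat logY,
                      arma::ivec herd, int H, bool prior_only = false,
                      bool centered = true) {
  DirModel mod{X, logY, herd, H, prior_only, centered};
  arma::vec grad;
  double lp = mod.lp_grad(theta, grad, nullptr);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
arma::vec dirichlet_ll_cpp(arma::vec theta, arma::mat X, arma::mat logY,
                           arma::ivec herd, int H, bool centered = true) {
  DirModel mod{X, logY, herd, H, false, centered};
  arma::vec grad, ll;
  mod.lp_grad(theta, grad, &ll);
  return ll;
}

// [[Rcpp::export]]
List dirichlet_sample_cpp(arma::mat X, arma::mat logY, arma::ivec herd,
                          int H, arma::vec start, arma::mat L, int n_chains,
                          int n_warmup, int n_iter, double eps0,
                          double jitter, int thin_ll, int n_leapfrog,
                          bool prior_only = false, bool centered = true) {
  DirModel mod{X, logY, herd, H, prior_only, centered};
  return run_hmc(mod, start, L, n_chains, n_warmup, n_iter, eps0, jitter,
                 prior_only ? 0 : thin_ll, n_leapfrog);
}

// [[Rcpp::export]]
List bernoulli_lp_cpp(arma::vec theta, arma::mat W, arma::vec y,
                      arma::ivec sess, int S, bool prior_only = false,
                      bool centered = false) {
  BernModel mod{W, y, sess, S, prior_only, centered};
  arma::vec grad;
  double lp = mod.lp_grad(theta, grad, nullptr);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
List bernoulli_sample_cpp(arma::mat W, arma::vec y, arma::ivec sess, int S,
                          arma::vec start, arma::mat L, int n_chains,
                          int n_warmup, int n_iter, double eps0,
                          double jitter, int thin_ll, int n_leapfrog,
                          bool prior_only = false, bool centered = false) {
  BernModel mod{W, y, sess, S, prior_only, centered};
  return run_hmc(mod, start, L, n_chains, n_warmup, n_iter, eps0, jitter,
                 prior_only ? 0 : thin_ll, n_leapfrog);
}
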