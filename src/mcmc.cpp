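// Metropolis-within-Gibbs kernel for the two-method N-mixture model.
//
// State: latent site abundances N_i, abundance coefficients (beta0, beta_j),
// Kuo-Mallick inclusion indicators w_j, per-method detection coefficients
// (alpha0_m, alpha_mk). One iteration sweeps, in order: N (per-site integer
// random walk), abundance coefficients (scalar Gaussian random walk; when
// w_j = 0 beta_j is drawn directly from its prior, which is its exact full
// conditional), indicators (Gibbs from the Bernoulli full conditional with
// beta_j held fixed), detection coefficients (one Gaussian random-walk block
// per method).
//
// Proposal scales adapt toward a target acceptance rate during burn-in only
// and are frozen afterwards, preserving stationarity of the post-burn-in
// chain.
//
// Observed site-occasion cells are flattened per method; log p and log(1-p)
// are both derived from one cached softplus of the detection linear
// predictor. All randomness comes from R's RNG (set.seed on the R side).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF_SENTINEL = -1e300;

// log-factorial table, grown on demand: lgt(k) = lgamma(k + 1)
struct LgTable {
  std::vector<double> v;
  LgTable() { grow(256); }
  void grow(int upto) {
    int old = (int)v.size();
    if (upto < old) return;
    v.resize(upto + 1);
    for (int k = old; k <= upto; ++k) v[k] = std::lgamma((double)k + 1.0);
  }
  inline double operator()(int k) {
    if (k >= (int)v.size()) grow(k * 2 + 16);
    return v[k];
  }
};

static inline double softplus(double x) {  // log(1 + e^x)
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// flattened observed cells for one detection method, grouped by site
struct MethodObs {
  int Tm, K;
  std::vector<int> y;                    // observed count per cell
  std::vector<int> row_ptr;              // site i -> cells [row_ptr[i], row_ptr[i+1])
  std::vector<std::vector<double> > V;   // K covariate values per cell
  std::vector<double> eta, q;            // cached linear predictor, softplus(eta)
  std::vector<double> eta2, q2;          // proposal scratch
  // log p = eta - q ; log(1 - p) = -q
};

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(List y_list, NumericMatrix X, List V_list,
                double prior_sd_coef, double prior_pi,
                int n_iter, int burn_in, int thin,
                bool select, bool sample_detection, bool save_N,
                int step_N, double prop_sd_coef, double prop_sd_alpha,
                int adapt_window,
                double init_beta0, NumericVector init_beta,
                IntegerVector init_w, List init_alpha, IntegerVector init_N,
                bool do_N, bool do_coef, bool gibbs_N) {
  const int M = y_list.size();
  const int n = X.nrow();
  const int J = X.ncol();

  // parameter state
  double beta0 = init_beta0;
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<int> w(init_w.begin(), init_w.end());
  std::vector<std::vector<double> > alpha(M);
  std::vector<int> N(init_N.begin(), init_N.end());

  std::vector<MethodObs> obs(M);
  std::vector<int> lb(n, 0);
  for (int m = 0; m < M; ++m) {
    IntegerMatrix Y = y_list[m];
    List vm = V_list[m];
    MethodObs &o = obs[m];
    o.Tm = Y.ncol();
    o.K = vm.size();
    std::vector<NumericMatrix> Vk;
    for (int k = 0; k < o.K; ++k) Vk.push_back(as<NumericMatrix>(vm[k]));
    o.V.resize(o.K);
    o.row_ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      o.row_ptr[i] = (int)o.y.size();
      for (int t = 0; t < o.Tm; ++t) {
        int yv = Y(i, t);
        if (yv == NA_INTEGER) continue;
        o.y.push_back(yv);
        if (yv > lb[i]) lb[i] = yv;
        for (int k = 0; k < o.K; ++k) o.V[k].push_back(Vk[k](i, t));
      }
    }
    o.row_ptr[n] = (int)o.y.size();
    o.eta.resize(o.y.size()); o.q.resize(o.y.size());
    o.eta2.resize(o.y.size()); o.q2.resize(o.y.size());
    NumericVector am = init_alpha[m];
    alpha[m].assign(am.begin(), am.end());  // intercept first, then slopes
  }
  for (int i = 0; i < n; ++i)
    if (N[i] < lb[i]) stop("initial latent N below max observed count at site %d", i + 1);

  // positive observed counts per site (only these enter the enumeration
  // ratios f(N+1)/f(N); zero counts contribute through Q alone)
  std::vector<int> ypos, ypos_ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    ypos_ptr[i] = (int)ypos.size();
    for (int m = 0; m < M; ++m) {
      MethodObs &o = obs[m];
      for (int c = o.row_ptr[i]; c < o.row_ptr[i + 1]; ++c)
        if (o.y[c] > 0) ypos.push_back(o.y[c]);
    }
  }
  ypos_ptr[n] = (int)ypos.size();

  LgTable lg;

  // cached abundance linear predictor and sums
  std::vector<double> eta(n), lam(n);
  double sumN = 0.0, sumLam = 0.0;
  {
    sumLam = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = beta0;
      for (int j = 0; j < J; ++j) if (w[j]) e += beta[j] * X(i, j);
      eta[i] = e;
      lam[i] = std::exp(e);
      sumLam += lam[i];
    }
    if (!std::isfinite(sumLam))
      stop("non-finite expected abundance at initialization");
    for (int i = 0; i < n; ++i) sumN += N[i];
  }

  // cached detection predictors over observed cells
  auto refresh_det = [&](int m) {
    MethodObs &o = obs[m];
    for (int i = 0; i < n; ++i)
      for (int c = o.row_ptr[i]; c < o.row_ptr[i + 1]; ++c) {
        double e = alpha[m][0];
        for (int k = 0; k < o.K; ++k) e += alpha[m][k + 1] * o.V[k][c];
        o.eta[c] = e;
        o.q[c] = softplus(e);
      }
  };
  for (int m = 0; m < M; ++m) refresh_det(m);

  // adaptive proposal scales: 1 + J scalar coefficient scales, M block
  // scales, one ridge scale
  std::vector<double> sd_b(1 + J, prop_sd_coef), sd_a(M, prop_sd_alpha);
  double sd_ridge = prop_sd_coef;
  std::vector<int> acc_b(1 + J, 0), try_b(1 + J, 0), acc_a(M, 0), try_a(M, 0);
  int acc_r = 0, try_r = 0;
  long accN_post = 0, tryN_post = 0, accr_post = 0, tryr_post = 0;
  std::vector<long> accb_post(1 + J, 0), tryb_post(1 + J, 0),
                    acca_post(M, 0), trya_post(M, 0);

  // exact Gibbs draw of every N_i from its enumerated full conditional
  std::vector<double> gprobs;
  auto gibbs_refresh = [&]() {
    for (int i = 0; i < n; ++i) {
      double Q = 0.0;  // sum of log(1-p) over the site's observed cells
      for (int m = 0; m < M; ++m) {
        MethodObs &o = obs[m];
        for (int c = o.row_ptr[i]; c < o.row_ptr[i + 1]; ++c) Q -= o.q[c];
      }
      double lamQ = lam[i] * std::exp(Q);
      if (ypos_ptr[i] == ypos_ptr[i + 1]) {
        // no positive counts: the full conditional is exactly
        // Poisson(lambda * prod(1-p)) (lower bound is 0 here)
        if (lamQ > 1e9) lamQ = 1e9;   // unphysical transient guard
        int pick = (int)R::rpois(lamQ);
        sumN += pick - N[i];
        N[i] = pick;
        continue;
      }
      double capd = lamQ + 10.0 * std::sqrt(lamQ + 1.0) + 30.0;
      if (capd > 200000.0) capd = 200000.0;  // unphysical transient guard
      int cap = lb[i] + (int)capd;
      gprobs.clear();
      gprobs.push_back(1.0);
      double f = 1.0, fsum = 1.0, fmax = 1.0;
      for (int Nn = lb[i] + 1; Nn <= cap; ++Nn) {
        // f(N)/f(N-1) for the Poisson-binomial full conditional
        double r = lamQ / (double)Nn;
        for (int c = ypos_ptr[i]; c < ypos_ptr[i + 1]; ++c)
          r *= (double)Nn / (double)(Nn - ypos[c]);
        f *= r;
        if (f > 1e250) {  // rescale to avoid overflow
          for (size_t k = 0; k < gprobs.size(); ++k) gprobs[k] *= 1e-200;
          f *= 1e-200; fsum *= 1e-200; fmax *= 1e-200;
        }
        gprobs.push_back(f);
        fsum += f;
        if (f > fmax) fmax = f;
        if (r < 1.0 && f < fmax * 1e-12) break;
      }
      double u = unif_rand() * fsum, accum = 0.0;
      int pick = lb[i] + (int)gprobs.size() - 1;
      for (size_t k = 0; k < gprobs.size(); ++k) {
        accum += gprobs[k];
        if (u <= accum) { pick = lb[i] + (int)k; break; }
      }
      sumN += pick - N[i];
      N[i] = pick;
    }
  };

  const double pv = 2.0 * prior_sd_coef * prior_sd_coef;  // 2 sigma^2
  const double logit_pi = std::log(prior_pi) - std::log1p(-prior_pi);

  const int n_saved = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  int nA = 0; for (int m = 0; m < M; ++m) nA += 1 + obs[m].K;
  int P = 1 + 2 * J + nA;
  NumericMatrix out(n_saved, P);
  IntegerMatrix Nout(save_N ? n_saved : 0, save_N ? n : 0);
  int isave = 0;
  std::vector<double> dlt;  // block proposal scratch

  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = (iter <= burn_in);

    // ---- latent abundance: per-site integer random walk ----
    if (do_N) {
      for (int i = 0; i < n; ++i) {
        int u = 1 + (int)(unif_rand() * step_N);
        if (u > step_N) u = step_N;
        int Nn = N[i] + ((unif_rand() < 0.5) ? -u : u);
        if (!adapting) ++tryN_post;
        if (Nn < lb[i]) continue;  // outside support: reject
        double d = (Nn - N[i]) * eta[i] - (lg(Nn) - lg(N[i]));  // Poisson part
        for (int m = 0; m < M; ++m) {
          MethodObs &o = obs[m];
          for (int c = o.row_ptr[i]; c < o.row_ptr[i + 1]; ++c) {
            int yv = o.y[c];
            d += (lg(Nn) - lg(Nn - yv)) - (lg(N[i]) - lg(N[i] - yv))
                 - (double)(Nn - N[i]) * o.q[c];   // log(1-p) = -q
          }
        }
        if (d >= 0.0 || std::log(unif_rand()) < d) {
          sumN += Nn - N[i];
          N[i] = Nn;
          if (!adapting) ++accN_post;
        }
      }
    }

    // ---- latent abundance: exact Gibbs refresh by enumeration ----
    // The random-walk move alone mixes slowly along the N ~ 1/p ridge when
    // detection is weak; drawing N_i from its full conditional
    // p(N | lambda_i, y_i, p_i) removes the latent autocorrelation.
    if (do_N && gibbs_N) gibbs_refresh();

    // ---- abundance coefficients ----
    if (do_coef) {
      {  // intercept: O(1) via cached sums
        double dl = norm_rand() * sd_b[0];
        double d = dl * sumN - std::expm1(dl) * sumLam
                   + (beta0 * beta0 - (beta0 + dl) * (beta0 + dl)) / pv;
        ++try_b[0]; if (!adapting) ++tryb_post[0];
        if (std::isfinite(d) && (d >= 0.0 || std::log(unif_rand()) < d)) {
          beta0 += dl;
          double f = std::exp(dl);
          sumLam = 0.0;
          for (int i = 0; i < n; ++i) { eta[i] += dl; lam[i] *= f; sumLam += lam[i]; }
          ++acc_b[0]; if (!adapting) ++accb_post[0];
        }
      }
      for (int j = 0; j < J; ++j) {
        if (!w[j]) {  // excluded: full conditional is the prior
          beta[j] = norm_rand() * prior_sd_coef;
          continue;
        }
        double dl = norm_rand() * sd_b[1 + j];
        double bn = beta[j] + dl;
        double d = (beta[j] * beta[j] - bn * bn) / pv;
        for (int i = 0; i < n; ++i) {
          double de = dl * X(i, j);
          d += N[i] * de - lam[i] * std::expm1(de);
        }
        ++try_b[1 + j]; if (!adapting) ++tryb_post[1 + j];
        if (std::isfinite(d) && (d >= 0.0 || std::log(unif_rand()) < d)) {
          beta[j] = bn;
          sumLam = 0.0;
          for (int i = 0; i < n; ++i) {
            eta[i] += dl * X(i, j);
            lam[i] = std::exp(eta[i]);
            sumLam += lam[i];
          }
          ++acc_b[1 + j]; if (!adapting) ++accb_post[1 + j];
        }
      }
    }

    // ---- inclusion indicators (Kuo-Mallick Gibbs) ----
    if (select) {
      for (int j = 0; j < J; ++j) {
        double s = w[j] ? -1.0 : 1.0;  // toggle direction
        double dtog = 0.0;             // loglik(toggled) - loglik(current)
        for (int i = 0; i < n; ++i) {
          double de = s * beta[j] * X(i, j);
          dtog += N[i] * de - lam[i] * std::expm1(de);
        }
        double llr = w[j] ? -dtog : dtog;  // loglik(w=1) - loglik(w=0)
        double z = logit_pi + llr;
        double p1 = z > 35 ? 1.0 : (z < -35 ? 0.0 : 1.0 / (1.0 + std::exp(-z)));
        int wn = (unif_rand() < p1) ? 1 : 0;
        if (wn != w[j]) {
          w[j] = wn;
          sumLam = 0.0;
          for (int i = 0; i < n; ++i) {
            eta[i] += s * beta[j] * X(i, j);
            lam[i] = std::exp(eta[i]);
            sumLam += lam[i];
          }
        }
      }
    }

    // ---- detection coefficients: one random-walk block per method ----
    if (sample_detection) {
      for (int m = 0; m < M; ++m) {
        MethodObs &o = obs[m];
        int nb = 1 + o.K;
        dlt.assign(nb, 0.0);
        double d = 0.0;
        for (int k = 0; k < nb; ++k) {
          dlt[k] = norm_rand() * sd_a[m];
          double an = alpha[m][k] + dlt[k];
          d += (alpha[m][k] * alpha[m][k] - an * an) / pv;
        }
        for (int i = 0; i < n; ++i) {
          int c0 = o.row_ptr[i], c1 = o.row_ptr[i + 1];
          for (int c = c0; c < c1; ++c) {
            double e2 = o.eta[c] + dlt[0];
            for (int k = 0; k < o.K; ++k) e2 += dlt[k + 1] * o.V[k][c];
            double q2 = softplus(e2);
            o.eta2[c] = e2; o.q2[c] = q2;
            // y (log p' - log p) + (N - y)(log(1-p') - log(1-p))
            d += o.y[c] * (e2 - o.eta[c]) - (double)N[i] * (q2 - o.q[c]);
          }
        }
        ++try_a[m]; if (!adapting) ++trya_post[m];
        if (std::isfinite(d) && (d >= 0.0 || std::log(unif_rand()) < d)) {
          for (int k = 0; k < nb; ++k) alpha[m][k] += dlt[k];
          o.eta.swap(o.eta2);
          o.q.swap(o.q2);
          ++acc_a[m]; if (!adapting) ++acca_post[m];
        }
      }
    }

    // ---- intercept ridge move ----
    // When detection is weak the marginal posterior has a long ridge along
    // (log lambda up, logit p down): total expected detections stay fixed.
    // Componentwise moves cross it slowly, so propose beta0 + d together
    // with every detection intercept - d, with the latent N summed out per
    // site by the same enumeration recurrence the Gibbs refresh uses.
    if (sample_detection && do_coef && gibbs_N) {
      double dl = norm_rand() * sd_ridge;
      double d = 0.0;
      // priors for beta0 and the shifted intercepts
      {
        double b2 = beta0 + dl;
        d += (beta0 * beta0 - b2 * b2) / pv;
        for (int m = 0; m < M; ++m) {
          double a2 = alpha[m][0] - dl;
          d += (alpha[m][0] * alpha[m][0] - a2 * a2) / pv;
        }
      }
      // proposed detection caches (intercept shift only)
      for (int m = 0; m < M; ++m) {
        MethodObs &o = obs[m];
        for (size_t c = 0; c < o.eta.size(); ++c) {
          o.eta2[c] = o.eta[c] - dl;
          o.q2[c] = softplus(o.eta2[c]);
        }
      }
      double edl = std::exp(dl);
      // marginal (over N) log-likelihood ratio, site by site
      for (int i = 0; i < n; ++i) {
        double base_cur = 0.0, base_new = 0.0;   // log f(lb) pieces
        double Qc = 0.0, Qn = 0.0;
        int lbi = lb[i], ncell = 0;
        for (int m = 0; m < M; ++m) {
          MethodObs &o = obs[m];
          for (int c = o.row_ptr[i]; c < o.row_ptr[i + 1]; ++c) {
            ++ncell;
            int yv = o.y[c];
            base_cur += lg(lbi) - lg(yv) - lg(lbi - yv)
                        + yv * (o.eta[c] - o.q[c]) - (lbi - yv) * o.q[c];
            base_new += lg(lbi) - lg(yv) - lg(lbi - yv)
                        + yv * (o.eta2[c] - o.q2[c]) - (lbi - yv) * o.q2[c];
            Qc -= o.q[c]; Qn -= o.q2[c];
          }
        }
        if (ncell == 0) continue;   // marginal is 1 under any parameters
        double lam_cur = lam[i], lam_new = lam[i] * edl;
        if (ypos_ptr[i] == ypos_ptr[i + 1]) {
          // all observed counts zero: marginal = exp(lambda (e^Q - 1))
          d += lam_new * std::expm1(Qn) - lam_cur * std::expm1(Qc);
          continue;
        }
        base_cur += lbi * eta[i] - lam_cur - lg(lbi);
        base_new += lbi * (eta[i] + dl) - lam_new - lg(lbi);
        d += base_new - base_cur;
        // truncated sums, each normalized to its own f(lb) = 1
        double lamQ_cur = lam_cur * std::exp(Qc);
        double lamQ_new = lam_new * std::exp(Qn);
        for (int pass = 0; pass < 2; ++pass) {
          double lamQ = pass ? lamQ_new : lamQ_cur;
          double capd = lamQ + 10.0 * std::sqrt(lamQ + 1.0) + 30.0;
          if (capd > 200000.0) capd = 200000.0;  // unphysical transient guard
          int cap = lbi + (int)capd;
          double f = 1.0, fsum = 1.0, fmax = 1.0;
          for (int Nn = lbi + 1; Nn <= cap; ++Nn) {
            double r = lamQ / (double)Nn;
            for (int c = ypos_ptr[i]; c < ypos_ptr[i + 1]; ++c)
              r *= (double)Nn / (double)(Nn - ypos[c]);
            f *= r;
            fsum += f;
            if (f > fmax) fmax = f;
            if (r < 1.0 && f < fmax * 1e-12) break;
            if (f > 1e250) { f *= 1e-250; fsum *= 1e-250; fmax *= 1e-250; }
          }
          d += pass ? std::log(fsum) : -std::log(fsum);
        }
      }
      ++try_r; if (!adapting) ++tryr_post;
      if (std::isfinite(d) && (d >= 0.0 || std::log(unif_rand()) < d)) {
        beta0 += dl;
        sumLam = 0.0;
        for (int i = 0; i < n; ++i) {
          eta[i] += dl; lam[i] *= edl; sumLam += lam[i];
        }
        for (int m = 0; m < M; ++m) {
          alpha[m][0] -= dl;
          obs[m].eta.swap(obs[m].eta2);
          obs[m].q.swap(obs[m].q2);
        }
        // exactness of the marginal ratio requires N to be redrawn from
        // its full conditional under the accepted parameters
        gibbs_refresh();
        ++acc_r; if (!adapting) ++accr_post;
      }
    }

    // ---- proposal-scale adaptation (burn-in only) ----
    if (adapting && adapt_window > 0 && iter % adapt_window == 0) {
      for (int j = 0; j < 1 + J; ++j) {
        if (try_b[j] > 0) {
          double r = (double)acc_b[j] / try_b[j];
          sd_b[j] *= std::exp(1.5 * (r - 0.35));
          if (sd_b[j] < 1e-4) sd_b[j] = 1e-4;
          if (sd_b[j] > 5.0) sd_b[j] = 5.0;
        }
        acc_b[j] = try_b[j] = 0;
      }
      for (int m = 0; m < M; ++m) {
        if (try_a[m] > 0) {
          double r = (double)acc_a[m] / try_a[m];
          sd_a[m] *= std::exp(1.5 * (r - 0.25));  // block target
          if (sd_a[m] < 1e-4) sd_a[m] = 1e-4;
          if (sd_a[m] > 5.0) sd_a[m] = 5.0;
        }
        acc_a[m] = try_a[m] = 0;
      }
      if (try_r > 0) {
        double r = (double)acc_r / try_r;
        sd_ridge *= std::exp(1.5 * (r - 0.35));
        if (sd_ridge < 1e-4) sd_ridge = 1e-4;
        if (sd_ridge > 5.0) sd_ridge = 5.0;
        acc_r = try_r = 0;
      }
    }

    // ---- save ----
    if (iter > burn_in && (iter - burn_in) % thin == 0 && isave < n_saved) {
      int c = 0;
      out(isave, c++) = beta0;
      for (int j = 0; j < J; ++j) out(isave, c++) = beta[j];
      for (int j = 0; j < J; ++j) out(isave, c++) = (double)w[j];
      for (int m = 0; m < M; ++m)
        for (int k = 0; k <= obs[m].K; ++k) out(isave, c++) = alpha[m][k];
      if (save_N) for (int i = 0; i < n; ++i) Nout(isave, i) = N[i];
      ++isave;
    }

    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rates_b(1 + J), acc_rates_a(M);
  for (int j = 0; j < 1 + J; ++j)
    acc_rates_b[j] = tryb_post[j] ? (double)accb_post[j] / tryb_post[j] : NA_REAL;
  for (int m = 0; m < M; ++m)
    acc_rates_a[m] = trya_post[m] ? (double)acca_post[m] / trya_post[m] : NA_REAL;
  double accN = tryN_post ? (double)accN_post / tryN_post : NA_REAL;
  double accR = tryr_post ? (double)accr_post / tryr_post : NA_REAL;

  List alpha_fin(M);
  for (int m = 0; m < M; ++m)
    alpha_fin[m] = NumericVector(alpha[m].begin(), alpha[m].end());
  List fin = List::create(
    _["beta0"] = beta0, _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["w"] = IntegerVector(w.begin(), w.end()),
    _["alpha"] = alpha_fin,
    _["N"] = IntegerVector(N.begin(), N.end()));

  return List::create(
    _["draws"] = out, _["N_draws"] = Nout,
    _["accept_coef"] = acc_rates_b, _["accept_alpha"] = acc_rates_a,
    _["accept_N"] = accN, _["accept_ridge"] = accR,
    _["prop_sd_coef"] = NumericVector(sd_b.begin(), sd_b.end()),
    _["prop_sd_alpha"] = NumericVector(sd_a.begin(), sd_a.end()),
    _["final_state"] = fin);
}
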