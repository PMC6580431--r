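#include <Rcpp.h>
using namespace Rcpp;

// Core likelihood machinery for the Jolly-Seber superpopulation model with
// finite-mixture heterogeneity.  An individual's history probability is the
// mixture (over latent classes) of sums over all (entry day b, departure day
// d) pairs consistent with its first and last detections:
//
//   P(y | h) = sum_{b <= f} sum_{d >= l}
//              beta_b * prod_{t=b}^{d-1} phi_{t,h} * [d < K] (1 - phi_{d,h})
//                     * prod_{t=b}^{d} p_{t,h}^{y_t} (1 - p_{t,h})^{1-y_t}
//
// with right truncation at occasion K (an individual present at K contributes
// no departure factor).  Everything is accumulated in linear space: factors
// are probabilities, windows are short (K ~ 15-21), so underflow is not a
// concern and exact-zero parameters give exact-zero path probabilities.

// Probability of one encounter history for one class, by direct summation
// over (entry, departure) pairs.  All indices 0-based; f = first detection,
// l = last detection.  For the never-detected "history" pass f = K-1, l = 0
// and an all-zero row.
static double history_prob_class(const IntegerMatrix &Y, int u, int f, int l,
                                 const NumericVector &beta,
                                 const NumericMatrix &phi,
                                 const NumericMatrix &p, int h, int K) {
  double tot = 0.0;
  for (int b = 0; b <= f; ++b) {
    int d0 = (b > l) ? b : l;
    double stay = 1.0, det = 1.0;
    for (int t = b; t <= d0; ++t)
      det *= (Y(u, t) == 1) ? p(t, h) : (1.0 - p(t, h));
    for (int t = b; t < d0; ++t)
      stay *= phi(t, h);
    double acc = 0.0;
    for (int d = d0; d < K; ++d) {
      if (d > d0) {
        stay *= phi(d - 1, h);
        det *= (Y(u, d) == 1) ? p(d, h) : (1.0 - p(d, h));
      }
      double dep = (d < K - 1) ? (1.0 - phi(d, h)) : 1.0;
      acc += stay * det * dep;
    }
    tot += beta[b] * acc;
  }
  return tot;
}

// [[Rcpp::export]]
List js_lik_core(NumericVector beta, NumericMatrix phi, NumericMatrix p,
                 NumericVector omega, IntegerMatrix Y, IntegerVector first,
                 IntegerVector last, NumericVector freq, bool conditional) {
  const int K = beta.size();
  const int H = omega.size();
  const int U = Y.nrow();

  // Fast path, available whenever no encounter probability sits on the
  // 0/1 boundary: the detection product over a window [b, d] factorizes
  // into prod_{t in [b,d]} (1 - p_t) times a per-history odds factor
  // prod_{detection days} p_t / (1 - p_t) (detections always fall inside
  // the window).  The window part is shared by all histories and only
  // its rectangle sums S(f, l) = sum_{b <= f, d >= max(b, l)} are needed.
  bool interior = true;
  for (int h = 0; h < H && interior; ++h)
    for (int t = 0; t < K; ++t)
      if (p(t, h) <= 1e-12 || p(t, h) >= 1.0 - 1e-12) {
        interior = false;
        break;
      }

  NumericVector p0h(H);
  double p0 = 0.0;
  NumericVector probs(U);
  double ll = 0.0;
  double n = 0.0;

  if (interior) {
    std::vector<double> SW(K * K * H);
    for (int h = 0; h < H; ++h) {
      std::vector<double> W(K * K, 0.0);
      for (int b = 0; b < K; ++b) {
        double stay = 1.0, q = 1.0;
        for (int d = b; d < K; ++d) {
          if (d > b)
            stay *= phi(d - 1, h);
          q *= (1.0 - p(d, h));
          double dep = (d < K - 1) ? (1.0 - phi(d, h)) : 1.0;
          W[b * K + d] = beta[b] * stay * q * dep;
        }
      }
      double *S = &SW[K * K * h];
      for (int d = 0; d < K; ++d)
        for (int b = 0; b < K; ++b)
          S[b * K + d] = W[b * K + d] + (b > 0 ? S[(b - 1) * K + d] : 0.0);
      for (int b = 0; b < K; ++b)
        for (int d = K - 2; d >= 0; --d)
          S[b * K + d] += S[b * K + d + 1];
      p0h[h] = S[(K - 1) * K + 0];
      p0 += omega[h] * p0h[h];
    }
    for (int u = 0; u < U; ++u) {
      double mix = 0.0;
      int f = first[u] - 1, l = last[u] - 1;
      for (int h = 0; h < H; ++h) {
        double r = 1.0;
        for (int t = f; t <= l; ++t)
          if (Y(u, t) == 1)
            r *= p(t, h) / (1.0 - p(t, h));
        mix += omega[h] * r * SW[f * K + l + K * K * h];
      }
      probs[u] = mix;
      ll += freq[u] * std::log(mix);
      n += freq[u];
    }
  } else {
    // boundary-safe direct summation per history
    IntegerMatrix Z(1, K); // zeros
    for (int h = 0; h < H; ++h) {
      p0h[h] = history_prob_class(Z, 0, K - 1, 0, beta, phi, p, h, K);
      p0 += omega[h] * p0h[h];
    }
    for (int u = 0; u < U; ++u) {
      double mix = 0.0;
      for (int h = 0; h < H; ++h)
        mix += omega[h] * history_prob_class(Y, u, first[u] - 1, last[u] - 1,
                                             beta, phi, p, h, K);
      probs[u] = mix;
      ll += freq[u] * std::log(mix); // log(0) = -Inf: impossible history
      n += freq[u];
    }
  }
  if (conditional && U > 0) {
    if (p0 >= 1.0)
      ll = R_NegInf;
    else
      ll -= n * std::log1p(-p0);
  }
  return List::create(_["loglik"] = ll, _["probs"] = probs, _["p0"] = p0,
                      _["p0_class"] = p0h);
}

// ---------------------------------------------------------------------------
// Collapsed Gibbs sampler for the Bayesian state-space formulation with
// parameter-expanded data augmentation.  Latent structure per augmented
// individual: inclusion w_i, class h_i, entry day b_i, departure day d_i
// (the presence row z_i is the contiguous run [b_i, d_i]).  The (h, b, d) of
// excluded (w = 0) individuals are marginalized out; they re-enter the state
// when w flips to 1, drawn from their exact joint conditional.
//
// Detection structures (det_mode):
//   0 : single constant p                      (conjugate)
//   1 : class-specific constants p_h           (conjugate)
//   2 : daily p_t shared across classes        (conjugate)
//   3 : daily p_t with additive class offset on the logit scale:
//       logit p_{t,h} = eta_t + delta * [h = 2]   (Metropolis within Gibbs)
// Staying structures (phi_mode): 0 pooled constant, 1 class-specific constant.
// Entry is always day-specific with a flat Dirichlet prior on beta.

static double rdirich_component(double shape) { return R::rgamma(shape, 1.0); }

// [[Rcpp::export]]
List jse_mcmc_core(IntegerMatrix Yobs, int A, int H, int phi_mode, int det_mode,
                   int n_iter, int n_burn, int thin, List inits, double rw_eta,
                   double rw_delta, bool store_latent, bool update_omega) {
  const int K = Yobs.ncol();
  const int nobs = Yobs.nrow();
  if (A < nobs)
    stop("augmented size smaller than number observed");

  // observed summaries
  std::vector<int> f(nobs), l(nobs);
  std::vector<std::vector<int> > detdays(nobs);
  for (int i = 0; i < nobs; ++i) {
    int fi = -1, li = -1;
    for (int t = 0; t < K; ++t)
      if (Yobs(i, t) == 1) {
        if (fi < 0)
          fi = t;
        li = t;
        detdays[i].push_back(t);
      }
    if (fi < 0)
      stop("observed history with no detections");
    f[i] = fi;
    l[i] = li;
  }

  // parameters
  double psi = as<double>(inits["psi"]);
  std::vector<double> omega = as<std::vector<double> >(inits["omega"]);
  std::vector<double> phiC = as<std::vector<double> >(inits["phi"]); // per class
  std::vector<double> beta = as<std::vector<double> >(inits["beta"]);
  std::vector<double> pt(K), eta(K);
  double pconst = 0.3, delta = 0.0;
  std::vector<double> ph(H, 0.3);
  if (det_mode == 0)
    pconst = as<double>(inits["p"]);
  else if (det_mode == 1)
    ph = as<std::vector<double> >(inits["p"]);
  else if (det_mode == 2) {
    NumericVector tmp = inits["p"];
    for (int t = 0; t < K; ++t)
      pt[t] = tmp[t % tmp.size()];
  } else {
    NumericVector tmp = inits["p"];
    for (int t = 0; t < K; ++t)
      eta[t] = std::log(tmp[t % tmp.size()] / (1 - tmp[t % tmp.size()]));
    delta = as<double>(inits["delta"]);
  }

  // latent state
  std::vector<int> w(A, 0), hcl(A, 0), bb(A, 0), dd(A, 0);
  for (int i = 0; i < nobs; ++i) {
    w[i] = 1;
    hcl[i] = i % H;
    bb[i] = f[i];
    dd[i] = l[i];
  }

  const int n_keep = (n_iter - n_burn) / thin;
  NumericVector d_psi(n_keep), d_M(n_keep), d_Sbar(n_keep), d_delta(n_keep);
  NumericMatrix d_omega(n_keep, H), d_phi(n_keep, H), d_beta(n_keep, K),
      d_p(n_keep, K * H);
  IntegerMatrix d_w, d_b, d_d;
  IntegerVector d_h;
  if (store_latent) {
    d_w = IntegerMatrix(n_keep, A);
    d_b = IntegerMatrix(n_keep, A);
    d_d = IntegerMatrix(n_keep, A);
  }
  int acc_eta = 0, prop_eta = 0, acc_delta = 0, prop_delta = 0;

  std::vector<double> pmat(K * H); // pmat[t + K*h]
  std::vector<double> W(K * K * H); // W[b*K + d + K*K*h], 0 for d < b
  std::vector<double> SW(K * K * H); // SW[f*K + l + ..] = sum_{b<=f, d>=l} W
  std::vector<double> lratio(K * H); // log(p/(1-p)) per day/class

  GetRNGstate();
  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // current detection matrix
    for (int h = 0; h < H; ++h)
      for (int t = 0; t < K; ++t) {
        double val;
        if (det_mode == 0)
          val = pconst;
        else if (det_mode == 1)
          val = ph[h];
        else if (det_mode == 2)
          val = pt[t];
        else
          val = 1.0 / (1.0 + std::exp(-(eta[t] + delta * h)));
        pmat[t + K * h] = val;
        lratio[t + K * h] = std::log(val) - std::log1p(-val);
      }

    // W and its rectangle sums
    for (int h = 0; h < H; ++h) {
      double phih = phiC[phi_mode == 1 ? h : 0];
      for (int b = 0; b < K; ++b) {
        // incremental products over the presence window [b, d]
        double stay = 1.0, q = 1.0;
        for (int d = b; d < K; ++d) {
          if (d > b)
            stay *= phih;
          q *= (1.0 - pmat[d + K * h]);
          double dep = (d < K - 1) ? (1.0 - phih) : 1.0;
          W[b * K + d + K * K * h] = beta[b] * stay * q * dep;
        }
        for (int d = 0; d < b; ++d)
          W[b * K + d + K * K * h] = 0.0;
      }
      // SW[f][l] = sum over b <= f of sum over d >= l of W[b][d]
      // first cumulative over b, then reverse-cumulative over d
      for (int d = 0; d < K; ++d)
        for (int b = 0; b < K; ++b) {
          double v = W[b * K + d + K * K * h];
          SW[b * K + d + K * K * h] = v + (b > 0 ? SW[(b - 1) * K + d + K * K * h] : 0.0);
        }
      for (int b = 0; b < K; ++b)
        for (int d = K - 2; d >= 0; --d)
          SW[b * K + d + K * K * h] += SW[b * K + d + 1 + K * K * h];
    }

    // class-wise never-detected probability
    std::vector<double> p0h(H);
    for (int h = 0; h < H; ++h)
      p0h[h] = SW[(K - 1) * K + 0 + K * K * h];

    // --- latent updates -------------------------------------------------
    // observed individuals: (h, b, d) jointly
    for (int i = 0; i < nobs; ++i) {
      double wts[2] = {0.0, 0.0};
      for (int h = 0; h < H; ++h) {
        double lr = 0.0;
        for (size_t k = 0; k < detdays[i].size(); ++k)
          lr += lratio[detdays[i][k] + K * h];
        wts[h] = omega[h] * std::exp(lr) * SW[f[i] * K + l[i] + K * K * h];
      }
      int h = 0;
      if (H == 2)
        h = (unif_rand() * (wts[0] + wts[1]) < wts[0]) ? 0 : 1;
      hcl[i] = h;
      // (b, d) | h from the restricted triangle
      double tot = SW[f[i] * K + l[i] + K * K * h];
      double u = unif_rand() * tot, acc = 0.0;
      int bs = 0, ds = K - 1;
      bool done = false;
      for (int b = 0; b <= f[i] && !done; ++b)
        for (int d = std::max(b, l[i]); d < K; ++d) {
          acc += W[b * K + d + K * K * h];
          if (acc >= u) {
            bs = b;
            ds = d;
            done = true;
            break;
          }
        }
      bb[i] = bs;
      dd[i] = ds;
    }
    // pseudo individuals: w, then (h, b, d) | w = 1
    double L0 = 0.0;
    for (int h = 0; h < H; ++h)
      L0 += omega[h] * p0h[h];
    double pw1 = psi * L0 / (psi * L0 + (1.0 - psi));
    for (int i = nobs; i < A; ++i) {
      if (unif_rand() < pw1) {
        w[i] = 1;
        int h = 0;
        if (H == 2)
          h = (unif_rand() * L0 < omega[0] * p0h[0]) ? 0 : 1;
        hcl[i] = h;
        double tot = p0h[h];
        double u = unif_rand() * tot, acc = 0.0;
        int bs = 0, ds = K - 1;
        bool done = false;
        for (int b = 0; b < K && !done; ++b)
          for (int d = b; d < K; ++d) {
            acc += W[b * K + d + K * K * h];
            if (acc >= u) {
              bs = b;
              ds = d;
              done = true;
              break;
            }
          }
        bb[i] = bs;
        dd[i] = ds;
      } else {
        w[i] = 0;
      }
    }

    // --- sufficient statistics from included individuals ----------------
    int M = 0;
    std::vector<int> ccl(H, 0), nb(K, 0);
    std::vector<double> stays(H, 0.0), deps(H, 0.0);
    std::vector<int> det_th(K * H, 0), expo_th(K * H, 0);
    for (int i = 0; i < A; ++i) {
      if (w[i] == 0)
        continue;
      ++M;
      int h = hcl[i];
      ++ccl[h];
      ++nb[bb[i]];
      stays[h] += dd[i] - bb[i];
      if (dd[i] < K - 1)
        deps[h] += 1.0;
      for (int t = bb[i]; t <= dd[i]; ++t)
        ++expo_th[t + K * h];
    }
    for (int i = 0; i < nobs; ++i)
      for (size_t k = 0; k < detdays[i].size(); ++k)
        ++det_th[detdays[i][k] + K * hcl[i]];

    // --- conjugate parameter updates ------------------------------------
    psi = R::rbeta(1.0 + M, 1.0 + A - M);
    if (H == 2 && update_omega) {
      double g1 = rdirich_component(1.0 + ccl[0]);
      double g2 = rdirich_component(1.0 + ccl[1]);
      omega[0] = g1 / (g1 + g2);
      omega[1] = 1.0 - omega[0];
    }
    {
      double s = 0.0;
      std::vector<double> g(K);
      for (int t = 0; t < K; ++t) {
        g[t] = rdirich_component(1.0 + nb[t]);
        s += g[t];
      }
      for (int t = 0; t < K; ++t)
        beta[t] = g[t] / s;
    }
    if (phi_mode == 1) {
      for (int h = 0; h < H; ++h)
        phiC[h] = R::rbeta(1.0 + stays[h], 1.0 + deps[h]);
    } else {
      double st = 0.0, de = 0.0;
      for (int h = 0; h < H; ++h) {
        st += stays[h];
        de += deps[h];
      }
      double v = R::rbeta(1.0 + st, 1.0 + de);
      for (size_t h = 0; h < phiC.size(); ++h)
        phiC[h] = v;
    }
    if (det_mode == 0) {
      double det = 0, expo = 0;
      for (int t = 0; t < K * H; ++t) {
        det += det_th[t];
        expo += expo_th[t];
      }
      pconst = R::rbeta(1.0 + det, 1.0 + expo - det);
    } else if (det_mode == 1) {
      for (int h = 0; h < H; ++h) {
        double det = 0, expo = 0;
        for (int t = 0; t < K; ++t) {
          det += det_th[t + K * h];
          expo += expo_th[t + K * h];
        }
        ph[h] = R::rbeta(1.0 + det, 1.0 + expo - det);
      }
    } else if (det_mode == 2) {
      for (int t = 0; t < K; ++t) {
        double det = 0, expo = 0;
        for (int h = 0; h < H; ++h) {
          det += det_th[t + K * h];
          expo += expo_th[t + K * h];
        }
        pt[t] = R::rbeta(1.0 + det, 1.0 + expo - det);
      }
    } else {
      // Metropolis updates for (eta_t, delta); logistic(0, 1) priors keep
      // p_{t,1} marginally uniform and the class offset symmetric around 0
      for (int t = 0; t < K; ++t) {
        double prop = eta[t] + norm_rand() * rw_eta;
        double cur_ll = 0.0, prop_ll = 0.0;
        for (int h = 0; h < H; ++h) {
          double pc = 1.0 / (1.0 + std::exp(-(eta[t] + delta * h)));
          double pp = 1.0 / (1.0 + std::exp(-(prop + delta * h)));
          double det = det_th[t + K * h], mis = expo_th[t + K * h] - det;
          cur_ll += det * std::log(pc) + mis * std::log1p(-pc);
          prop_ll += det * std::log(pp) + mis * std::log1p(-pp);
        }
        cur_ll += R::dlogis(eta[t], 0.0, 1.0, 1);
        prop_ll += R::dlogis(prop, 0.0, 1.0, 1);
        ++prop_eta;
        if (std::log(unif_rand()) < prop_ll - cur_ll) {
          eta[t] = prop;
          ++acc_eta;
        }
      }
      if (H == 2) {
        double prop = delta + norm_rand() * rw_delta;
        double cur_ll = R::dlogis(delta, 0.0, 1.0, 1),
               prop_ll = R::dlogis(prop, 0.0, 1.0, 1);
        for (int t = 0; t < K; ++t) {
          double pc = 1.0 / (1.0 + std::exp(-(eta[t] + delta)));
          double pp = 1.0 / (1.0 + std::exp(-(eta[t] + prop)));
          double det = det_th[t + K], mis = expo_th[t + K] - det;
          cur_ll += det * std::log(pc) + mis * std::log1p(-pc);
          prop_ll += det * std::log(pp) + mis * std::log1p(-pp);
        }
        ++prop_delta;
        if (std::log(unif_rand()) < prop_ll - cur_ll) {
          delta = prop;
          ++acc_delta;
        }
      }
    }

    // --- store ----------------------------------------------------------
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      d_psi[keep] = psi;
      d_M[keep] = M;
      double S = 0.0;
      for (int i = 0; i < A; ++i)
        if (w[i] == 1)
          S += dd[i] - bb[i] + 1;
      d_Sbar[keep] = (M > 0) ? S / M : NA_REAL;
      for (int h = 0; h < H; ++h) {
        d_omega(keep, h) = omega[h];
        d_phi(keep, h) = phiC[phi_mode == 1 ? h : 0];
      }
      for (int t = 0; t < K; ++t)
        d_beta(keep, t) = beta[t];
      for (int h = 0; h < H; ++h)
        for (int t = 0; t < K; ++t) {
          double val;
          if (det_mode == 0)
            val = pconst;
          else if (det_mode == 1)
            val = ph[h];
          else if (det_mode == 2)
            val = pt[t];
          else
            val = 1.0 / (1.0 + std::exp(-(eta[t] + delta * h)));
          d_p(keep, t + K * h) = val;
        }
      d_delta[keep] = delta;
      if (store_latent)
        for (int i = 0; i < A; ++i) {
          d_w(keep, i) = w[i];
          d_b(keep, i) = w[i] ? bb[i] + 1 : NA_INTEGER;
          d_d(keep, i) = w[i] ? dd[i] + 1 : NA_INTEGER;
        }
      ++keep;
    }
  }
  PutRNGstate();

  List out = List::create(
      _["psi"] = d_psi, _["omega"] = d_omega, _["phi"] = d_phi, _["p"] = d_p,
      _["beta"] = d_beta, _["Mstar"] = d_M, _["Sbar"] = d_Sbar,
      _["delta"] = d_delta,
      _["accept"] = NumericVector::create(
          _["eta"] = prop_eta ? (double)acc_eta / prop_eta : NA_REAL,
          _["delta"] = prop_delta ? (double)acc_delta / prop_delta : NA_REAL));
  if (store_latent) {
    out["w"] = d_w;
    out["entry"] = d_b;
    out["depart"] = d_d;
  }
  return out;
}
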