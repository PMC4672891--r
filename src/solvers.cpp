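// Sparse logistic solvers.
//
// cpp_lasso_path: lasso-penalized logistic regression by cyclic coordinate
//   descent on the quadratic-majorized (IRLS) working response, warm starts
//   along the lambda grid, convergence verified against the exact KKT
//   conditions of the true objective.
//
// cpp_group_screen: overlapped ("latent") group-lasso logistic regression
//   for hierarchical pairwise-interaction screening. Each candidate pair
//   (j,k) owns a 3-vector latent group (copies of both main effects plus
//   the product column), so an active interaction always carries its main
//   effects: strong hierarchy by construction. Solved by FISTA with
//   backtracking line search on an exact active set: the restricted
//   problem is solved, then a full KKT sweep adds violating groups until
//   none remain, which reproduces the full-space optimum.

#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// (1/n) sum log(1+exp(eta)) - y*eta, overflow-safe
static double nll(const vec& eta, const vec& y) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    s += (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::abs(e))) - y[i] * e;
  }
  return s / eta.n_elem;
}

static inline vec sigmoid(const vec& eta) {
  return 1.0 / (1.0 + exp(-eta));
}

// ---------------------------------------------------------------------------
// lasso logistic path
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambdas,
                          double tol, int maxit, double kkt_tol) {
  const uword n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
  mat betas(p, L, fill::zeros);
  vec b0s(L, fill::zeros), kkts(L, fill::zeros), objs(L, fill::zeros);
  ivec iters(L, fill::zeros);
  uvec conv(L, fill::zeros);

  double ym = mean(y);
  ym = std::min(1.0 - 1e-10, std::max(1e-10, ym));
  double b0 = std::log(ym / (1.0 - ym));
  vec beta(p, fill::zeros);
  const mat X2 = square(X);

  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int it = 0;
    double kkt_max = datum::inf;
    for (; it < maxit; ++it) {
      vec eta = b0 + X * beta;
      vec prob = clamp(sigmoid(eta), 1e-9, 1.0 - 1e-9);
      vec w = prob % (1.0 - prob);
      w = clamp(w, 1e-5, 0.25);   // glmnet-style floor keeps z bounded
      vec r = (y - prob) / w;  // working residual z - eta
      const double sw = accu(w);
      vec xwx = X2.t() * w;    // sum_i w_i x_ij^2
      // inner cyclic coordinate descent on the weighted LS surrogate
      for (int inner = 0; inner < 1000; ++inner) {
        double maxdel = 0.0;
        double d0 = dot(w, r) / sw;
        b0 += d0; r -= d0;
        maxdel = std::max(maxdel, sw / n * d0 * d0);
        for (uword j = 0; j < p; ++j) {
          const double a = xwx[j] / n;
          if (a < 1e-12) continue;
          const double bj = beta[j];
          const double rho = dot(w % X.col(j), r) / n + a * bj;
          const double bn = soft(rho, lam) / a;
          if (bn != bj) {
            r += X.col(j) * (bj - bn);
            beta[j] = bn;
            maxdel = std::max(maxdel, a * (bj - bn) * (bj - bn));
          }
        }
        if (maxdel < tol) break;
      }
      // exact KKT on the true objective
      eta = b0 + X * beta;
      prob = sigmoid(eta);
      vec g = X.t() * (prob - y) / n;
      kkt_max = std::abs(mean(prob - y));
      for (uword j = 0; j < p; ++j) {
        if (beta[j] != 0.0)
          kkt_max = std::max(kkt_max, std::abs(g[j] + lam * (beta[j] > 0 ? 1.0 : -1.0)));
        else
          kkt_max = std::max(kkt_max, std::max(0.0, std::abs(g[j]) - lam));
      }
      if (kkt_max < kkt_tol) break;
    }
    betas.col(l) = beta;
    b0s[l] = b0;
    iters[l] = it + 1;
    kkts[l] = kkt_max;
    conv[l] = kkt_max < kkt_tol ? 1 : 0;
    vec eta = b0 + X * beta;
    objs[l] = nll(eta, y) + lam * accu(abs(beta));
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = betas, Rcpp::Named("intercept") = b0s,
      Rcpp::Named("iterations") = iters, Rcpp::Named("kkt") = kkts,
      Rcpp::Named("converged") = conv, Rcpp::Named("objective") = objs);
}

// ---------------------------------------------------------------------------
// overlapped group lasso screening
// ---------------------------------------------------------------------------

struct GroupState {
  double b0;
  vec am;           // latent main-effect singletons (p)
  mat Ap;           // latent pair groups (3 x G), only active columns used
  std::vector<uword> act;       // indices of active (optimized) pair groups
  std::vector<char> in_act;     // membership flags (G)
};

// aggregated main coefficients: singleton latents plus pair-group copies
static vec aggregate_mains(const GroupState& s, const umat& pairs) {
  vec btot = s.am;
  for (uword a = 0; a < s.act.size(); ++a) {
    uword g = s.act[a];
    btot[pairs(g, 0)] += s.Ap(0, g);
    btot[pairs(g, 1)] += s.Ap(1, g);
  }
  return btot;
}

static vec eta_of(const GroupState& s, const mat& X, const mat& P,
                  const umat& pairs) {
  vec eta = s.b0 + X * aggregate_mains(s, pairs);
  for (uword a = 0; a < s.act.size(); ++a) {
    uword g = s.act[a];
    if (s.Ap(2, g) != 0.0) eta += P.col(g) * s.Ap(2, g);
  }
  return eta;
}

static double penalty_of(const GroupState& s, double lam, double pw) {
  double pen = lam * accu(abs(s.am));
  for (uword a = 0; a < s.act.size(); ++a)
    pen += lam * pw * norm(s.Ap.col(s.act[a]));
  return pen;
}

// FISTA with backtracking on (intercept, mains, active pair groups)
static void fista_solve(GroupState& s, const mat& X, const mat& P,
                        const umat& pairs, const vec& y, double lam,
                        double pw, double tol, int maxit, double& Lip,
                        int& used_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword na = s.act.size();
  // flatten: [b0, am(p), Ap(3 x na)]
  const uword dim = 1 + p + 3 * na;
  vec x(dim), xprev;
  x[0] = s.b0;
  x.subvec(1, p) = s.am;
  for (uword a = 0; a < na; ++a)
    x.subvec(1 + p + 3 * a, 1 + p + 3 * a + 2) = s.Ap.col(s.act[a]);

  auto unpack = [&](const vec& v, GroupState& out) {
    out.b0 = v[0];
    out.am = v.subvec(1, p);
    for (uword a = 0; a < na; ++a)
      out.Ap.col(s.act[a]) = v.subvec(1 + p + 3 * a, 1 + p + 3 * a + 2);
  };
  auto smooth_f = [&](const vec& v) {
    GroupState t = s;
    unpack(v, t);
    return nll(eta_of(t, X, P, pairs), y);
  };
  auto grad_f = [&](const vec& v) {
    GroupState t = s;
    unpack(v, t);
    vec r = (sigmoid(eta_of(t, X, P, pairs)) - y) / n;
    vec g(dim);
    g[0] = accu(r);
    vec gm = X.t() * r;
    g.subvec(1, p) = gm;
    for (uword a = 0; a < na; ++a) {
      uword gidx = s.act[a];
      g[1 + p + 3 * a] = gm[pairs(gidx, 0)];
      g[1 + p + 3 * a + 1] = gm[pairs(gidx, 1)];
      g[1 + p + 3 * a + 2] = dot(P.col(gidx), r);
    }
    return g;
  };
  auto prox = [&](const vec& v, double step) {
    vec o = v;
    for (uword j = 1; j <= p; ++j) o[j] = soft(v[j], step * lam);
    for (uword a = 0; a < na; ++a) {
      uword off = 1 + p + 3 * a;
      double nm = norm(v.subvec(off, off + 2));
      double sh = nm > 0 ? std::max(0.0, 1.0 - step * lam * pw / nm) : 0.0;
      o.subvec(off, off + 2) = v.subvec(off, off + 2) * sh;
    }
    return o;
  };
  auto full_obj = [&](const vec& v) {
    double pen = lam * accu(abs(v.subvec(1, p)));
    for (uword a = 0; a < na; ++a) {
      uword off = 1 + p + 3 * a;
      pen += lam * pw * norm(v.subvec(off, off + 2));
    }
    return smooth_f(v) + pen;
  };

  vec vpt = x;
  xprev = x;
  double t_mom = 1.0;
  double obj = full_obj(x);
  int it = 0;
  for (; it < maxit; ++it) {
    vec g = grad_f(vpt);
    double fv = smooth_f(vpt);
    vec xn;
    for (int bt = 0; bt < 60; ++bt) {
      xn = prox(vpt - g / Lip, 1.0 / Lip);
      vec d = xn - vpt;
      double q = fv + dot(g, d) + 0.5 * Lip * dot(d, d);
      if (smooth_f(xn) <= q + 1e-14 * std::abs(q)) break;
      Lip *= 2.0;
    }
    double tn = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom));
    vec vn = xn + ((t_mom - 1.0) / tn) * (xn - xprev);
    double objn = full_obj(xn);
    if (objn > obj) {          // adaptive restart
      vn = xn;
      tn = 1.0;
    }
    double rel = std::abs(obj - objn) / std::max(1.0, std::abs(obj));
    xprev = xn;
    vpt = vn;
    t_mom = tn;
    bool done = rel < tol && it > 0;
    obj = objn;
    Lip = std::max(1e-4, Lip * 0.97);
    if (done) break;
  }
  used_iter += it + 1;
  unpack(xprev, s);
}

// [[Rcpp::export]]
Rcpp::List cpp_group_screen(const arma::mat& X, const arma::vec& y,
                            const arma::umat& pairs,      // G x 2, 0-based
                            const arma::uvec& scale_prod, // G
                            arma::vec lambdas,            // empty -> build grid
                            int nlambda, double floor_ratio,
                            double pair_weight, double tol, int maxit,
                            int ndi_stop, double kkt_tol) {
  const uword n = X.n_rows, p = X.n_cols, G = pairs.n_rows;

  // product columns, optionally scaled to unit sd for penalty fairness
  mat P(n, std::max<uword>(G, 1), fill::zeros);
  vec sg(std::max<uword>(G, 1), fill::ones);
  for (uword g = 0; g < G; ++g) {
    vec col = X.col(pairs(g, 0)) % X.col(pairs(g, 1));
    if (scale_prod[g]) {
      double s = stddev(col);
      if (s > 1e-12) { col /= s; sg[g] = s; }
    }
    P.col(g) = col;
  }

  double ym = mean(y);
  ym = std::min(1.0 - 1e-10, std::max(1e-10, ym));
  const double b0_null = std::log(ym / (1.0 - ym));

  // lambda_max from the null-model gradient
  vec r0 = (ym - y) / n;
  vec gm0 = X.t() * r0;
  vec gP0 = G > 0 ? vec(P.cols(0, G - 1).t() * r0) : vec();
  double lmax = p > 0 ? abs(gm0).max() : 0.0;
  for (uword g = 0; g < G; ++g) {
    double nm = std::sqrt(gm0[pairs(g, 0)] * gm0[pairs(g, 0)] +
                          gm0[pairs(g, 1)] * gm0[pairs(g, 1)] +
                          gP0[g] * gP0[g]) / pair_weight;
    lmax = std::max(lmax, nm);
  }
  if (lambdas.n_elem == 0) {
    lambdas = exp(linspace(std::log(lmax), std::log(lmax * floor_ratio),
                           nlambda));
  }
  const uword L = lambdas.n_elem;

  GroupState s;
  s.b0 = b0_null;
  s.am = vec(p, fill::zeros);
  s.Ap = mat(3, std::max<uword>(G, 1), fill::zeros);
  s.in_act.assign(G, 0);

  mat mains(p, L, fill::zeros), norms(G, L, fill::zeros),
      prodc(G, L, fill::zeros);
  vec b0s(L, fill::zeros), objs(L, fill::zeros), kkts(L, fill::zeros);
  ivec iters(L, fill::zeros), entry(G);
  entry.fill(-1);
  mat latent(1 + p + 3 * G, L, fill::zeros);
  double Lip = 1.0;
  uword L_used = L;
  bool truncated_path = false;

  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int used_iter = 0;
    double kkt_max = 0.0;
    for (int round = 0; round < 100; ++round) {
      fista_solve(s, X, P, pairs, y, lam, pair_weight, tol, maxit, Lip,
                  used_iter);
      // full KKT sweep over inactive pair groups
      vec r = (sigmoid(eta_of(s, X, P, pairs)) - y) / n;
      vec gm = X.t() * r;
      vec gP = G > 0 ? vec(P.cols(0, G - 1).t() * r) : vec();
      kkt_max = 0.0;
      std::vector<uword> add;
      for (uword g = 0; g < G; ++g) {
        if (s.in_act[g]) continue;
        double nm = std::sqrt(gm[pairs(g, 0)] * gm[pairs(g, 0)] +
                              gm[pairs(g, 1)] * gm[pairs(g, 1)] +
                              gP[g] * gP[g]);
        double viol = nm - lam * pair_weight;
        if (viol > kkt_tol) add.push_back(g);
        kkt_max = std::max(kkt_max, viol);
      }
      if (add.empty()) break;
      for (uword i = 0; i < add.size(); ++i) {
        s.act.push_back(add[i]);
        s.in_act[add[i]] = 1;
      }
    }
    vec btot = aggregate_mains(s, pairs);
    mains.col(l) = btot;
    for (uword a = 0; a < s.act.size(); ++a) {
      uword g = s.act[a];
      norms(g, l) = norm(s.Ap.col(g));
      prodc(g, l) = s.Ap(2, g) / sg[g];
    }
    b0s[l] = s.b0;
    iters[l] = used_iter;
    kkts[l] = kkt_max;
    objs[l] = nll(eta_of(s, X, P, pairs), y) + penalty_of(s, lam, pair_weight);
    latent(0, l) = s.b0;
    latent.submat(1, l, p, l) = s.am;
    for (uword g = 0; g < G; ++g)
      latent.submat(1 + p + 3 * g, l, 1 + p + 3 * g + 2, l) = s.Ap.col(g);
    // entry bookkeeping and NDI early stop
    uword n_active = 0;
    for (uword g = 0; g < G; ++g) {
      if (norms(g, l) > 0) {
        ++n_active;
        if (entry[g] < 0) entry[g] = l;
      }
    }
    if (ndi_stop >= 0 && (int)n_active >= ndi_stop) {
      L_used = l + 1;
      truncated_path = true;
      break;
    }
  }

  uvec keep = regspace<uvec>(0, L_used - 1);
  return Rcpp::List::create(
      Rcpp::Named("lambdas") = vec(lambdas.elem(keep)),
      Rcpp::Named("lambda_max") = lmax,
      Rcpp::Named("intercept") = vec(b0s.elem(keep)),
      Rcpp::Named("mains") = mat(mains.cols(keep)),
      Rcpp::Named("prod_coef") = mat(prodc.cols(keep)),
      Rcpp::Named("group_norms") = mat(norms.cols(keep)),
      Rcpp::Named("entry") = entry,
      Rcpp::Named("objective") = vec(objs.elem(keep)),
      Rcpp::Named("kkt") = vec(kkts.elem(keep)),
      Rcpp::Named("iterations") = ivec(iters.elem(keep)),
      Rcpp::Named("latent") = mat(latent.cols(keep)),
      Rcpp::Named("prod_scale") = sg,
      Rcpp::Named("stopped_early") = truncated_path);
}
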