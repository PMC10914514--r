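// Recurrent probabilistic interaction network: two LSTM layers and five dense
// layers mapping a 5-step history of the 11-dimensional two-agent system
// state to a diagonal-Gaussian distribution over the focal agent's next-step
// acceleration (mu_x, mu_y, sigma_x, sigma_y). Training minimizes the
// Gaussian negative log-likelihood with Adam. All randomness (initial
// shuffling, acceleration sampling in rollouts) goes through R's RNG so that
// set.seed() makes every run reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum ParId { WX1, WH1, B1, WD1, BD1, WD2, BD2,
             WX2, WH2, B2, WE1, BE1, WE2, BE2, WO, BO, NPAR };

static const char* PAR_NAMES[NPAR] = {
  "Wx1", "Wh1", "b1", "Wd1", "bd1", "Wd2", "bd2",
  "Wx2", "Wh2", "b2", "We1", "be1", "We2", "be2", "Wo", "bo" };

typedef std::vector<mat> Net;

static Net net_from_list(const Rcpp::List& w) {
  Net net(NPAR);
  for (int k = 0; k < NPAR; ++k)
    net[k] = Rcpp::as<mat>(w[PAR_NAMES[k]]);
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List out;
  for (int k = 0; k < NPAR; ++k)
    out[PAR_NAMES[k]] = net[k];
  return out;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// numerically stable softplus, keeps sigma strictly positive
static inline mat softplus(const mat& x) {
  mat out(size(x));
  for (uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    out(i) = v > 30.0 ? v : std::log1p(std::exp(v));
  }
  return out + 1e-6;
}

struct LstmCache {
  cube I, F, G, O, C, H; // gate activations and states, H x B x T
};

static void lstm_forward(const mat& Wx, const mat& Wh, const mat& b,
                         const cube& X, LstmCache& cc) {
  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  cc.I.set_size(H, B, T); cc.F.set_size(H, B, T); cc.G.set_size(H, B, T);
  cc.O.set_size(H, B, T); cc.C.set_size(H, B, T); cc.H.set_size(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat z = Wx * X.slice(t) + Wh * h;
    z.each_col() += b.col(0);
    mat i = sigm(z.rows(0, H - 1));
    mat f = sigm(z.rows(H, 2 * H - 1));
    mat g = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = sigm(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
}

// backward through one LSTM; dHext carries the gradient arriving at each h_t;
// returns dX and accumulates parameter gradients
static cube lstm_backward(const mat& Wx, const mat& Wh, const cube& X,
                          const LstmCache& cc, const cube& dHext,
                          mat& dWx, mat& dWh, mat& db) {
  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  cube dX(X.n_rows, B, T, fill::zeros);
  mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * H, 1);
  for (int t = T - 1; t >= 0; --t) {
    dh += dHext.slice(t);
    mat tc = tanh(cc.C.slice(t));
    const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    mat dzo = (dh % tc) % o % (1 - o);
    dc += dh % o % (1 - tc % tc);
    mat cprev = t > 0 ? cc.C.slice(t - 1) : mat(H, B, fill::zeros);
    mat dzf = (dc % cprev) % f % (1 - f);
    mat dzi = (dc % g) % i % (1 - i);
    mat dzg = (dc % i) % (1 - g % g);
    mat dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
    dWx += dz * X.slice(t).t();
    mat hprev = t > 0 ? cc.H.slice(t - 1) : mat(H, B, fill::zeros);
    dWh += dz * hprev.t();
    db.col(0) += sum(dz, 1);
    dX.slice(t) = Wx.t() * dz;
    dh = Wh.t() * dz;
    dc = dc % f;
  }
  return dX;
}

struct FwdCache {
  LstmCache l1, l2;
  cube A1, A2;        // per-step dense activations, (d x B x T)
  mat e1, e2, out;    // head
};

// full forward pass; X is 11 x B x T (T = history length)
static mat net_forward(const Net& net, const cube& X, FwdCache& fc) {
  const uword B = X.n_cols, T = X.n_slices;
  lstm_forward(net[WX1], net[WH1], net[B1], X, fc.l1);
  const uword d1 = net[WD1].n_rows, d2 = net[WD2].n_rows;
  fc.A1.set_size(d1, B, T);
  fc.A2.set_size(d2, B, T);
  for (uword t = 0; t < T; ++t) {
    mat a1 = net[WD1] * fc.l1.H.slice(t);
    a1.each_col() += net[BD1].col(0);
    a1 = tanh(a1);
    mat a2 = net[WD2] * a1;
    a2.each_col() += net[BD2].col(0);
    a2 = tanh(a2);
    fc.A1.slice(t) = a1;
    fc.A2.slice(t) = a2;
  }
  lstm_forward(net[WX2], net[WH2], net[B2], fc.A2, fc.l2);
  mat h2 = fc.l2.H.slice(T - 1);
  fc.e1 = tanh(net[WE1] * h2 + repmat(net[BE1], 1, B));
  fc.e2 = tanh(net[WE2] * fc.e1 + repmat(net[BE2], 1, B));
  fc.out = net[WO] * fc.e2 + repmat(net[BO], 1, B);
  return fc.out; // rows: mu_x, mu_y, sraw_x, sraw_y
}

// backward pass from dOut (4 x B) to all parameter gradients
static void net_backward(const Net& net, const cube& X, const FwdCache& fc,
                         const mat& dOut, Net& grad) {
  const uword B = X.n_cols, T = X.n_slices;
  grad.assign(NPAR, mat());
  // head
  grad[WO] = dOut * fc.e2.t();
  grad[BO] = sum(dOut, 1);
  mat de2 = net[WO].t() * dOut;
  mat dz2 = de2 % (1 - fc.e2 % fc.e2);
  grad[WE2] = dz2 * fc.e1.t();
  grad[BE2] = sum(dz2, 1);
  mat de1 = net[WE2].t() * dz2;
  mat dz1 = de1 % (1 - fc.e1 % fc.e1);
  grad[WE1] = dz1 * fc.l2.H.slice(T - 1).t();
  grad[BE1] = sum(dz1, 1);
  mat dh2 = net[WE1].t() * dz1;
  // second LSTM: gradient only at the last step
  cube dH2(fc.l2.H.n_rows, B, T, fill::zeros);
  dH2.slice(T - 1) = dh2;
  cube dA2 = lstm_backward(net[WX2], net[WH2], fc.A2, fc.l2, dH2,
                           grad[WX2], grad[WH2], grad[B2]);
  // per-step dense layers
  const uword d1 = net[WD1].n_rows;
  cube dH1(fc.l1.H.n_rows, B, T, fill::zeros);
  grad[WD1].zeros(net[WD1].n_rows, net[WD1].n_cols);
  grad[BD1].zeros(d1, 1);
  grad[WD2].zeros(net[WD2].n_rows, net[WD2].n_cols);
  grad[BD2].zeros(net[WD2].n_rows, 1);
  for (uword t = 0; t < T; ++t) {
    mat dza2 = dA2.slice(t) % (1 - fc.A2.slice(t) % fc.A2.slice(t));
    grad[WD2] += dza2 * fc.A1.slice(t).t();
    grad[BD2].col(0) += sum(dza2, 1);
    mat da1 = net[WD2].t() * dza2;
    mat dza1 = da1 % (1 - fc.A1.slice(t) % fc.A1.slice(t));
    grad[WD1] += dza1 * fc.l1.H.slice(t).t();
    grad[BD1].col(0) += sum(dza1, 1);
    dH1.slice(t) = net[WD1].t() * dza1;
  }
  lstm_backward(net[WX1], net[WH1], X, fc.l1, dH1,
                grad[WX1], grad[WH1], grad[B1]);
}

// per-sample Gaussian NLL and the gradient w.r.t. the raw network output
static vec nll_and_grad(const mat& out, const mat& Y, mat& dOut) {
  const uword B = out.n_cols;
  mat mu = out.rows(0, 1);
  mat sraw = out.rows(2, 3);
  mat sigma = softplus(sraw);
  mat eps = Y - mu;
  vec loss(B);
  for (uword b = 0; b < B; ++b) {
    double l = 0;
    for (int k = 0; k < 2; ++k) {
      double e = eps(k, b), s = sigma(k, b);
      l += 0.5 * (e * e) / (s * s) + std::log(s);
    }
    loss(b) = l;
  }
  mat dmu = -(eps / square(sigma)) / double(B);
  mat dsig = (-square(eps) / pow(sigma, 3) + 1.0 / sigma) / double(B);
  mat dsraw = dsig % sigm(sraw); // softplus'
  dOut = join_cols(dmu, dsraw);
  return loss;
}

// [[Rcpp::export]]
arma::mat cpp_dli_forward(const Rcpp::List& weights, const arma::cube& X) {
  Net net = net_from_list(weights);
  FwdCache fc;
  mat out = net_forward(net, X, fc);
  mat res(4, X.n_cols);
  res.rows(0, 1) = out.rows(0, 1);
  res.rows(2, 3) = softplus(out.rows(2, 3));
  return res; // mu_x, mu_y, sigma_x, sigma_y
}

// [[Rcpp::export]]
arma::vec cpp_dli_nll(const arma::mat& mu, const arma::mat& sigma,
                      const arma::mat& targets) {
  const uword B = mu.n_cols;
  vec loss(B);
  for (uword b = 0; b < B; ++b) {
    double l = 0;
    for (int k = 0; k < 2; ++k) {
      double e = targets(k, b) - mu(k, b), s = sigma(k, b);
      if (s <= 0) Rcpp::stop("sigma must be strictly positive");
      l += 0.5 * (e * e) / (s * s) + std::log(s);
    }
    loss(b) = l;
  }
  return loss;
}

// analytic loss gradients for one batch (used by the gradient-check tests)
// [[Rcpp::export]]
Rcpp::List cpp_dli_grad(const Rcpp::List& weights, const arma::cube& X,
                        const arma::mat& Y) {
  Net net = net_from_list(weights);
  FwdCache fc;
  mat out = net_forward(net, X, fc);
  mat dOut;
  vec l = nll_and_grad(out, Y, dOut);
  Net grad;
  net_backward(net, X, fc, dOut, grad);
  Rcpp::List g = net_to_list(grad);
  g["loss"] = mean(l);
  return g;
}

static double eval_loss(const Net& net, const cube& X, const mat& Y,
                        uword chunk = 4096) {
  const uword K = X.n_cols;
  double tot = 0;
  for (uword at = 0; at < K; at += chunk) {
    uword hi = std::min(at + chunk, K) - 1;
    cube Xb = X.cols(at, hi);
    FwdCache fc;
    mat out = net_forward(net, Xb, fc);
    mat dOut;
    vec l = nll_and_grad(out, Y.cols(at, hi), dOut);
    tot += accu(l);
  }
  return tot / double(K);
}

// Fisher-Yates permutation driven by R's RNG (reproducible under set.seed)
static uvec r_permutation(uword n) {
  uvec p = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p(i), p(j));
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List cpp_dli_train(const Rcpp::List& weights,
                         const arma::cube& Xtr, const arma::mat& Ytr,
                         const arma::cube& Xval, const arma::mat& Yval,
                         int epochs, int batch, double lr, double lr_decay,
                         double clip, bool verbose) {
  Rcpp::RNGScope rng;
  Net net = net_from_list(weights);
  Net m(NPAR), v(NPAR);
  for (int k = 0; k < NPAR; ++k) {
    m[k] = mat(size(net[k]), fill::zeros);
    v[k] = mat(size(net[k]), fill::zeros);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const uword K = Xtr.n_cols;
  vec train_curve(epochs), val_curve(epochs);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr * std::pow(lr_decay, ep);
    uvec perm = r_permutation(K);
    double ep_loss = 0; uword seen = 0;
    for (uword at = 0; at < K; at += batch) {
      uword hi = std::min<uword>(at + batch, K) - 1;
      uvec idx = perm.subvec(at, hi);
      cube Xb(Xtr.n_rows, idx.n_elem, Xtr.n_slices);
      for (uword t = 0; t < Xtr.n_slices; ++t)
        Xb.slice(t) = Xtr.slice(t).cols(idx);
      mat Yb = Ytr.cols(idx);
      FwdCache fc;
      mat out = net_forward(net, Xb, fc);
      if (!out.is_finite())
        Rcpp::stop("training diverged: non-finite activations at epoch %d", ep + 1);
      mat dOut;
      vec l = nll_and_grad(out, Yb, dOut);
      ep_loss += accu(l); seen += idx.n_elem;
      Net grad;
      net_backward(net, Xb, fc, dOut, grad);
      // global-norm gradient clipping
      double g2 = 0;
      for (int k = 0; k < NPAR; ++k) g2 += accu(square(grad[k]));
      double gn = std::sqrt(g2);
      double scale = (clip > 0 && gn > clip) ? clip / gn : 1.0;
      ++step;
      double bc1 = 1 - std::pow(b1, (double)step);
      double bc2 = 1 - std::pow(b2, (double)step);
      for (int k = 0; k < NPAR; ++k) {
        mat g = grad[k] * scale;
        m[k] = b1 * m[k] + (1 - b1) * g;
        v[k] = b2 * v[k] + (1 - b2) * square(g);
        net[k] -= lr_ep * (m[k] / bc1) / (sqrt(v[k] / bc2) + eps);
      }
    }
    train_curve(ep) = ep_loss / double(seen);
    val_curve(ep) = Xval.n_cols > 0 ? eval_loss(net, Xval, Yval) : NA_REAL;
    if (!std::isfinite(train_curve(ep)))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "  train " << train_curve(ep)
                  << "  val " << val_curve(ep) << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(net),
    Rcpp::Named("train_loss") = train_curve,
    Rcpp::Named("val_loss") = val_curve);
}

// Build the 11-dim system state for focal agent a (normalized units):
// (u_a, v_a, rw_a, u_b, v_b, rw_b, d_ab)
static void system_state(const mat& u, const mat& v, int a, vec& s) {
  int b = 1 - a;
  double rwa = 1.0 - std::sqrt(u(0, a) * u(0, a) + u(1, a) * u(1, a));
  double rwb = 1.0 - std::sqrt(u(0, b) * u(0, b) + u(1, b) * u(1, b));
  double dx = u(0, a) - u(0, b), dy = u(1, a) - u(1, b);
  s = { u(0, a), u(1, a), v(0, a), v(1, a), rwa,
        u(0, b), u(1, b), v(0, b), v(1, b), rwb,
        std::sqrt(dx * dx + dy * dy) };
}

// Closed-loop pair rollout in normalized units (tank = unit disc).
// init_u: 6 x 2 x 2 cube of positions (time, coord, agent) spaced dt apart.
// Returns positions for `steps` new timesteps, plus status fields.
// [[Rcpp::export]]
Rcpp::List cpp_dli_rollout(const Rcpp::List& weights, const arma::cube& init_u,
                           double dt, int steps, bool reject, int cap,
                           double stop_margin, const arma::vec& ascale) {
  Rcpp::RNGScope rng;
  Net net = net_from_list(weights);
  const int T = 5;
  if ((int)init_u.n_rows != T + 1)
    Rcpp::stop("init_u must provide 6 consecutive positions per agent");
  // state: positions/velocities at the most recent timestep
  mat u(2, 2), v(2, 2);
  for (int a = 0; a < 2; ++a) {
    u(0, a) = init_u(T, 0, a); u(1, a) = init_u(T, 1, a);
    v(0, a) = (init_u(T, 0, a) - init_u(T - 1, 0, a)) / dt;
    v(1, a) = (init_u(T, 1, a) - init_u(T - 1, 1, a)) / dt;
  }
  // history buffers: 11 x T per focal agent, oldest first
  cube hist(11, 2, T);
  for (int t = 0; t < T; ++t) {
    mat ut(2, 2), vt(2, 2);
    for (int a = 0; a < 2; ++a) {
      ut(0, a) = init_u(t + 1, 0, a); ut(1, a) = init_u(t + 1, 1, a);
      vt(0, a) = (init_u(t + 1, 0, a) - init_u(t, 0, a)) / dt;
      vt(1, a) = (init_u(t + 1, 1, a) - init_u(t, 1, a)) / dt;
    }
    for (int a = 0; a < 2; ++a) {
      vec s;
      system_state(ut, vt, a, s);
      hist.slice(t).col(a) = s;
    }
  }
  cube out_pos(steps, 2, 2, fill::zeros);
  int escaped_step = 0;
  for (int n = 0; n < steps; ++n) {
    // both agents predict from the state at time n (synchronous update)
    cube X(11, 2, T);
    for (int t = 0; t < T; ++t) X.slice(t) = hist.slice(t);
    FwdCache fc;
    mat out = net_forward(net, X, fc);
    mat mu = out.rows(0, 1);
    mat sigma = softplus(out.rows(2, 3));
    mu.each_col() %= ascale;
    sigma.each_col() %= ascale;
    mat unew(2, 2), vnew(2, 2);
    // After `cap` redraws at the predicted sigma, the proposal is widened
    // (sigma doubled per further block of `cap` draws, bounded so the
    // one-step displacement scale never exceeds half the tank radius):
    // off-distribution trap states near the wall would otherwise have an
    // acceptance probability of essentially zero.
    const double sig_max = 0.5 / (dt * dt);
    const int blocks = 64;
    for (int a = 0; a < 2; ++a) {
      bool ok = false;
      for (int attempt = 0; attempt < std::max(cap, 1) * blocks; ++attempt) {
        int k = attempt / std::max(cap, 1);
        double sx = sigma(0, a), sy = sigma(1, a);
        if (k > 0) {
          double f = std::pow(2.0, k);
          sx = std::min(sx * f, std::max(sx, sig_max));
          sy = std::min(sy * f, std::max(sy, sig_max));
        }
        double ax = mu(0, a) + sx * R::norm_rand();
        double ay = mu(1, a) + sy * R::norm_rand();
        double vx = v(0, a) + dt * ax, vy = v(1, a) + dt * ay;
        double ux = u(0, a) + dt * vx, uy = u(1, a) + dt * vy;
        if (!reject || std::sqrt(ux * ux + uy * uy) <= 1.0) {
          unew(0, a) = ux; unew(1, a) = uy;
          vnew(0, a) = vx; vnew(1, a) = vy;
          ok = true;
          break;
        }
      }
      if (!ok)
        Rcpp::stop("rollout rejection cap exhausted at step %d (agent %d at r = %.3f R)",
                   n + 1, a + 1, std::sqrt(u(0, a) * u(0, a) + u(1, a) * u(1, a)));
    }
    u = unew; v = vnew;
    for (int a = 0; a < 2; ++a) {
      out_pos(n, 0, a) = u(0, a);
      out_pos(n, 1, a) = u(1, a);
    }
    // shift histories and append the new system states
    for (int t = 0; t < T - 1; ++t) hist.slice(t) = hist.slice(t + 1);
    for (int a = 0; a < 2; ++a) {
      vec s;
      system_state(u, v, a, s);
      hist.slice(T - 1).col(a) = s;
    }
    if (stop_margin >= 0) {
      double r1 = std::sqrt(u(0, 0) * u(0, 0) + u(1, 0) * u(1, 0));
      double r2 = std::sqrt(u(0, 1) * u(0, 1) + u(1, 1) * u(1, 1));
      if (r1 > 1.0 + stop_margin || r2 > 1.0 + stop_margin) {
        escaped_step = n + 1;
        out_pos = out_pos.rows(0, n);
        break;
      }
    }
    if (n % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("pos") = out_pos,
    Rcpp::Named("escaped_step") = escaped_step);
}
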