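// Causal-transformer policy core: token embedding, attention stack,
// action-position loss, manual backprop and Adam. All randomness draws from
// R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

constexpr double LN_EPS = 1e-5;

struct Cfg {
  int ds, act_dim, D, H, L, max_pos, dh, Dff, out_dim;
  bool discrete;
};

Cfg read_cfg(const List& c) {
  Cfg g;
  g.ds = as<int>(c["d_s"]);
  g.discrete = as<bool>(c["discrete"]);
  g.act_dim = as<int>(c["act_dim"]);
  g.D = as<int>(c["width"]);
  g.H = as<int>(c["heads"]);
  g.L = as<int>(c["depth"]);
  g.max_pos = as<int>(c["max_pos"]);
  if (g.D % g.H != 0) stop("width must be divisible by heads");
  g.dh = g.D / g.H;
  g.Dff = 4 * g.D;
  g.out_dim = g.act_dim;
  return g;
}

struct Layer {
  mat ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
      ln2_g, ln2_b, W1, b1, W2, b2;
};

// Parameters; also reused (same shapes) for gradients and Adam moments.
struct Params {
  mat type_marker;            // 8 x D additive type vectors
  mat emb_z;                  // 2 x D avoid-success embedding
  mat W_box;                  // 2ds x D box-coordinate projector
  mat W_state;                // ds x D state/goal projector
  mat W_act;                  // act_dim x D (table for discrete, projector for continuous)
  mat W_pos;                  // max_pos x D learned positions (trajectory tokens only)
  std::vector<Layer> layers;
  mat lnf_g, lnf_b;
  mat W_head, b_head;         // D x out, out x 1
};

void alloc_params(Params& P, const Cfg& c) {
  P.type_marker.set_size(8, c.D);
  P.emb_z.set_size(2, c.D);
  P.W_box.set_size(2 * c.ds, c.D);
  P.W_state.set_size(c.ds, c.D);
  P.W_act.set_size(c.act_dim, c.D);
  P.W_pos.set_size(c.max_pos, c.D);
  P.layers.resize(c.L);
  for (auto& l : P.layers) {
    l.ln1_g.set_size(c.D, 1); l.ln1_b.set_size(c.D, 1);
    l.Wq.set_size(c.D, c.D);  l.bq.set_size(c.D, 1);
    l.Wk.set_size(c.D, c.D);  l.bk.set_size(c.D, 1);
    l.Wv.set_size(c.D, c.D);  l.bv.set_size(c.D, 1);
    l.Wo.set_size(c.D, c.D);  l.bo.set_size(c.D, 1);
    l.ln2_g.set_size(c.D, 1); l.ln2_b.set_size(c.D, 1);
    l.W1.set_size(c.D, c.Dff); l.b1.set_size(c.Dff, 1);
    l.W2.set_size(c.Dff, c.D); l.b2.set_size(c.D, 1);
  }
  P.lnf_g.set_size(c.D, 1); P.lnf_b.set_size(c.D, 1);
  P.W_head.set_size(c.D, c.out_dim);
  P.b_head.set_size(c.out_dim, 1);
}

void collect(Params& P, std::vector<mat*>& v) {
  v.clear();
  v.push_back(&P.type_marker); v.push_back(&P.emb_z); v.push_back(&P.W_box);
  v.push_back(&P.W_state); v.push_back(&P.W_act); v.push_back(&P.W_pos);
  for (auto& l : P.layers) {
    v.push_back(&l.ln1_g); v.push_back(&l.ln1_b);
    v.push_back(&l.Wq); v.push_back(&l.bq);
    v.push_back(&l.Wk); v.push_back(&l.bk);
    v.push_back(&l.Wv); v.push_back(&l.bv);
    v.push_back(&l.Wo); v.push_back(&l.bo);
    v.push_back(&l.ln2_g); v.push_back(&l.ln2_b);
    v.push_back(&l.W1); v.push_back(&l.b1);
    v.push_back(&l.W2); v.push_back(&l.b2);
  }
  v.push_back(&P.lnf_g); v.push_back(&P.lnf_b);
  v.push_back(&P.W_head); v.push_back(&P.b_head);
}

size_t n_params(const Cfg& c) {
  Params P; alloc_params(P, c);
  std::vector<mat*> v; collect(P, v);
  size_t n = 0;
  for (mat* m : v) n += m->n_elem;
  return n;
}

NumericVector pack(Params& P) {
  std::vector<mat*> v; collect(P, v);
  size_t n = 0;
  for (mat* m : v) n += m->n_elem;
  NumericVector out(n);
  size_t o = 0;
  for (mat* m : v) {
    std::copy(m->memptr(), m->memptr() + m->n_elem, out.begin() + o);
    o += m->n_elem;
  }
  return out;
}

void unpack(const NumericVector& theta, const Cfg& c, Params& P) {
  alloc_params(P, c);
  std::vector<mat*> v; collect(P, v);
  size_t n = 0;
  for (mat* m : v) n += m->n_elem;
  if ((size_t)theta.size() != n) stop("parameter vector has wrong length");
  size_t o = 0;
  for (mat* m : v) {
    std::copy(theta.begin() + o, theta.begin() + o + m->n_elem, m->memptr());
    o += m->n_elem;
  }
}

void zero_params(Params& P) {
  std::vector<mat*> v; collect(P, v);
  for (mat* m : v) m->zeros();
}

// --- sequence container -----------------------------------------------------

struct Seq {
  int z;            // avoid-success prompt token
  mat boxes;        // nb x 2ds (nb may be 0)
  rowvec goal;      // ds
  mat states;       // n_state x ds
  mat actions_c;    // (continuous) rows aligned with states
  ivec actions_d;   // (discrete) 0-based codes aligned with states
  bool ends_on_state; // true: last state has no following action token
};

Seq read_seq(const List& s, const Cfg& c) {
  Seq q;
  q.z = as<int>(s["z"]);
  if (q.z != 0 && q.z != 1) stop("z must be 0 or 1");
  q.boxes = as<mat>(s["boxes"]);
  if (q.boxes.n_rows > 0 && (int)q.boxes.n_cols != 2 * c.ds)
    stop("boxes must have 2*d_s columns");
  q.goal = as<rowvec>(s["goal"]);
  if ((int)q.goal.n_elem != c.ds) stop("goal has wrong dimension");
  q.states = as<mat>(s["states"]);
  if ((int)q.states.n_cols != c.ds) stop("states have wrong dimension");
  if (c.discrete) {
    q.actions_d = as<ivec>(s["actions"]);
  } else {
    q.actions_c = as<mat>(s["actions"]);
    if (q.actions_c.n_rows > 0 && (int)q.actions_c.n_cols != c.act_dim)
      stop("actions have wrong dimension");
  }
  int n_state = q.states.n_rows;
  int n_act = c.discrete ? q.actions_d.n_elem : q.actions_c.n_rows;
  if (n_act == n_state) q.ends_on_state = false;
  else if (n_act == n_state - 1) q.ends_on_state = true;
  else stop("action count must equal state count or state count - 1");
  return q;
}

// slice transitions [t0, t0+K) of a full trajectory (n_state states, n_state-1
// actions) into a training window ending on an action token
Seq window_seq(const Seq& full, int t0, int K, const Cfg& c) {
  Seq w;
  w.z = full.z; w.boxes = full.boxes; w.goal = full.goal;
  w.states = full.states.rows(t0, t0 + K - 1);
  if (c.discrete) w.actions_d = full.actions_d.subvec(t0, t0 + K - 1);
  else w.actions_c = full.actions_c.rows(t0, t0 + K - 1);
  w.ends_on_state = false;
  return w;
}

// --- layer norm -------------------------------------------------------------

struct LNCache { mat xhat; vec rstd; };

mat ln_fwd(const mat& X, const mat& g, const mat& b, LNCache& cch) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = mean(square(Xc), 1);
  cch.rstd = 1.0 / sqrt(v + LN_EPS);
  cch.xhat = Xc.each_col() % cch.rstd;
  mat Y = cch.xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

mat ln_bwd(const mat& dY, const mat& g, const LNCache& cch, mat& dg, mat& db) {
  dg += sum(dY % cch.xhat, 0).t();
  db += sum(dY, 0).t();
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % cch.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= cch.xhat.each_col() % m2;
  dX.each_col() %= cch.rstd;
  return dX;
}

inline double gelu(double x) { return 0.5 * x * (1.0 + std::erf(x * M_SQRT1_2)); }
inline double gelu_d(double x) {
  return 0.5 * (1.0 + std::erf(x * M_SQRT1_2)) +
         x * 0.3989422804014327 * std::exp(-0.5 * x * x);
}

struct LayerCache {
  mat Xin, N1, Q, K, V, Z, Xmid, N2, H1pre, H1;
  LNCache ln1c, ln2c;
  cube Ph; // T x T x H attention weights
};

// --- forward / backward over one sequence -----------------------------------
// Returns mean loss over action targets (0 if none / preds-only). If G is
// non-null, accumulates gradients. If preds non-null, fills one row per state
// token (logits for discrete, regressed action for continuous).
double run_seq(const Params& P, const Cfg& c, const Seq& q,
               Params* G, mat* preds) {
  const int nb = q.boxes.n_rows;
  const int Tp = 5 + nb;
  const int n_state = q.states.n_rows;
  const int n_act = c.discrete ? q.actions_d.n_elem
                               : (int)q.actions_c.n_rows;
  if (n_state < 1) stop("sequence needs at least one state");
  if (2 * (n_state - 1) + 1 > c.max_pos)
    stop("sequence exceeds the model's positional range; truncate first");
  const int T = Tp + n_state + n_act;

  // embed
  mat X(T, c.D);
  X.row(0) = P.emb_z.row(q.z) + P.type_marker.row(0);
  X.row(1) = P.type_marker.row(1);
  for (int j = 0; j < nb; ++j)
    X.row(2 + j) = q.boxes.row(j) * P.W_box + P.type_marker.row(2);
  X.row(2 + nb) = P.type_marker.row(3);
  X.row(3 + nb) = q.goal * P.W_state + P.type_marker.row(4);
  X.row(4 + nb) = P.type_marker.row(5);
  for (int t = 0; t < n_state; ++t) {
    int r = Tp + 2 * t;
    // z is broadcast onto every state token so avoid-success conditioning
    // does not depend solely on attention to the prompt
    X.row(r) = q.states.row(t) * P.W_state + P.type_marker.row(6) +
               P.W_pos.row(2 * t) + P.emb_z.row(q.z);
    if (t < n_act) {
      rowvec ae = c.discrete ? rowvec(P.W_act.row(q.actions_d(t)))
                             : rowvec(q.actions_c.row(t) * P.W_act);
      X.row(r + 1) = ae + P.type_marker.row(7) + P.W_pos.row(2 * t + 1);
    }
  }

  const double scale = 1.0 / std::sqrt((double)c.dh);
  std::vector<LayerCache> cache(c.L);
  for (int l = 0; l < c.L; ++l) {
    LayerCache& cc = cache[l];
    const Layer& Ly = P.layers[l];
    cc.Xin = X;
    cc.N1 = ln_fwd(cc.Xin, Ly.ln1_g, Ly.ln1_b, cc.ln1c);
    cc.Q = cc.N1 * Ly.Wq; cc.Q.each_row() += Ly.bq.t();
    cc.K = cc.N1 * Ly.Wk; cc.K.each_row() += Ly.bk.t();
    cc.V = cc.N1 * Ly.Wv; cc.V.each_row() += Ly.bv.t();
    cc.Z.set_size(T, c.D);
    cc.Ph.set_size(T, T, c.H);
    for (int h = 0; h < c.H; ++h) {
      int c0 = h * c.dh, c1 = c0 + c.dh - 1;
      mat S = cc.Q.cols(c0, c1) * cc.K.cols(c0, c1).t() * scale;
      for (int i = 0; i < T; ++i) {
        double mx = -datum::inf;
        for (int j = 0; j <= i; ++j) mx = std::max(mx, S(i, j));
        double sm = 0.0;
        for (int j = 0; j <= i; ++j) { S(i, j) = std::exp(S(i, j) - mx); sm += S(i, j); }
        for (int j = 0; j <= i; ++j) S(i, j) /= sm;
        for (int j = i + 1; j < T; ++j) S(i, j) = 0.0;
      }
      cc.Ph.slice(h) = S;
      cc.Z.cols(c0, c1) = S * cc.V.cols(c0, c1);
    }
    mat O = cc.Z * Ly.Wo; O.each_row() += Ly.bo.t();
    cc.Xmid = cc.Xin + O;
    cc.N2 = ln_fwd(cc.Xmid, Ly.ln2_g, Ly.ln2_b, cc.ln2c);
    cc.H1pre = cc.N2 * Ly.W1; cc.H1pre.each_row() += Ly.b1.t();
    cc.H1 = cc.H1pre;
    cc.H1.for_each([](double& x) { x = gelu(x); });
    mat M = cc.H1 * Ly.W2; M.each_row() += Ly.b2.t();
    X = cc.Xmid + M;
  }
  LNCache lnfc;
  mat NF = ln_fwd(X, P.lnf_g, P.lnf_b, lnfc);

  // head at state positions
  double loss = 0.0;
  const int n_tgt = c.discrete ? n_act : n_act; // targets exist where an action follows
  mat dNF;
  if (G) dNF.zeros(T, c.D);
  if (preds) preds->set_size(n_state, c.out_dim);
  for (int t = 0; t < n_state; ++t) {
    int r = Tp + 2 * t;
    rowvec out = NF.row(r) * P.W_head + P.b_head.t();
    if (preds) preds->row(t) = out;
    if (t >= n_act) continue; // no target after the final state
    rowvec dout(c.out_dim, fill::zeros);
    if (c.discrete) {
      double mx = out.max();
      rowvec e = exp(out - mx);
      double sm = accu(e);
      rowvec p = e / sm;
      int a = q.actions_d(t);
      loss += -(out(a) - mx - std::log(sm)) / n_tgt;
      if (G) { dout = p / n_tgt; dout(a) -= 1.0 / n_tgt; }
    } else {
      rowvec diff = out - q.actions_c.row(t);
      loss += dot(diff, diff) / (n_tgt * c.out_dim);
      if (G) dout = 2.0 * diff / (n_tgt * c.out_dim);
    }
    if (G) {
      G->W_head += NF.row(r).t() * dout;
      G->b_head += dout.t();
      dNF.row(r) += dout * P.W_head.t();
    }
  }
  if (!G) return loss;

  mat dX = ln_bwd(dNF, P.lnf_g, lnfc, G->lnf_g, G->lnf_b);

  for (int l = c.L - 1; l >= 0; --l) {
    LayerCache& cc = cache[l];
    const Layer& Ly = P.layers[l];
    Layer& Gl = G->layers[l];
    // MLP branch
    mat dM = dX;                       // d(Xout) w.r.t. MLP output
    mat dH1 = dM * Ly.W2.t();
    Gl.W2 += cc.H1.t() * dM;
    Gl.b2 += sum(dM, 0).t();
    mat dH1pre = dH1;
    for (uword i = 0; i < dH1pre.n_elem; ++i) dH1pre(i) *= gelu_d(cc.H1pre(i));
    mat dN2 = dH1pre * Ly.W1.t();
    Gl.W1 += cc.N2.t() * dH1pre;
    Gl.b1 += sum(dH1pre, 0).t();
    mat dXmid = dX + ln_bwd(dN2, Ly.ln2_g, cc.ln2c, Gl.ln2_g, Gl.ln2_b);
    // attention branch
    mat dO = dXmid;
    mat dZ = dO * Ly.Wo.t();
    Gl.Wo += cc.Z.t() * dO;
    Gl.bo += sum(dO, 0).t();
    mat dQ(T, c.D, fill::zeros), dK(T, c.D, fill::zeros), dV(T, c.D, fill::zeros);
    for (int h = 0; h < c.H; ++h) {
      int c0 = h * c.dh, c1 = c0 + c.dh - 1;
      const mat& Ph = cc.Ph.slice(h);
      mat dZh = dZ.cols(c0, c1);
      mat dP = dZh * cc.V.cols(c0, c1).t();
      dV.cols(c0, c1) = Ph.t() * dZh;
      vec rs = sum(dP % Ph, 1);
      mat dS = Ph % (dP.each_col() - rs);
      dQ.cols(c0, c1) = dS * cc.K.cols(c0, c1) * scale;
      dK.cols(c0, c1) = dS.t() * cc.Q.cols(c0, c1) * scale;
    }
    mat dN1 = dQ * Ly.Wq.t() + dK * Ly.Wk.t() + dV * Ly.Wv.t();
    Gl.Wq += cc.N1.t() * dQ; Gl.bq += sum(dQ, 0).t();
    Gl.Wk += cc.N1.t() * dK; Gl.bk += sum(dK, 0).t();
    Gl.Wv += cc.N1.t() * dV; Gl.bv += sum(dV, 0).t();
    dX = dXmid + ln_bwd(dN1, Ly.ln1_g, cc.ln1c, Gl.ln1_g, Gl.ln1_b);
  }

  // embedding gradients
  G->emb_z.row(q.z) += dX.row(0);
  G->type_marker.row(0) += dX.row(0);
  G->type_marker.row(1) += dX.row(1);
  for (int j = 0; j < nb; ++j) {
    G->W_box += q.boxes.row(j).t() * dX.row(2 + j);
    G->type_marker.row(2) += dX.row(2 + j);
  }
  G->type_marker.row(3) += dX.row(2 + nb);
  G->W_state += q.goal.t() * dX.row(3 + nb);
  G->type_marker.row(4) += dX.row(3 + nb);
  G->type_marker.row(5) += dX.row(4 + nb);
  for (int t = 0; t < n_state; ++t) {
    int r = Tp + 2 * t;
    G->W_state += q.states.row(t).t() * dX.row(r);
    G->type_marker.row(6) += dX.row(r);
    G->W_pos.row(2 * t) += dX.row(r);
    G->emb_z.row(q.z) += dX.row(r);
    if (t < n_act) {
      if (c.discrete) G->W_act.row(q.actions_d(t)) += dX.row(r + 1);
      else G->W_act += q.actions_c.row(t).t() * dX.row(r + 1);
      G->type_marker.row(7) += dX.row(r + 1);
      G->W_pos.row(2 * t + 1) += dX.row(r + 1);
    }
  }
  return loss;
}

} // namespace

// [[Rcpp::export]]
int cpp_n_params(List cfg) {
  Cfg c = read_cfg(cfg);
  return (int)n_params(c);
}

// [[Rcpp::export]]
NumericVector cpp_init_params(List cfg) {
  Cfg c = read_cfg(cfg);
  Params P; alloc_params(P, c);
  zero_params(P);
  RNGScope scope;
  auto gauss = [](mat& m, double sd) {
    for (uword i = 0; i < m.n_elem; ++i) m(i) = norm_rand() * sd;
  };
  gauss(P.type_marker, 0.02); gauss(P.emb_z, 0.02); gauss(P.W_box, 0.02);
  gauss(P.W_state, 0.02); gauss(P.W_act, 0.02); gauss(P.W_pos, 0.02);
  double resid_sd = 0.02 / std::sqrt(2.0 * c.L); // residual-branch scaling
  for (auto& l : P.layers) {
    l.ln1_g.ones(); l.ln2_g.ones();
    gauss(l.Wq, 0.02); gauss(l.Wk, 0.02); gauss(l.Wv, 0.02);
    gauss(l.Wo, resid_sd);
    gauss(l.W1, 0.02); gauss(l.W2, resid_sd);
  }
  P.lnf_g.ones();
  gauss(P.W_head, 0.02);
  return pack(P);
}

// [[Rcpp::export]]
List cpp_loss_grad(NumericVector theta, List seq, List cfg) {
  Cfg c = read_cfg(cfg);
  Params P; unpack(theta, c, P);
  Params G; alloc_params(G, c); zero_params(G);
  Seq q = read_seq(seq, c);
  double loss = run_seq(P, c, q, &G, nullptr);
  return List::create(_["loss"] = loss, _["grad"] = pack(G));
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(NumericVector theta, List seq, List cfg) {
  Cfg c = read_cfg(cfg);
  Params P; unpack(theta, c, P);
  Seq q = read_seq(seq, c);
  mat preds;
  run_seq(P, c, q, nullptr, &preds);
  return wrap(preds);
}

// [[Rcpp::export]]
List cpp_train(NumericVector theta, List seqs, List cfg, int epochs,
               int batch_size, double lr, int context_steps, double clip,
               double lr_min_frac) {
  Cfg c = read_cfg(cfg);
  Params P; unpack(theta, c, P);
  Params G, M, V;
  alloc_params(G, c); zero_params(G);
  alloc_params(M, c); zero_params(M);
  alloc_params(V, c); zero_params(V);
  std::vector<mat*> vp, vg, vm, vv;
  collect(P, vp); collect(G, vg); collect(M, vm); collect(V, vv);

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  RNGScope scope;

  std::vector<Seq> data;
  for (int i = 0; i < seqs.size(); ++i) {
    Seq q = read_seq(seqs[i], c);
    if (!q.ends_on_state) stop("training trajectories must have one fewer action than states");
    if (q.states.n_rows >= 2) data.push_back(std::move(q));
  }
  if (data.empty()) stop("no trainable trajectories (need >= 2 states each)");
  const int n = data.size();

  std::vector<int> order(n);
  NumericVector loss_hist(epochs);
  long step = 0;
  long total_steps = (long)epochs * ((n + batch_size - 1) / batch_size);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates via R RNG
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    int in_batch = 0;
    for (int i = 0; i < n; ++i) {
      const Seq& full = data[order[i]];
      int n_trans = full.states.n_rows - 1;
      Seq w;
      if (n_trans > context_steps) {
        int t0 = (int)std::floor(unif_rand() * (n_trans - context_steps + 1));
        if (t0 > n_trans - context_steps) t0 = n_trans - context_steps;
        w = window_seq(full, t0, context_steps, c);
      } else {
        w = window_seq(full, 0, n_trans, c);
      }
      ep_loss += run_seq(P, c, w, &G, nullptr);
      ++in_batch;
      if (in_batch == batch_size || i == n - 1) {
        double inv = 1.0 / in_batch;
        double sq = 0.0;
        for (mat* g : vg) { *g *= inv; sq += accu(square(*g)); }
        double gn = std::sqrt(sq);
        if (clip > 0 && gn > clip) {
          double sc = clip / gn;
          for (mat* g : vg) *g *= sc;
        }
        ++step;
        // cosine decay from lr to lr * lr_min_frac over the whole run
        double prog = total_steps > 1 ? (double)(step - 1) / (total_steps - 1) : 0.0;
        double lr_t = lr * (lr_min_frac + (1.0 - lr_min_frac) *
                            0.5 * (1.0 + std::cos(M_PI * prog)));
        double alpha = lr_t * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                       (1.0 - std::pow(b1, (double)step));
        for (size_t k = 0; k < vp.size(); ++k) {
          double* p = vp[k]->memptr();
          double* g = vg[k]->memptr();
          double* m = vm[k]->memptr();
          double* v = vv[k]->memptr();
          uword ne = vp[k]->n_elem;
          for (uword e = 0; e < ne; ++e) {
            m[e] = b1 * m[e] + (1.0 - b1) * g[e];
            v[e] = b2 * v[e] + (1.0 - b2) * g[e] * g[e];
            p[e] -= alpha * m[e] / (std::sqrt(v[e]) + eps);
          }
        }
        for (mat* g : vg) g->zeros();
        in_batch = 0;
      }
      if ((i & 63) == 0) Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / n;
  }
  return List::create(_["params"] = pack(P), _["loss"] = loss_hist);
}
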