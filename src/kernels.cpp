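// Recurrent kernels for the EIDT pipeline.
//
// All networks are gated recurrent units (GRU) in the convention
//   u_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)          (update gate)
//   r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)          (reset gate)
//   c_t = tanh(Wc x_t + Uc (r_t . h_{t-1}) + bc)     (candidate)
//   h_t = (1 - u_t) . h_{t-1} + u_t . c_t
// with h_0 = 0.  Weight vectors are packed column-major in the order
// [Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc]; a task solver appends the readout
// matrix Wout (K x Q, no bias): logits v_t = Wout h_t, probabilities by
// softmax.  The same layout is shared by decoder-generated and directly
// trained solver weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruW {
  mat Wz, Wr, Wc, Uz, Ur, Uc;
  vec bz, br, bc;
};

static int gru_npar(int I, int H) { return 3 * H * I + 3 * H * H + 3 * H; }

static GruW gru_unpack(const vec& w, int I, int H, int off) {
  GruW g;
  const double* p = w.memptr() + off;
  g.Wz = mat(p, H, I); p += H * I;
  g.Wr = mat(p, H, I); p += H * I;
  g.Wc = mat(p, H, I); p += H * I;
  g.Uz = mat(p, H, H); p += H * H;
  g.Ur = mat(p, H, H); p += H * H;
  g.Uc = mat(p, H, H); p += H * H;
  g.bz = vec(p, H); p += H;
  g.br = vec(p, H); p += H;
  g.bc = vec(p, H);
  return g;
}

struct GruCache {
  mat H, U, R, C;  // hidden, update gate, reset gate, candidate; each Q x L
};

static void gru_forward(const GruW& w, const mat& X, GruCache& c) {
  const int H = w.bz.n_elem, L = X.n_cols;
  c.H.set_size(H, L); c.U.set_size(H, L); c.R.set_size(H, L); c.C.set_size(H, L);
  vec h(H, fill::zeros);
  for (int t = 0; t < L; ++t) {
    const vec x = X.col(t);
    vec u = sigm(w.Wz * x + w.Uz * h + w.bz);
    vec r = sigm(w.Wr * x + w.Ur * h + w.br);
    vec cd = tanh(w.Wc * x + w.Uc * (r % h) + w.bc);
    vec hn = (1.0 - u) % h + u % cd;
    c.U.col(t) = u; c.R.col(t) = r; c.C.col(t) = cd; c.H.col(t) = hn;
    h = hn;
  }
}

// Accumulates packed GRU weight gradients at `goff` of `g`, given per-step
// external gradients dHext (H x L) on the hidden states.
static void gru_backward(const GruW& w, const mat& X, const GruCache& c,
                         const mat& dHext, vec& g, int goff) {
  const int H = w.bz.n_elem, I = X.n_rows, L = X.n_cols;
  double* p = g.memptr() + goff;
  mat gWz(p, H, I, false); p += H * I;
  mat gWr(p, H, I, false); p += H * I;
  mat gWc(p, H, I, false); p += H * I;
  mat gUz(p, H, H, false); p += H * H;
  mat gUr(p, H, H, false); p += H * H;
  mat gUc(p, H, H, false); p += H * H;
  vec gbz(p, H, false); p += H;
  vec gbr(p, H, false); p += H;
  vec gbc(p, H, false);
  vec carry(H, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    vec dh = dHext.col(t) + carry;
    vec hp = (t == 0) ? vec(H, fill::zeros) : vec(c.H.col(t - 1));
    const vec u = c.U.col(t), r = c.R.col(t), cd = c.C.col(t), x = X.col(t);
    vec dcd = dh % u;
    vec du = dh % (cd - hp);
    vec dhp = dh % (1.0 - u);
    vec dac = dcd % (1.0 - cd % cd);
    gWc += dac * x.t(); gUc += dac * (r % hp).t(); gbc += dac;
    vec drh = w.Uc.t() * dac;
    vec dr = drh % hp;
    dhp += drh % r;
    vec dau = du % u % (1.0 - u);
    gWz += dau * x.t(); gUz += dau * hp.t(); gbz += dau;
    dhp += w.Uz.t() * dau;
    vec dar = dr % r % (1.0 - r);
    gWr += dar * x.t(); gUr += dar * hp.t(); gbr += dar;
    dhp += w.Ur.t() * dar;
    carry = dhp;
  }
}

static mat softmax_cols(const mat& V) {
  mat P = V;
  for (uword j = 0; j < P.n_cols; ++j) {
    vec v = P.col(j);
    v -= v.max();
    v = exp(v);
    P.col(j) = v / accu(v);
  }
  return P;
}

// ---- task solver ----------------------------------------------------------

// [[Rcpp::export]]
int cpp_solver_npar(int I, int Q, int K) { return gru_npar(I, Q) + K * Q; }

// [[Rcpp::export]]
arma::mat cpp_solver_forward(const arma::vec& theta, int I, int Q, int K,
                             const arma::mat& X) {
  if ((int)theta.n_elem != gru_npar(I, Q) + K * Q)
    Rcpp::stop("solver weight vector has wrong length");
  if ((int)X.n_rows != I) Rcpp::stop("input row dimension mismatch");
  GruW w = gru_unpack(theta, I, Q, 0);
  mat Wout(theta.memptr() + gru_npar(I, Q), K, Q);
  GruCache c;
  gru_forward(w, X, c);
  return softmax_cols(Wout * c.H);  // K x L
}

// Mean NLL of `actions` (0-based) under the solver, with gradient w.r.t.
// the flattened weights.  `score` marks which time steps contribute; for the
// value-guided task every step is scored, for the perceptual task only the
// response-time step of each trial.
static double solver_nll_grad_one(const vec& theta, int I, int Q, int K,
                                  const mat& X, const ivec& actions,
                                  const ivec& score_t, double wloss,
                                  vec& grad, bool want_grad) {
  GruW w = gru_unpack(theta, I, Q, 0);
  const int ngru = gru_npar(I, Q), L = X.n_cols;
  mat Wout(theta.memptr() + ngru, K, Q);
  GruCache c;
  gru_forward(w, X, c);
  mat P = softmax_cols(Wout * c.H);
  double nll = 0.0;
  mat dV(K, L, fill::zeros);
  for (uword i = 0; i < score_t.n_elem; ++i) {
    int t = score_t(i), a = actions(i);
    if (t < 0 || t >= L || a < 0 || a >= K) Rcpp::stop("score index out of range");
    nll += -std::log(P(a, t)) * wloss;
    if (want_grad) {
      dV.col(t) += P.col(t) * wloss;
      dV(a, t) -= wloss;
    }
  }
  if (want_grad) {
    mat gWout(grad.memptr() + ngru, K, Q, false);
    gWout += dV * c.H.t();
    gru_backward(w, X, c, Wout.t() * dV, grad, 0);
  }
  return nll;
}

// [[Rcpp::export]]
Rcpp::List cpp_solver_nll_grad(const arma::vec& theta, int I, int Q, int K,
                               const arma::mat& X, const arma::ivec& actions,
                               bool want_grad) {
  if ((int)actions.n_elem != (int)X.n_cols) Rcpp::stop("one action per time step required");
  vec grad(theta.n_elem, fill::zeros);
  ivec score_t = regspace<ivec>(0, X.n_cols - 1);
  double nll = solver_nll_grad_one(theta, I, Q, K, X, actions, score_t,
                                   1.0 / X.n_cols, grad, want_grad);
  return Rcpp::List::create(Rcpp::Named("nll") = nll, Rcpp::Named("grad") = grad);
}

// Evidence-accumulation solver: E is I x S x U (one slice per trial); the
// loss is the mean over trials of -log P_{t~}(a).
// [[Rcpp::export]]
Rcpp::List cpp_acc_nll_grad(const arma::vec& theta, int I, int Q, int K,
                            const arma::cube& E, const arma::ivec& tsteps,
                            const arma::ivec& actions, bool want_grad) {
  const int U = E.n_slices;
  if ((int)tsteps.n_elem != U || (int)actions.n_elem != U)
    Rcpp::stop("tsteps/actions must have one entry per trial");
  vec grad(theta.n_elem, fill::zeros);
  double nll = 0.0;
  for (int u = 0; u < U; ++u) {
    ivec st(1), ac(1);
    st(0) = tsteps(u); ac(0) = actions(u);
    nll += solver_nll_grad_one(theta, I, Q, K, E.slice(u), ac, st, 1.0 / U,
                               grad, want_grad);
  }
  return Rcpp::List::create(Rcpp::Named("nll") = nll, Rcpp::Named("grad") = grad);
}

// ---- multilayer perceptron head -------------------------------------------

struct Mlp {
  std::vector<mat> W;
  std::vector<vec> b;
};

static int mlp_npar(const ivec& sz) {
  int n = 0;
  for (uword i = 1; i < sz.n_elem; ++i) n += sz(i) * sz(i - 1) + sz(i);
  return n;
}

static Mlp mlp_unpack(const vec& w, const ivec& sz, int off) {
  Mlp m;
  const double* p = w.memptr() + off;
  for (uword i = 1; i < sz.n_elem; ++i) {
    m.W.push_back(mat(p, sz(i), sz(i - 1))); p += sz(i) * sz(i - 1);
    m.b.push_back(vec(p, sz(i))); p += sz(i);
  }
  return m;
}

// tanh on hidden layers, linear output layer
static vec mlp_forward(const Mlp& m, const vec& x, std::vector<vec>& acts) {
  acts.clear();
  acts.push_back(x);
  vec h = x;
  const int D = m.W.size();
  for (int i = 0; i < D; ++i) {
    h = m.W[i] * h + m.b[i];
    if (i < D - 1) h = tanh(h);
    acts.push_back(h);
  }
  return h;
}

static vec mlp_backward(const Mlp& m, const std::vector<vec>& acts,
                        const vec& dy, vec& g, int off) {
  const int D = m.W.size();
  double* p = g.memptr() + off;
  std::vector<double*> wp(D), bp(D);
  for (int i = 0; i < D; ++i) {
    wp[i] = p; p += m.W[i].n_elem;
    bp[i] = p; p += m.b[i].n_elem;
  }
  vec d = dy;
  for (int i = D - 1; i >= 0; --i) {
    if (i < D - 1) d = d % (1.0 - acts[i + 1] % acts[i + 1]);
    mat gW(wp[i], m.W[i].n_rows, m.W[i].n_cols, false);
    vec gb(bp[i], m.b[i].n_elem, false);
    gW += d * acts[i].t();
    gb += d;
    d = m.W[i].t() * d;
  }
  return d;  // gradient w.r.t. the input
}

// ---- encoder --------------------------------------------------------------

// [[Rcpp::export]]
int cpp_encoder_npar(int Ie, int R, const arma::ivec& head_sizes) {
  return gru_npar(Ie, R) + mlp_npar(head_sizes);
}

// Latent representation of one sequence: z = head(h_L).
// [[Rcpp::export]]
arma::vec cpp_encode(const arma::vec& encpar, int Ie, int R,
                     const arma::ivec& head_sizes, const arma::mat& X) {
  if ((int)encpar.n_elem != cpp_encoder_npar(Ie, R, head_sizes))
    Rcpp::stop("encoder weight vector has wrong length");
  if ((int)X.n_rows != Ie) Rcpp::stop("encoder input row dimension mismatch");
  GruW w = gru_unpack(encpar, Ie, R, 0);
  Mlp head = mlp_unpack(encpar, head_sizes, gru_npar(Ie, R));
  GruCache c;
  gru_forward(w, X, c);
  std::vector<vec> acts;
  return mlp_forward(head, c.H.col(X.n_cols - 1), acts);
}

// Set encoder: average of final hidden states over slices, then the head.
// [[Rcpp::export]]
arma::vec cpp_set_encode(const arma::vec& encpar, int Ie, int R,
                         const arma::ivec& head_sizes, const arma::cube& X) {
  GruW w = gru_unpack(encpar, Ie, R, 0);
  Mlp head = mlp_unpack(encpar, head_sizes, gru_npar(Ie, R));
  vec hbar(R, fill::zeros);
  GruCache c;
  for (uword u = 0; u < X.n_slices; ++u) {
    gru_forward(w, X.slice(u), c);
    hbar += c.H.col(X.n_cols - 1);
  }
  hbar /= X.n_slices;
  std::vector<vec> acts;
  return mlp_forward(head, hbar, acts);
}

// ---- end-to-end pair loss -------------------------------------------------
//
// Joint parameter vector layout:
//   [encoder GRU | encoder head | decoder W (Nts x M, column-major) | decoder b]
// Forward pass: z = head(GRU(Xsrc) last hidden), theta = W z + b,
// loss = teacher-forced mean NLL of the target actions under the solver.

// [[Rcpp::export]]
int cpp_eidt_npar(int Ie, int R, const arma::ivec& head_sizes,
                  int I, int Q, int K) {
  int M = head_sizes(head_sizes.n_elem - 1);
  int Nts = cpp_solver_npar(I, Q, K);
  return cpp_encoder_npar(Ie, R, head_sizes) + Nts * M + Nts;
}

// [[Rcpp::export]]
Rcpp::List cpp_eidt_pair_grad(const arma::vec& par, int Ie, int R,
                              const arma::ivec& head_sizes,
                              int I, int Q, int K,
                              const arma::mat& Xsrc, const arma::mat& Xtgt,
                              const arma::ivec& actions_tgt, bool want_grad) {
  const int M = head_sizes(head_sizes.n_elem - 1);
  const int Nts = cpp_solver_npar(I, Q, K);
  const int nenc = cpp_encoder_npar(Ie, R, head_sizes);
  if ((int)par.n_elem != nenc + Nts * M + Nts)
    Rcpp::stop("joint parameter vector has wrong length");

  GruW ew = gru_unpack(par, Ie, R, 0);
  Mlp head = mlp_unpack(par, head_sizes, gru_npar(Ie, R));
  mat decW(par.memptr() + nenc, Nts, M);
  vec decb(par.memptr() + nenc + Nts * M, Nts);

  GruCache ec;
  gru_forward(ew, Xsrc, ec);
  std::vector<vec> acts;
  vec z = mlp_forward(head, ec.H.col(Xsrc.n_cols - 1), acts);
  vec theta = decW * z + decb;

  vec grad(par.n_elem, fill::zeros);
  vec dtheta(theta.n_elem, fill::zeros);
  ivec score_t = regspace<ivec>(0, Xtgt.n_cols - 1);
  double nll = solver_nll_grad_one(theta, I, Q, K, Xtgt, actions_tgt, score_t,
                                   1.0 / Xtgt.n_cols, dtheta, want_grad);
  if (want_grad) {
    mat gdecW(grad.memptr() + nenc, Nts, M, false);
    vec gdecb(grad.memptr() + nenc + Nts * M, Nts, false);
    gdecW += dtheta * z.t();
    gdecb += dtheta;
    vec dz = decW.t() * dtheta;
    vec dhL = mlp_backward(head, acts, dz, grad, gru_npar(Ie, R));
    mat dHext(R, Xsrc.n_cols, fill::zeros);
    dHext.col(Xsrc.n_cols - 1) = dhL;
    gru_backward(ew, Xsrc, ec, dHext, grad, 0);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = nll,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("z") = z);
}

// Variant used for training with the individual's latent averaged over all
// of their source blocks (matching how the latent is inferred at test time):
// z = head(mean_b h_L(Xsrc_b)), then decode and score the target block.
// [[Rcpp::export]]
Rcpp::List cpp_eidt_indiv_grad(const arma::vec& par, int Ie, int R,
                               const arma::ivec& head_sizes,
                               int I, int Q, int K,
                               const Rcpp::List& Xsrcs, const arma::mat& Xtgt,
                               const arma::ivec& actions_tgt, bool want_grad) {
  const int M = head_sizes(head_sizes.n_elem - 1);
  const int Nts = cpp_solver_npar(I, Q, K);
  const int nenc = cpp_encoder_npar(Ie, R, head_sizes);
  if ((int)par.n_elem != nenc + Nts * M + Nts)
    Rcpp::stop("joint parameter vector has wrong length");
  const int B = Xsrcs.size();

  GruW ew = gru_unpack(par, Ie, R, 0);
  Mlp head = mlp_unpack(par, head_sizes, gru_npar(Ie, R));
  mat decW(par.memptr() + nenc, Nts, M);
  vec decb(par.memptr() + nenc + Nts * M, Nts);

  std::vector<GruCache> ecs(B);
  std::vector<mat> Xs(B);
  vec hbar(R, fill::zeros);
  for (int b = 0; b < B; ++b) {
    Xs[b] = Rcpp::as<mat>(Xsrcs[b]);
    gru_forward(ew, Xs[b], ecs[b]);
    hbar += ecs[b].H.col(Xs[b].n_cols - 1);
  }
  hbar /= B;
  std::vector<vec> acts;
  vec z = mlp_forward(head, hbar, acts);
  vec theta = decW * z + decb;

  vec grad(par.n_elem, fill::zeros);
  vec dtheta(theta.n_elem, fill::zeros);
  ivec score_t = regspace<ivec>(0, Xtgt.n_cols - 1);
  double nll = solver_nll_grad_one(theta, I, Q, K, Xtgt, actions_tgt, score_t,
                                   1.0 / Xtgt.n_cols, dtheta, want_grad);
  if (want_grad) {
    mat gdecW(grad.memptr() + nenc, Nts, M, false);
    vec gdecb(grad.memptr() + nenc + Nts * M, Nts, false);
    gdecW += dtheta * z.t();
    gdecb += dtheta;
    vec dz = decW.t() * dtheta;
    vec dhbar = mlp_backward(head, acts, dz, grad, gru_npar(Ie, R));
    for (int b = 0; b < B; ++b) {
      mat dHext(R, Xs[b].n_cols, fill::zeros);
      dHext.col(Xs[b].n_cols - 1) = dhbar / B;
      gru_backward(ew, Xs[b], ecs[b], dHext, grad, 0);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = nll,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("z") = z);
}

// Perceptual variant: the encoder consumes U source-trial slices and averages
// final hidden states; the solver scores each target trial at its converted
// response-time step.
// [[Rcpp::export]]
Rcpp::List cpp_perc_pair_grad(const arma::vec& par, int Ie, int R,
                              const arma::ivec& head_sizes,
                              int I, int Q, int K,
                              const arma::cube& Xsrc,
                              const arma::cube& Etgt,
                              const arma::ivec& tgt_tsteps,
                              const arma::ivec& tgt_actions,
                              bool want_grad) {
  const int M = head_sizes(head_sizes.n_elem - 1);
  const int Nts = cpp_solver_npar(I, Q, K);
  const int nenc = cpp_encoder_npar(Ie, R, head_sizes);
  if ((int)par.n_elem != nenc + Nts * M + Nts)
    Rcpp::stop("joint parameter vector has wrong length");
  const int U = Xsrc.n_slices;

  GruW ew = gru_unpack(par, Ie, R, 0);
  Mlp head = mlp_unpack(par, head_sizes, gru_npar(Ie, R));
  mat decW(par.memptr() + nenc, Nts, M);
  vec decb(par.memptr() + nenc + Nts * M, Nts);

  std::vector<GruCache> ecs(U);
  vec hbar(R, fill::zeros);
  for (int u = 0; u < U; ++u) {
    gru_forward(ew, Xsrc.slice(u), ecs[u]);
    hbar += ecs[u].H.col(Xsrc.n_cols - 1);
  }
  hbar /= U;
  std::vector<vec> acts;
  vec z = mlp_forward(head, hbar, acts);
  vec theta = decW * z + decb;

  vec grad(par.n_elem, fill::zeros);
  vec dtheta(theta.n_elem, fill::zeros);
  double nll = 0.0;
  const int V = Etgt.n_slices;
  for (int v = 0; v < V; ++v) {
    ivec st(1), ac(1);
    st(0) = tgt_tsteps(v); ac(0) = tgt_actions(v);
    nll += solver_nll_grad_one(theta, I, Q, K, Etgt.slice(v), ac, st, 1.0 / V,
                               dtheta, want_grad);
  }
  if (want_grad) {
    mat gdecW(grad.memptr() + nenc, Nts, M, false);
    vec gdecb(grad.memptr() + nenc + Nts * M, Nts, false);
    gdecW += dtheta * z.t();
    gdecb += dtheta;
    vec dz = decW.t() * dtheta;
    vec dhbar = mlp_backward(head, acts, dz, grad, gru_npar(Ie, R));
    mat dHext(R, Xsrc.n_cols, fill::zeros);
    for (int u = 0; u < U; ++u) {
      dHext.col(Xsrc.n_cols - 1) = dhbar / U;
      gru_backward(ew, Xsrc.slice(u), ecs[u], dHext, grad, 0);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = nll,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("z") = z);
}

// ---- Q-learning replay ----------------------------------------------------
//
// Replays logged trials through the tabular Q model (softmax policy with
// inverse temperature q_it; one-step update with learning rate q_lr, discount
// q_dr, terminal bootstrap 0) and returns the 2 x L matrix of policy
// probabilities evaluated *before* each update.  `block_starts` are 0-based
// trial indices at which the table resets to q_init.

// [[Rcpp::export]]
arma::mat cpp_q_replay(const arma::vec& qpar, int n_states,
                       const arma::ivec& svec, const arma::ivec& nextvec,
                       const arma::ivec& avec, const arma::vec& rvec,
                       const arma::ivec& block_starts) {
  const double q_lr = qpar(0), q_dr = qpar(1), q_it = qpar(2), q_init = qpar(3);
  const int L = svec.n_elem;
  mat P(2, L);
  mat Q(2, n_states, fill::zeros);
  uword bi = 0;
  for (int t = 0; t < L; ++t) {
    if (bi < block_starts.n_elem && block_starts(bi) == t) {
      Q.fill(q_init);
      ++bi;
    }
    const int s = svec(t), a = avec(t);
    double v0 = q_it * Q(0, s), v1 = q_it * Q(1, s);
    double m = std::max(v0, v1);
    double e0 = std::exp(v0 - m), e1 = std::exp(v1 - m);
    P(0, t) = e0 / (e0 + e1);
    P(1, t) = e1 / (e0 + e1);
    double boot = (nextvec(t) >= 0) ? q_dr * Q.col(nextvec(t)).max() : 0.0;
    Q(a, s) = (1.0 - q_lr) * Q(a, s) + q_lr * (rvec(t) + boot);
  }
  return P;
}
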