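// Recurrent sequence classifiers over visit-structured code sequences.
//
// Two architectures share one parameter vector layout and one LSTM kernel:
//   * tlstm  — stacked LSTM whose input/forget/output gates use tanh (or
//              sigmoid) activation; final hidden state -> affine -> sigmoid.
//   * retain — two single-layer LSTMs run over the REVERSED visit order
//              produce visit-level attention scores (softmax alpha) and
//              variable-level gates (tanh beta); the context vector
//              sum_j alpha_j * (beta_j o v_j) feeds an affine + sigmoid head.
//
// Gradients are fully analytic and verified against finite differences in
// the test suite. Dropout consumes R's RNG stream so training runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct NNConfig {
  int arch;      // 0 = tlstm, 1 = retain
  int V, D, H, L;
  int gate;      // 0 = sigmoid, 1 = tanh
  double dropout;
  int agg;       // 0 = sum, 1 = mean
};

NNConfig parse_cfg(const List& cfg) {
  NNConfig c;
  std::string arch = as<std::string>(cfg["arch"]);
  c.arch = (arch == "retain") ? 1 : 0;
  c.V = as<int>(cfg["V"]);
  c.D = as<int>(cfg["D"]);
  c.H = as<int>(cfg["H"]);
  c.L = as<int>(cfg["L"]);
  std::string gate = as<std::string>(cfg["gate"]);
  c.gate = (gate == "sigmoid") ? 0 : 1;
  c.dropout = cfg.containsElementNamed("dropout") ? as<double>(cfg["dropout"]) : 0.0;
  std::string agg = cfg.containsElementNamed("agg") ? as<std::string>(cfg["agg"]) : "sum";
  c.agg = (agg == "mean") ? 1 : 0;
  if (c.V < 1 || c.D < 1 || c.H < 1 || c.L < 1) stop("invalid network dimensions");
  return c;
}

// Parameter block sizes. One LSTM layer with input dim Din:
//   W (4H x Din), U (4H x H), b (4H).
long lstm_count(int H, int Din) { return 4L * H * Din + 4L * H * H + 4L * H; }

long par_count(const NNConfig& c) {
  long n = (long)c.V * c.D;  // embedding
  if (c.arch == 0) {
    for (int l = 0; l < c.L; ++l) n += lstm_count(c.H, l == 0 ? c.D : c.H);
    n += c.H + 1;  // head
  } else {
    n += 2 * lstm_count(c.H, c.D);        // alpha + beta RNNs
    n += c.H + 1;                         // w_a, b_a
    n += (long)c.D * c.H + c.D;           // W_b, b_b
    n += c.D + 1;                         // head
  }
  return n;
}

inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

inline void act_gate(vec& x, int gate) {
  if (gate == 0) x.transform([](double v) { return sigm(v); });
  else x = arma::tanh(x);
}
// derivative of gate activation expressed through the activated value
inline vec actd_gate(const vec& a, int gate) {
  if (gate == 0) return a % (1.0 - a);
  return 1.0 - arma::square(a);
}

// Cache for one LSTM layer forward pass over T steps.
struct LSTMCache {
  mat I, F, G, O, C, Hout, Xin;
};

// Forward one layer. X: Din x T. Returns hidden states H x T in cache.Hout.
void lstm_forward(const double* W, const double* U, const double* b,
                  const mat& X, int H, int gate, LSTMCache& cc) {
  const int Din = X.n_rows, T = X.n_cols;
  mat Wm(const_cast<double*>(W), 4 * H, Din, false, true);
  mat Um(const_cast<double*>(U), 4 * H, H, false, true);
  vec bm(const_cast<double*>(b), 4 * H, false, true);
  mat ZX = Wm * X;
  ZX.each_col() += bm;
  cc.I.set_size(H, T); cc.F.set_size(H, T); cc.G.set_size(H, T);
  cc.O.set_size(H, T); cc.C.set_size(H, T); cc.Hout.set_size(H, T);
  cc.Xin = X;
  vec h(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec z = ZX.col(t) + Um * h;
    vec i = z.subvec(0, H - 1), f = z.subvec(H, 2 * H - 1),
        g = z.subvec(2 * H, 3 * H - 1), o = z.subvec(3 * H, 4 * H - 1);
    act_gate(i, gate); act_gate(f, gate); act_gate(o, gate);
    g = arma::tanh(g);
    vec cnew = f % cprev + i % g;
    h = o % arma::tanh(cnew);
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = cnew; cc.Hout.col(t) = h;
    cprev = cnew;
  }
}

// Backward one layer. dH: H x T gradient w.r.t. hidden outputs.
// Accumulates into dW,dU,db (same layout as forward); returns dX (Din x T).
mat lstm_backward(const double* W, const double* U,
                  double* dW, double* dU, double* db,
                  const LSTMCache& cc, const mat& dH, int H, int gate) {
  const int Din = cc.Xin.n_rows, T = cc.Xin.n_cols;
  mat Wm(const_cast<double*>(W), 4 * H, Din, false, true);
  mat Um(const_cast<double*>(U), 4 * H, H, false, true);
  mat dWm(dW, 4 * H, Din, false, true);
  mat dUm(dU, 4 * H, H, false, true);
  vec dbm(db, 4 * H, false, true);
  mat dX(Din, T, arma::fill::zeros);
  vec dh_rec(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec i = cc.I.col(t), f = cc.F.col(t), g = cc.G.col(t), o = cc.O.col(t);
    vec tc = arma::tanh(cc.C.col(t));
    vec dh = dH.col(t) + dh_rec;
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - arma::square(tc));
    vec cprev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(H, arma::fill::zeros);
    vec di = dc % g, df = dc % cprev, dg = dc % i;
    vec dcnext = dc % f;
    vec dz(4 * H);
    dz.subvec(0, H - 1)         = di % actd_gate(i, gate);
    dz.subvec(H, 2 * H - 1)     = df % actd_gate(f, gate);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - arma::square(g));
    dz.subvec(3 * H, 4 * H - 1) = do_ % actd_gate(o, gate);
    vec hprev = (t > 0) ? vec(cc.Hout.col(t - 1)) : vec(H, arma::fill::zeros);
    dWm += dz * cc.Xin.col(t).t();
    dUm += dz * hprev.t();
    dbm += dz;
    dX.col(t) = Wm.t() * dz;
    dh_rec = Um.t() * dz;
    dc = dcnext;
  }
  return dX;
}

// Embed one sample's visits: X (D x T), column t = aggregated token embeddings.
mat embed_sample(const double* E, const NNConfig& c, const List& visits) {
  int T = visits.size();
  mat Em(const_cast<double*>(E), c.D, c.V, false, true);
  if (T == 0) return mat(c.D, 1, arma::fill::zeros);
  mat X(c.D, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    IntegerVector ids = visits[t];
    for (int k = 0; k < ids.size(); ++k) {
      int id = ids[k] - 1;
      if (id < 0 || id >= c.V) stop("token id out of vocabulary range");
      X.col(t) += Em.col(id);
    }
    if (c.agg == 1 && ids.size() > 1) X.col(t) /= (double)ids.size();
  }
  return X;
}

void scatter_dE(double* dE, const NNConfig& c, const List& visits, const mat& dX) {
  mat dEm(dE, c.D, c.V, false, true);
  int T = visits.size();
  if (T == 0) return;
  for (int t = 0; t < T; ++t) {
    IntegerVector ids = visits[t];
    double w = (c.agg == 1 && ids.size() > 1) ? 1.0 / ids.size() : 1.0;
    for (int k = 0; k < ids.size(); ++k) dEm.col(ids[k] - 1) += w * dX.col(t);
  }
}

mat dropout_mask(int r, int cnum, double p) {
  mat M(r, cnum);
  for (uword j = 0; j < M.n_elem; ++j)
    M(j) = (R::unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return M;
}

// ---------------- TLSTM ----------------

struct TlstmOffsets {
  long E; std::vector<long> W, U, b; long w, b0;
};

TlstmOffsets tlstm_offsets(const NNConfig& c) {
  TlstmOffsets o; o.E = 0;
  long pos = (long)c.V * c.D;
  for (int l = 0; l < c.L; ++l) {
    int Din = (l == 0) ? c.D : c.H;
    o.W.push_back(pos); pos += 4L * c.H * Din;
    o.U.push_back(pos); pos += 4L * c.H * c.H;
    o.b.push_back(pos); pos += 4L * c.H;
  }
  o.w = pos; pos += c.H;
  o.b0 = pos;
  return o;
}

// Forward a single sample from a precomputed input matrix X (D x T).
// If grad != nullptr, computes dlogit = (sigmoid(logit) - y) * wgt from this
// same forward pass (so dropout masks are consistent) and runs backward,
// accumulating into grad; *dX0 receives the gradient w.r.t. X if non-null.
double tlstm_logit(const double* par, const NNConfig& c, const mat& X,
                   bool training, double* grad, double y, double wgt, mat* dX0) {
  TlstmOffsets off = tlstm_offsets(c);
  const int T = X.n_cols;
  std::vector<LSTMCache> caches(c.L);
  std::vector<mat> masks;
  mat cur = X;
  for (int l = 0; l < c.L; ++l) {
    lstm_forward(par + off.W[l], par + off.U[l], par + off.b[l], cur, c.H, c.gate, caches[l]);
    cur = caches[l].Hout;
    if (l < c.L - 1) {
      if (training && c.dropout > 0) {
        mat M = dropout_mask(c.H, T, c.dropout);
        cur = cur % M;
        masks.push_back(M);
      } else if (grad) {
        masks.push_back(mat(c.H, T, arma::fill::ones));
      }
    }
  }
  vec hT = cur.col(T - 1);
  vec w(const_cast<double*>(par) + off.w, c.H, false, true);
  double logit = arma::dot(w, hT) + par[off.b0];
  if (grad) {
    double dlogit = (sigm(logit) - y) * wgt;
    vec dw(grad + off.w, c.H, false, true);
    dw += dlogit * hT;
    grad[off.b0] += dlogit;
    mat dH(c.H, T, arma::fill::zeros);
    dH.col(T - 1) = dlogit * w;
    for (int l = c.L - 1; l >= 0; --l) {
      mat dX = lstm_backward(par + off.W[l], par + off.U[l],
                             grad + off.W[l], grad + off.U[l], grad + off.b[l],
                             caches[l], dH, c.H, c.gate);
      if (l > 0) dH = dX % masks[l - 1];
      else if (dX0) *dX0 = dX;
    }
  }
  return logit;
}

// ---------------- RETAIN ----------------

struct RetainOffsets {
  long E, aW, aU, ab, wa, ba, bW, bU, bb, Wb, bb2, w, b0;
};

RetainOffsets retain_offsets(const NNConfig& c) {
  RetainOffsets o; o.E = 0;
  long pos = (long)c.V * c.D;
  o.aW = pos; pos += 4L * c.H * c.D;
  o.aU = pos; pos += 4L * c.H * c.H;
  o.ab = pos; pos += 4L * c.H;
  o.wa = pos; pos += c.H;
  o.ba = pos; pos += 1;
  o.bW = pos; pos += 4L * c.H * c.D;
  o.bU = pos; pos += 4L * c.H * c.H;
  o.bb = pos; pos += 4L * c.H;
  o.Wb = pos; pos += (long)c.D * c.H;
  o.bb2 = pos; pos += c.D;
  o.w = pos; pos += c.D;
  o.b0 = pos;
  return o;
}

double retain_logit(const double* par, const NNConfig& c, const mat& X,
                    bool training, double* grad, double y, double wgt, mat* dX0,
                    vec* alpha_out) {
  RetainOffsets off = retain_offsets(c);
  const int T = X.n_cols;
  mat Xr = arma::fliplr(X);  // most recent visit first
  LSTMCache ca, cb;
  lstm_forward(par + off.aW, par + off.aU, par + off.ab, Xr, c.H, c.gate, ca);
  lstm_forward(par + off.bW, par + off.bU, par + off.bb, Xr, c.H, c.gate, cb);
  vec wa(const_cast<double*>(par) + off.wa, c.H, false, true);
  mat Wb(const_cast<double*>(par) + off.Wb, c.D, c.H, false, true);
  vec bb2(const_cast<double*>(par) + off.bb2, c.D, false, true);
  vec w(const_cast<double*>(par) + off.w, c.D, false, true);

  vec e = ca.Hout.t() * wa + par[off.ba];
  vec alpha = arma::exp(e - e.max());
  alpha /= arma::accu(alpha);
  mat Beta = arma::tanh(Wb * cb.Hout + arma::repmat(bb2, 1, T));
  vec ctx(c.D, arma::fill::zeros);
  for (int j = 0; j < T; ++j) ctx += alpha(j) * (Beta.col(j) % Xr.col(j));
  vec cmask;
  if (training && c.dropout > 0) {
    cmask = dropout_mask(c.D, 1, c.dropout).col(0);
    ctx = ctx % cmask;
  }
  double logit = arma::dot(w, ctx) + par[off.b0];
  if (alpha_out) *alpha_out = arma::reverse(alpha);  // back to chronological order

  if (grad) {
    double dlogit = (sigm(logit) - y) * wgt;
    vec dw(grad + off.w, c.D, false, true);
    dw += dlogit * ctx;
    grad[off.b0] += dlogit;
    vec dctx = dlogit * w;
    if (cmask.n_elem) dctx = dctx % cmask;
    vec dalpha(T);
    mat dBeta(c.D, T), dXr(c.D, T, arma::fill::zeros);
    for (int j = 0; j < T; ++j) {
      dalpha(j) = arma::dot(dctx, Beta.col(j) % Xr.col(j));
      dBeta.col(j) = alpha(j) * (dctx % Xr.col(j));
      dXr.col(j) = alpha(j) * (dctx % Beta.col(j));
    }
    vec de = alpha % (dalpha - arma::dot(alpha, dalpha));
    // attention-score head
    vec dwa(grad + off.wa, c.H, false, true);
    dwa += ca.Hout * de;
    grad[off.ba] += arma::accu(de);
    mat dHa = wa * de.t();
    // beta head
    mat dZb = dBeta % (1.0 - arma::square(Beta));
    mat dWb(grad + off.Wb, c.D, c.H, false, true);
    dWb += dZb * cb.Hout.t();
    vec dbb2(grad + off.bb2, c.D, false, true);
    dbb2 += arma::sum(dZb, 1);
    mat dHb = Wb.t() * dZb;
    // recurrent paths
    dXr += lstm_backward(par + off.aW, par + off.aU,
                         grad + off.aW, grad + off.aU, grad + off.ab,
                         ca, dHa, c.H, c.gate);
    dXr += lstm_backward(par + off.bW, par + off.bU,
                         grad + off.bW, grad + off.bU, grad + off.bb,
                         cb, dHb, c.H, c.gate);
    if (dX0) *dX0 = arma::fliplr(dXr);
  }
  return logit;
}

double sample_logit(const double* par, const NNConfig& c, const mat& X,
                    bool training, double* grad, double y, double wgt, mat* dX0,
                    vec* alpha_out = nullptr) {
  if (c.arch == 0) return tlstm_logit(par, c, X, training, grad, y, wgt, dX0);
  return retain_logit(par, c, X, training, grad, y, wgt, dX0, alpha_out);
}

}  // namespace

// [[Rcpp::export]]
double cpp_par_count(List cfg) {
  return (double)par_count(parse_cfg(cfg));
}

// 1-based indices of the input/forget/output gate bias entries, used to
// initialise gates open (a closed tanh gate at zero bias kills both the
// forward signal and the gradient).
// [[Rcpp::export]]
IntegerVector cpp_gate_bias_idx(List cfg) {
  NNConfig c = parse_cfg(cfg);
  std::vector<long> idx;
  // bias layout within one layer is [i; f; g; o] * H — pick i, f and o
  auto add_lstm = [&](long b_off) {
    for (int j = 0; j < c.H; ++j) idx.push_back(b_off + j);            // i
    for (int j = c.H; j < 2 * c.H; ++j) idx.push_back(b_off + j);      // f
    for (int j = 3 * c.H; j < 4 * c.H; ++j) idx.push_back(b_off + j);  // o
  };
  if (c.arch == 0) {
    TlstmOffsets off = tlstm_offsets(c);
    for (int l = 0; l < c.L; ++l) add_lstm(off.b[l]);
  } else {
    RetainOffsets off = retain_offsets(c);
    add_lstm(off.ab);
    add_lstm(off.bb);
  }
  IntegerVector out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = (int)(idx[i] + 1);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nn_forward(NumericVector par, List cfg, List samples) {
  NNConfig c = parse_cfg(cfg);
  if ((long)par.size() != par_count(c)) stop("parameter vector length mismatch");
  int n = samples.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    mat X = embed_sample(par.begin(), c, samples[s]);
    out[s] = sigm(sample_logit(par.begin(), c, X, false, nullptr, 0.0, 0.0, nullptr));
  }
  return out;
}

// [[Rcpp::export]]
double cpp_nn_forward_x(NumericVector par, List cfg, NumericMatrix X) {
  NNConfig c = parse_cfg(cfg);
  if ((long)par.size() != par_count(c)) stop("parameter vector length mismatch");
  if ((int)X.nrow() != c.D) stop("input matrix row count must equal embedding dim");
  mat Xm(X.begin(), X.nrow(), X.ncol(), false, true);
  mat Xu = (X.ncol() == 0) ? mat(c.D, 1, arma::fill::zeros) : mat(Xm);
  return sigm(sample_logit(par.begin(), c, Xu, false, nullptr, 0.0, 0.0, nullptr));
}

// [[Rcpp::export]]
List cpp_nn_loss_grad(NumericVector par, List cfg, List samples,
                      NumericVector labels, bool training) {
  NNConfig c = parse_cfg(cfg);
  long np = par_count(c);
  if ((long)par.size() != np) stop("parameter vector length mismatch");
  int n = samples.size();
  if (labels.size() != n) stop("labels length must match samples");
  NumericVector grad(np);
  NumericVector probs(n);
  double loss = 0.0;
  const double invn = 1.0 / std::max(1, n);
  for (int s = 0; s < n; ++s) {
    List visits = samples[s];
    mat X = embed_sample(par.begin(), c, visits);
    mat dX;
    double y = labels[s];
    double logit = sample_logit(par.begin(), c, X, training, grad.begin(), y, invn, &dX);
    double p = sigm(logit);
    probs[s] = p;
    double pc = std::min(1.0 - 1e-12, std::max(1e-12, p));
    loss += -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc)) * invn;
    scatter_dE(grad.begin(), c, visits, dX);
  }
  return List::create(_["loss"] = loss, _["grad"] = grad, _["probs"] = probs);
}

// [[Rcpp::export]]
List cpp_retain_attention(NumericVector par, List cfg, List sample) {
  NNConfig c = parse_cfg(cfg);
  if (c.arch != 1) stop("attention weights are defined for the retain architecture only");
  if ((long)par.size() != par_count(c)) stop("parameter vector length mismatch");
  mat X = embed_sample(par.begin(), c, sample);
  vec alpha;
  double logit = retain_logit(par.begin(), c, X, false, nullptr, 0.0, 0.0, nullptr, &alpha);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["prob"] = sigm(logit));
}
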