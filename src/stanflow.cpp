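// Batched forward/backward core for the spatial-temporal attention encoder and
// the conditional normalizing flow over interspike intervals.
//
// Parameters travel as ONE flat numeric vector; the layout is fixed and mirrored
// by stanflowParamLayout() on the R side:
//   LSTM1 Wx(4H x N), Wh(4H x H), b(4H)
//   We(d x Dlt), be(d)
//   Wa(Dlt x H), ba(Dlt)
//   wb(H + d + Q), bb(1)
//   LSTM2 Wx(4H x N), Wh(4H x H), b(4H)
//   K flow layers, each: Ws1(M x X), bs1(M), ws2(M), bs2(1),
//                        Wt1(M x X), bt1(M), Wt2(3 x M), bt2(3)
// with X = H + Q + 1.  Gate rows are ordered [input; forget; cell; output].
//
// Each flow layer maps y -> u where v = exp(s)*y + t, u = v + a*tanh(v + c),
// with s = 5 tanh(shat/5) and a = a_max tanh(ahat); |a| <= a_max < 1 keeps
// du/dv >= 1 - a_max > 0, so every layer is strictly monotone and the scalar
// Jacobian (and hence the likelihood) is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Dims {
  int N, Dlt, H, d, Q, K, M, X;
};

Dims read_dims(const Rcpp::IntegerVector& dv) {
  Dims dm;
  dm.N = dv[0]; dm.Dlt = dv[1]; dm.H = dv[2]; dm.d = dv[3];
  dm.Q = dv[4]; dm.K = dv[5]; dm.M = dv[6];
  dm.X = dm.H + dm.Q + 1;
  return dm;
}

struct FlowLayer {
  mat Ws1; vec bs1; vec ws2; double bs2;
  mat Wt1; vec bt1; mat Wt2; vec bt2;
};

struct Params {
  mat Wx1, Wh1; vec b1;
  mat We; vec be;
  mat Wa; vec ba;
  vec wb; double bb;
  mat Wx2, Wh2; vec b2;
  std::vector<FlowLayer> fl;
};

size_t param_length(const Dims& dm) {
  size_t n = 0;
  size_t H4 = 4 * (size_t)dm.H;
  n += H4 * dm.N + H4 * dm.H + H4;                  // LSTM1
  n += (size_t)dm.d * dm.Dlt + dm.d;                // embedding
  n += (size_t)dm.Dlt * dm.H + dm.Dlt;              // temporal head
  n += dm.H + dm.d + dm.Q + 1;                      // spatial head
  n += H4 * dm.N + H4 * dm.H + H4;                  // LSTM2
  n += (size_t)dm.K * (2 * ((size_t)dm.M * dm.X + dm.M) + dm.M + 1 + 3 * (size_t)dm.M + 3);
  return n;
}

Params unpack(const double* p, const Dims& dm) {
  Params P;
  size_t o = 0;
  auto gm = [&](mat& m, int r, int c) { m = mat(p + o, r, c); o += (size_t)r * c; };
  auto gv = [&](vec& v, int n) { v = vec(p + o, n); o += n; };
  int H4 = 4 * dm.H;
  gm(P.Wx1, H4, dm.N); gm(P.Wh1, H4, dm.H); gv(P.b1, H4);
  gm(P.We, dm.d, dm.Dlt); gv(P.be, dm.d);
  gm(P.Wa, dm.Dlt, dm.H); gv(P.ba, dm.Dlt);
  gv(P.wb, dm.H + dm.d + dm.Q); P.bb = p[o++];
  gm(P.Wx2, H4, dm.N); gm(P.Wh2, H4, dm.H); gv(P.b2, H4);
  P.fl.resize(dm.K);
  for (int k = 0; k < dm.K; ++k) {
    FlowLayer& L = P.fl[k];
    gm(L.Ws1, dm.M, dm.X); gv(L.bs1, dm.M); gv(L.ws2, dm.M); L.bs2 = p[o++];
    gm(L.Wt1, dm.M, dm.X); gv(L.bt1, dm.M); gm(L.Wt2, 3, dm.M); gv(L.bt2, 3);
  }
  return P;
}

Params zeros_like(const Dims& dm) {
  Params P;
  int H4 = 4 * dm.H;
  P.Wx1.zeros(H4, dm.N); P.Wh1.zeros(H4, dm.H); P.b1.zeros(H4);
  P.We.zeros(dm.d, dm.Dlt); P.be.zeros(dm.d);
  P.Wa.zeros(dm.Dlt, dm.H); P.ba.zeros(dm.Dlt);
  P.wb.zeros(dm.H + dm.d + dm.Q); P.bb = 0.0;
  P.Wx2.zeros(H4, dm.N); P.Wh2.zeros(H4, dm.H); P.b2.zeros(H4);
  P.fl.resize(dm.K);
  for (int k = 0; k < dm.K; ++k) {
    FlowLayer& L = P.fl[k];
    L.Ws1.zeros(dm.M, dm.X); L.bs1.zeros(dm.M); L.ws2.zeros(dm.M); L.bs2 = 0.0;
    L.Wt1.zeros(dm.M, dm.X); L.bt1.zeros(dm.M); L.Wt2.zeros(3, dm.M); L.bt2.zeros(3);
  }
  return P;
}

void pack(const Params& P, const Dims& dm, double* out, double scale) {
  size_t o = 0;
  auto pm = [&](const mat& m) { for (uword i = 0; i < m.n_elem; ++i) out[o++] = m[i] * scale; };
  auto pv = [&](const vec& v) { for (uword i = 0; i < v.n_elem; ++i) out[o++] = v[i] * scale; };
  pm(P.Wx1); pm(P.Wh1); pv(P.b1);
  pm(P.We); pv(P.be);
  pm(P.Wa); pv(P.ba);
  pv(P.wb); out[o++] = P.bb * scale;
  pm(P.Wx2); pm(P.Wh2); pv(P.b2);
  for (int k = 0; k < dm.K; ++k) {
    const FlowLayer& L = P.fl[k];
    pm(L.Ws1); pv(L.bs1); pv(L.ws2); out[o++] = L.bs2 * scale;
    pm(L.Wt1); pv(L.bt1); pm(L.Wt2); pv(L.bt2);
  }
}

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LSTMTrace {
  std::vector<mat> i, f, g, o, c, tc, h; // per step, each H x B
  const std::vector<mat>* x = nullptr;   // inputs, n_in x B per step
};

void lstm_forward(const mat& Wx, const mat& Wh, const vec& b,
                  const std::vector<mat>& xs, int H, LSTMTrace& tr) {
  int T = xs.size();
  int B = xs[0].n_cols;
  mat h = zeros<mat>(H, B), c = zeros<mat>(H, B);
  tr.x = &xs;
  for (int t = 0; t < T; ++t) {
    mat z = Wx * xs[t] + Wh * h;
    z.each_col() += b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    tr.i.push_back(gi); tr.f.push_back(gf); tr.g.push_back(gg); tr.o.push_back(go);
    tr.c.push_back(c); tr.tc.push_back(tc); tr.h.push_back(h);
  }
}

// BPTT; dh_last is the gradient arriving at the final hidden state (the only tap).
void lstm_backward(const mat& Wx, const mat& Wh, const LSTMTrace& tr,
                   const mat& dh_last, int H,
                   mat& dWx, mat& dWh, vec& db,
                   std::vector<mat>* dx_out) {
  int T = tr.h.size();
  int B = dh_last.n_cols;
  mat dh = dh_last, dc = zeros<mat>(H, B);
  for (int t = T - 1; t >= 0; --t) {
    const mat& gi = tr.i[t]; const mat& gf = tr.f[t];
    const mat& gg = tr.g[t]; const mat& go = tr.o[t];
    const mat& tc = tr.tc[t];
    mat dgo = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat cprev = (t > 0) ? tr.c[t - 1] : zeros<mat>(H, B);
    mat dgi = dc % gg;
    mat dgf = dc % cprev;
    mat dgg = dc % gi;
    mat dz(4 * H, B);
    dz.rows(0, H - 1)         = dgi % gi % (1.0 - gi);
    dz.rows(H, 2 * H - 1)     = dgf % gf % (1.0 - gf);
    dz.rows(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    dWx += dz * (*tr.x)[t].t();
    if (t > 0) dWh += dz * tr.h[t - 1].t();
    db += sum(dz, 1);
    if (dx_out) (*dx_out)[t] = Wx.t() * dz;
    dh = Wh.t() * dz;
    dc = dc % gf;
  }
}

// Sparsemax of a column vector: Euclidean projection onto the probability simplex.
vec sparsemax_vec(const vec& z) {
  vec zs = sort(z, "descend");
  int n = z.n_elem;
  double cum = 0.0, tau = 0.0;
  for (int j = 0; j < n; ++j) {
    cum += zs[j];
    if (1.0 + (j + 1) * zs[j] > cum) tau = (cum - 1.0) / (j + 1);
    else break;
  }
  vec p = z - tau;
  p.elem(find(p < 0)).zeros();
  return p;
}

struct EncodeTrace {
  LSTMTrace lstm1, lstm2;
  mat hstar;            // H x B
  mat u_alpha, alpha;   // Dlt x B
  cube E;               // d x N x B embeddings (e_m columns)
  mat beta_pre, beta;   // N x B
  mat ctx;              // H x B (h')
  std::vector<mat> Xs;  // window columns, N x B per step
  std::vector<mat> Xs2; // reweighted columns
  cube S;               // (possibly binarized) windows, N x Dlt x B
};

void encode_forward(const Params& P, const Dims& dm, const cube& S_in,
                    const mat& qmat, bool binarize, EncodeTrace& tr) {
  int B = S_in.n_slices;
  tr.S = S_in;
  if (binarize) tr.S.transform([](double v) { return v > 0 ? 1.0 : 0.0; });
  tr.Xs.resize(dm.Dlt);
  for (int t = 0; t < dm.Dlt; ++t) {
    mat xt(dm.N, B);
    for (int b = 0; b < B; ++b) xt.col(b) = tr.S.slice(b).col(t);
    tr.Xs[t] = xt;
  }
  lstm_forward(P.Wx1, P.Wh1, P.b1, tr.Xs, dm.H, tr.lstm1);
  tr.hstar = tr.lstm1.h.back();

  mat v = P.Wa * tr.hstar;
  v.each_col() += P.ba;
  tr.u_alpha = tanh(v);
  mat ex = exp(tr.u_alpha.each_row() - max(tr.u_alpha, 0));
  tr.alpha = ex.each_row() / sum(ex, 0);

  tr.E.set_size(dm.d, dm.N, B);
  tr.beta_pre.set_size(dm.N, B);
  tr.beta.set_size(dm.N, B);
  vec wb_h = P.wb.subvec(0, dm.H - 1);
  vec wb_e = P.wb.subvec(dm.H, dm.H + dm.d - 1);
  vec wb_q = P.wb.subvec(dm.H + dm.d, dm.H + dm.d + dm.Q - 1);
  for (int b = 0; b < B; ++b) {
    mat Et = P.We * tr.S.slice(b).t();   // d x N
    Et.each_col() += P.be;
    tr.E.slice(b) = Et;
    double base = dot(wb_h, tr.hstar.col(b)) + dot(wb_q, qmat.col(b)) + P.bb;
    vec r = Et.t() * wb_e + base;
    vec pre = tanh(r);
    tr.beta_pre.col(b) = pre;
    tr.beta.col(b) = sparsemax_vec(pre);
  }

  double scale = (double)dm.N * dm.Dlt;  // mean normalization of beta alpha^T
  tr.Xs2.resize(dm.Dlt);
  for (int t = 0; t < dm.Dlt; ++t) {
    mat w = tr.beta.each_row() % tr.alpha.row(t);  // N x B
    tr.Xs2[t] = scale * (w % tr.Xs[t]);
  }
  lstm_forward(P.Wx2, P.Wh2, P.b2, tr.Xs2, dm.H, tr.lstm2);
  tr.ctx = tr.lstm2.h.back();
}

struct FlowTrace {
  std::vector<mat> hs, ht;                             // M x B per layer
  std::vector<rowvec> shat, s, ahat, a, tcoef, ccoef;  // 1 x B per layer
  std::vector<rowvec> y;                               // y_0 .. y_K
  std::vector<rowvec> th, D, v;
  rowvec logdet;
};

void flow_forward(const Params& P, const Dims& dm, const mat& Xc,
                  const rowvec& y0, FlowTrace& ft, double a_max) {
  int B = Xc.n_cols;
  ft.y.push_back(y0);
  ft.logdet = zeros<rowvec>(B);
  for (int k = 0; k < dm.K; ++k) {
    const FlowLayer& L = P.fl[k];
    mat hs = tanh(L.Ws1 * Xc + repmat(L.bs1, 1, B));
    rowvec shat = L.ws2.t() * hs + L.bs2;
    rowvec s = 5.0 * tanh(shat / 5.0);
    mat ht = tanh(L.Wt1 * Xc + repmat(L.bt1, 1, B));
    mat out = L.Wt2 * ht;
    out.each_col() += L.bt2;
    rowvec tcoef = out.row(0);
    rowvec ahat = out.row(1);
    rowvec ccoef = out.row(2);
    rowvec a = a_max * tanh(ahat);
    rowvec v = exp(s) % ft.y.back() + tcoef;
    rowvec th = tanh(v + ccoef);
    rowvec sech2 = 1.0 - th % th;
    rowvec D = 1.0 + a % sech2;
    ft.logdet += s + log(D);
    ft.hs.push_back(hs); ft.ht.push_back(ht);
    ft.shat.push_back(shat); ft.s.push_back(s);
    ft.ahat.push_back(ahat); ft.a.push_back(a);
    ft.tcoef.push_back(tcoef); ft.ccoef.push_back(ccoef);
    ft.v.push_back(v); ft.th.push_back(th); ft.D.push_back(D);
    ft.y.push_back(v + a % th);
  }
}

} // namespace

// [[Rcpp::export]]
double stanflow_param_length(Rcpp::IntegerVector dims) {
  return (double)param_length(read_dims(dims));
}

// Mean NLL over the batch and (optionally) its gradient, averaged over examples.
// windows: N x Dlt x B cube; qmat: Q x B; trel, tau: length B.
// [[Rcpp::export]]
Rcpp::List stanflow_nll_grad(Rcpp::NumericVector pvec, Rcpp::IntegerVector dims,
                             arma::cube windows, arma::mat qmat,
                             arma::vec trel, arma::vec tau,
                             double tau_ref, double a_max,
                             bool binarize, bool want_grad) {
  Dims dm = read_dims(dims);
  if ((size_t)pvec.size() != param_length(dm))
    Rcpp::stop("parameter vector has wrong length");
  Params P = unpack(pvec.begin(), dm);
  int B = windows.n_slices;

  EncodeTrace tr;
  encode_forward(P, dm, windows, qmat, binarize, tr);

  mat Xc(dm.X, B);
  Xc.rows(0, dm.H - 1) = tr.ctx;
  Xc.rows(dm.H, dm.H + dm.Q - 1) = qmat;
  Xc.row(dm.X - 1) = trel.t();

  rowvec y0 = log(tau.t() / tau_ref);
  FlowTrace ft;
  flow_forward(P, dm, Xc, y0, ft, a_max);
  rowvec z = ft.y.back();
  rowvec nll = 0.5 * (z % z) + 0.5 * std::log(2.0 * M_PI) - ft.logdet + log(tau.t());
  double mean_nll = mean(nll);

  Rcpp::List res = Rcpp::List::create(
    Rcpp::Named("nll") = mean_nll,
    Rcpp::Named("nll_each") = Rcpp::NumericVector(nll.begin(), nll.end()),
    Rcpp::Named("z") = Rcpp::NumericVector(z.begin(), z.end()));
  if (!want_grad) return res;

  Params G = zeros_like(dm);

  // ----- flow backward (objective contains -logdet, so dL/d(ld_k) = -1) -----
  mat dXc = zeros<mat>(dm.X, B);
  rowvec dy = z;
  for (int k = dm.K - 1; k >= 0; --k) {
    const FlowLayer& L = P.fl[k];
    FlowLayer& Lg = G.fl[k];
    const rowvec& a = ft.a[k]; const rowvec& th = ft.th[k];
    const rowvec& D = ft.D[k]; const rowvec& s = ft.s[k];
    rowvec sech2 = 1.0 - th % th;
    rowvec dv = dy % D + (2.0 * (a % th % sech2)) / D;
    rowvec da = dy % th - sech2 / D;
    rowvec dcc = dy % (a % sech2) + (2.0 * (a % th % sech2)) / D;
    rowvec es = exp(s);
    rowvec dyprev = dv % es;
    rowvec dt = dv;
    rowvec ds = dv % es % ft.y[k] - 1.0;
    rowvec dshat = ds % (1.0 - square(tanh(ft.shat[k] / 5.0)));
    rowvec dahat = da % (a_max * (1.0 - square(tanh(ft.ahat[k]))));
    Lg.ws2 += ft.hs[k] * dshat.t();
    Lg.bs2 += accu(dshat);
    mat dhs = (L.ws2 * dshat) % (1.0 - square(ft.hs[k]));
    Lg.Ws1 += dhs * Xc.t();
    Lg.bs1 += sum(dhs, 1);
    dXc += L.Ws1.t() * dhs;
    mat dout(3, B);
    dout.row(0) = dt; dout.row(1) = dahat; dout.row(2) = dcc;
    Lg.Wt2 += dout * ft.ht[k].t();
    Lg.bt2 += sum(dout, 1);
    mat dht = (L.Wt2.t() * dout) % (1.0 - square(ft.ht[k]));
    Lg.Wt1 += dht * Xc.t();
    Lg.bt1 += sum(dht, 1);
    dXc += L.Wt1.t() * dht;
    dy = dyprev;
  }

  // ----- encoder backward -----
  mat dctx = dXc.rows(0, dm.H - 1);
  std::vector<mat> dXs2(dm.Dlt);
  lstm_backward(P.Wx2, P.Wh2, tr.lstm2, dctx, dm.H, G.Wx2, G.Wh2, G.b2, &dXs2);

  double scale = (double)dm.N * dm.Dlt;
  mat dbeta = zeros<mat>(dm.N, B);
  mat dalpha = zeros<mat>(dm.Dlt, B);
  for (int t = 0; t < dm.Dlt; ++t) {
    mat Gw = (dXs2[t] % tr.Xs[t]) * scale;          // N x B
    dbeta += Gw.each_row() % tr.alpha.row(t);
    dalpha.row(t) = sum(Gw % tr.beta, 0);
  }

  mat du = tr.alpha % (dalpha.each_row() - sum(tr.alpha % dalpha, 0));
  mat dv_a = du % (1.0 - square(tr.u_alpha));
  G.Wa += dv_a * tr.hstar.t();
  G.ba += sum(dv_a, 1);
  mat dhstar = P.Wa.t() * dv_a;

  vec wb_h = P.wb.subvec(0, dm.H - 1);
  vec wb_e = P.wb.subvec(dm.H, dm.H + dm.d - 1);
  for (int b = 0; b < B; ++b) {
    vec bet = tr.beta.col(b);
    uvec supp = find(bet > 0);
    vec db = dbeta.col(b);
    vec dpre = zeros<vec>(dm.N);
    if (supp.n_elem > 0) {
      double m = mean(db.elem(supp));
      dpre.elem(supp) = db.elem(supp) - m;
    }
    vec pre = tr.beta_pre.col(b);
    vec dr = dpre % (1.0 - pre % pre);
    double drsum = accu(dr);
    G.wb.subvec(0, dm.H - 1) += drsum * tr.hstar.col(b);
    mat Et = tr.E.slice(b);                        // d x N
    G.wb.subvec(dm.H, dm.H + dm.d - 1) += Et * dr;
    G.wb.subvec(dm.H + dm.d, dm.H + dm.d + dm.Q - 1) += drsum * qmat.col(b);
    G.bb += drsum;
    dhstar.col(b) += drsum * wb_h;
    mat dE = wb_e * dr.t();                        // d x N
    G.We += dE * tr.S.slice(b);                    // (d x N)(N x Dlt)
    G.be += sum(dE, 1);
  }

  lstm_backward(P.Wx1, P.Wh1, tr.lstm1, dhstar, dm.H, G.Wx1, G.Wh1, G.b1, nullptr);

  Rcpp::NumericVector gvec((int)param_length(dm));
  pack(G, dm, gvec.begin(), 1.0 / B);
  res["grad"] = gvec;
  return res;
}

// Forward encode only: attention weights and the flow context per example.
// [[Rcpp::export]]
Rcpp::List stanflow_encode(Rcpp::NumericVector pvec, Rcpp::IntegerVector dims,
                           arma::cube windows, arma::mat qmat, bool binarize) {
  Dims dm = read_dims(dims);
  if ((size_t)pvec.size() != param_length(dm))
    Rcpp::stop("parameter vector has wrong length");
  Params P = unpack(pvec.begin(), dm);
  EncodeTrace tr;
  encode_forward(P, dm, windows, qmat, binarize, tr);
  return Rcpp::List::create(
    Rcpp::Named("context") = tr.ctx,
    Rcpp::Named("alpha") = tr.alpha,
    Rcpp::Named("beta") = tr.beta,
    Rcpp::Named("hstar") = tr.hstar);
}

// Flow coefficients s, t, a, c (each K x B) for given contexts x (X x B).
// [[Rcpp::export]]
Rcpp::List stanflow_flow_coeffs(Rcpp::NumericVector pvec, Rcpp::IntegerVector dims,
                                arma::mat Xc, double a_max) {
  Dims dm = read_dims(dims);
  if ((size_t)pvec.size() != param_length(dm))
    Rcpp::stop("parameter vector has wrong length");
  Params P = unpack(pvec.begin(), dm);
  int B = Xc.n_cols;
  mat S(dm.K, B), T(dm.K, B), A(dm.K, B), C(dm.K, B);
  for (int k = 0; k < dm.K; ++k) {
    const FlowLayer& L = P.fl[k];
    mat hs = tanh(L.Ws1 * Xc + repmat(L.bs1, 1, B));
    S.row(k) = 5.0 * tanh((L.ws2.t() * hs + L.bs2) / 5.0);
    mat ht = tanh(L.Wt1 * Xc + repmat(L.bt1, 1, B));
    mat out = L.Wt2 * ht;
    out.each_col() += L.bt2;
    T.row(k) = out.row(0);
    A.row(k) = a_max * tanh(out.row(1));
    C.row(k) = out.row(2);
  }
  return Rcpp::List::create(Rcpp::Named("s") = S, Rcpp::Named("t") = T,
                            Rcpp::Named("a") = A, Rcpp::Named("c") = C);
}
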