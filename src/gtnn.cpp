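// Fast path for GTNN training: one C++ call evaluates the full model on a
// stacked graph batch (both towers, condition embedding, output head) and,
// when requested, the exact gradient of the MSE loss with respect to the
// flattened parameter vector.  The parameter memory layout mirrors
// unlist(model$params) from the R side; the R implementation in
// R/gtnn_core.R is the reference and the two are checked for equality in the
// test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Dims {
  int in, h, e, p, L, heads, rdim, ncond;
};

// parameter shapes in flattened order (must match init_gtnn())
static std::vector<std::pair<int, int>> param_shapes(const Dims& d) {
  std::vector<std::pair<int, int>> s;
  s.push_back({d.in, d.e}); s.push_back({1, d.e});        // emb.W1,b1
  s.push_back({d.e, d.h}); s.push_back({1, d.h});         // emb.W2,b2
  s.push_back({d.ncond, d.e}); s.push_back({1, d.e});     // cond.W,b
  s.push_back({3 * d.e, d.p}); s.push_back({1, d.p});     // head.W1,b1
  s.push_back({d.p, d.p}); s.push_back({1, d.p});         // head.W2,b2
  s.push_back({d.p, 1}); s.push_back({1, 1});             // head.W3,b3
  for (int t = 0; t < 2; ++t) {
    for (int l = 0; l < d.L; ++l) {
      s.push_back({2 * d.h + d.rdim, 2 * d.h}); s.push_back({1, 2 * d.h});
      s.push_back({2 * d.h, d.h}); s.push_back({1, d.h});  // psi
      s.push_back({2 * d.h, 2 * d.h}); s.push_back({1, 2 * d.h});
      s.push_back({2 * d.h, d.h}); s.push_back({1, d.h});  // phi
    }
    s.push_back({d.L * d.h, 2 * d.h}); s.push_back({1, 2 * d.h});  // fin.W1,b1
    s.push_back({2 * d.h, d.h}); s.push_back({1, d.h});            // fin.W2,b2
    s.push_back({d.heads, d.h});                                    // pool.S
    s.push_back({d.h, d.h}); s.push_back({1, d.h});                 // Wq,bq
    s.push_back({d.h, d.h}); s.push_back({1, d.h});                 // Wk,bk
    s.push_back({d.h, d.h}); s.push_back({1, d.h});                 // Wv,bv
    s.push_back({d.heads * d.h, d.e}); s.push_back({1, d.e});       // Wo,bo
  }
  return s;
}

static void wrap_params(double* base,
                        const std::vector<std::pair<int, int>>& shapes,
                        std::vector<mat>& out) {
  size_t off = 0;
  out.clear();
  out.reserve(shapes.size());
  for (auto& sh : shapes) {
    out.emplace_back(base + off, sh.first, sh.second, false, true);
    off += (size_t)sh.first * sh.second;
  }
}

static inline mat relu_of(const mat& X) {
  mat A = X;
  A.elem(find(A < 0)).zeros();
  return A;
}

static inline void relu_bwd(mat& dZ, const mat& A) {
  dZ.elem(find(A <= 0)).zeros();
}

static inline mat lin_of(const mat& X, const mat& W, const mat& b) {
  mat Z = X * W;
  Z.each_row() += b.row(0);
  return Z;
}

// scatter-add rows of M into n groups given 0-based indices
static mat group_sum(const mat& M, const ivec& g, int n) {
  mat S(n, M.n_cols, fill::zeros);
  for (uword j = 0; j < M.n_cols; ++j) {
    const double* mc = M.colptr(j);
    double* sc = S.colptr(j);
    for (uword k = 0; k < M.n_rows; ++k) sc[g[k]] += mc[k];
  }
  return S;
}

struct TowerCache {
  mat A_emb, H0, Hcat, A1f, Ffin, K, V, Q, Attn, Pcat;
  umat scmask;
  std::vector<mat> Hs, Min, A1, U, A2;
};

// tower parameter index origin in the flattened layout
static int tower_base(const Dims& d, int t) {
  return 12 + t * (8 * d.L + 4 + 9);
}

static mat tower_fwd(const std::vector<mat>& P, const Dims& d, int t,
                     const mat& X, const ivec& src, const ivec& dst,
                     const mat& R, bool use_r, const ivec& gid, int G,
                     TowerCache& cc) {
  const int tb = tower_base(d, t);
  cc.A_emb = relu_of(lin_of(X, P[0], P[1]));
  cc.H0 = relu_of(lin_of(cc.A_emb, P[2], P[3]));
  mat H = cc.H0;
  const int n = X.n_rows;
  cc.Hs.resize(d.L); cc.Min.resize(d.L); cc.A1.resize(d.L);
  cc.U.resize(d.L); cc.A2.resize(d.L);
  uvec usrc = conv_to<uvec>::from(src);
  uvec udst = conv_to<uvec>::from(dst);
  for (int l = 0; l < d.L; ++l) {
    const int lb = tb + 8 * l;
    mat Min = join_rows(H.rows(usrc), H.rows(udst));
    if (use_r) Min = join_rows(Min, R);
    mat A1 = relu_of(lin_of(Min, P[lb + 0], P[lb + 1]));
    mat M = lin_of(A1, P[lb + 2], P[lb + 3]);
    mat S = group_sum(M, src, n);
    mat U = join_rows(H, S);
    mat A2 = relu_of(lin_of(U, P[lb + 4], P[lb + 5]));
    mat D = lin_of(A2, P[lb + 6], P[lb + 7]);
    H = H + D;
    cc.Hs[l] = H; cc.Min[l] = Min; cc.A1[l] = A1; cc.U[l] = U; cc.A2[l] = A2;
  }
  cc.Hcat = cc.Hs[0];
  for (int l = 1; l < d.L; ++l) cc.Hcat = join_rows(cc.Hcat, cc.Hs[l]);
  const int fb = tb + 8 * d.L;
  cc.A1f = relu_of(lin_of(cc.Hcat, P[fb + 0], P[fb + 1]));
  cc.Ffin = lin_of(cc.A1f, P[fb + 2], P[fb + 3]);
  // pool layout: S=pb0, Wq=pb1, bq=pb2, Wk=pb3, bk=pb4, Wv=pb5, bv=pb6,
  // Wo=pb7, bo=pb8
  const int pb = fb + 4;
  cc.Q = lin_of(P[pb + 0], P[pb + 1], P[pb + 2]);
  cc.K = lin_of(cc.Ffin, P[pb + 3], P[pb + 4]);
  cc.V = lin_of(cc.Ffin, P[pb + 5], P[pb + 6]);
  mat Sc = cc.K * cc.Q.t() / std::sqrt((double)d.h);
  cc.scmask = (abs(Sc) < 30.0);
  Sc.clamp(-30.0, 30.0);
  mat E = exp(Sc);
  mat Den = group_sum(E, gid, G);
  mat Attn = E;
  for (uword j = 0; j < Attn.n_cols; ++j) {
    double* ac = Attn.colptr(j);
    const double* dc = Den.colptr(j);
    for (uword k = 0; k < Attn.n_rows; ++k) ac[k] /= dc[gid[k]];
  }
  cc.Attn = Attn;
  mat Pcat(G, d.heads * d.h);
  for (int k = 0; k < d.heads; ++k) {
    mat VA = cc.V.each_col() % Attn.col(k);
    Pcat.cols(k * d.h, (k + 1) * d.h - 1) = group_sum(VA, gid, G);
  }
  cc.Pcat = Pcat;
  return lin_of(Pcat, P[pb + 7], P[pb + 8]);
}

static void tower_bwd(const std::vector<mat>& P, std::vector<mat>& Gr,
                      const Dims& d, int t, const mat& X, const ivec& src,
                      const ivec& dst, const ivec& gid, int G,
                      const TowerCache& cc, const mat& dPm) {
  const int tb = tower_base(d, t);
  const int fb = tb + 8 * d.L;
  const int pb = fb + 4;
  const int n = X.n_rows;

  Gr[pb + 7] += cc.Pcat.t() * dPm;
  Gr[pb + 8] += sum(dPm, 0);
  mat dPcat = dPm * P[pb + 7].t();

  mat dV(n, d.h, fill::zeros);
  mat dAttn(n, d.heads, fill::zeros);
  for (int k = 0; k < d.heads; ++k) {
    mat dPk = dPcat.cols(k * d.h, (k + 1) * d.h - 1);
    // expand per node
    mat dPk_nodes(n, d.h);
    for (uword j = 0; j < (uword)d.h; ++j) {
      const double* pc = dPk.colptr(j);
      double* oc = dPk_nodes.colptr(j);
      for (int v = 0; v < n; ++v) oc[v] = pc[gid[v]];
    }
    dV += dPk_nodes.each_col() % cc.Attn.col(k);
    dAttn.col(k) = sum(cc.V % dPk_nodes, 1);
  }
  mat Tg = group_sum(cc.Attn % dAttn, gid, G);
  mat dSc = dAttn;
  for (uword j = 0; j < dSc.n_cols; ++j) {
    double* sc = dSc.colptr(j);
    const double* tc = Tg.colptr(j);
    const double* ac = cc.Attn.colptr(j);
    for (int v = 0; v < n; ++v) sc[v] = ac[v] * (sc[v] - tc[gid[v]]);
  }
  dSc.elem(find(cc.scmask == 0)).zeros();

  const double sh = std::sqrt((double)d.h);
  mat dK = dSc * cc.Q / sh;
  mat dQ = dSc.t() * cc.K / sh;
  Gr[pb + 2] += sum(dQ, 0);
  Gr[pb + 1] += P[pb + 0].t() * dQ;
  Gr[pb + 0] += dQ * P[pb + 1].t();
  Gr[pb + 3] += cc.Ffin.t() * dK;
  Gr[pb + 4] += sum(dK, 0);
  Gr[pb + 5] += cc.Ffin.t() * dV;
  Gr[pb + 6] += sum(dV, 0);
  mat dF = dK * P[pb + 3].t() + dV * P[pb + 5].t();

  Gr[fb + 2] += cc.A1f.t() * dF;
  Gr[fb + 3] += sum(dF, 0);
  mat dA1f = dF * P[fb + 2].t();
  relu_bwd(dA1f, cc.A1f);
  Gr[fb + 0] += cc.Hcat.t() * dA1f;
  Gr[fb + 1] += sum(dA1f, 0);
  mat dHcat = dA1f * P[fb + 0].t();

  uvec usrc = conv_to<uvec>::from(src);
  uvec udst = conv_to<uvec>::from(dst);
  mat dH_next(n, d.h, fill::zeros);
  for (int l = d.L - 1; l >= 0; --l) {
    const int lb = tb + 8 * l;
    mat dHl = dH_next + dHcat.cols(l * d.h, (l + 1) * d.h - 1);
    // phi backward
    mat dD = dHl;
    mat dA2 = dD * P[lb + 6].t();
    Gr[lb + 6] += cc.A2[l].t() * dD;
    Gr[lb + 7] += sum(dD, 0);
    relu_bwd(dA2, cc.A2[l]);
    mat dU = dA2 * P[lb + 4].t();
    Gr[lb + 4] += cc.U[l].t() * dA2;
    Gr[lb + 5] += sum(dA2, 0);
    mat dH = dU.cols(0, d.h - 1);
    mat dS = dU.cols(d.h, 2 * d.h - 1);
    dH += dHl;  // residual
    // psi backward
    mat dM = dS.rows(usrc);
    mat dA1 = dM * P[lb + 2].t();
    Gr[lb + 2] += cc.A1[l].t() * dM;
    Gr[lb + 3] += sum(dM, 0);
    relu_bwd(dA1, cc.A1[l]);
    mat dMin = dA1 * P[lb + 0].t();
    Gr[lb + 0] += cc.Min[l].t() * dA1;
    Gr[lb + 1] += sum(dA1, 0);
    dH += group_sum(dMin.cols(0, d.h - 1), src, n);
    dH += group_sum(dMin.cols(d.h, 2 * d.h - 1), dst, n);
    dH_next = dH;
  }
  // embedding backward (accumulated over towers)
  mat dZe2 = dH_next;
  relu_bwd(dZe2, cc.H0);
  Gr[2] += cc.A_emb.t() * dZe2;
  Gr[3] += sum(dZe2, 0);
  mat dAe = dZe2 * P[2].t();
  relu_bwd(dAe, cc.A_emb);
  Gr[0] += X.t() * dAe;
  Gr[1] += sum(dAe, 0);
}

// [[Rcpp::export(name = ".gtnn_pass_cpp")]]
Rcpp::List gtnn_pass_cpp(Rcpp::NumericVector theta,
                         Rcpp::IntegerVector dims,
                         const arma::mat& Xa, Rcpp::IntegerVector srca,
                         Rcpp::IntegerVector dsta, Rcpp::IntegerVector gida,
                         Rcpp::Nullable<Rcpp::NumericMatrix> Ra,
                         const arma::mat& Xb, Rcpp::IntegerVector srcb,
                         Rcpp::IntegerVector dstb, Rcpp::IntegerVector gidb,
                         Rcpp::Nullable<Rcpp::NumericMatrix> Rb,
                         Rcpp::IntegerVector mapa, Rcpp::IntegerVector mapb,
                         const arma::mat& C, Rcpp::NumericVector y,
                         bool want_grad) {
  Dims d;
  d.in = dims[0]; d.h = dims[1]; d.e = dims[2]; d.p = dims[3];
  d.L = dims[4]; d.heads = dims[5]; d.rdim = dims[6]; d.ncond = dims[7];

  auto shapes = param_shapes(d);
  size_t total = 0;
  for (auto& sh : shapes) total += (size_t)sh.first * sh.second;
  if ((size_t)theta.size() != total) {
    Rcpp::stop("parameter vector length %d does not match layout %d",
               (int)theta.size(), (int)total);
  }
  std::vector<mat> P;
  wrap_params(theta.begin(), shapes, P);

  Rcpp::NumericVector gradv(want_grad ? total : 0);
  std::vector<mat> Gr;
  if (want_grad) wrap_params(gradv.begin(), shapes, Gr);

  const int G = C.n_rows;
  auto to0 = [](Rcpp::IntegerVector v) {
    ivec out(v.size());
    for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
    return out;
  };
  ivec sa = to0(srca), da = to0(dsta), ga = to0(gida);
  ivec sb = to0(srcb), db = to0(dstb), gb = to0(gidb);
  mat Ram, Rbm;
  bool use_r = d.rdim > 0;
  if (use_r) {
    Ram = Rcpp::as<mat>(Ra.get());
    Rbm = Rcpp::as<mat>(Rb.get());
  }

  // towers run once per unique molecule; map vectors scatter the pooled
  // molecular vectors to the per-reaction rows
  ivec ma = to0(mapa), mb = to0(mapb);
  const int Ga = ma.max() + 1, Gb = mb.max() + 1;
  uvec uma = conv_to<uvec>::from(ma), umb = conv_to<uvec>::from(mb);
  TowerCache ca, cb;
  mat Pa = tower_fwd(P, d, 0, Xa, sa, da, Ram, use_r, ga, Ga, ca);
  mat Pb = tower_fwd(P, d, 1, Xb, sb, db, Rbm, use_r, gb, Gb, cb);
  mat Ce = lin_of(C, P[4], P[5]);
  mat Zc = join_rows(join_rows(Pa.rows(uma), Pb.rows(umb)), Ce);
  mat T1 = relu_of(lin_of(Zc, P[6], P[7]));
  mat T2 = relu_of(lin_of(T1, P[8], P[9]));
  mat logit = lin_of(T2, P[10], P[11]);
  logit.clamp(-35.0, 35.0);
  mat yhat = 1.0 / (1.0 + exp(-logit));

  double loss = NA_REAL;
  Rcpp::List out;
  if (want_grad || y.size() == G) {
    vec yt(y.begin(), y.size(), false);
    if ((int)yt.n_elem == G) {
      vec resid = yhat.col(0) - yt;
      loss = dot(resid, resid) / G;
      if (want_grad) {
        vec dy = 2.0 * resid / G;
        mat dlogit = (dy % yhat.col(0) % (1.0 - yhat.col(0)));
        dlogit.reshape(G, 1);
        Gr[10] += T2.t() * dlogit;
        Gr[11] += sum(dlogit, 0);
        mat dT2 = dlogit * P[10].t(); relu_bwd(dT2, T2);
        Gr[8] += T1.t() * dT2;
        Gr[9] += sum(dT2, 0);
        mat dT1 = dT2 * P[8].t(); relu_bwd(dT1, T1);
        Gr[6] += Zc.t() * dT1;
        Gr[7] += sum(dT1, 0);
        mat dZc = dT1 * P[6].t();
        mat dPa = group_sum(dZc.cols(0, d.e - 1), ma, Ga);
        mat dPb = group_sum(dZc.cols(d.e, 2 * d.e - 1), mb, Gb);
        mat dCe = dZc.cols(2 * d.e, 3 * d.e - 1);
        Gr[4] += C.t() * dCe;
        Gr[5] += sum(dCe, 0);
        tower_bwd(P, Gr, d, 0, Xa, sa, da, ga, Ga, ca, dPa);
        tower_bwd(P, Gr, d, 1, Xb, sb, db, gb, Gb, cb, dPb);
      }
    }
  }
  out["y"] = Rcpp::NumericVector(yhat.begin_col(0), yhat.end_col(0));
  out["loss"] = loss;
  if (want_grad) out["grad"] = gradv;
  return out;
}
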