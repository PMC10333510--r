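// Compiled hot paths of the network: the multi-scale convolution
// (channel-mix GEMM plus shifted accumulation) and the GRU recurrence
// (forward and backward-through-time). Layout conventions match R/engine.R:
// time-major matrices (T*B rows, row = t + b*T, 0-based here), same-padding
// with the extra sample on the left for even kernels, GRU gate order
// (update, reset, candidate), h' = (1-z)*h + z*n.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


// ---- templated cores (double for the reference surface, float for the
// ---- batched training path; same arithmetic, two precisions) ----

template <typename MT, typename VT>
MT conv_forward_core(const MT& M, const MT& Wall, const VT& ball,
                     const Rcpp::IntegerVector& klens, int Fk, int T, int B) {
  const arma::uword TB = M.n_rows;
  MT U = M * Wall;
  const int nb = klens.size();
  MT H(TB, (arma::uword)(nb * Fk), arma::fill::zeros);
  int ucol = 0;
  for (int i = 0; i < nb; ++i) {
    const int k = klens[i];
    const int pad_left = (k - 1 + 1) / 2;  // ceil((k-1)/2)
    MT Z(TB, Fk);
    Z.each_row() = ball.subvec(i * Fk, (i + 1) * Fk - 1).t();
    for (int j = 0; j < k; ++j) {
      const int d = j - pad_left;
      const int lo = std::max(0, -d), hi = std::min(T, T - d);
      if (hi > lo) {
        for (int b = 0; b < B; ++b) {
          const arma::uword r0 = (arma::uword)b * T;
          Z.rows(r0 + lo, r0 + hi - 1) +=
            U(arma::span(r0 + lo + d, r0 + hi - 1 + d),
              arma::span(ucol, ucol + Fk - 1));
        }
      }
      ucol += Fk;
    }
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    H.cols(i * Fk, (i + 1) * Fk - 1) = Z;
  }
  return H;
}

template <typename MT, typename VT>
void conv_backward_core(const MT& M, const MT& dH,
                        const Rcpp::IntegerVector& klens, int Fk, int T,
                        int B, MT& dWall, VT& db) {
  const arma::uword TB = M.n_rows;
  const int nb = klens.size();
  int tot = 0;
  for (int i = 0; i < nb; ++i) tot += klens[i] * Fk;
  MT dU(TB, (arma::uword)tot, arma::fill::zeros);
  db.zeros((arma::uword)(nb * Fk));
  int ucol = 0;
  for (int i = 0; i < nb; ++i) {
    const int k = klens[i];
    const int pad_left = (k - 1 + 1) / 2;
    const MT dZ = dH.cols(i * Fk, (i + 1) * Fk - 1);
    db.subvec(i * Fk, (i + 1) * Fk - 1) = arma::sum(dZ, 0).t();
    for (int j = 0; j < k; ++j) {
      const int d = j - pad_left;
      const int lo = std::max(0, -d), hi = std::min(T, T - d);
      if (hi > lo) {
        for (int b = 0; b < B; ++b) {
          const arma::uword r0 = (arma::uword)b * T;
          dU(arma::span(r0 + lo + d, r0 + hi - 1 + d),
             arma::span(ucol, ucol + Fk - 1)) =
            dZ.rows(r0 + lo, r0 + hi - 1);
        }
      }
      ucol += Fk;
    }
  }
  dWall = M.t() * dU;
}

template <typename MT>
MT sigm_core(const MT& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

template <typename MT, typename CT, typename VT>
void gru_forward_core(const MT& P, const MT& Wx, const MT& Wh, const VT& b,
                      int Tn, int B, CT& hs, CT& zs, CT& rs, CT& ns,
                      MT& avg) {
  const arma::uword H = Wh.n_rows;
  MT PX = P * Wx;
  PX.each_row() += b.t();
  hs.set_size(B, H, Tn); zs.set_size(B, H, Tn);
  rs.set_size(B, H, Tn); ns.set_size(B, H, Tn);
  MT h(B, H, arma::fill::zeros);
  avg.zeros(B, H);
  arma::uvec rows(B);
  for (int t = 0; t < Tn; ++t) {
    for (int bb = 0; bb < B; ++bb) rows[bb] = (arma::uword)bb * Tn + t;
    const MT g = PX.rows(rows);
    const MT rec = h * Wh.cols(0, 2 * H - 1);
    const MT z = sigm_core<MT>(g.cols(0, H - 1) + rec.cols(0, H - 1));
    const MT r = sigm_core<MT>(g.cols(H, 2 * H - 1) + rec.cols(H, 2 * H - 1));
    const MT n = arma::tanh(g.cols(2 * H, 3 * H - 1) +
                            (r % h) * Wh.cols(2 * H, 3 * H - 1));
    h = (1.0 - z) % h + z % n;
    hs.slice(t) = h; zs.slice(t) = z; rs.slice(t) = r; ns.slice(t) = n;
    avg += h;
  }
  avg /= (double)Tn;
}

template <typename MT, typename CT, typename VT>
void gru_backward_core(const MT& P, const MT& Wx, const MT& Wh,
                       const CT& hs, const CT& zs, const CT& rs,
                       const CT& ns, const MT& davg, int Tn, int B,
                       MT& dWx, MT& dWh, VT& db, MT& dP) {
  const arma::uword H = Wh.n_rows;
  MT dG(P.n_rows, 3 * H, arma::fill::zeros);
  dWh.zeros(H, 3 * H);
  MT dh(B, H, arma::fill::zeros);
  const MT per_step = davg / (double)Tn;
  arma::uvec rows(B);
  for (int t = Tn - 1; t >= 0; --t) {
    dh += per_step;
    const MT z = zs.slice(t), r = rs.slice(t), n = ns.slice(t);
    const MT hprev = (t > 0) ? hs.slice(t - 1) : MT(B, H, arma::fill::zeros);
    const MT dn = dh % z;
    const MT dz = dh % (n - hprev);
    MT dhp = dh % (1.0 - z);
    const MT dan = dn % (1.0 - n % n);
    const MT daz = dz % z % (1.0 - z);
    const MT drh = dan * Wh.cols(2 * H, 3 * H - 1).t();
    const MT dr = drh % hprev;
    dhp += drh % r;
    const MT dar = dr % r % (1.0 - r);
    dWh.cols(2 * H, 3 * H - 1) += (r % hprev).t() * dan;
    dWh.cols(0, H - 1) += hprev.t() * daz;
    dWh.cols(H, 2 * H - 1) += hprev.t() * dar;
    dhp += daz * Wh.cols(0, H - 1).t() + dar * Wh.cols(H, 2 * H - 1).t();
    for (int bb = 0; bb < B; ++bb) rows[bb] = (arma::uword)bb * Tn + t;
    dG.submat(rows, arma::regspace<arma::uvec>(0, H - 1)) = daz;
    dG.submat(rows, arma::regspace<arma::uvec>(H, 2 * H - 1)) = dar;
    dG.submat(rows, arma::regspace<arma::uvec>(2 * H, 3 * H - 1)) = dan;
    dh = dhp;
  }
  dWx = P.t() * dG;
  db = arma::sum(dG, 0).t();
  dP = dG * Wx.t();
}

// ---- double-precision exports (reference surface) ----

// [[Rcpp::export]]
arma::mat cpp_conv_forward(const arma::mat& M, const arma::mat& Wall,
                           const arma::vec& ball, const IntegerVector& klens,
                           int Fk, int T, int B) {
  return conv_forward_core<arma::mat, arma::vec>(M, Wall, ball, klens, Fk, T, B);
}

// [[Rcpp::export]]
List cpp_conv_backward(const arma::mat& M, const arma::mat& dH,
                       const IntegerVector& klens, int Fk, int T, int B) {
  arma::mat dWall; arma::vec db;
  conv_backward_core<arma::mat, arma::vec>(M, dH, klens, Fk, T, B, dWall, db);
  return List::create(_["dWall"] = dWall, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_gru_forward(const arma::mat& P, const arma::mat& Wx,
                     const arma::mat& Wh, const arma::vec& b,
                     int Tn, int B) {
  arma::cube hs, zs, rs, ns; arma::mat avg;
  gru_forward_core<arma::mat, arma::cube, arma::vec>(P, Wx, Wh, b, Tn, B,
                                                     hs, zs, rs, ns, avg);
  return List::create(_["hs"] = hs, _["zs"] = zs, _["rs"] = rs,
                      _["ns"] = ns, _["avg"] = avg);
}

// [[Rcpp::export]]
List cpp_gru_backward(const arma::mat& P, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::cube& hs,
                      const arma::cube& zs, const arma::cube& rs,
                      const arma::cube& ns, const arma::mat& davg,
                      int Tn, int B) {
  arma::mat dWx, dWh, dP; arma::vec db;
  gru_backward_core<arma::mat, arma::cube, arma::vec>(
      P, Wx, Wh, hs, zs, rs, ns, davg, Tn, B, dWx, dWh, db, dP);
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db,
                      _["dP"] = dP);
}

// ---- single-precision exports (batched training path; double in/out,
// ---- float arithmetic inside) ----

// [[Rcpp::export]]
arma::mat cpp_conv_forward_f(const arma::mat& M, const arma::mat& Wall,
                             const arma::vec& ball, const IntegerVector& klens,
                             int Fk, int T, int B) {
  arma::fmat Mf = arma::conv_to<arma::fmat>::from(M);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wall);
  arma::fvec bf = arma::conv_to<arma::fvec>::from(ball);
  arma::fmat H = conv_forward_core<arma::fmat, arma::fvec>(Mf, Wf, bf, klens,
                                                           Fk, T, B);
  return arma::conv_to<arma::mat>::from(H);
}

// [[Rcpp::export]]
List cpp_conv_backward_f(const arma::mat& M, const arma::mat& dH,
                         const IntegerVector& klens, int Fk, int T, int B) {
  arma::fmat Mf = arma::conv_to<arma::fmat>::from(M);
  arma::fmat dHf = arma::conv_to<arma::fmat>::from(dH);
  arma::fmat dWall; arma::fvec db;
  conv_backward_core<arma::fmat, arma::fvec>(Mf, dHf, klens, Fk, T, B,
                                             dWall, db);
  return List::create(_["dWall"] = arma::conv_to<arma::mat>::from(dWall),
                      _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
List cpp_gru_forward_f(const arma::mat& P, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::vec& b,
                       int Tn, int B) {
  arma::fmat Pf = arma::conv_to<arma::fmat>::from(P);
  arma::fmat Wxf = arma::conv_to<arma::fmat>::from(Wx);
  arma::fmat Whf = arma::conv_to<arma::fmat>::from(Wh);
  arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
  arma::fcube hs, zs, rs, ns; arma::fmat avg;
  gru_forward_core<arma::fmat, arma::fcube, arma::fvec>(Pf, Wxf, Whf, bf,
                                                        Tn, B, hs, zs, rs,
                                                        ns, avg);
  return List::create(_["hs"] = arma::conv_to<arma::cube>::from(hs),
                      _["zs"] = arma::conv_to<arma::cube>::from(zs),
                      _["rs"] = arma::conv_to<arma::cube>::from(rs),
                      _["ns"] = arma::conv_to<arma::cube>::from(ns),
                      _["avg"] = arma::conv_to<arma::mat>::from(avg));
}

// [[Rcpp::export]]
List cpp_gru_backward_f(const arma::mat& P, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::cube& hs_,
                        const arma::cube& zs_, const arma::cube& rs_,
                        const arma::cube& ns_, const arma::mat& davg,
                        int Tn, int B) {
  arma::fcube hs = arma::conv_to<arma::fcube>::from(hs_);
  arma::fcube zs = arma::conv_to<arma::fcube>::from(zs_);
  arma::fcube rs = arma::conv_to<arma::fcube>::from(rs_);
  arma::fcube ns = arma::conv_to<arma::fcube>::from(ns_);
  arma::fmat Pf = arma::conv_to<arma::fmat>::from(P);
  arma::fmat Wxf = arma::conv_to<arma::fmat>::from(Wx);
  arma::fmat Whf = arma::conv_to<arma::fmat>::from(Wh);
  arma::fmat davgf = arma::conv_to<arma::fmat>::from(davg);
  arma::fmat dWx, dWh, dP; arma::fvec db;
  gru_backward_core<arma::fmat, arma::fcube, arma::fvec>(
      Pf, Wxf, Whf, hs, zs, rs, ns, davgf, Tn, B, dWx, dWh, db, dP);
  return List::create(_["dWx"] = arma::conv_to<arma::mat>::from(dWx),
                      _["dWh"] = arma::conv_to<arma::mat>::from(dWh),
                      _["db"] = arma::conv_to<arma::vec>::from(db),
                      _["dP"] = arma::conv_to<arma::mat>::from(dP));
}

// temporal max-pool with non-overlapping windows; returns pooled matrix and
// 1-based within-window argmax (earliest wins on ties)
// [[Rcpp::export]]
List cpp_pool_forward(const arma::mat& H, int T, int B, int pool) {
  const int n_pool = T / pool;
  const arma::uword F = H.n_cols;
  arma::mat P((arma::uword)n_pool * B, F);
  arma::imat bestp((arma::uword)n_pool * B, F);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < n_pool; ++w) {
      const arma::uword orow = (arma::uword)b * n_pool + w;
      const arma::uword irow = (arma::uword)b * T + (arma::uword)w * pool;
      for (arma::uword f = 0; f < F; ++f) {
        double best = H(irow, f);
        int bp = 1;
        for (int p = 1; p < pool; ++p) {
          const double v = H(irow + p, f);
          if (v > best) { best = v; bp = p + 1; }
        }
        P(orow, f) = best;
        bestp(orow, f) = bp;
      }
    }
  }
  return List::create(_["P"] = P, _["bestp"] = bestp, _["n_pool"] = n_pool);
}

// [[Rcpp::export]]
arma::mat cpp_pool_backward(const arma::mat& dP, const arma::imat& bestp,
                            int T, int B, int pool, int Fdim) {
  const int n_pool = T / pool;
  arma::mat dH((arma::uword)T * B, (arma::uword)Fdim, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < n_pool; ++w) {
      const arma::uword orow = (arma::uword)b * n_pool + w;
      const arma::uword irow = (arma::uword)b * T + (arma::uword)w * pool;
      for (int f = 0; f < Fdim; ++f) {
        dH(irow + bestp(orow, f) - 1, f) = dP(orow, f);
      }
    }
  }
  return dH;
}
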