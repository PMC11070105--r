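// Bidirectional-GRU building block: sequential recurrence is the only part
// of the network that cannot be vectorised in R, so forward and backward
// passes for a single directional GRU layer live here. Batch-first layout:
// cubes are (batch, features, time); slice t is the (batch x features)
// matrix at time t. Gate order in the 3H-wide weight blocks is [r | z | n].
//
// Update equations (per time step, h_prev = previous hidden state):
//   gx = x W + b_ih            (b x 3H)
//   gh = h_prev U + b_hh       (b x 3H)
//   r  = sigmoid(gx_r + gh_r)
//   z  = sigmoid(gx_z + gh_z)
//   n  = tanh(gx_n + r .* gh_n)
//   h  = (1 - z) .* n + z .* h_prev
//
// The input projection and the weight-gradient accumulations are batched
// into single GEMMs across all time steps; the per-step gate arithmetic is
// fused into plain loops over the contiguous cube slices to avoid
// temporaries inside the recurrence.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// stack cube slices vertically into a (b*T x c) matrix
static arma::mat cube_to_tall(const arma::cube& X) {
  const arma::uword b = X.n_rows, c = X.n_cols, T = X.n_slices;
  arma::mat out(b * T, c);
  for (arma::uword t = 0; t < T; ++t)
    out.rows(t * b, t * b + b - 1) = X.slice(t);
  return out;
}

// [[Rcpp::export]]
List cs_gru_forward(const arma::cube& X, const arma::mat& W, const arma::mat& U,
                    const arma::vec& b_ih, const arma::vec& b_hh, bool reverse,
                    bool need_cache = true) {
  const arma::uword b = X.n_rows, T = X.n_slices;
  const arma::uword H = U.n_rows;
  const arma::uword bH = b * H;

  // input projection for every time step in one GEMM, stored slice-major
  arma::mat GX2 = cube_to_tall(X) * W;
  GX2.each_row() += b_ih.t();
  arma::cube GX(b, 3 * H, T);
  for (arma::uword t = 0; t < T; ++t)
    GX.slice(t) = GX2.rows(t * b, t * b + b - 1);

  // gate caches are only materialised when a backward pass will follow
  const arma::uword Tc = need_cache ? T : 1;
  arma::cube Hout(b, H, T), R(b, H, Tc), Z(b, H, Tc), N(b, H, Tc),
             HUN(b, H, Tc);
  arma::mat gh(b, 3 * H);
  arma::mat h0(b, H, arma::fill::zeros);
  const arma::rowvec bh = b_hh.t();

  const double* hp = h0.memptr();
  for (arma::uword i = 0; i < T; ++i) {
    const arma::uword t = reverse ? (T - 1 - i) : i;
    const arma::uword tc = need_cache ? t : 0;
    {
      const arma::mat hprev(const_cast<double*>(hp), b, H, false, true);
      gh = hprev * U;
    }
    gh.each_row() += bh;
    const double* gx = GX.slice_memptr(t);
    const double* ghp = gh.memptr();
    double* rp = R.slice_memptr(tc);
    double* zp = Z.slice_memptr(tc);
    double* np = N.slice_memptr(tc);
    double* hunp = HUN.slice_memptr(tc);
    double* hop = Hout.slice_memptr(t);
    for (arma::uword j = 0; j < bH; ++j) {
      const double r = 1.0 / (1.0 + std::exp(-(gx[j] + ghp[j])));
      const double z = 1.0 / (1.0 + std::exp(-(gx[bH + j] + ghp[bH + j])));
      const double hun = ghp[2 * bH + j];
      const double n = std::tanh(gx[2 * bH + j] + r * hun);
      rp[j] = r; zp[j] = z; hunp[j] = hun; np[j] = n;
      hop[j] = (1.0 - z) * n + z * hp[j];
    }
    hp = hop;
  }
  return List::create(_["h"] = Hout, _["r"] = R, _["z"] = Z,
                      _["n"] = N, _["hun"] = HUN);
}

// [[Rcpp::export]]
List cs_gru_backward(const arma::cube& dH, const arma::cube& X, const arma::cube& Hout,
                     const arma::cube& R, const arma::cube& Z, const arma::cube& N,
                     const arma::cube& HUN, const arma::mat& W, const arma::mat& U,
                     bool reverse) {
  const arma::uword b = X.n_rows, in = X.n_cols, T = X.n_slices;
  const arma::uword H = U.n_rows;
  const arma::uword bH = b * H;

  // per-step pre-activation gradients, consumed by batched GEMMs at the
  // end: DGX gate order [dr_pre | dz_pre | dn_pre] (x-projection), DGH
  // [dr_pre | dz_pre | dhun] (h-projection)
  arma::cube DGX(b, 3 * H, T), DGH(b, 3 * H, T);
  arma::mat dh_carry(b, H, arma::fill::zeros);
  arma::mat zeros_h(b, H, arma::fill::zeros);
  const arma::mat Ut = U.t();

  for (arma::uword i = T; i-- > 0;) {
    const arma::uword t = reverse ? (T - 1 - i) : i;
    const bool has_prev = (i > 0);
    const arma::uword t_prev = has_prev ? (reverse ? (T - i) : (i - 1)) : 0;
    const double* hp = has_prev ? Hout.slice_memptr(t_prev)
                                : zeros_h.memptr();
    const double* dhs = dH.slice_memptr(t);
    const double* rp = R.slice_memptr(t);
    const double* zp = Z.slice_memptr(t);
    const double* np = N.slice_memptr(t);
    const double* hunp = HUN.slice_memptr(t);
    double* dgx = DGX.slice_memptr(t);
    double* dgh = DGH.slice_memptr(t);
    double* dcp = dh_carry.memptr();

    for (arma::uword j = 0; j < bH; ++j) {
      const double dh = dhs[j] + dcp[j];
      const double r = rp[j], z = zp[j], n = np[j];
      const double dz_pre = dh * (hp[j] - n) * z * (1.0 - z);
      const double dn_pre = dh * (1.0 - z) * (1.0 - n * n);
      const double dhun = dn_pre * r;
      const double dr_pre = dn_pre * hunp[j] * r * (1.0 - r);
      dgx[j] = dr_pre; dgx[bH + j] = dz_pre; dgx[2 * bH + j] = dn_pre;
      dgh[j] = dr_pre; dgh[bH + j] = dz_pre; dgh[2 * bH + j] = dhun;
      dcp[j] = dh * z;                    // + dgh * U^T added below
    }
    dh_carry += DGH.slice(t) * Ut;
  }

  // batched weight/bias gradients and input gradient
  arma::mat X2 = cube_to_tall(X);
  arma::mat DGX2 = cube_to_tall(DGX);
  arma::mat DGH2 = cube_to_tall(DGH);
  arma::mat HP2(b * T, H, arma::fill::zeros);   // h_{t-1} per step
  for (arma::uword i = 1; i < T; ++i) {
    const arma::uword t = reverse ? (T - 1 - i) : i;
    const arma::uword t_prev = reverse ? (T - i) : (i - 1);
    HP2.rows(t * b, t * b + b - 1) = Hout.slice(t_prev);
  }
  arma::mat dW = X2.t() * DGX2;
  arma::mat dU = HP2.t() * DGH2;
  arma::vec db_ih = arma::sum(DGX2, 0).t();
  arma::vec db_hh = arma::sum(DGH2, 0).t();
  arma::mat dX2 = DGX2 * W.t();
  arma::cube dX(b, in, T);
  for (arma::uword t = 0; t < T; ++t)
    dX.slice(t) = dX2.rows(t * b, t * b + b - 1);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU,
                      _["db_ih"] = db_ih, _["db_hh"] = db_hh);
}
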