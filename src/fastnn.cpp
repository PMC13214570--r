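// Compute kernels for the dense-block networks: forward/backward passes
// and the InfoNCE gradient.  Mirrors the reference semantics of R/nn.R
// (population-variance layer norm with eps 1e-5, inverted dropout); the
// dropout mask generator is a local xorshift64* seeded per call from the
// caller's R stream.  The test suite pins these kernels both to the
// pure-R reference implementations and to finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

// plain numeric vector (no dim attribute) from a row vector
static NumericVector nv(const arma::rowvec& x) {
  return NumericVector(x.begin(), x.end());
}

// layer normalization over rows; returns Y and fills xhat, inv
static arma::mat ln_forward(const arma::mat& X, const arma::rowvec& gamma,
                            const arma::rowvec& beta, arma::mat& xhat,
                            arma::vec& inv) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xc), 1);
  inv = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = xc.each_col() % inv;
  arma::mat Y = xhat.each_row() % gamma;
  Y.each_row() += beta;
  return Y;
}

static arma::mat ln_backward(const arma::mat& dY, const arma::mat& xhat,
                             const arma::vec& inv, const arma::rowvec& gamma,
                             arma::rowvec& dgamma, arma::rowvec& dbeta) {
  dgamma = arma::sum(dY % xhat, 0);
  dbeta = arma::sum(dY, 0);
  arma::mat dxhat = dY.each_row() % gamma;
  arma::vec r1 = arma::mean(dxhat, 1);
  arma::vec r2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat;
  dX.each_col() -= r1;
  dX -= xhat.each_col() % r2;
  dX.each_col() %= inv;
  return dX;
}

// [[Rcpp::export(name = ".cpp_mlp_forward")]]
List cpp_mlp_forward(const arma::mat& X, List Ws, List bs, List gammas,
                     List betas, const arma::mat& Wout,
                     const arma::rowvec& bout, bool relu_first,
                     double dropout, bool training, int rng_seed) {
  int L = Ws.size();
  List caches(L);
  arma::mat H = X;
  // fast local generator for dropout masks (xorshift64*), seeded from the
  // caller's R stream so results remain fully determined by the config seed
  uint64_t st = static_cast<uint64_t>(rng_seed) * 2654435761ULL + 1442695040888963407ULL;
  auto unif_next = [&st]() {
    st ^= st >> 12; st ^= st << 25; st ^= st >> 27;
    return static_cast<double>((st * 2685821657736338717ULL) >> 11) *
      (1.0 / 9007199254740992.0);
  };
  for (int i = 0; i < L; ++i) {
    arma::mat W = as<arma::mat>(Ws[i]);
    arma::rowvec b = as<arma::rowvec>(bs[i]);
    arma::rowvec gamma = as<arma::rowvec>(gammas[i]);
    arma::rowvec beta = as<arma::rowvec>(betas[i]);
    arma::mat A = H * W;
    A.each_row() += b;
    arma::mat xhat, pos, D;
    arma::vec inv;
    if (relu_first) {
      pos = arma::conv_to<arma::mat>::from(A > 0.0);
      arma::mat R = A % pos;
      D = ln_forward(R, gamma, beta, xhat, inv);
    } else {
      arma::mat Y = ln_forward(A, gamma, beta, xhat, inv);
      pos = arma::conv_to<arma::mat>::from(Y > 0.0);
      D = Y % pos;
    }
    List cache = List::create(Named("X") = H, Named("pos") = pos,
                              Named("xhat") = xhat, Named("inv") = inv);
    if (training && dropout > 0) {
      arma::mat mask(D.n_rows, D.n_cols);
      double keep = 1.0 - dropout;
      for (arma::uword k = 0; k < D.n_elem; ++k)
        mask(k) = (unif_next() >= dropout) ? 1.0 / keep : 0.0;
      D %= mask;
      cache["mask"] = mask;
    }
    caches[i] = cache;
    H = D;
  }
  arma::mat out = H * Wout;
  out.each_row() += bout;
  return List::create(Named("out") = out, Named("H_last") = H,
                      Named("caches") = caches);
}

// [[Rcpp::export(name = ".cpp_mlp_backward")]]
List cpp_mlp_backward(List fwd, List Ws, List gammas, const arma::mat& Wout,
                      bool relu_first, const arma::mat& d_out) {
  int L = Ws.size();
  List caches = fwd["caches"];
  arma::mat H_last = as<arma::mat>(fwd["H_last"]);
  List layer_grads(L);
  arma::mat dWout = H_last.t() * d_out;
  NumericVector dbout = nv(arma::sum(d_out, 0));
  arma::mat dH = d_out * Wout.t();
  for (int i = L - 1; i >= 0; --i) {
    List cache = caches[i];
    arma::mat W = as<arma::mat>(Ws[i]);
    arma::rowvec gamma = as<arma::rowvec>(gammas[i]);
    arma::mat Xin = as<arma::mat>(cache["X"]);
    arma::mat pos = as<arma::mat>(cache["pos"]);
    arma::mat xhat = as<arma::mat>(cache["xhat"]);
    arma::vec inv = as<arma::vec>(cache["inv"]);
    if (cache.containsElementNamed("mask"))
      dH %= as<arma::mat>(cache["mask"]);
    arma::rowvec dgamma, dbeta;
    arma::mat dA;
    if (relu_first) {
      arma::mat dR = ln_backward(dH, xhat, inv, gamma, dgamma, dbeta);
      dA = dR % pos;
    } else {
      arma::mat dY = dH % pos;
      dA = ln_backward(dY, xhat, inv, gamma, dgamma, dbeta);
    }
    layer_grads[i] = List::create(Named("W") = Xin.t() * dA,
                                  Named("b") = nv(arma::sum(dA, 0)),
                                  Named("gamma") = nv(dgamma),
                                  Named("beta") = nv(dbeta));
    dH = dA * W.t();
  }
  return List::create(Named("out") = List::create(Named("W") = dWout,
                                                  Named("b") = dbout),
                      Named("layers") = layer_grads,
                      Named("d_input") = dH);
}

// InfoNCE loss and gradient w.r.t. unit-row embeddings Z (2N x d), with
// row i paired to row i +/- N; all 2N - 1 other rows are negatives.
// [[Rcpp::export(name = ".cpp_infonce_grad")]]
List cpp_infonce_grad(const arma::mat& Z, double tau) {
  int n2 = Z.n_rows;
  int N = n2 / 2;
  arma::mat S = Z * Z.t() / tau;
  double mx = 1.0 / tau;           // rows are unit vectors: S <= 1/tau
  arma::mat E = arma::exp(S - mx);
  E.diag().zeros();
  arma::vec ssum = arma::sum(E, 1);
  arma::mat P = E.each_col() / ssum;
  double loss = 0.0;
  for (int i = 0; i < n2; ++i) {
    int p = (i < N) ? i + N : i - N;
    loss += std::log(ssum(i)) + mx - S(i, p);
  }
  loss /= n2;
  arma::mat G = P;
  for (int i = 0; i < n2; ++i) {
    int p = (i < N) ? i + N : i - N;
    G(i, p) -= 1.0;
  }
  G /= n2;
  arma::mat dZ = (G * Z + G.t() * Z) / tau;
  return List::create(Named("loss") = loss, Named("dZ") = dZ);
}

// cache-free inference pass (identical arithmetic to cpp_mlp_forward with
// training = FALSE; used by the predict methods where no backward pass
// will follow)
// [[Rcpp::export(name = ".cpp_mlp_infer")]]
arma::mat cpp_mlp_infer(const arma::mat& X, List Ws, List bs, List gammas,
                        List betas, const arma::mat& Wout,
                        const arma::rowvec& bout, bool relu_first) {
  int L = Ws.size();
  arma::mat H = X;
  for (int i = 0; i < L; ++i) {
    arma::mat W = as<arma::mat>(Ws[i]);
    arma::rowvec b = as<arma::rowvec>(bs[i]);
    arma::rowvec gamma = as<arma::rowvec>(gammas[i]);
    arma::rowvec beta = as<arma::rowvec>(betas[i]);
    arma::mat A = H * W;
    A.each_row() += b;
    arma::mat xhat;
    arma::vec inv;
    if (relu_first) {
      arma::mat pos = arma::conv_to<arma::mat>::from(A > 0.0);
      arma::mat R = A % pos;
      H = ln_forward(R, gamma, beta, xhat, inv);
    } else {
      arma::mat Y = ln_forward(A, gamma, beta, xhat, inv);
      arma::mat pos = arma::conv_to<arma::mat>::from(Y > 0.0);
      H = Y % pos;
    }
  }
  arma::mat out = H * Wout;
  out.each_row() += bout;
  return out;
}
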