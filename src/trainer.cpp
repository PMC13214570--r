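// Fused training steps for the contrastive embedder and the regressor.
// A trainer object (held behind an external pointer) keeps network
// parameters, AdamW state and scratch buffers in C++ across steps, so a
// step involves no R-level marshalling beyond the augmented batch.
// Semantics match the R/nn.R reference exactly at dropout = 0 (the test
// suite asserts one-step equivalence); dropout masks come from a local
// mt19937 seeded per step from the caller's R stream.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TLN_EPS = 1e-5;

// fast deterministic uniform generator for dropout masks (xorshift64*);
// quality is ample for Bernoulli masks and it is ~30x faster than
// mt19937 + uniform_real_distribution
struct FastUnif {
  uint64_t s;
  explicit FastUnif(uint64_t seed) : s(seed * 2654435761ULL + 1442695040888963407ULL) {}
  double next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return static_cast<double>((s * 2685821657736338717ULL) >> 11) *
      (1.0 / 9007199254740992.0);
  }
};

struct DenseNet {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b, g, be;
  arma::mat Wout;
  arma::rowvec bout;
  bool relu_first;
  double dropout;

  // AdamW first/second moments
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb, mg, vg, mbe, vbe;
  arma::mat mWout, vWout;
  arma::rowvec mbout, vbout;

  // per-step caches and gradients
  std::vector<arma::mat> cX, cpos, cxhat, cmask;
  std::vector<arma::vec> cinv;
  arma::mat H_last, out;
  std::vector<arma::mat> gW;
  std::vector<arma::rowvec> gb, gg, gbe;
  arma::mat gWout;
  arma::rowvec gbout;

  int L() const { return static_cast<int>(W.size()); }

  void init_from(List layers, List out_l, bool relu, double drop) {
    relu_first = relu;
    dropout = drop;
    int nl = layers.size();
    W.resize(nl); b.resize(nl); g.resize(nl); be.resize(nl);
    for (int i = 0; i < nl; ++i) {
      List ly = layers[i];
      W[i] = as<arma::mat>(ly["W"]);
      b[i] = as<arma::rowvec>(ly["b"]);
      g[i] = as<arma::rowvec>(ly["gamma"]);
      be[i] = as<arma::rowvec>(ly["beta"]);
    }
    Wout = as<arma::mat>(out_l["W"]);
    bout = as<arma::rowvec>(out_l["b"]);
    auto zm = [](const arma::mat& x) { return arma::mat(x.n_rows, x.n_cols, arma::fill::zeros); };
    auto zr = [](const arma::rowvec& x) { return arma::rowvec(x.n_elem, arma::fill::zeros); };
    mW.clear(); vW.clear(); mb.clear(); vb.clear();
    mg.clear(); vg.clear(); mbe.clear(); vbe.clear();
    for (int i = 0; i < nl; ++i) {
      mW.push_back(zm(W[i])); vW.push_back(zm(W[i]));
      mb.push_back(zr(b[i])); vb.push_back(zr(b[i]));
      mg.push_back(zr(g[i])); vg.push_back(zr(g[i]));
      mbe.push_back(zr(be[i])); vbe.push_back(zr(be[i]));
    }
    mWout = zm(Wout); vWout = zm(Wout);
    mbout = zr(bout); vbout = zr(bout);
    cX.resize(nl); cpos.resize(nl); cxhat.resize(nl); cmask.resize(nl);
    cinv.resize(nl);
    gW.resize(nl); gb.resize(nl); gg.resize(nl); gbe.resize(nl);
  }

  void forward(const arma::mat& X, bool training, FastUnif& gen) {
    arma::mat H = X;
    for (int i = 0; i < L(); ++i) {
      cX[i] = H;
      arma::mat A = H * W[i];
      A.each_row() += b[i];
      const arma::uword n = A.n_rows, d = A.n_cols;
      cpos[i].set_size(n, d);
      cxhat[i].set_size(n, d);
      cinv[i].set_size(n);
      arma::mat D(n, d);
      bool use_mask = training && dropout > 0;
      if (use_mask) cmask[i].set_size(n, d); else cmask[i].reset();
      double keep = 1.0 - dropout;
      arma::vec mu(n, arma::fill::zeros), vr(n, arma::fill::zeros);
      double* pa = A.memptr();
      double* pp = cpos[i].memptr();
      double* px = cxhat[i].memptr();
      double* pd = D.memptr();
      double* pm = use_mask ? cmask[i].memptr() : nullptr;
      if (relu_first) {
        // R = relu(A) overwrites A in place; accumulate row means
        for (arma::uword j = 0; j < d; ++j) {
          double* col = pa + j * n;
          double* pc = pp + j * n;
          for (arma::uword r = 0; r < n; ++r) {
            bool hot = col[r] > 0.0;
            pc[r] = hot ? 1.0 : 0.0;
            col[r] = hot ? col[r] : 0.0;
            mu(r) += col[r];
          }
        }
        mu /= d;
        for (arma::uword j = 0; j < d; ++j) {
          double* col = pa + j * n;
          for (arma::uword r = 0; r < n; ++r) {
            double xc = col[r] - mu(r);
            vr(r) += xc * xc;
          }
        }
        for (arma::uword r = 0; r < n; ++r)
          cinv[i](r) = 1.0 / std::sqrt(vr(r) / d + TLN_EPS);
        for (arma::uword j = 0; j < d; ++j) {
          double gj = g[i](j), bj = be[i](j);
          double* col = pa + j * n;
          double* xh = px + j * n;
          double* dc = pd + j * n;
          double* mc = use_mask ? pm + j * n : nullptr;
          for (arma::uword r = 0; r < n; ++r) {
            double x = (col[r] - mu(r)) * cinv[i](r);
            xh[r] = x;
            double y = x * gj + bj;
            if (use_mask) {
              double mval = (gen.next() >= dropout) ? 1.0 / keep : 0.0;
              mc[r] = mval;
              y *= mval;
            }
            dc[r] = y;
          }
        }
      } else {
        for (arma::uword j = 0; j < d; ++j) {
          double* col = pa + j * n;
          for (arma::uword r = 0; r < n; ++r) mu(r) += col[r];
        }
        mu /= d;
        for (arma::uword j = 0; j < d; ++j) {
          double* col = pa + j * n;
          for (arma::uword r = 0; r < n; ++r) {
            double xc = col[r] - mu(r);
            vr(r) += xc * xc;
          }
        }
        for (arma::uword r = 0; r < n; ++r)
          cinv[i](r) = 1.0 / std::sqrt(vr(r) / d + TLN_EPS);
        for (arma::uword j = 0; j < d; ++j) {
          double gj = g[i](j), bj = be[i](j);
          double* col = pa + j * n;
          double* xh = px + j * n;
          double* pc = pp + j * n;
          double* dc = pd + j * n;
          double* mc = use_mask ? pm + j * n : nullptr;
          for (arma::uword r = 0; r < n; ++r) {
            double x = (col[r] - mu(r)) * cinv[i](r);
            xh[r] = x;
            double y = x * gj + bj;
            bool hot = y > 0.0;
            pc[r] = hot ? 1.0 : 0.0;
            y = hot ? y : 0.0;
            if (use_mask) {
              double mval = (gen.next() >= dropout) ? 1.0 / keep : 0.0;
              mc[r] = mval;
              y *= mval;
            }
            dc[r] = y;
          }
        }
      }
      H = std::move(D);
    }
    H_last = H;
    out = H * Wout;
    out.each_row() += bout;
  }

  arma::mat backward(const arma::mat& d_out) {
    gWout = H_last.t() * d_out;
    gbout = arma::sum(d_out, 0);
    arma::mat dH = d_out * Wout.t();
    for (int i = L() - 1; i >= 0; --i) {
      const arma::uword n = dH.n_rows, d = dH.n_cols;
      bool use_mask = cmask[i].n_elem > 0;
      arma::mat dxhat(n, d);
      gg[i].set_size(d); gbe[i].set_size(d);
      arma::vec r1(n, arma::fill::zeros), r2(n, arma::fill::zeros);
      double* ph = dH.memptr();
      double* pxh = cxhat[i].memptr();
      double* pdx = dxhat.memptr();
      double* ppos = cpos[i].memptr();
      double* pmask = use_mask ? cmask[i].memptr() : nullptr;
      // pass 1: mask, (relu for ln_relu order), layer-norm param grads,
      // dxhat, and the row accumulators r1 = mean(dxhat), r2 = mean(dxhat*xhat)
      for (arma::uword j = 0; j < d; ++j) {
        double gj = g[i](j);
        double accg = 0.0, accb = 0.0;
        double* hc = ph + j * n;
        double* xc = pxh + j * n;
        double* dc = pdx + j * n;
        double* pc = ppos + j * n;
        double* mc = use_mask ? pmask + j * n : nullptr;
        for (arma::uword r = 0; r < n; ++r) {
          double y = hc[r];
          if (use_mask) y *= mc[r];
          if (!relu_first) y *= pc[r];   // relu sits after the norm
          accb += y;
          accg += y * xc[r];
          double dx = y * gj;
          dc[r] = dx;
          r1(r) += dx;
          r2(r) += dx * xc[r];
        }
        gg[i](j) = accg;
        gbe[i](j) = accb;
      }
      r1 /= d; r2 /= d;
      // pass 2: dA = layer-norm backward (times the relu mask for the
      // relu-first order), with the bias gradient accumulated in place
      arma::mat dA(n, d);
      gb[i].set_size(d);
      double* pda = dA.memptr();
      for (arma::uword j = 0; j < d; ++j) {
        double accb = 0.0;
        double* dc = pdx + j * n;
        double* xc = pxh + j * n;
        double* pc = ppos + j * n;
        double* ac = pda + j * n;
        for (arma::uword r = 0; r < n; ++r) {
          double v = (dc[r] - r1(r) - xc[r] * r2(r)) * cinv[i](r);
          if (relu_first) v *= pc[r];
          ac[r] = v;
          accb += v;
        }
        gb[i](j) = accb;
      }
      gW[i] = cX[i].t() * dA;
      dH = dA * W[i].t();
    }
    return dH;  // gradient w.r.t. the input batch
  }

  // AdamW on all tensors; `scale` multiplies the stored gradients (used
  // for the adversarial weights w_c / w_s); decay on weight matrices only.
  // Fused elementwise loops; decay uses the pre-step parameter value:
  // p_new = p - lr*step - lr*wd*p_old.
  void adam(double lr, double wd, int t, double scale,
            double beta1 = 0.9, double beta2 = 0.999, double eps = 1e-8) {
    double b1t = 1.0 - std::pow(beta1, t);
    double b2t = 1.0 - std::pow(beta2, t);
    auto upd = [&](double* p, const double* grad, double* m, double* v,
                   arma::uword nel, bool decay) {
      for (arma::uword k = 0; k < nel; ++k) {
        double gsc = scale * grad[k];
        m[k] = beta1 * m[k] + (1.0 - beta1) * gsc;
        v[k] = beta2 * v[k] + (1.0 - beta2) * gsc * gsc;
        double step = (m[k] / b1t) / (std::sqrt(v[k] / b2t) + eps);
        double pnew = p[k] - lr * step;
        if (decay) pnew -= lr * wd * p[k];
        p[k] = pnew;
      }
    };
    for (int i = 0; i < L(); ++i) {
      upd(W[i].memptr(), gW[i].memptr(), mW[i].memptr(), vW[i].memptr(),
          W[i].n_elem, true);
      upd(b[i].memptr(), gb[i].memptr(), mb[i].memptr(), vb[i].memptr(),
          b[i].n_elem, false);
      upd(g[i].memptr(), gg[i].memptr(), mg[i].memptr(), vg[i].memptr(),
          g[i].n_elem, false);
      upd(be[i].memptr(), gbe[i].memptr(), mbe[i].memptr(), vbe[i].memptr(),
          be[i].n_elem, false);
    }
    upd(Wout.memptr(), gWout.memptr(), mWout.memptr(), vWout.memptr(),
        Wout.n_elem, true);
    upd(bout.memptr(), gbout.memptr(), mbout.memptr(), vbout.memptr(),
        bout.n_elem, false);
  }

  List export_params() const {
    List layers(L());
    for (int i = 0; i < L(); ++i) {
      layers[i] = List::create(
        Named("W") = W[i],
        Named("b") = NumericVector(b[i].begin(), b[i].end()),
        Named("gamma") = NumericVector(g[i].begin(), g[i].end()),
        Named("beta") = NumericVector(be[i].begin(), be[i].end()));
    }
    return List::create(Named("layers") = layers,
                        Named("out") = List::create(
                          Named("W") = Wout,
                          Named("b") = NumericVector(bout.begin(), bout.end())));
  }
};

// stable softmax cross-entropy on a logit block; fills G (grad w.r.t.
// logits, scaled by `scale`), returns the mean loss
static double ce_block(const arma::mat& logits, const arma::ivec& lab0,
                       double scale, arma::mat& G) {
  int n = logits.n_rows;
  arma::vec mx = arma::max(logits, 1);
  arma::mat E = arma::exp(logits.each_col() - mx);
  arma::vec s = arma::sum(E, 1);
  G = E.each_col() / s;
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    loss += std::log(s(i)) + mx(i) - logits(i, lab0(i));
    G(i, lab0(i)) -= 1.0;
  }
  G *= scale / n;
  return loss / n;
}

struct EmbTrainer {
  DenseNet enc, ch, sh;
  double tau, wc, ws, lambda, lr, wd;
  int n_bins, t;
};

// [[Rcpp::export(name = ".cpp_emb_trainer_create")]]
SEXP cpp_emb_trainer_create(List enc_layers, List enc_out, List ch_layers,
                            List ch_out, List sh_layers, List sh_out,
                            double dropout, double tau, double wc, double ws,
                            double lambda, double lr, double wd, int n_bins) {
  XPtr<EmbTrainer> ptr(new EmbTrainer(), true);
  ptr->enc.init_from(enc_layers, enc_out, true, dropout);   // relu -> LN
  ptr->ch.init_from(ch_layers, ch_out, false, dropout);     // LN -> relu
  ptr->sh.init_from(sh_layers, sh_out, false, dropout);
  ptr->tau = tau; ptr->wc = wc; ptr->ws = ws; ptr->lambda = lambda;
  ptr->lr = lr; ptr->wd = wd; ptr->n_bins = n_bins; ptr->t = 0;
  return ptr;
}

// one full training step on an augmented batch (2N rows); coordinate
// labels are 2N x 3 (1-based bins), subject labels length 2N (1-based)
// [[Rcpp::export(name = ".cpp_emb_trainer_step")]]
NumericVector cpp_emb_trainer_step(SEXP trainer, const arma::mat& Xb,
                                   const arma::imat& coord_lab,
                                   const arma::ivec& subj_lab, int rng_seed) {
  XPtr<EmbTrainer> ptr(trainer);
  EmbTrainer& tr = *ptr;
  FastUnif gen(static_cast<uint64_t>(rng_seed));
  int n2 = Xb.n_rows;
  int N = n2 / 2;
  int nb = tr.n_bins;

  // encoder forward + L2 normalization
  tr.enc.forward(Xb, true, gen);
  arma::vec nrm = arma::sqrt(arma::sum(arma::square(tr.enc.out), 1));
  nrm = arma::clamp(nrm, 1e-12, arma::datum::inf);
  arma::mat Z = tr.enc.out.each_col() / nrm;

  // InfoNCE loss and gradient (rows unit-norm: 1/tau bounds the logits)
  arma::mat S = Z * Z.t() / tr.tau;
  double mx = 1.0 / tr.tau;
  arma::mat G = arma::exp(S - mx);
  G.diag().zeros();
  arma::vec ssum = arma::sum(G, 1);
  G.each_col() /= ssum;
  double l_nce = 0.0;
  for (int i = 0; i < n2; ++i) {
    int p = (i < N) ? i + N : i - N;
    l_nce += std::log(ssum(i)) + mx - S(i, p);
    G(i, p) -= 1.0;
  }
  l_nce /= n2;
  G /= n2;
  arma::mat dZ_nce = (G * Z + G.t() * Z) / tr.tau;

  // coordinate head: CE averaged over the three axes
  tr.ch.forward(Z, true, gen);
  arma::mat dlog_c(n2, 3 * nb, arma::fill::zeros);
  double l_coord = 0.0;
  for (int a = 0; a < 3; ++a) {
    arma::mat blk = tr.ch.out.cols(a * nb, (a + 1) * nb - 1);
    arma::ivec lab0 = coord_lab.col(a) - 1;
    arma::mat Ga;
    l_coord += ce_block(blk, lab0, 1.0 / 3.0, Ga) / 3.0;
    dlog_c.cols(a * nb, (a + 1) * nb - 1) = Ga;
  }
  arma::mat dZ_c = tr.ch.backward(dlog_c);

  // subject head
  tr.sh.forward(Z, true, gen);
  arma::ivec slab0 = subj_lab - 1;
  arma::mat Gs;
  double l_subj = ce_block(tr.sh.out, slab0, 1.0, Gs);
  arma::mat dZ_s = tr.sh.backward(Gs);

  // gradient reversal at the embedding boundary
  arma::mat dZ = dZ_nce - tr.lambda * (tr.wc * dZ_c + tr.ws * dZ_s);
  // back through L2 normalization
  arma::vec dot = arma::sum(dZ % Z, 1);
  arma::mat dU = (dZ - Z.each_col() % dot);
  dU.each_col() /= nrm;
  tr.enc.backward(dU);

  tr.t += 1;
  tr.enc.adam(tr.lr, tr.wd, tr.t, 1.0);
  tr.ch.adam(tr.lr, tr.wd, tr.t, tr.wc);
  tr.sh.adam(tr.lr, tr.wd, tr.t, tr.ws);

  return NumericVector::create(l_nce, l_coord, l_subj);
}

// [[Rcpp::export(name = ".cpp_emb_trainer_params")]]
List cpp_emb_trainer_params(SEXP trainer) {
  XPtr<EmbTrainer> ptr(trainer);
  return List::create(Named("encoder") = ptr->enc.export_params(),
                      Named("coord_head") = ptr->ch.export_params(),
                      Named("subject_head") = ptr->sh.export_params());
}

struct RegTrainer {
  DenseNet net;
  double wd;
  int t;
};

// [[Rcpp::export(name = ".cpp_reg_trainer_create")]]
SEXP cpp_reg_trainer_create(List layers, List out_l, double dropout, double wd) {
  XPtr<RegTrainer> ptr(new RegTrainer(), true);
  ptr->net.init_from(layers, out_l, false, dropout);   // LN -> relu blocks
  ptr->wd = wd;
  ptr->t = 0;
  return ptr;
}

// one MSE step at learning rate `lr` (cosine schedule computed in R)
// [[Rcpp::export(name = ".cpp_reg_trainer_step")]]
double cpp_reg_trainer_step(SEXP trainer, const arma::mat& Z,
                            const arma::vec& y, double lr, int rng_seed) {
  XPtr<RegTrainer> ptr(trainer);
  RegTrainer& tr = *ptr;
  FastUnif gen(static_cast<uint64_t>(rng_seed));
  tr.net.forward(Z, true, gen);
  arma::vec err = tr.net.out.col(0) - y;
  double loss = arma::mean(arma::square(err));
  arma::mat d_out = 2.0 * err / static_cast<double>(err.n_elem);
  tr.net.backward(d_out);
  tr.t += 1;
  tr.net.adam(lr, tr.wd, tr.t, 1.0);
  return loss;
}

// [[Rcpp::export(name = ".cpp_reg_trainer_params")]]
List cpp_reg_trainer_params(SEXP trainer) {
  XPtr<RegTrainer> ptr(trainer);
  return ptr->net.export_params();
}
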