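// Minimal CNN engine: a static DAG of conv / batch-norm / relu / max-pool /
// concat / global-max nodes with reverse-mode gradients and an Adam update,
// all in single precision so the convolution GEMMs run through BLAS sgemm.
// The graph is lowered from an ArchSpec on the R side; this file knows
// nothing about particular architectures.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>
#include <string>
#include <map>

using arma::fmat;
using arma::fvec;
using arma::uword;

enum Kind { K_INPUT = 0, K_CONV, K_BN, K_RELU, K_POOL, K_CONCAT, K_GMAX };

struct Node {
  int kind = K_INPUT;
  std::string name;
  std::vector<int> par;  // parent node ids (0-based)
  int k = 0;             // conv kernel size (1 or 3)
  int cin = 0, cout = 0; // conv channels
  int ch = 0;            // output channel count (all kinds)
};

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;
static const float ADAM_B1 = 0.9f;
static const float ADAM_B2 = 0.999f;
static const float ADAM_EPS = 1e-8f;

class Net {
public:
  std::vector<Node> nd;

  // conv parameters, indexed by node id (empty mats for non-conv nodes)
  std::vector<fmat> W, gW, mW, vW;
  // batch-norm parameters
  std::vector<fvec> gam, bet, ggam, gbet;
  std::vector<fvec> mgam, vgam, mbet, vbet;
  std::vector<fvec> rmean, rvar;   // running statistics for eval mode
  long adam_t = 0;

  // per-forward caches
  std::vector<fmat> act, grd;
  std::vector<int> aH, aW;
  std::vector<fvec> bn_mu, bn_istd;
  std::vector<arma::umat> pool_idx;  // (C, HWout*N) source pixel within image
  std::vector<arma::umat> gmax_idx;  // (C, N) argmax pixel within image
  int N = 0;
  bool last_train = false;
  bool have_grads = false;
  fmat colbuf;  // scratch for im2col, reused across convs

  explicit Net(const std::vector<Node>& nodes) : nd(nodes) {
    size_t n = nd.size();
    W.resize(n); gW.resize(n); mW.resize(n); vW.resize(n);
    gam.resize(n); bet.resize(n); ggam.resize(n); gbet.resize(n);
    mgam.resize(n); vgam.resize(n); mbet.resize(n); vbet.resize(n);
    rmean.resize(n); rvar.resize(n);
    act.resize(n); grd.resize(n);
    aH.resize(n); aW.resize(n);
    bn_mu.resize(n); bn_istd.resize(n);
    pool_idx.resize(n); gmax_idx.resize(n);
    for (size_t i = 0; i < n; ++i) {
      const Node& o = nd[i];
      if (o.kind == K_CONV) {
        int cols = o.k * o.k * o.cin;
        W[i].zeros(o.cout, cols);
        mW[i].zeros(o.cout, cols);
        vW[i].zeros(o.cout, cols);
      } else if (o.kind == K_BN) {
        gam[i].ones(o.ch); bet[i].zeros(o.ch);
        mgam[i].zeros(o.ch); vgam[i].zeros(o.ch);
        mbet[i].zeros(o.ch); vbet[i].zeros(o.ch);
        rmean[i].zeros(o.ch); rvar[i].ones(o.ch);
      }
    }
  }

  int num_classes() const { return nd.back().ch; }

  // ---- im2col for 3x3, pad 1, stride 1; pixel index = col*H + row ----
  // Writes every element of B exactly once (borders zeroed in place), so no
  // full-buffer pre-zeroing pass is needed.
  static void im2col3(const fmat& A, int H, int Wd, int Nimg, fmat& B) {
    int C = A.n_rows, HW = H * Wd;
    B.set_size(9 * (size_t)C, (size_t)HW * Nimg);
    const float* ap = A.memptr();
    float* bp = B.memptr();
    size_t bld = 9 * (size_t)C;  // column stride of B
    for (int g = 0; g < 9; ++g) {
      int dr = g % 3 - 1, dc = g / 3 - 1;
      for (int n = 0; n < Nimg; ++n) {
        size_t base = (size_t)n * HW;
        for (int c0 = 0; c0 < Wd; ++c0) {
          int cs = c0 + dc;
          float* dst0 = bp + (base + (size_t)c0 * H) * bld + (size_t)g * C;
          if (cs < 0 || cs >= Wd) {
            float* dst = dst0;
            for (int r = 0; r < H; ++r, dst += bld)
              std::memset(dst, 0, C * sizeof(float));
            continue;
          }
          int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
          float* dst = dst0;
          for (int r = 0; r < r0; ++r, dst += bld)
            std::memset(dst, 0, C * sizeof(float));
          const float* src = ap + (base + (size_t)cs * H + r0 + dr) * (size_t)C;
          if (C == 1) {
            for (int r = r0; r <= r1; ++r, dst += bld, ++src) *dst = *src;
          } else {
            for (int r = r0; r <= r1; ++r, dst += bld, src += C)
              std::memcpy(dst, src, C * sizeof(float));
          }
          for (int r = r1 + 1; r < H; ++r, dst += bld)
            std::memset(dst, 0, C * sizeof(float));
        }
      }
    }
  }

  static void col2im3_add(const fmat& B, int H, int Wd, int Nimg, fmat& dA) {
    int C = dA.n_rows, HW = H * Wd;
    const float* bp = B.memptr();
    float* ap = dA.memptr();
    size_t bld = 9 * (size_t)C;
    for (int g = 0; g < 9; ++g) {
      int dr = g % 3 - 1, dc = g / 3 - 1;
      for (int n = 0; n < Nimg; ++n) {
        size_t base = (size_t)n * HW;
        for (int c0 = 0; c0 < Wd; ++c0) {
          int cs = c0 + dc;
          if (cs < 0 || cs >= Wd) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
          if (r0 > r1) continue;
          size_t bcol = base + (size_t)c0 * H + r0;
          size_t acol = base + (size_t)cs * H + r0 + dr;
          const float* src = bp + bcol * bld + (size_t)g * C;
          float* dst = ap + acol * (size_t)C;
          for (int r = r0; r <= r1; ++r, src += bld, dst += C)
            for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }

  void forward(const fmat& x, int H, int Wd, int Nimg, bool train) {
    N = Nimg;
    last_train = train;
    have_grads = false;
    act[0] = x; aH[0] = H; aW[0] = Wd;
    for (size_t i = 1; i < nd.size(); ++i) {
      Node& o = nd[i];
      int p = o.par.empty() ? -1 : o.par[0];
      switch (o.kind) {
      case K_CONV: {
        aH[i] = aH[p]; aW[i] = aW[p];
        if (o.k == 1) {
          act[i] = W[i] * act[p];
        } else {
          im2col3(act[p], aH[p], aW[p], N, colbuf);
          act[i] = W[i] * colbuf;
        }
        break;
      }
      case K_BN: {
        aH[i] = aH[p]; aW[i] = aW[p];
        const fmat& X = act[p];
        float M = (float)X.n_cols;
        if (train) {
          fvec mu = arma::mean(X, 1);
          fvec var = arma::mean(arma::square(X), 1) - arma::square(mu);
          var.transform([](float v) { return v < 0.0f ? 0.0f : v; });
          fvec istd = 1.0f / arma::sqrt(var + BN_EPS);
          bn_mu[i] = mu; bn_istd[i] = istd;
          float unb = M > 1.5f ? M / (M - 1.0f) : 1.0f;
          rmean[i] = (1.0f - BN_MOMENTUM) * rmean[i] + BN_MOMENTUM * mu;
          rvar[i] = (1.0f - BN_MOMENTUM) * rvar[i] + BN_MOMENTUM * (unb * var);
          fmat Y = X;
          Y.each_col() -= mu;
          Y.each_col() %= istd % gam[i];
          Y.each_col() += bet[i];
          act[i] = std::move(Y);
        } else {
          fvec istd = 1.0f / arma::sqrt(rvar[i] + BN_EPS);
          bn_mu[i] = rmean[i]; bn_istd[i] = istd;
          fmat Y = X;
          Y.each_col() -= rmean[i];
          Y.each_col() %= istd % gam[i];
          Y.each_col() += bet[i];
          act[i] = std::move(Y);
        }
        break;
      }
      case K_RELU: {
        aH[i] = aH[p]; aW[i] = aW[p];
        act[i] = act[p];
        act[i].transform([](float v) { return v > 0.0f ? v : 0.0f; });
        break;
      }
      case K_POOL: {
        int H0 = aH[p], W0 = aW[p];
        int Ho = H0 / 2, Wo = W0 / 2;
        aH[i] = Ho; aW[i] = Wo;
        int C = act[p].n_rows;
        int HWo = Ho * Wo, HW0 = H0 * W0;
        act[i].set_size(C, (size_t)HWo * N);
        pool_idx[i].set_size(C, (size_t)HWo * N);
        const float* xp = act[p].memptr();
        float* yp = act[i].memptr();
        uword* ip = pool_idx[i].memptr();
        for (int n = 0; n < N; ++n) {
          size_t ob = (size_t)n * HWo, ib = (size_t)n * HW0;
          for (int oc = 0; oc < Wo; ++oc) {
            for (int orow = 0; orow < Ho; ++orow) {
              size_t out = ob + (size_t)oc * Ho + orow;
              size_t p00 = ib + (size_t)(2 * oc) * H0 + 2 * orow;
              size_t cand[4] = { p00, p00 + 1, p00 + (size_t)H0, p00 + (size_t)H0 + 1 };
              const float* s0 = xp + cand[0] * C;
              const float* s1 = xp + cand[1] * C;
              const float* s2 = xp + cand[2] * C;
              const float* s3 = xp + cand[3] * C;
              float* dst = yp + out * C;
              uword* idx = ip + out * C;
              for (int c = 0; c < C; ++c) {
                float best = s0[c]; size_t bi = cand[0];
                if (s1[c] > best) { best = s1[c]; bi = cand[1]; }
                if (s2[c] > best) { best = s2[c]; bi = cand[2]; }
                if (s3[c] > best) { best = s3[c]; bi = cand[3]; }
                dst[c] = best;
                idx[c] = bi;
              }
            }
          }
        }
        break;
      }
      case K_CONCAT: {
        aH[i] = aH[p]; aW[i] = aW[p];
        fmat Y = act[o.par[0]];
        for (size_t q = 1; q < o.par.size(); ++q)
          Y = arma::join_cols(Y, act[o.par[q]]);
        act[i] = std::move(Y);
        break;
      }
      case K_GMAX: {
        int HW = aH[p] * aW[p];
        aH[i] = 1; aW[i] = 1;
        int C = act[p].n_rows;
        act[i].set_size(C, N);
        gmax_idx[i].set_size(C, N);
        const float* xp = act[p].memptr();
        float* yp = act[i].memptr();
        uword* ip = gmax_idx[i].memptr();
        for (int n = 0; n < N; ++n) {
          size_t ib = (size_t)n * HW;
          for (int c = 0; c < C; ++c) {
            yp[(size_t)n * C + c] = xp[ib * C + c];
            ip[(size_t)n * C + c] = ib;
          }
          for (int q = 1; q < HW; ++q) {
            const float* col = xp + (ib + q) * C;
            for (int c = 0; c < C; ++c) {
              if (col[c] > yp[(size_t)n * C + c]) {
                yp[(size_t)n * C + c] = col[c];
                ip[(size_t)n * C + c] = ib + q;
              }
            }
          }
        }
        break;
      }
      default: Rcpp::stop("unknown node kind in forward");
      }
    }
  }

  void backward(const fmat& dout) {
    size_t n = nd.size();
    for (size_t i = 0; i < n; ++i) {
      grd[i].zeros(act[i].n_rows, act[i].n_cols);
      if (nd[i].kind == K_CONV) gW[i].zeros(W[i].n_rows, W[i].n_cols);
      if (nd[i].kind == K_BN) { ggam[i].zeros(nd[i].ch); gbet[i].zeros(nd[i].ch); }
    }
    grd[n - 1] = dout;
    for (size_t ii = n; ii-- > 1; ) {
      Node& o = nd[ii];
      int p = o.par.empty() ? -1 : o.par[0];
      const fmat& dy = grd[ii];
      switch (o.kind) {
      case K_CONV: {
        if (o.k == 1) {
          gW[ii] += dy * act[p].t();
          if (nd[p].kind != K_INPUT) grd[p] += W[ii].t() * dy;
        } else {
          im2col3(act[p], aH[p], aW[p], N, colbuf);
          gW[ii] += dy * colbuf.t();
          if (nd[p].kind != K_INPUT) {
            fmat dbuf = W[ii].t() * dy;
            col2im3_add(dbuf, aH[p], aW[p], N, grd[p]);
          }
        }
        break;
      }
      case K_BN: {
        const fmat& X = act[p];
        float M = (float)X.n_cols;
        if (last_train) {
          fmat xhat = X;
          xhat.each_col() -= bn_mu[ii];
          xhat.each_col() %= bn_istd[ii];
          ggam[ii] = arma::sum(dy % xhat, 1);
          gbet[ii] = arma::sum(dy, 1);
          fmat dxhat = dy;
          dxhat.each_col() %= gam[ii];
          fvec s1 = arma::sum(dxhat, 1) / M;
          fvec s2 = arma::sum(dxhat % xhat, 1) / M;
          fmat dX = dxhat;
          dX.each_col() -= s1;
          dX -= xhat.each_col() % s2;
          dX.each_col() %= bn_istd[ii];
          grd[p] += dX;
        } else {
          fmat xhat = X;
          xhat.each_col() -= bn_mu[ii];
          xhat.each_col() %= bn_istd[ii];
          ggam[ii] = arma::sum(dy % xhat, 1);
          gbet[ii] = arma::sum(dy, 1);
          fmat dX = dy;
          dX.each_col() %= gam[ii] % bn_istd[ii];
          grd[p] += dX;
        }
        break;
      }
      case K_RELU: {
        fmat dX = dy;
        const fmat& Y = act[ii];
        for (size_t q = 0; q < Y.n_elem; ++q)
          if (Y(q) <= 0.0f) dX(q) = 0.0f;
        grd[p] += dX;
        break;
      }
      case K_POOL: {
        int C = act[ii].n_rows;
        size_t HWoN = act[ii].n_cols;
        for (size_t col = 0; col < HWoN; ++col)
          for (int c = 0; c < C; ++c)
            grd[p](c, pool_idx[ii](c, col)) += dy(c, col);
        break;
      }
      case K_CONCAT: {
        uword r0 = 0;
        for (size_t q = 0; q < o.par.size(); ++q) {
          int pq = o.par[q];
          uword rc = act[pq].n_rows;
          grd[pq] += dy.rows(r0, r0 + rc - 1);
          r0 += rc;
        }
        break;
      }
      case K_GMAX: {
        int C = act[ii].n_rows;
        for (int n2 = 0; n2 < N; ++n2)
          for (int c = 0; c < C; ++c)
            grd[p](c, gmax_idx[ii](c, n2)) += dy(c, n2);
        break;
      }
      default: break;
      }
    }
    have_grads = true;
  }

  void adam_step(double lr) {
    adam_t += 1;
    float c1 = 1.0f - std::pow(ADAM_B1, (float)adam_t);
    float c2 = 1.0f - std::pow(ADAM_B2, (float)adam_t);
    float flr = (float)lr;
    for (size_t i = 0; i < nd.size(); ++i) {
      if (nd[i].kind == K_CONV) {
        mW[i] = ADAM_B1 * mW[i] + (1.0f - ADAM_B1) * gW[i];
        vW[i] = ADAM_B2 * vW[i] + (1.0f - ADAM_B2) * arma::square(gW[i]);
        W[i] -= flr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + ADAM_EPS);
      } else if (nd[i].kind == K_BN) {
        mgam[i] = ADAM_B1 * mgam[i] + (1.0f - ADAM_B1) * ggam[i];
        vgam[i] = ADAM_B2 * vgam[i] + (1.0f - ADAM_B2) * arma::square(ggam[i]);
        gam[i] -= flr * (mgam[i] / c1) / (arma::sqrt(vgam[i] / c2) + ADAM_EPS);
        mbet[i] = ADAM_B1 * mbet[i] + (1.0f - ADAM_B1) * gbet[i];
        vbet[i] = ADAM_B2 * vbet[i] + (1.0f - ADAM_B2) * arma::square(gbet[i]);
        bet[i] -= flr * (mbet[i] / c1) / (arma::sqrt(vbet[i] / c2) + ADAM_EPS);
      }
    }
  }

  void release_caches() {
    for (size_t i = 0; i < nd.size(); ++i) {
      act[i].reset(); grd[i].reset();
      pool_idx[i].reset(); gmax_idx[i].reset();
    }
    colbuf.reset();
  }
};

typedef Rcpp::XPtr<Net> NetPtr;

static std::vector<Node> parse_ir(Rcpp::List ir) {
  std::vector<Node> out;
  std::map<std::string, int> kinds = {
    {"input", K_INPUT}, {"conv", K_CONV}, {"bn", K_BN}, {"relu", K_RELU},
    {"pool", K_POOL}, {"concat", K_CONCAT}, {"gmax", K_GMAX}
  };
  for (int i = 0; i < ir.size(); ++i) {
    Rcpp::List e = ir[i];
    Node o;
    o.name = Rcpp::as<std::string>(e["name"]);
    std::string kd = Rcpp::as<std::string>(e["kind"]);
    auto it = kinds.find(kd);
    if (it == kinds.end()) Rcpp::stop("unknown node kind: %s", kd.c_str());
    o.kind = it->second;
    if (e.containsElementNamed("parents")) {
      Rcpp::IntegerVector pv = e["parents"];
      for (int q = 0; q < pv.size(); ++q) o.par.push_back(pv[q] - 1);
    }
    if (o.kind == K_CONV) {
      o.k = Rcpp::as<int>(e["kernel"]);
      o.cin = Rcpp::as<int>(e["in"]);
      o.cout = Rcpp::as<int>(e["out"]);
    }
    o.ch = Rcpp::as<int>(e["channels"]);
    out.push_back(o);
  }
  return out;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(Rcpp::List ir) {
  NetPtr p(new Net(parse_ir(ir)), true);
  return p;
}

// input x: numeric array dim (H, W, N); single input channel
static fmat input_to_fmat(const Rcpp::NumericVector& x, int& H, int& Wd, int& Nimg) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("input must be an (H, W, N) array");
  H = d[0]; Wd = d[1]; Nimg = d[2];
  fmat A(1, (size_t)H * Wd * Nimg);
  const double* src = x.begin();
  // R array is column-major: index r + H*c + H*W*n matches pixel = c*H + r
  for (size_t q = 0; q < (size_t)H * Wd * Nimg; ++q) A(0, q) = (float)src[q];
  return A;
}

// [[Rcpp::export(name = ".net_forward")]]
Rcpp::NumericMatrix net_forward(SEXP ptr, Rcpp::NumericVector x, bool train) {
  NetPtr net(ptr);
  int H, Wd, Nimg;
  fmat A = input_to_fmat(x, H, Wd, Nimg);
  net->forward(A, H, Wd, Nimg, train);
  const fmat& L = net->act.back();   // (K, N)
  Rcpp::NumericMatrix out(Nimg, L.n_rows);
  for (int n = 0; n < Nimg; ++n)
    for (uword c = 0; c < L.n_rows; ++c)
      out(n, c) = L(c, n);
  return out;
}

// [[Rcpp::export(name = ".net_train_batch")]]
Rcpp::List net_train_batch(SEXP ptr, Rcpp::NumericVector x,
                           Rcpp::IntegerVector labels, double lr) {
  NetPtr net(ptr);
  int H, Wd, Nimg;
  fmat A = input_to_fmat(x, H, Wd, Nimg);
  if (labels.size() != Nimg) Rcpp::stop("labels length must equal batch size");
  net->forward(A, H, Wd, Nimg, true);
  const fmat& L = net->act.back();
  int K = L.n_rows;
  fmat P(K, Nimg);
  double loss = 0.0;
  for (int n = 0; n < Nimg; ++n) {
    int y = labels[n];
    if (y < 0 || y >= K) Rcpp::stop("label out of range [0, K)");
    float mx = L.col(n).max();
    fvec e = arma::exp(L.col(n) - mx);
    float Z = arma::accu(e);
    P.col(n) = e / Z;
    loss += -(double)(L(y, n) - mx - std::log(Z));
  }
  loss /= Nimg;
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
  fmat dL = P;
  for (int n = 0; n < Nimg; ++n) dL(labels[n], n) -= 1.0f;
  dL /= (float)Nimg;
  // logits snapshot before backward/update
  Rcpp::NumericMatrix logits(Nimg, K);
  for (int n = 0; n < Nimg; ++n)
    for (int c = 0; c < K; ++c) logits(n, c) = L(c, n);
  net->backward(dL);
  net->adam_step(lr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("logits") = logits);
}

// [[Rcpp::export(name = ".net_eval_loss")]]
Rcpp::List net_eval_loss(SEXP ptr, Rcpp::NumericVector x,
                         Rcpp::IntegerVector labels) {
  NetPtr net(ptr);
  int H, Wd, Nimg;
  fmat A = input_to_fmat(x, H, Wd, Nimg);
  net->forward(A, H, Wd, Nimg, false);
  const fmat& L = net->act.back();
  int K = L.n_rows;
  double loss = 0.0;
  Rcpp::NumericMatrix logits(Nimg, K);
  for (int n = 0; n < Nimg; ++n) {
    int y = labels[n];
    if (y < 0 || y >= K) Rcpp::stop("label out of range [0, K)");
    float mx = L.col(n).max();
    fvec e = arma::exp(L.col(n) - mx);
    loss += -(double)(L(y, n) - mx - std::log(arma::accu(e)));
    for (int c = 0; c < K; ++c) logits(n, c) = L(c, n);
  }
  loss /= Nimg;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("logits") = logits);
}

// [[Rcpp::export(name = ".net_get_params")]]
Rcpp::List net_get_params(SEXP ptr) {
  NetPtr net(ptr);
  Rcpp::List out;
  for (size_t i = 0; i < net->nd.size(); ++i) {
    const Node& o = net->nd[i];
    if (o.kind == K_CONV) {
      out[o.name + ".W"] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net->W[i]));
    } else if (o.kind == K_BN) {
      out[o.name + ".gamma"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->gam[i]));
      out[o.name + ".beta"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->bet[i]));
      out[o.name + ".running_mean"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->rmean[i]));
      out[o.name + ".running_var"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->rvar[i]));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP ptr, Rcpp::List params) {
  NetPtr net(ptr);
  for (size_t i = 0; i < net->nd.size(); ++i) {
    const Node& o = net->nd[i];
    if (o.kind == K_CONV) {
      std::string nm = o.name + ".W";
      if (!params.containsElementNamed(nm.c_str()))
        Rcpp::stop("missing parameter tensor: %s", nm.c_str());
      arma::mat Wd = Rcpp::as<arma::mat>(params[nm]);
      if (Wd.n_rows != net->W[i].n_rows || Wd.n_cols != net->W[i].n_cols)
        Rcpp::stop("shape mismatch for %s", nm.c_str());
      net->W[i] = arma::conv_to<fmat>::from(Wd);
    } else if (o.kind == K_BN) {
      for (const std::string& suf : {".gamma", ".beta", ".running_mean", ".running_var"}) {
        std::string nm = o.name + suf;
        if (!params.containsElementNamed(nm.c_str()))
          Rcpp::stop("missing parameter tensor: %s", nm.c_str());
        arma::vec v = Rcpp::as<arma::vec>(params[nm]);
        if ((int)v.n_elem != o.ch) Rcpp::stop("length mismatch for %s", nm.c_str());
        fvec fv = arma::conv_to<fvec>::from(v);
        if (suf == ".gamma") net->gam[i] = fv;
        else if (suf == ".beta") net->bet[i] = fv;
        else if (suf == ".running_mean") net->rmean[i] = fv;
        else net->rvar[i] = fv;
      }
    }
  }
}

// [[Rcpp::export(name = ".net_get_grads")]]
Rcpp::List net_get_grads(SEXP ptr) {
  NetPtr net(ptr);
  if (!net->have_grads) Rcpp::stop("no gradients available; run a training step first");
  Rcpp::List out;
  for (size_t i = 0; i < net->nd.size(); ++i) {
    const Node& o = net->nd[i];
    if (o.kind == K_CONV) {
      out[o.name + ".W"] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net->gW[i]));
    } else if (o.kind == K_BN) {
      out[o.name + ".gamma"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->ggam[i]));
      out[o.name + ".beta"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->gbet[i]));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".net_adam_reset")]]
void net_adam_reset(SEXP ptr) {
  NetPtr net(ptr);
  net->adam_t = 0;
  for (size_t i = 0; i < net->nd.size(); ++i) {
    if (net->nd[i].kind == K_CONV) { net->mW[i].zeros(); net->vW[i].zeros(); }
    if (net->nd[i].kind == K_BN) {
      net->mgam[i].zeros(); net->vgam[i].zeros();
      net->mbet[i].zeros(); net->vbet[i].zeros();
    }
  }
}

// Forward one image in eval mode, backward from a one-hot class gradient,
// and return the feature maps and gradients at a named node (for GradCAM).
// [[Rcpp::export(name = ".net_capture")]]
Rcpp::List net_capture(SEXP ptr, Rcpp::NumericVector x, int target_class,
                       std::string node_name) {
  NetPtr net(ptr);
  int H, Wd, Nimg;
  fmat A = input_to_fmat(x, H, Wd, Nimg);
  if (Nimg != 1) Rcpp::stop("GradCAM capture expects a single image");
  int id = -1;
  for (size_t i = 0; i < net->nd.size(); ++i)
    if (net->nd[i].name == node_name) { id = (int)i; break; }
  if (id < 0) Rcpp::stop("unknown layer id: %s", node_name.c_str());
  net->forward(A, H, Wd, 1, false);
  int K = net->num_classes();
  if (target_class < 0 || target_class >= K)
    Rcpp::stop("target class out of range [0, K)");
  fmat dL(K, 1, arma::fill::zeros);
  dL(target_class, 0) = 1.0f;
  net->backward(dL);
  int h = net->aH[id], w = net->aW[id];
  int C = net->act[id].n_rows;
  Rcpp::NumericVector feat((size_t)h * w * C), grad((size_t)h * w * C);
  // output as (h, w, C) arrays; pixel index = col*h + row
  for (int c = 0; c < C; ++c)
    for (size_t q = 0; q < (size_t)h * w; ++q) {
      feat[(size_t)c * h * w + q] = net->act[id](c, q);
      grad[(size_t)c * h * w + q] = net->grd[id](c, q);
    }
  feat.attr("dim") = Rcpp::IntegerVector::create(h, w, C);
  grad.attr("dim") = Rcpp::IntegerVector::create(h, w, C);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("features") = feat,
    Rcpp::Named("gradients") = grad,
    Rcpp::Named("logits") = Rcpp::wrap(arma::conv_to<arma::vec>::from(net->act.back().col(0))));
  net->release_caches();
  return out;
}

// [[Rcpp::export(name = ".net_node_names")]]
Rcpp::CharacterVector net_node_names(SEXP ptr) {
  NetPtr net(ptr);
  Rcpp::CharacterVector out(net->nd.size());
  for (size_t i = 0; i < net->nd.size(); ++i) out[i] = net->nd[i].name;
  return out;
}

// [[Rcpp::export(name = ".net_release")]]
void net_release(SEXP ptr) {
  NetPtr net(ptr);
  net->release_caches();
}
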