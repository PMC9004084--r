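// Fused training step for the fixed 3-conv + maxpool + dense-sigmoid
// network: forward, weighted binary cross-entropy and full backward pass
// for one minibatch. Single-precision internals (sgemm) for speed; weights
// and gradients cross the R boundary as doubles. Dropout masks come from a
// per-batch seed so runs are reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ConvDims { uword outC, inC, K; };

static fmat im2colF(const fcube& X, const uword K) {
  const uword C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword T = L - K + 1;
  fmat out(C * K, T * B);
  for (uword b = 0; b < B; ++b) {
    const fmat& S = X.slice(b);
    for (uword t = 0; t < T; ++t)
      std::memcpy(out.colptr(t + b * T), S.colptr(t),
                  C * K * sizeof(float));
  }
  return out;
}

static fmat wmatF(const Rcpp::NumericVector& W, ConvDims d) {
  // R array outC x inC x K -> outC x (inC*K)
  fmat out(d.outC, d.inC * d.K);
  const double* p = W.begin();
  for (uword i = 0; i < d.outC * d.inC * d.K; ++i)
    out((i % (d.outC * d.inC)) % d.outC,
        (i / (d.outC * d.inC)) * d.inC + (i % (d.outC * d.inC)) / d.outC)
      = (float)p[i];
  return out;
}

static void dropoutMask(fcube& A, float rate, std::mt19937& rng,
                        fcube& mask) {
  std::uniform_real_distribution<float> U(0.0f, 1.0f);
  const float scale = 1.0f / (1.0f - rate);
  mask.set_size(size(A));
  float* m = mask.memptr();
  float* a = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i) {
    m[i] = (U(rng) > rate) ? scale : 0.0f;
    a[i] *= m[i];
  }
}

// forward one conv layer: returns preactivation Z (caller applies relu)
static fcube convF(const fmat& Wm, const fvec& b, const fcube& X,
                   uword K, fmat& Xcol) {
  const uword T = X.n_cols - K + 1, B = X.n_slices;
  Xcol = im2colF(X, K);
  fmat Y = Wm * Xcol;
  Y.each_col() += b;
  return fcube(Y.memptr(), Wm.n_rows, T, B);
}

static fcube convBwdXF(const fmat& Wm, const fcube& dY, uword K,
                       uword inC) {
  const uword T = dY.n_cols, B = dY.n_slices, L = T + K - 1;
  const fmat dYm(const_cast<float*>(dY.memptr()), dY.n_rows, T * B,
                 false, true);
  fmat dXcol = Wm.t() * dYm;
  fcube dX(inC, L, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    fmat& S = dX.slice(b);
    for (uword t = 0; t < T; ++t) {
      const float* src = dXcol.colptr(t + b * T);
      float* dst = S.colptr(t);
      for (uword i = 0; i < inC * K; ++i) dst[i] += src[i];
    }
  }
  return dX;
}

static Rcpp::NumericVector gradToR(const fmat& g, ConvDims d) {
  Rcpp::NumericVector out(d.outC * d.inC * d.K);
  for (uword k = 0; k < d.K; ++k)
    for (uword i = 0; i < d.inC; ++i)
      for (uword o = 0; o < d.outC; ++o)
        out[k * d.outC * d.inC + i * d.outC + o] =
          g(o, k * d.inC + i);
  out.attr("dim") =
    Rcpp::IntegerVector::create(d.outC, d.inC, d.K);
  return out;
}

// [[Rcpp::export(name = ".cnnStepC")]]
Rcpp::List cnnStepC(Rcpp::List params, const arma::cube& X,
                    const arma::vec& y, const arma::vec& w,
                    double dropout, int poolWidth, int poolStride,
                    int dropSeed) {
  std::mt19937 rng((unsigned)dropSeed);
  const uword B = X.n_slices;
  ConvDims d1, d2, d3;
  Rcpp::NumericVector W1r = params["W1"], W2r = params["W2"],
    W3r = params["W3"];
  Rcpp::IntegerVector s1 = W1r.attr("dim"), s2 = W2r.attr("dim"),
    s3 = W3r.attr("dim");
  d1 = {(uword)s1[0], (uword)s1[1], (uword)s1[2]};
  d2 = {(uword)s2[0], (uword)s2[1], (uword)s2[2]};
  d3 = {(uword)s3[0], (uword)s3[1], (uword)s3[2]};
  fmat W1 = wmatF(W1r, d1), W2 = wmatF(W2r, d2), W3 = wmatF(W3r, d3);
  fvec b1 = conv_to<fvec>::from(
    Rcpp::as<vec>(params["b1"]));
  fvec b2 = conv_to<fvec>::from(Rcpp::as<vec>(params["b2"]));
  fvec b3 = conv_to<fvec>::from(Rcpp::as<vec>(params["b3"]));
  fvec wd = conv_to<fvec>::from(Rcpp::as<vec>(params["wd"]));
  float bd = (float)Rcpp::as<double>(params["bd"]);
  fcube Xf = conv_to<fcube>::from(X);

  // ---- forward ----
  fmat X1col, X2col, X3col;
  fcube Z1 = convF(W1, b1, Xf, d1.K, X1col);
  fcube A1 = clamp(Z1, 0.0f, std::numeric_limits<float>::max());
  fcube M1; dropoutMask(A1, (float)dropout, rng, M1);
  fcube Z2 = convF(W2, b2, A1, d2.K, X2col);
  fcube A2 = clamp(Z2, 0.0f, std::numeric_limits<float>::max());
  fcube M2; dropoutMask(A2, (float)dropout, rng, M2);
  fcube Z3 = convF(W3, b3, A2, d3.K, X3col);
  fcube A3 = clamp(Z3, 0.0f, std::numeric_limits<float>::max());
  fcube M3; dropoutMask(A3, (float)dropout, rng, M3);
  const uword C3 = d3.outC, T3 = A3.n_cols;
  const uword nw = T3 / (uword)poolStride;
  fcube pool(C3, nw, B);
  ucube argm(C3, nw, B);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < nw; ++t)
      for (uword c = 0; c < C3; ++c) {
        float best = -1e30f; uword bi = 0;
        for (int j = 0; j < poolWidth; ++j) {
          float v = A3(c, t * poolStride + j, b);
          if (v > best) { best = v; bi = j; }
        }
        pool(c, t, b) = best;
        argm(c, t, b) = bi;
      }
  fmat P(pool.memptr(), C3 * nw, B, false, true);
  fvec z = P.t() * wd + bd;
  fvec yhat = 1.0f / (1.0f + exp(-z));

  // ---- weighted BCE ----
  double loss = 0.0;
  const float eps = 1e-7f;
  fvec dz(B);
  for (uword i = 0; i < B; ++i) {
    float yi = (float)y[i], wi = (float)w[i];
    loss -= wi * (yi * std::log(yhat[i] + eps) +
                  (1 - yi) * std::log(1 - yhat[i] + eps));
    dz[i] = wi * (yhat[i] - yi) / (float)B;
  }

  // ---- backward ----
  fvec dwd = P * dz;
  float dbd = accu(dz);
  fmat dPm = wd * dz.t();            // D x B
  fcube dA3(C3, T3, B, fill::zeros);
  {
    const fcube dPool(dPm.memptr(), C3, nw, B, false, true);
    for (uword b = 0; b < B; ++b)
      for (uword t = 0; t < nw; ++t)
        for (uword c = 0; c < C3; ++c)
          dA3(c, t * poolStride + argm(c, t, b), b) = dPool(c, t, b);
  }
  dA3 %= M3;
  fcube dZ3 = dA3;
  dZ3.elem(find(Z3 <= 0)).zeros();
  fmat dZ3m(dZ3.memptr(), C3, dZ3.n_cols * B, false, true);
  fmat g3 = dZ3m * X3col.t();
  fvec gb3 = sum(dZ3m, 1);
  fcube dA2 = convBwdXF(W3, dZ3, d3.K, d3.inC);
  dA2 %= M2;
  fcube dZ2 = dA2;
  dZ2.elem(find(Z2 <= 0)).zeros();
  fmat dZ2m(dZ2.memptr(), d2.outC, dZ2.n_cols * B, false, true);
  fmat g2 = dZ2m * X2col.t();
  fvec gb2 = sum(dZ2m, 1);
  fcube dA1 = convBwdXF(W2, dZ2, d2.K, d2.inC);
  dA1 %= M1;
  fcube dZ1 = dA1;
  dZ1.elem(find(Z1 <= 0)).zeros();
  fmat dZ1m(dZ1.memptr(), d1.outC, dZ1.n_cols * B, false, true);
  fmat g1 = dZ1m * X1col.t();
  fvec gb1 = sum(dZ1m, 1);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("yhat") = conv_to<vec>::from(yhat),
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = gradToR(g1, d1),
      Rcpp::Named("b1") = conv_to<vec>::from(gb1),
      Rcpp::Named("W2") = gradToR(g2, d2),
      Rcpp::Named("b2") = conv_to<vec>::from(gb2),
      Rcpp::Named("W3") = gradToR(g3, d3),
      Rcpp::Named("b3") = conv_to<vec>::from(gb3),
      Rcpp::Named("wd") = conv_to<vec>::from(dwd),
      Rcpp::Named("bd") = (double)dbd));
}

// Inference-only forward pass (no dropout), returning sigmoid outputs.
// [[Rcpp::export(name = ".cnnPredictC")]]
arma::vec cnnPredictC(Rcpp::List params, const arma::cube& X,
                      int poolWidth, int poolStride) {
  ConvDims d1, d2, d3;
  Rcpp::NumericVector W1r = params["W1"], W2r = params["W2"],
    W3r = params["W3"];
  Rcpp::IntegerVector s1 = W1r.attr("dim"), s2 = W2r.attr("dim"),
    s3 = W3r.attr("dim");
  d1 = {(uword)s1[0], (uword)s1[1], (uword)s1[2]};
  d2 = {(uword)s2[0], (uword)s2[1], (uword)s2[2]};
  d3 = {(uword)s3[0], (uword)s3[1], (uword)s3[2]};
  fmat W1 = wmatF(W1r, d1), W2 = wmatF(W2r, d2), W3 = wmatF(W3r, d3);
  fvec b1 = conv_to<fvec>::from(Rcpp::as<vec>(params["b1"]));
  fvec b2 = conv_to<fvec>::from(Rcpp::as<vec>(params["b2"]));
  fvec b3 = conv_to<fvec>::from(Rcpp::as<vec>(params["b3"]));
  fvec wd = conv_to<fvec>::from(Rcpp::as<vec>(params["wd"]));
  float bd = (float)Rcpp::as<double>(params["bd"]);
  fcube Xf = conv_to<fcube>::from(X);
  fmat c1, c2, c3;
  fcube A1 = convF(W1, b1, Xf, d1.K, c1);
  A1 = clamp(A1, 0.0f, std::numeric_limits<float>::max());
  fcube A2 = convF(W2, b2, A1, d2.K, c2);
  A2 = clamp(A2, 0.0f, std::numeric_limits<float>::max());
  fcube A3 = convF(W3, b3, A2, d3.K, c3);
  A3 = clamp(A3, 0.0f, std::numeric_limits<float>::max());
  const uword B = X.n_slices, C3 = d3.outC, T3 = A3.n_cols;
  const uword nw = T3 / (uword)poolStride;
  fmat P(C3 * nw, B);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < nw; ++t)
      for (uword c = 0; c < C3; ++c) {
        float best = -1e30f;
        for (int j = 0; j < poolWidth; ++j)
          best = std::max(best, A3(c, t * poolStride + j, b));
        P(t * C3 + c, b) = best;
      }
  fvec z = P.t() * wd + bd;
  return conv_to<vec>::from(1.0f / (1.0f + exp(-z)));
}
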