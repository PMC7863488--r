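#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
using namespace Rcpp;

// CBOW-style stochastic gradient trainer over 3-token triple sentences.
//
// Both weight matrices are stored size x n so a token's vector is a
// contiguous column: W1t column j is token j's input (entity) vector, W2
// column j its output vector. Samples are (context1, context2, target)
// vocabulary indices, 0-based. The hidden vector is the SUM of the two
// context input vectors, matching f(x1,x2) = softmax((x1+x2) W1 W2).
//
// The full-softmax update is three BLAS-2 operations per sample:
//   u  = W2' h        (scores over the vocabulary)
//   dh = W2 e         (back-propagated error, e = softmax(u) - onehot(t))
//   W2 -= lr h e'     (rank-1 output update)
//
// Learning rate decays linearly from lr_initial to lr_final across the
// total number of updates. Shuffling and negative draws use R's RNG, so a
// run is bit-for-bit reproducible under set.seed().

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List sgd_train_cpp(NumericMatrix W1t, NumericMatrix W2, IntegerMatrix samples,
                   int iters, double lr_initial, double lr_final,
                   bool negative_sampling, int k_neg) {
  const int size = W1t.nrow();
  const int n = W1t.ncol();
  const int m = samples.nrow();
  if (W2.nrow() != size || W2.ncol() != n)
    stop("weight matrix shapes inconsistent");
  if (m == 0) stop("empty training sample set");

  double *w1 = REAL(W1t), *w2 = REAL(W2);
  std::vector<double> h(size), dh(size), u(n), e(n);
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;

  const double total_updates = std::max(1.0, (double)iters * m - 1.0);
  double update = 0.0;
  NumericVector epoch_loss(iters);
  const int one = 1;
  const double d_one = 1.0, d_zero = 0.0;

  for (int epoch = 0; epoch < iters; ++epoch) {
    // Fisher-Yates shuffle, fixed per-epoch rule on R's RNG stream.
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double loss_sum = 0.0;

    for (int s = 0; s < m; ++s) {
      const int row = order[s];
      const int c1 = samples(row, 0), c2 = samples(row, 1), t = samples(row, 2);
      if (c1 < 0 || c1 >= n || c2 < 0 || c2 >= n || t < 0 || t >= n)
        stop("sample index out of range");
      const double lr =
          lr_initial + (lr_final - lr_initial) * (update / total_updates);
      update += 1.0;

      double *v1 = w1 + (size_t)c1 * size, *v2 = w1 + (size_t)c2 * size;
      for (int d = 0; d < size; ++d) h[d] = v1[d] + v2[d];

      if (!negative_sampling) {
        F77_CALL(dgemv)("T", &size, &n, &d_one, w2, &size, h.data(), &one,
                        &d_zero, u.data(), &one FCONE);
        double umax = u[0];
        for (int j = 1; j < n; ++j) if (u[j] > umax) umax = u[j];
        double z = 0.0;
        for (int j = 0; j < n; ++j) { e[j] = std::exp(u[j] - umax); z += e[j]; }
        const double loss = -(u[t] - umax - std::log(z));
        if (!std::isfinite(loss))
          stop("non-finite loss at epoch %d, sample %d", epoch + 1, s + 1);
        loss_sum += loss;
        const double inv_z = 1.0 / z;
        for (int j = 0; j < n; ++j) e[j] *= inv_z;
        e[t] -= 1.0;
        F77_CALL(dgemv)("N", &size, &n, &d_one, w2, &size, e.data(), &one,
                        &d_zero, dh.data(), &one FCONE);
        const double neg_lr = -lr;
        F77_CALL(dger)(&size, &n, &neg_lr, h.data(), &one, e.data(), &one,
                       w2, &size);
      } else {
        // Negative sampling on the CBOW-sum hidden vector: one positive
        // (the target) plus k uniform negatives != target.
        std::fill(dh.begin(), dh.end(), 0.0);
        for (int rep = 0; rep <= k_neg; ++rep) {
          int j;
          double label;
          if (rep == 0) { j = t; label = 1.0; }
          else {
            do { j = (int)(unif_rand() * n); } while (j == t || j >= n);
            label = 0.0;
          }
          double *col = w2 + (size_t)j * size;
          double acc = 0.0;
          for (int d = 0; d < size; ++d) acc += h[d] * col[d];
          const double sig = sigmoid(acc);
          const double ls = label > 0.5
              ? -std::log(std::max(sig, 1e-300))
              : -std::log(std::max(1.0 - sig, 1e-300));
          if (!std::isfinite(ls))
            stop("non-finite loss at epoch %d, sample %d", epoch + 1, s + 1);
          loss_sum += ls;
          const double g = sig - label;
          const double lg = lr * g;
          for (int d = 0; d < size; ++d) {
            dh[d] += g * col[d];
            col[d] -= lg * h[d];
          }
        }
      }

      for (int d = 0; d < size; ++d) {
        const double delta = lr * dh[d];
        v1[d] -= delta;
        v2[d] -= delta;
      }
    }
    epoch_loss[epoch] = loss_sum / m;
  }

  return List::create(_["W1t"] = W1t, _["W2"] = W2,
                      _["epoch_loss"] = epoch_loss);
}
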