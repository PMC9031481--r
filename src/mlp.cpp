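// Single-hidden-layer sigmoid MLP trained by online backpropagation with
// momentum, reproducing the behavioral contract of the classic Weka-style
// perceptron: squared-error gradient, per-epoch example shuffling, weights
// initialized uniformly in (-0.5, 0.5) from an integer seed.  A private
// splitmix64 PRNG keeps training bit-reproducible across platforms and
// independent of R's RNG stream.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x < -45.0) return 0.0;
  if (x > 45.0) return 1.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// Train the network.  X: n x p matrix of normalized inputs; y: class codes
// 0..k-1.  Returns hidden weights W1 ((p+1) x h, last row = bias) and output
// weights W2 ((h+1) x k).
// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                   int n_hidden, double learning_rate, double momentum,
                   int epochs, int seed) {
  const int n = X.nrow(), p = X.ncol(), h = n_hidden, k = n_classes;
  SplitMix64 rng(static_cast<uint64_t>(static_cast<int64_t>(seed)));

  std::vector<double> W1((p + 1) * h), W2((h + 1) * k);
  std::vector<double> dW1((p + 1) * h, 0.0), dW2((h + 1) * k, 0.0);
  for (double &w : W1) w = rng.unif() - 0.5;
  for (double &w : W2) w = rng.unif() - 0.5;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hid(h), out(k), dout(k), dhid(h), xi(p);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < n; ++s) {
      const int i = order[s];
      for (int j = 0; j < p; ++j) xi[j] = X(i, j);
      // forward
      for (int a = 0; a < h; ++a) {
        double z = W1[p * h + a];  // bias row
        for (int j = 0; j < p; ++j) z += W1[j * h + a] * xi[j];
        hid[a] = sigmoid(z);
      }
      for (int c = 0; c < k; ++c) {
        double z = W2[h * k + c];
        for (int a = 0; a < h; ++a) z += W2[a * k + c] * hid[a];
        out[c] = sigmoid(z);
      }
      // backward: squared error, sigmoid derivative
      for (int c = 0; c < k; ++c) {
        const double t = (y[i] == c) ? 1.0 : 0.0;
        dout[c] = (t - out[c]) * out[c] * (1.0 - out[c]);
      }
      for (int a = 0; a < h; ++a) {
        double acc = 0.0;
        for (int c = 0; c < k; ++c) acc += W2[a * k + c] * dout[c];
        dhid[a] = acc * hid[a] * (1.0 - hid[a]);
      }
      // update output layer
      for (int a = 0; a <= h; ++a) {
        const double act = (a == h) ? 1.0 : hid[a];
        for (int c = 0; c < k; ++c) {
          double &prev = dW2[a * k + c];
          prev = learning_rate * dout[c] * act + momentum * prev;
          W2[a * k + c] += prev;
        }
      }
      // update hidden layer
      for (int j = 0; j <= p; ++j) {
        const double act = (j == p) ? 1.0 : xi[j];
        for (int a = 0; a < h; ++a) {
          double &prev = dW1[j * h + a];
          prev = learning_rate * dhid[a] * act + momentum * prev;
          W1[j * h + a] += prev;
        }
      }
    }
  }

  NumericMatrix W1m(p + 1, h), W2m(h + 1, k);
  for (int j = 0; j <= p; ++j)
    for (int a = 0; a < h; ++a) W1m(j, a) = W1[j * h + a];
  for (int a = 0; a <= h; ++a)
    for (int c = 0; c < k; ++c) W2m(a, c) = W2[a * k + c];
  return List::create(_["W1"] = W1m, _["W2"] = W2m);
}

// Forward pass: returns n x k matrix of output activations.
// [[Rcpp::export]]
NumericMatrix mlp_forward_cpp(NumericMatrix X, NumericMatrix W1,
                              NumericMatrix W2) {
  const int n = X.nrow(), p = X.ncol(), h = W1.ncol(), k = W2.ncol();
  if (W1.nrow() != p + 1) stop("weight/input dimension mismatch");
  if (W2.nrow() != h + 1) stop("hidden/output dimension mismatch");
  NumericMatrix out(n, k);
  std::vector<double> hid(h);
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < h; ++a) {
      double z = W1(p, a);
      for (int j = 0; j < p; ++j) z += W1(j, a) * X(i, j);
      hid[a] = sigmoid(z);
    }
    for (int c = 0; c < k; ++c) {
      double z = W2(h, c);
      for (int a = 0; a < h; ++a) z += W2(a, c) * hid[a];
      out(i, c) = z;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < k; ++c) out(i, c) = sigmoid(out(i, c));
  return out;
}
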