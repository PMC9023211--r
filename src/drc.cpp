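// Dense statevector evaluation of the data-reuploading ansatz.
//
// Layout conventions (must match the R side):
//  - qubit 0 is the most significant bit of the basis index;
//  - params is an R array of dim (L, Q, 3), column-major, so the angle
//    triple (phi, theta, omega) of layer l, qubit q sits at
//    l + L*q, l + L*(q + Q), l + L*(q + 2Q);
//  - each layer applies Rot(phi + pi*x_q, theta + pi*x_q, omega + pi*x_q)
//    to every qubit, then the linear CNOT cascade 0->1, 1->2, ..., Q-2->Q-1;
//  - class probabilities are the marginal of the first k qubits, outcome
//    index = basis index >> (Q - k).
#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double PROB_CLIP = 1e-12;

static inline void apply_rot(std::vector<cplx>& amp, int Q, int q,
                             double phi, double theta, double omega) {
  // Rot = RZ(omega) * RY(theta) * RZ(phi)
  double c = std::cos(theta / 2.0), s = std::sin(theta / 2.0);
  cplx m00 = std::polar(c, -(phi + omega) / 2.0);
  cplx m01 = -std::polar(s, (phi - omega) / 2.0);
  cplx m10 = std::polar(s, -(phi - omega) / 2.0);
  cplx m11 = std::polar(c, (phi + omega) / 2.0);
  int dim = 1 << Q;
  int stride = 1 << (Q - 1 - q);
  for (int base = 0; base < dim; base += 2 * stride) {
    for (int i = base; i < base + stride; ++i) {
      cplx a0 = amp[i], a1 = amp[i + stride];
      amp[i] = m00 * a0 + m01 * a1;
      amp[i + stride] = m10 * a0 + m11 * a1;
    }
  }
}

static inline void apply_cnot_cpp(std::vector<cplx>& amp, int Q,
                                  int control, int target) {
  int dim = 1 << Q;
  int cs = 1 << (Q - 1 - control);
  int ts = 1 << (Q - 1 - target);
  for (int i = 0; i < dim; ++i) {
    if (((i / cs) & 1) == 1 && ((i / ts) & 1) == 0) {
      std::swap(amp[i], amp[i + ts]);
    }
  }
}

// probabilities of the first-k-qubits marginal after the full circuit
static void forward_probs(const double* par, int L, int Q,
                          const double* x, int k, double* out) {
  int dim = 1 << Q;
  std::vector<cplx> amp(dim, cplx(0.0, 0.0));
  amp[0] = cplx(1.0, 0.0);
  for (int l = 0; l < L; ++l) {
    for (int q = 0; q < Q; ++q) {
      double inj = M_PI * x[q];
      double phi = par[l + L * q] + inj;
      double theta = par[l + L * (q + Q)] + inj;
      double omega = par[l + L * (q + 2 * Q)] + inj;
      apply_rot(amp, Q, q, phi, theta, omega);
    }
    for (int q = 0; q + 1 < Q; ++q) apply_cnot_cpp(amp, Q, q, q + 1);
  }
  int kdim = 1 << k;
  int shift = Q - k;
  for (int o = 0; o < kdim; ++o) out[o] = 0.0;
  for (int i = 0; i < dim; ++i) out[i >> shift] += std::norm(amp[i]);
}

// [[Rcpp::export]]
NumericMatrix cpp_batch_probs(NumericVector params, NumericMatrix X,
                              int n_layers, int n_qubits, int k_readout) {
  int n = X.nrow();
  int kdim = 1 << k_readout;
  NumericMatrix out(n, kdim);
  std::vector<double> x(n_qubits), p(kdim);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < n_qubits; ++q) x[q] = X(i, q);
    forward_probs(params.begin(), n_layers, n_qubits, x.data(), k_readout,
                  p.data());
    for (int o = 0; o < kdim; ++o) out(i, o) = p[o];
  }
  return out;
}

static double batch_loss(const double* par, int L, int Q,
                         const NumericMatrix& X, const IntegerVector& y,
                         int k) {
  int n = X.nrow();
  int kdim = 1 << k;
  std::vector<double> x(Q), p(kdim);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) x[q] = X(i, q);
    forward_probs(par, L, Q, x.data(), k, p.data());
    double pt = p[y[i]];
    total += -std::log(pt > PROB_CLIP ? pt : PROB_CLIP);
  }
  return total / n;
}

// [[Rcpp::export]]
double cpp_batch_loss(NumericVector params, NumericMatrix X, IntegerVector y,
                      int n_layers, int n_qubits, int k_readout) {
  return batch_loss(params.begin(), n_layers, n_qubits, X, y, k_readout);
}

// central finite differences on the batch loss
// [[Rcpp::export]]
NumericVector cpp_grad_fd(NumericVector params, NumericMatrix X,
                          IntegerVector y, int n_layers, int n_qubits,
                          int k_readout, double h) {
  int m = params.size();
  std::vector<double> par(params.begin(), params.end());
  NumericVector grad(m);
  for (int j = 0; j < m; ++j) {
    double orig = par[j];
    par[j] = orig + h;
    double lp = batch_loss(par.data(), n_layers, n_qubits, X, y, k_readout);
    par[j] = orig - h;
    double lm = batch_loss(par.data(), n_layers, n_qubits, X, y, k_readout);
    par[j] = orig;
    grad[j] = (lp - lm) / (2.0 * h);
  }
  return grad;
}

// exact parameter-shift gradient: every trainable angle enters one rotation
// with generator eigenvalues +/-1/2, so dp/dtheta = (p(theta + pi/2) -
// p(theta - pi/2)) / 2 exactly; the loss derivative follows by chain rule
// through -log(p_true).
// [[Rcpp::export]]
NumericVector cpp_grad_pshift(NumericVector params, NumericMatrix X,
                              IntegerVector y, int n_layers, int n_qubits,
                              int k_readout) {
  int m = params.size();
  int n = X.nrow();
  int kdim = 1 << k_readout;
  std::vector<double> par(params.begin(), params.end());
  std::vector<double> x(n_qubits), p(kdim);
  // unshifted true-class probabilities, one pass
  std::vector<double> p0(n);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < n_qubits; ++q) x[q] = X(i, q);
    forward_probs(par.data(), n_layers, n_qubits, x.data(), k_readout,
                  p.data());
    p0[i] = p[y[i]];
  }
  const double shift = M_PI / 2.0;
  NumericVector grad(m);
  for (int j = 0; j < m; ++j) {
    double orig = par[j];
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int q = 0; q < n_qubits; ++q) x[q] = X(i, q);
      par[j] = orig + shift;
      forward_probs(par.data(), n_layers, n_qubits, x.data(), k_readout,
                    p.data());
      double pp = p[y[i]];
      par[j] = orig - shift;
      forward_probs(par.data(), n_layers, n_qubits, x.data(), k_readout,
                    p.data());
      double pm = p[y[i]];
      double dp = (pp - pm) / 2.0;
      // below the clip the loss is flat, matching the clipped -log
      if (p0[i] > PROB_CLIP) acc += -dp / p0[i];
    }
    par[j] = orig;
    grad[j] = acc / n;
  }
  return grad;
}
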