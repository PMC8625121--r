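// Gradient-descent engines for encoder-free representation learning.
//
// Three entry points:
//   cpp_train_joint    - minimize sum_k L(x_k, g_w(z_k)) over weights w AND
//                        per-sample representations z_k (decoder training)
//   cpp_infer_reps     - same minimization over z only, frozen weights
//                        (test-time representation inference)
//   cpp_train_composed - encoder(+decoder) trained end-to-end on the composed
//                        reconstruction loss, with optional frozen decoder,
//                        optional fresh input noise per epoch, and optional
//                        direct regression onto stored representation targets
//
// Conventions: weight matrices are (out x in); activations are applied
// elementwise after each linear map; no biases (the sparse regulatory decoder
// has no additive term, and parameter counts then equal weight counts).
// Weight gradients come from the element-mean loss and are stepped with Adam
// (plus L2 weight decay); representation gradients are each sample's own loss
// summed over output dimensions and are stepped with momentum SGD, so the
// representation step size does not depend on batch size or input dimension.
// All randomness (shuffles, noise) draws from R's RNG, so set.seed() in R
// makes every run reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::uvec;

namespace {

// activation codes shared with R/layers.R
enum Act { ACT_LINEAR = 0, ACT_RELU = 1, ACT_LEAKY = 2, ACT_SIGMOID = 3 };
enum Loss { LOSS_MSE = 0, LOSS_BCE = 1 };

struct Layer {
  mat W;      // out x in
  mat mask;   // out x in binary; empty when dense
  bool masked;
  int act;
  double slope;
};

std::vector<Layer> parse_layers(const List& layers_in) {
  std::vector<Layer> layers;
  const int L = layers_in.size();
  for (int l = 0; l < L; ++l) {
    List li = layers_in[l];
    Layer lay;
    lay.W = as<mat>(li["W"]);
    lay.act = as<int>(li["act"]);
    lay.slope = as<double>(li["slope"]);
    SEXP msk = li["mask"];
    lay.masked = !Rf_isNull(msk);
    if (lay.masked) {
      lay.mask = as<mat>(msk);
      lay.W %= lay.mask;  // masked entries are structurally zero
    }
    layers.push_back(lay);
  }
  return layers;
}

List export_layers(const std::vector<Layer>& layers) {
  List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) out[l] = wrap(layers[l].W);
  return out;
}

mat activate(const mat& P, int act, double slope) {
  switch (act) {
    case ACT_RELU:    return arma::clamp(P, 0.0, arma::datum::inf);
    case ACT_LEAKY: { mat A = P; A.elem(arma::find(P < 0.0)) *= slope; return A; }
    case ACT_SIGMOID: return 1.0 / (1.0 + arma::exp(-P));
    default:          return P;
  }
}

// derivative of the activation, from pre-activation P and activation A
mat act_deriv(const mat& P, const mat& A, int act, double slope) {
  switch (act) {
    case ACT_RELU:    return arma::conv_to<mat>::from(P > 0.0);
    case ACT_LEAKY: {
      mat D(P.n_rows, P.n_cols, arma::fill::ones);
      D.elem(arma::find(P < 0.0)).fill(slope);
      return D;
    }
    case ACT_SIGMOID: return A % (1.0 - A);
    default:          return mat(P.n_rows, P.n_cols, arma::fill::ones);
  }
}

struct ForwardCache {
  std::vector<mat> A;  // A[0] = input, A[l+1] = activation of layer l
  std::vector<mat> P;  // P[l]  = pre-activation of layer l
};

mat forward(const std::vector<Layer>& layers, const mat& input, ForwardCache* cache) {
  mat a = input;
  if (cache) { cache->A.clear(); cache->P.clear(); cache->A.push_back(a); }
  for (size_t l = 0; l < layers.size(); ++l) {
    mat p = a * layers[l].W.t();
    a = activate(p, layers[l].act, layers[l].slope);
    if (cache) { cache->P.push_back(p); cache->A.push_back(a); }
  }
  return a;
}

// element-mean loss over a batch
double loss_value(const mat& target, const mat& out, int loss_type) {
  if (loss_type == LOSS_MSE) {
    return arma::accu(arma::square(out - target)) / out.n_elem;
  }
  mat p = arma::clamp(out, 1e-12, 1.0 - 1e-12);
  return -arma::accu(target % arma::log(p) + (1.0 - target) % arma::log(1.0 - p)) /
         out.n_elem;
}

// delta = d(element-mean loss)/d(pre-activation of final layer)
mat output_delta(const mat& target, const ForwardCache& cache,
                 const std::vector<Layer>& layers, int loss_type) {
  const mat& out = cache.A.back();
  const size_t L = layers.size();
  if (loss_type == LOSS_BCE) {
    // requires a final sigmoid; the sigmoid+BCE composition simplifies
    return (out - target) / out.n_elem;
  }
  mat d = (2.0 / out.n_elem) * (out - target);
  return d % act_deriv(cache.P[L - 1], out, layers[L - 1].act, layers[L - 1].slope);
}

// backpropagate; fills grads[l] (same shape as W) and returns the gradient
// with respect to the input rows
mat backward(const std::vector<Layer>& layers, const ForwardCache& cache,
             mat delta, std::vector<mat>& grads) {
  const int L = (int)layers.size();
  grads.assign(L, mat());
  for (int l = L - 1; l >= 0; --l) {
    grads[l] = delta.t() * cache.A[l];
    if (layers[l].masked) grads[l] %= layers[l].mask;
    mat g_in = delta * layers[l].W;
    if (l > 0) {
      delta = g_in % act_deriv(cache.P[l - 1], cache.A[l], layers[l - 1].act,
                               layers[l - 1].slope);
    } else {
      return g_in;
    }
  }
  return mat();
}

struct AdamState {
  std::vector<mat> m, v;
  long t = 0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const std::vector<Layer>& layers) {
    m.clear(); v.clear();
    for (size_t l = 0; l < layers.size(); ++l) {
      m.push_back(mat(layers[l].W.n_rows, layers[l].W.n_cols, arma::fill::zeros));
      v.push_back(mat(layers[l].W.n_rows, layers[l].W.n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<Layer>& layers, const std::vector<mat>& grads,
            double lr, double weight_decay) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t l = 0; l < layers.size(); ++l) {
      mat g = grads[l] + weight_decay * layers[l].W;
      if (layers[l].masked) g %= layers[l].mask;
      m[l] = b1 * m[l] + (1.0 - b1) * g;
      v[l] = b2 * v[l] + (1.0 - b2) * arma::square(g);
      layers[l].W -= lr * (m[l] / c1) / (arma::sqrt(v[l] / c2) + eps);
      if (layers[l].masked) layers[l].W %= layers[l].mask;
    }
  }
};

uvec shuffled_indices(int n) {
  IntegerVector idx = sample(n, n, false);  // R RNG, 1-based
  uvec out(n);
  for (int i = 0; i < n; ++i) out[i] = (arma::uword)(idx[i] - 1);
  return out;
}

mat r_gaussian(int nrow, int ncol, double sd) {
  NumericVector draws = rnorm(nrow * ncol, 0.0, sd);
  return mat(draws.begin(), nrow, ncol);  // column-major copy
}

void check_finite(double loss, int epoch) {
  if (!std::isfinite(loss))
    stop("training diverged (non-finite loss) at epoch %d", epoch + 1);
}

}  // namespace

// [[Rcpp::export]]
List cpp_forward(List layers_in, const arma::mat& input) {
  std::vector<Layer> layers = parse_layers(layers_in);
  mat out = forward(layers, input, nullptr);
  return List::create(_["output"] = out);
}

// [[Rcpp::export]]
List cpp_train_joint(const arma::mat& X, List layers_in, const arma::mat& Z0,
                     double lr_w, double lr_z, double momentum_z,
                     double weight_decay, int batch_size, int epochs,
                     int loss_type, bool nonneg_reps) {
  std::vector<Layer> layers = parse_layers(layers_in);
  const int N = X.n_rows;
  const int n_out = X.n_cols;
  mat Z = Z0;
  mat Vz(Z.n_rows, Z.n_cols, arma::fill::zeros);  // momentum buffer
  AdamState adam;
  adam.init(layers);
  NumericVector history(epochs);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    uvec order = shuffled_indices(N);
    double epoch_sse = 0.0;  // accumulated element loss numerator
    for (int start = 0; start < N; start += batch_size) {
      const int stop_ = std::min(start + batch_size - 1, N - 1);
      uvec idx = order.subvec(start, stop_);
      mat Xb = X.rows(idx);
      mat Zb = Z.rows(idx);

      ForwardCache cache;
      forward(layers, Zb, &cache);
      epoch_sse += loss_value(Xb, cache.A.back(), loss_type) * Xb.n_elem;

      std::vector<mat> grads;
      mat delta = output_delta(Xb, cache, layers, loss_type);
      mat g_z_mean = backward(layers, cache, delta, grads);

      adam.step(layers, grads, lr_w, weight_decay);

      // per-sample loss gradient (sum over output dims): undo the batch-mean
      mat g_z = g_z_mean * (double)(Xb.n_rows * n_out);
      mat vb = momentum_z * Vz.rows(idx) + g_z;
      Vz.rows(idx) = vb;
      mat zb = Z.rows(idx) - lr_z * vb;
      // projected step for sign-identifiable non-negative representations
      if (nonneg_reps) zb = arma::clamp(zb, 0.0, arma::datum::inf);
      Z.rows(idx) = zb;
    }
    history[epoch] = epoch_sse / ((double)N * n_out);
    check_finite(history[epoch], epoch);
  }
  return List::create(_["layers"] = export_layers(layers), _["Z"] = Z,
                      _["loss_history"] = history);
}

// [[Rcpp::export]]
List cpp_infer_reps(const arma::mat& X, List layers_in, const arma::mat& Z0,
                    double lr_z, double momentum_z, int max_epochs,
                    double tol, int patience, int loss_type, bool nonneg_reps) {
  std::vector<Layer> layers = parse_layers(layers_in);
  const int n_out = X.n_cols;
  mat Z = Z0;
  mat Vz(Z.n_rows, Z.n_cols, arma::fill::zeros);
  std::vector<double> history;
  double best = arma::datum::inf;
  int stalled = 0;
  int used = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    ForwardCache cache;
    forward(layers, Z, &cache);
    double loss = loss_value(X, cache.A.back(), loss_type);
    history.push_back(loss);
    check_finite(loss, epoch);

    std::vector<mat> grads;
    mat delta = output_delta(X, cache, layers, loss_type);
    mat g_z_mean = backward(layers, cache, delta, grads);
    mat g_z = g_z_mean * (double)(X.n_rows * n_out);
    Vz = momentum_z * Vz + g_z;
    Z -= lr_z * Vz;
    if (nonneg_reps) Z = arma::clamp(Z, 0.0, arma::datum::inf);
    used = epoch + 1;

    if (best - loss < tol) {
      if (++stalled >= patience) break;
    } else {
      stalled = 0;
    }
    if (loss < best) best = loss;
  }

  // per-sample element-mean losses at the returned representations
  mat out = forward(layers, Z, nullptr);
  arma::vec per_sample;
  if (loss_type == LOSS_MSE) {
    per_sample = arma::mean(arma::square(out - X), 1);
  } else {
    mat p = arma::clamp(out, 1e-12, 1.0 - 1e-12);
    per_sample = -arma::mean(X % arma::log(p) + (1.0 - X) % arma::log(1.0 - p), 1);
  }
  return List::create(_["Z"] = Z, _["per_sample_loss"] = per_sample,
                      _["loss_history"] = wrap(history), _["epochs"] = used);
}

// [[Rcpp::export]]
List cpp_train_composed(const arma::mat& X, List enc_in, List dec_in,
                        double lr, double weight_decay, int batch_size,
                        int epochs, double noise_sd, bool freeze_decoder,
                        int loss_type, Nullable<NumericMatrix> z_target) {
  std::vector<Layer> enc = parse_layers(enc_in);
  std::vector<Layer> dec = parse_layers(dec_in);
  const int N = X.n_rows;
  const bool regress_z = z_target.isNotNull();
  mat Zt;
  if (regress_z) Zt = as<mat>(z_target.get());

  AdamState adam_e, adam_d;
  adam_e.init(enc);
  if (!freeze_decoder) adam_d.init(dec);
  NumericVector history(epochs);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    mat Xin = X;
    if (noise_sd > 0.0) Xin += r_gaussian(N, X.n_cols, noise_sd);
    uvec order = shuffled_indices(N);
    double epoch_sse = 0.0;
    double denom = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop_ = std::min(start + batch_size - 1, N - 1);
      uvec idx = order.subvec(start, stop_);
      mat Xb_in = Xin.rows(idx);

      ForwardCache ce;
      forward(enc, Xb_in, &ce);

      std::vector<mat> g_enc;
      if (regress_z) {
        mat Tb = Zt.rows(idx);
        const mat& zo = ce.A.back();
        epoch_sse += arma::accu(arma::square(zo - Tb));
        denom += zo.n_elem;
        mat delta = (2.0 / zo.n_elem) * (zo - Tb) %
                    act_deriv(ce.P.back(), zo, enc.back().act, enc.back().slope);
        backward(enc, ce, delta, g_enc);
      } else {
        mat Xb = X.rows(idx);  // clean target even under input noise
        ForwardCache cd;
        forward(dec, ce.A.back(), &cd);
        epoch_sse += loss_value(Xb, cd.A.back(), loss_type) * Xb.n_elem;
        denom += Xb.n_elem;

        std::vector<mat> g_dec;
        mat delta_d = output_delta(Xb, cd, dec, loss_type);
        mat g_into_z = backward(dec, cd, delta_d, g_dec);
        if (!freeze_decoder) adam_d.step(dec, g_dec, lr, weight_decay);

        mat delta_e = g_into_z % act_deriv(ce.P.back(), ce.A.back(),
                                           enc.back().act, enc.back().slope);
        backward(enc, ce, delta_e, g_enc);
      }
      adam_e.step(enc, g_enc, lr, weight_decay);
    }
    history[epoch] = epoch_sse / denom;
    check_finite(history[epoch], epoch);
  }
  return List::create(_["enc_layers"] = export_layers(enc),
                      _["dec_layers"] = export_layers(dec),
                      _["loss_history"] = history);
}
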