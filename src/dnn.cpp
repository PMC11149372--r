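// Mini-batch SGD trainer for the single-hidden-layer (pyramid) network:
// input -> dense(hidden, ReLU) -> dropout -> sigmoid output, trained with
// Nesterov momentum, per-update learning-rate decay lr0 / (1 + decay * t),
// and L1 + L2 penalties on the weight matrices (not biases). All randomness
// (initialization, batch order, dropout masks) comes from one seeded
// generator so training is fully deterministic. hidden = 0 degenerates to a
// plain logistic-regression layer.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

struct Net {
  arma::mat W1;  // p x h (empty when hidden == 0)
  arma::vec b1;  // h
  arma::vec W2;  // h x 1 (or p x 1 when hidden == 0)
  double b2;
  int hidden;
};

static arma::vec net_forward(const Net& net, const arma::mat& X) {
  if (net.hidden > 0) {
    arma::mat H = X * net.W1;
    H.each_row() += net.b1.t();
    H = arma::clamp(H, 0.0, arma::datum::inf);  // ReLU
    return sigmoid(H * net.W2 + net.b2);
  }
  return sigmoid(X * net.W2 + net.b2);
}

static double penalty(const Net& net, double lambda1, double lambda2) {
  double l1 = arma::accu(arma::abs(net.W2));
  double l2 = arma::accu(arma::square(net.W2));
  if (net.hidden > 0) {
    l1 += arma::accu(arma::abs(net.W1));
    l2 += arma::accu(arma::square(net.W1));
  }
  return lambda1 * l1 + lambda2 * l2;
}

static double bce(const arma::vec& p, const arma::vec& y) {
  arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// Nesterov update in the Keras SGD formulation:
//   v <- momentum * v - lr * g;  w <- w + momentum * v - lr * g
template <typename T>
static inline void nesterov(T& w, T& v, const T& g, double lr, double mom) {
  v = mom * v - lr * g;
  w += mom * v - lr * g;
}

// [[Rcpp::export]]
List dnn_train_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xval, const arma::vec& yval,
                   int hidden, double dropout, double lr0, double decay,
                   double momentum, double lambda1, double lambda2,
                   int batch_size, int max_epochs, int patience,
                   int seed, double clipnorm, int t0,
                   Nullable<List> init_weights) {
  const int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Net net; net.hidden = hidden;
  if (init_weights.isNotNull()) {
    List w(init_weights);
    if (hidden > 0) {
      net.W1 = as<arma::mat>(w["W1"]);
      net.b1 = as<arma::vec>(w["b1"]);
    }
    net.W2 = as<arma::vec>(w["W2"]);
    net.b2 = as<double>(w["b2"]);
    if ((hidden > 0 && ((int)net.W1.n_rows != p || (int)net.W1.n_cols != hidden)) ||
        (hidden == 0 && (int)net.W2.n_elem != p))
      stop("initial weights do not match the feature schema");
  } else {
    // Glorot-uniform initialization from the seeded stream
    if (hidden > 0) {
      double lim1 = std::sqrt(6.0 / (p + hidden));
      net.W1.set_size(p, hidden);
      for (auto& v : net.W1) v = (2.0 * unif(rng) - 1.0) * lim1;
      net.b1 = arma::zeros(hidden);
      double lim2 = std::sqrt(6.0 / (hidden + 1));
      net.W2.set_size(hidden);
      for (auto& v : net.W2) v = (2.0 * unif(rng) - 1.0) * lim2;
    } else {
      double lim2 = std::sqrt(6.0 / (p + 1));
      net.W2.set_size(p);
      for (auto& v : net.W2) v = (2.0 * unif(rng) - 1.0) * lim2;
    }
    net.b2 = 0.0;
  }

  // momentum buffers
  arma::mat vW1; arma::vec vb1;
  if (hidden > 0) { vW1 = arma::zeros(p, hidden); vb1 = arma::zeros<arma::vec>(hidden); }
  arma::vec vW2 = arma::zeros<arma::vec>(net.W2.n_elem);
  double vb2 = 0.0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Net best = net;
  double best_val = -1.0;
  // t counts SGD updates and drives the learning-rate decay; fine-tuning
  // passes the pretraining count so the schedule continues rather than
  // restarting at the full initial rate
  int best_epoch = 0, wait = 0, t = t0, stopped_epoch = 0;
  std::vector<double> hist_loss, hist_val;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int B = end - start;
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order[start + i];
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);
      double lr = lr0 / (1.0 + decay * t);

      if (hidden > 0) {
        arma::mat A1 = Xb * net.W1;
        A1.each_row() += net.b1.t();
        arma::mat H = arma::clamp(A1, 0.0, arma::datum::inf);
        arma::mat mask;
        if (dropout > 0.0) {
          mask.set_size(H.n_rows, H.n_cols);
          double scale = 1.0 / (1.0 - dropout);
          for (auto& v : mask) v = (unif(rng) < dropout) ? 0.0 : scale;
          H %= mask;
        }
        arma::vec pr = sigmoid(H * net.W2 + net.b2);
        arma::vec delta = (pr - yb) / B;
        arma::vec gW2 = H.t() * delta + lambda1 * arma::sign(net.W2) +
          2.0 * lambda2 * net.W2;
        double gb2 = arma::accu(delta);
        arma::mat dH = delta * net.W2.t();      // B x h
        if (dropout > 0.0) dH %= mask;
        dH %= arma::conv_to<arma::mat>::from(A1 > 0.0);
        arma::mat gW1 = Xb.t() * dH + lambda1 * arma::sign(net.W1) +
          2.0 * lambda2 * net.W1;
        arma::vec gb1 = arma::sum(dH, 0).t();
        if (clipnorm > 0.0) {
          // rescale the global gradient so its overall L2 norm is <= clipnorm
          double gn = std::sqrt(arma::accu(arma::square(gW1)) +
                                arma::accu(arma::square(gb1)) +
                                arma::accu(arma::square(gW2)) + gb2 * gb2);
          if (gn > clipnorm) {
            double s = clipnorm / gn;
            gW1 *= s; gb1 *= s; gW2 *= s; gb2 *= s;
          }
        }
        nesterov(net.W1, vW1, gW1, lr, momentum);
        nesterov(net.b1, vb1, gb1, lr, momentum);
        nesterov(net.W2, vW2, gW2, lr, momentum);
        double vnew = momentum * vb2 - lr * gb2;
        net.b2 += momentum * vnew - lr * gb2; vb2 = vnew;
      } else {
        arma::vec pr = sigmoid(Xb * net.W2 + net.b2);
        arma::vec delta = (pr - yb) / B;
        arma::vec gW2 = Xb.t() * delta + lambda1 * arma::sign(net.W2) +
          2.0 * lambda2 * net.W2;
        double gb2 = arma::accu(delta);
        if (clipnorm > 0.0) {
          double gn = std::sqrt(arma::accu(arma::square(gW2)) + gb2 * gb2);
          if (gn > clipnorm) {
            double s = clipnorm / gn;
            gW2 *= s; gb2 *= s;
          }
        }
        nesterov(net.W2, vW2, gW2, lr, momentum);
        double vnew = momentum * vb2 - lr * gb2;
        net.b2 += momentum * vnew - lr * gb2; vb2 = vnew;
      }
      ++t;
    }

    // epoch-end bookkeeping: full-train loss (penalties included), val accuracy
    arma::vec pr_train = net_forward(net, X);
    double loss = bce(pr_train, y) + penalty(net, lambda1, lambda2);
    if (!std::isfinite(loss))
      stop("NaN/Inf training loss at epoch %d; lower the learning rate", epoch);
    arma::vec pr_val = net_forward(net, Xval);
    double val_acc = arma::mean(arma::conv_to<arma::vec>::from(
        (pr_val > 0.5) == (yval > 0.5)));
    hist_loss.push_back(loss);
    hist_val.push_back(val_acc);
    stopped_epoch = epoch;
    if (val_acc > best_val) {
      best_val = val_acc; best = net; best_epoch = epoch; wait = 0;
    } else if (++wait > patience) break;
  }
  if (max_epochs == 0) { best = net; best_epoch = 0; }

  List weights = List::create(_["W2"] = best.W2, _["b2"] = best.b2);
  if (hidden > 0) { weights["W1"] = best.W1; weights["b1"] = best.b1; }
  return List::create(
    _["weights"] = weights,
    _["history"] = DataFrame::create(_["epoch"] = seq_len(hist_loss.size()),
                                     _["train_loss"] = hist_loss,
                                     _["val_accuracy"] = hist_val),
    _["best_epoch"] = best_epoch,
    _["best_val_accuracy"] = best_val,
    _["stopped_epoch"] = stopped_epoch,
    _["n_updates"] = t - t0);
}

// [[Rcpp::export]]
arma::vec dnn_predict_cpp(const arma::mat& X, int hidden, List weights) {
  Net net; net.hidden = hidden;
  if (hidden > 0) {
    net.W1 = as<arma::mat>(weights["W1"]);
    net.b1 = as<arma::vec>(weights["b1"]);
  }
  net.W2 = as<arma::vec>(weights["W2"]);
  net.b2 = as<double>(weights["b2"]);
  return net_forward(net, X);
}
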