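// Feed-forward regression network with ReLU hidden layers, Adam updates and
// validation-based early stopping. One network is one ensemble member; all
// randomness (init, validation split, batch order) comes from the supplied
// seed so retraining is bit-reproducible on a single thread.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
};

static vec forward(const Net &net, const mat &X, std::vector<mat> *acts = nullptr) {
  // X: n x p (rows = samples); activations stored as n x units
  mat A = X;
  if (acts) acts->push_back(A);
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    mat Z = A * net.W[l].t();
    Z.each_row() += net.b[l].t();
    if (l + 1 < L) Z = clamp(Z, 0.0, datum::inf); // ReLU
    A = Z;
    if (acts && l + 1 < L) acts->push_back(A);
  }
  return A.col(0);
}

// [[Rcpp::export(name = ".mlp_fit")]]
Rcpp::List mlp_fit(const arma::mat &X, const arma::vec &y,
                   const arma::ivec &hidden,
                   double lr, int batch_size, int max_epochs,
                   int patience, double val_frac, int seed) {
  const uword n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // architecture: p -> hidden... -> 1
  std::vector<uword> sizes;
  sizes.push_back(p);
  for (uword i = 0; i < hidden.n_elem; ++i) sizes.push_back(static_cast<uword>(hidden[i]));
  sizes.push_back(1);

  Net net;
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    mat W(sizes[l + 1], sizes[l]);
    const double sd = std::sqrt(2.0 / static_cast<double>(sizes[l])); // He init
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sd * gauss(rng);
    net.W.push_back(W);
    net.b.push_back(zeros<vec>(sizes[l + 1]));
    mW.push_back(zeros<mat>(size(W))); vW.push_back(zeros<mat>(size(W)));
    mb.push_back(zeros<vec>(sizes[l + 1])); vb.push_back(zeros<vec>(sizes[l + 1]));
  }

  // validation split
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  uword n_val = static_cast<uword>(std::max(1.0, std::floor(val_frac * n)));
  if (n_val >= n) n_val = n > 1 ? n - 1 : 0;
  uvec val_idx(n_val), tr_idx(n - n_val);
  for (uword i = 0; i < n_val; ++i) val_idx[i] = idx[i];
  for (uword i = n_val; i < n; ++i) tr_idx[i - n_val] = idx[i];
  mat Xtr = X.rows(tr_idx), Xval = n_val ? X.rows(val_idx) : mat();
  vec ytr = y(tr_idx), yval = n_val ? y(val_idx) : vec();
  const uword ntr = Xtr.n_rows;

  const double beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8;
  long step = 0;
  double best_val = datum::inf;
  int best_epoch = -1, since_best = 0;
  Net best = net;
  std::vector<double> train_curve, val_curve;
  std::vector<uword> order(ntr);
  for (uword i = 0; i < ntr; ++i) order[i] = i;

  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < ntr; start += static_cast<uword>(batch_size)) {
      const uword stop = std::min(ntr, start + static_cast<uword>(batch_size));
      uvec bidx(stop - start);
      for (uword i = start; i < stop; ++i) bidx[i - start] = order[i];
      mat Xb = Xtr.rows(bidx);
      vec yb = ytr(bidx);
      const double nb = static_cast<double>(Xb.n_rows);

      std::vector<mat> acts;
      vec out = forward(net, Xb, &acts);
      vec delta = 2.0 * (out - yb) / nb; // d(MSE)/d(out)

      mat D = mat(delta); // n x 1
      ++step;
      const double c1 = 1.0 - std::pow(beta1, step), c2 = 1.0 - std::pow(beta2, step);
      for (int l = static_cast<int>(net.W.size()) - 1; l >= 0; --l) {
        mat gW = D.t() * acts[l];
        vec gb = sum(D, 0).t();
        if (l > 0) {
          mat back = D * net.W[l];
          back.elem(find(acts[l] <= 0)).zeros(); // ReLU gradient
          D = back;
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        net.W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps_adam);
        net.b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps_adam);
      }
    }
    const double tr_loss = mean(square(forward(net, Xtr) - ytr));
    const double va_loss = n_val ? mean(square(forward(net, Xval) - yval)) : tr_loss;
    train_curve.push_back(tr_loss);
    val_curve.push_back(va_loss);
    if (!std::isfinite(tr_loss) || !std::isfinite(va_loss)) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("reason") = "non-finite loss");
    }
    if (va_loss < best_val - 1e-12) {
      best_val = va_loss;
      best = net;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best > patience) {
      break;
    }
  }

  Rcpp::List Wout(best.W.size()), bout(best.b.size());
  for (size_t l = 0; l < best.W.size(); ++l) {
    Wout[l] = Rcpp::wrap(best.W[l]);
    bout[l] = Rcpp::wrap(best.b[l]);
  }
  return Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("W") = Wout,
      Rcpp::Named("b") = bout,
      Rcpp::Named("best_val_loss") = best_val,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("epochs_run") = epoch,
      Rcpp::Named("train_curve") = train_curve,
      Rcpp::Named("val_curve") = val_curve);
}

// [[Rcpp::export(name = ".mlp_predict")]]
arma::vec mlp_predict(const Rcpp::List &W, const Rcpp::List &b, const arma::mat &X) {
  Net net;
  for (int l = 0; l < W.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(W[l]));
    net.b.push_back(Rcpp::as<vec>(b[l]));
  }
  return forward(net, X);
}
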