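// Contrastive-divergence batch gradients for the RBM and the RTRBM
// (teacher-forced CD per time-step plus backpropagation through time).
// Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigmoid_mat(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

static inline arma::mat bernoulli_mat(const arma::mat& p) {
  arma::mat out(p.n_rows, p.n_cols);
  for (arma::uword j = 0; j < p.n_cols; ++j)
    for (arma::uword i = 0; i < p.n_rows; ++i)
      out(i, j) = (unif_rand() < p(i, j)) ? 1.0 : 0.0;
  return out;
}

// [[Rcpp::export(name = ".rbm_batch_gradient_cpp")]]
List rbm_batch_gradient_cpp(const arma::mat& V, const arma::mat& W,
                            const arma::vec& bv, const arma::vec& bh,
                            int K, int mf_iter = 0) {
  const double B = static_cast<double>(V.n_cols);
  arma::mat r_data = sigmoid_mat(W * V + arma::repmat(bh, 1, V.n_cols));
  arma::mat Vn, r_model;
  if (mf_iter > 0) {
    Vn = arma::repmat(1.0 / (1.0 + arma::exp(-bv)), 1, V.n_cols);
    r_model = sigmoid_mat(W * Vn + arma::repmat(bh, 1, V.n_cols));
    for (int i = 0; i < mf_iter; ++i) {
      Vn = 0.5 * Vn + 0.5 * sigmoid_mat(W.t() * r_model + arma::repmat(bv, 1, V.n_cols));
      r_model = 0.5 * r_model + 0.5 * sigmoid_mat(W * Vn + arma::repmat(bh, 1, V.n_cols));
    }
  } else {
    Vn = V;
    for (int k = 0; k < K; ++k) {
      arma::mat ph = sigmoid_mat(W * Vn + arma::repmat(bh, 1, V.n_cols));
      arma::mat H = bernoulli_mat(ph);
      arma::mat pv = sigmoid_mat(W.t() * H + arma::repmat(bv, 1, V.n_cols));
      Vn = bernoulli_mat(pv);
    }
    r_model = sigmoid_mat(W * Vn + arma::repmat(bh, 1, V.n_cols));
  }
  arma::vec dbv = (arma::sum(V, 1) - arma::sum(Vn, 1)) / B;
  arma::vec dbh = (arma::sum(r_data, 1) - arma::sum(r_model, 1)) / B;
  return List::create(
    _["dW"] = arma::mat((r_data * V.t() - r_model * Vn.t()) / B),
    _["dbv"] = NumericVector(dbv.begin(), dbv.end()),
    _["dbh"] = NumericVector(dbh.begin(), dbh.end())
  );
}

// mf_iter > 0 replaces the Gibbs negative phase by damped mean-field
// iterations from a neutral visible state (free-running pressure on U).
// [[Rcpp::export(name = ".rtrbm_batch_gradient_cpp")]]
List rtrbm_batch_gradient_cpp(const arma::mat& V, const arma::mat& W,
                              const arma::mat& U, const arma::vec& bv,
                              const arma::vec& bh, const arma::vec& binit,
                              int K, int mf_iter = 0) {
  const arma::uword T = V.n_cols;
  const arma::uword Nh = W.n_rows;
  const double Td = static_cast<double>(T);

  // mean-field forward pass and per-step conditional hidden biases
  arma::mat WV = W * V;
  arma::mat r(Nh, T), Bias(Nh, T);
  Bias.col(0) = binit;
  r.col(0) = sigmoid_mat(WV.col(0) + binit);
  for (arma::uword t = 1; t < T; ++t) {
    Bias.col(t) = bh + U * r.col(t - 1);
    r.col(t) = sigmoid_mat(WV.col(t) + Bias.col(t));
  }

  // negative phase: K Gibbs sweeps per column under its conditional RBM,
  // or damped mean-field from a neutral start
  arma::mat Vn, r_model;
  if (mf_iter > 0) {
    Vn = arma::repmat(1.0 / (1.0 + arma::exp(-bv)), 1, T);
    r_model = sigmoid_mat(W * Vn + Bias);
    for (int i = 0; i < mf_iter; ++i) {
      Vn = 0.5 * Vn + 0.5 * sigmoid_mat(W.t() * r_model + arma::repmat(bv, 1, T));
      r_model = 0.5 * r_model + 0.5 * sigmoid_mat(W * Vn + Bias);
    }
  } else {
    Vn = V;
    for (int k = 0; k < K; ++k) {
      arma::mat ph = sigmoid_mat(W * Vn + Bias);
      arma::mat H = bernoulli_mat(ph);
      arma::mat pv = sigmoid_mat(W.t() * H + arma::repmat(bv, 1, T));
      Vn = bernoulli_mat(pv);
    }
    r_model = sigmoid_mat(W * Vn + Bias);
  }

  arma::mat dh = r - r_model;
  arma::mat dW = r * V.t() - r_model * Vn.t();
  arma::vec dbv = arma::sum(V - Vn, 1);
  arma::vec dbinit = dh.col(0);
  arma::vec dbh(Nh, arma::fill::zeros);
  arma::mat dU(Nh, Nh, arma::fill::zeros);
  if (T > 1) {
    dbh = arma::sum(dh.cols(1, T - 1), 1);
    dU = dh.cols(1, T - 1) * r.cols(0, T - 2).t();
    // backward pass through the mean-field recursion
    arma::mat D(Nh, T, arma::fill::zeros);
    for (arma::uword t = T - 1; t-- > 0; ) {
      arma::vec inner = D.col(t + 1) % r.col(t + 1) % (1.0 - r.col(t + 1)) +
        dh.col(t + 1);
      D.col(t) = U.t() * inner;
    }
    arma::mat E = D.cols(0, T - 2) % r.cols(0, T - 2) % (1.0 - r.cols(0, T - 2));
    dW += E * V.cols(0, T - 2).t();
    dbinit += E.col(0);
    if (T > 2) {
      dbh += arma::sum(E.cols(1, T - 2), 1);
      dU += E.cols(1, T - 2) * r.cols(0, T - 3).t();
    }
  }
  dbv /= Td; dbh /= Td; dbinit /= Td;
  return List::create(
    _["dW"] = arma::mat(dW / Td), _["dU"] = arma::mat(dU / Td),
    _["dbv"] = NumericVector(dbv.begin(), dbv.end()),
    _["dbh"] = NumericVector(dbh.begin(), dbh.end()),
    _["dbinit"] = NumericVector(dbinit.begin(), dbinit.end())
  );
}
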