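// Exact-gradient t-SNE with precision bisection, early exaggeration and a
// momentum schedule. O(n^2) per iteration, intended for cohort-scale maps
// (hundreds to a few thousand samples). Returns the embedding and the final
// Kullback-Leibler divergence of the unexaggerated objective.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

// Squared Euclidean distance matrix.
static mat sqDist(const mat& X) {
  colvec s = sum(square(X), 1);
  mat D = repmat(s, 1, X.n_rows) + repmat(s.t(), X.n_rows, 1) - 2.0 * X * X.t();
  D.diag().zeros();
  D.elem(find(D < 0)).zeros();
  return D;
}

// Row-conditional affinities at the requested perplexity (binary search on
// the Gaussian precision beta, 50 iterations).
static mat condP(const mat& D, double perplexity) {
  const uword n = D.n_rows;
  const double logU = std::log(perplexity);
  mat P(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -datum::inf, betamax = datum::inf;
    rowvec Di = D.row(i);
    Di(i) = 0.0;
    for (int it = 0; it < 50; ++it) {
      rowvec Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP < EPS) sumP = EPS;
      double H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) { P.row(i) = Pi; break; }
      if (diff > 0) {
        betamin = beta;
        beta = std::isfinite(betamax) ? (beta + betamax) / 2.0 : beta * 2.0;
      } else {
        betamax = beta;
        beta = std::isfinite(betamin) ? (beta + betamin) / 2.0 : beta / 2.0;
      }
      if (it == 49) P.row(i) = Pi;
    }
  }
  return P;
}

// [[Rcpp::export(name = ".tsneCpp")]]
Rcpp::List tsneCpp(const arma::mat& X, const arma::mat& Y0,
                   double perplexity, int maxIter,
                   double eta, double exaggeration, int stopLying,
                   int momSwitch, double thetaMomStart, double thetaMomFinal) {
  const uword n = X.n_rows;
  mat P = condP(sqDist(X), perplexity);
  P = (P + P.t()) / (2.0 * n);
  P.elem(find(P < EPS)).fill(EPS);
  double Psum = accu(P);
  P /= Psum;                      // renormalize after flooring
  mat Pex = P * exaggeration;

  mat Y = Y0;
  mat dY(n, Y.n_cols, fill::zeros);
  mat gains(n, Y.n_cols, fill::ones);
  double momentum = thetaMomStart;

  for (int iter = 0; iter < maxIter; ++iter) {
    const mat& Pit = (iter < stopLying) ? Pex : P;
    mat num = 1.0 / (1.0 + sqDist(Y));  // Student-t kernel
    num.diag().zeros();
    double sumNum = accu(num);
    if (sumNum < EPS) sumNum = EPS;
    mat Q = num / sumNum;
    Q.elem(find(Q < EPS)).fill(EPS);

    mat L = (Pit - Q) % num;
    mat grad = 4.0 * (diagmat(sum(L, 1)) - L) * Y;

    mat ds = conv_to<mat>::from(sign(grad) != sign(dY));
    gains = (gains + 0.2) % ds + (gains * 0.8) % (1.0 - ds);
    gains.elem(find(gains < 0.01)).fill(0.01);
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= mean(Y, 0);
    if (iter == momSwitch) momentum = thetaMomFinal;
  }

  // final KL on the plain objective
  mat num = 1.0 / (1.0 + sqDist(Y));
  num.diag().zeros();
  double sumNum = accu(num);
  if (sumNum < EPS) sumNum = EPS;
  mat Q = num / sumNum;
  Q.elem(find(Q < EPS)).fill(EPS);
  double kl = accu(P % log(P / Q));

  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("kl") = kl);
}
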