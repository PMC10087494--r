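// Dense Swish-MLP forward/backward passes. Hot path of every INR fit:
// written against Armadillo so the matrix products go through BLAS and the
// elementwise sigmoid stays in compiled code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// forward pass caching layer inputs, pre-activations and sigmoids
// [[Rcpp::export]]
List cpp_mlp_forward_train(List Ws, List bs, const arma::mat &X) {
  int L = Ws.size();
  List A_in(L), Z(L), S(L);
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    A_in[l] = A;
    arma::mat Zl = A * W;
    Zl.each_row() += b;
    if (l < L - 1) {
      arma::mat Sl = 1.0 / (1.0 + arma::exp(-Zl));
      A = Zl % Sl;
      Z[l] = Zl;
      S[l] = Sl;
    } else {
      A = Zl;
    }
  }
  return List::create(_["out"] = A, _["A_in"] = A_in, _["Z"] = Z, _["S"] = S);
}

// plain forward (no cache)
// [[Rcpp::export]]
arma::mat cpp_mlp_forward(List Ws, List bs, const arma::mat &X) {
  int L = Ws.size();
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    A = A * W;
    A.each_row() += b;
    if (l < L - 1) A = A % (1.0 / (1.0 + arma::exp(-A)));
  }
  return A;
}

// backward pass; g_out is dLoss/d(output). Gradient w.r.t. the input is not
// needed (inputs are frozen encodings), so layer 1 skips it.
// [[Rcpp::export]]
List cpp_mlp_backward(List Ws, List A_in, List Z, List S, const arma::mat &g_out) {
  int L = Ws.size();
  List gWs(L), gbs(L);
  arma::mat g = g_out;
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      arma::mat Zl = as<arma::mat>(Z[l]);
      arma::mat Sl = as<arma::mat>(S[l]);
      g = g % (Sl % (1.0 + Zl % (1.0 - Sl)));
    }
    arma::mat Al = as<arma::mat>(A_in[l]);
    gWs[l] = Al.t() * g;
    gbs[l] = arma::sum(g, 0);
    if (l > 0) {
      arma::mat W = as<arma::mat>(Ws[l]);
      g = g * W.t();
    }
  }
  return List::create(_["W"] = gWs, _["b"] = gbs);
}

// Persistent workspace for repeated passes over a fixed encoding matrix
// (the INR training loops): the encodings and all layer caches live in C++
// memory, and activations are moved (never copied) between forward and cache.
struct MlpWS {
  arma::mat X;
  std::vector<arma::mat> A, Z, S;   // A[l]: activated output of hidden layer l
};

// [[Rcpp::export]]
SEXP cpp_mlp_ws_new(const arma::mat &X) {
  XPtr<MlpWS> p(new MlpWS, true);
  p->X = X;
  return p;
}

// [[Rcpp::export]]
arma::vec cpp_mlp_ws_fwd(SEXP ws, List Ws, List bs) {
  XPtr<MlpWS> p(ws);
  int L = Ws.size();
  p->A.assign(L - 1, arma::mat());
  p->Z.assign(L - 1, arma::mat());
  p->S.assign(L - 1, arma::mat());
  const arma::mat *Ain = &p->X;
  arma::mat out;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    arma::mat Zl = (*Ain) * W;
    Zl.each_row() += b;
    if (l < L - 1) {
      arma::mat Sl = 1.0 / (1.0 + arma::exp(-Zl));
      p->A[l] = Zl % Sl;
      p->Z[l] = std::move(Zl);
      p->S[l] = std::move(Sl);
      Ain = &p->A[l];
    } else {
      out = std::move(Zl);
    }
  }
  return arma::vec(out.col(0));
}

// [[Rcpp::export]]
List cpp_mlp_ws_bwd(SEXP ws, List Ws, const arma::vec &g_out) {
  XPtr<MlpWS> p(ws);
  int L = Ws.size();
  List gWs(L), gbs(L);
  arma::mat g = g_out;
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      g = g % (p->S[l] % (1.0 + p->Z[l] % (1.0 - p->S[l])));
    }
    const arma::mat &Ain = (l == 0) ? p->X : p->A[l - 1];
    gWs[l] = Ain.t() * g;
    gbs[l] = arma::sum(g, 0);
    if (l > 0) {
      arma::mat W = as<arma::mat>(Ws[l]);
      g = g * W.t();
    }
  }
  return List::create(_["W"] = gWs, _["b"] = gbs);
}
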