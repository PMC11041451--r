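// Bi-LSTM emission encoder with a linear-chain CRF output layer.
// Forward pass, full backpropagation through time, CRF negative
// log-likelihood gradients (via forward-backward, see crf.cpp) and Adam
// updates. Single-threaded and deterministic given fixed parameters and
// sentence order.
//
// Parameter list (R side, named): emb (V x E), Wf/Wb (4H x E), Uf/Ub (4H x H),
// bf/bb (4H x 1), Wo (L x 2H), bo (L x 1), trans ((L+2) x (L+2)).
// Gate order within the 4H rows: input, forget, candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

List crf_forward_backward_cpp(const arma::mat& emissions,
                              const arma::mat& transitions);

struct LstmCache {
  arma::mat i, f, g, o, c, h, tanhc; // H x T each
};

static arma::mat sigmoid(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// X is E x T; returns h (H x T) in original token order.
static void lstm_forward(const arma::mat& W, const arma::mat& U,
                         const arma::vec& b, const arma::mat& X,
                         bool reverse, LstmCache& cc) {
  const int T = X.n_cols, H = U.n_cols;
  cc.i.set_size(H, T); cc.f.set_size(H, T); cc.g.set_size(H, T);
  cc.o.set_size(H, T); cc.c.set_size(H, T); cc.h.set_size(H, T);
  cc.tanhc.set_size(H, T);
  arma::vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    arma::vec z = W * X.col(t) + U * hprev + b;
    arma::vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
    arma::vec f = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
    arma::vec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    arma::vec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
    arma::vec c = f % cprev + i % g;
    arma::vec tc = arma::tanh(c);
    arma::vec h = o % tc;
    cc.i.col(t) = i; cc.f.col(t) = f; cc.g.col(t) = g; cc.o.col(t) = o;
    cc.c.col(t) = c; cc.h.col(t) = h; cc.tanhc.col(t) = tc;
    hprev = h; cprev = c;
  }
}

// dH is H x T (dLoss/dh_t); accumulates parameter grads and returns dX (E x T).
static arma::mat lstm_backward(const arma::mat& W, const arma::mat& U,
                               const arma::mat& X, bool reverse,
                               const LstmCache& cc, const arma::mat& dH,
                               arma::mat& gW, arma::mat& gU, arma::vec& gb) {
  const int T = X.n_cols, H = U.n_cols;
  arma::mat dX(X.n_rows, T, arma::fill::zeros);
  arma::vec dh_carry(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    int tprev = reverse ? t + 1 : t - 1; // previous step in processing order
    arma::vec cprev = (s == 0) ? arma::vec(H, arma::fill::zeros)
                               : arma::vec(cc.c.col(tprev));
    arma::vec hprev = (s == 0) ? arma::vec(H, arma::fill::zeros)
                               : arma::vec(cc.h.col(tprev));
    arma::vec dh = dH.col(t) + dh_carry;
    arma::vec i = cc.i.col(t), f = cc.f.col(t), g = cc.g.col(t),
              o = cc.o.col(t), tc = cc.tanhc.col(t);
    arma::vec do_ = dh % tc;
    arma::vec dct = dc + dh % o % (1.0 - tc % tc);
    arma::vec di = dct % g;
    arma::vec df = dct % cprev;
    arma::vec dg = dct % i;
    dc = dct % f;
    arma::vec dz(4 * H);
    dz.subvec(0, H - 1)         = di % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    gW += dz * X.col(t).t();
    gU += dz * hprev.t();
    gb += dz;
    dh_carry = U.t() * dz;
    dX.col(t) += W.t() * dz;
  }
  return dX;
}

// [[Rcpp::export(name = ".bilstm_emissions_cpp")]]
arma::mat bilstm_emissions_cpp(const List& params, const IntegerVector& words) {
  arma::mat emb = params["emb"], Wf = params["Wf"], Uf = params["Uf"],
            Wb = params["Wb"], Ub = params["Ub"], Wo = params["Wo"],
            bf = params["bf"], bb = params["bb"], bo = params["bo"];
  const int T = words.size();
  arma::mat X(emb.n_cols, T);
  for (int t = 0; t < T; ++t) X.col(t) = emb.row(words[t] - 1).t();
  LstmCache cf, cb;
  lstm_forward(Wf, Uf, bf.col(0), X, false, cf);
  lstm_forward(Wb, Ub, bb.col(0), X, true, cb);
  arma::mat HH = arma::join_cols(cf.h, cb.h); // 2H x T
  arma::mat em = (Wo * HH).t();               // T x L
  em.each_row() += bo.col(0).t();
  return em;
}

static void adam_update(arma::mat& p, arma::mat& m, arma::mat& v,
                        const arma::mat& g, double lr, double b1, double b2,
                        double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// One training epoch over the given sentence order (1-based indices into
// `sentences`). Returns updated parameters, Adam state, step counter and the
// mean per-sentence negative log-likelihood.
// [[Rcpp::export(name = ".bilstm_train_epoch_cpp")]]
List bilstm_train_epoch_cpp(List params, List adam_m, List adam_v,
                            const List& sentences, const List& labels,
                            const IntegerVector& order, double lr,
                            double beta1, double beta2, double eps,
                            int batch_size, int step0) {
  const char* keys[10] = {"emb", "Wf", "Uf", "bf", "Wb", "Ub", "bb",
                          "Wo", "bo", "trans"};
  std::vector<arma::mat> P(10), M(10), V(10), G(10);
  for (int k = 0; k < 10; ++k) {
    P[k] = as<arma::mat>(params[keys[k]]);
    M[k] = as<arma::mat>(adam_m[keys[k]]);
    V[k] = as<arma::mat>(adam_v[keys[k]]);
    G[k] = arma::mat(P[k].n_rows, P[k].n_cols, arma::fill::zeros);
  }
  arma::mat &emb = P[0], &Wf = P[1], &Uf = P[2], &bf = P[3], &Wb = P[4],
            &Ub = P[5], &bb = P[6], &Wo = P[7], &bo = P[8], &trans = P[9];
  const int L = Wo.n_rows, H = Uf.n_cols;
  int step = step0, in_batch = 0;
  double total_loss = 0.0;

  for (int oi = 0; oi < order.size(); ++oi) {
    IntegerVector words = sentences[order[oi] - 1];
    IntegerVector gold = labels[order[oi] - 1];
    const int T = words.size();
    if (T == 0) continue;

    arma::mat X(emb.n_cols, T);
    for (int t = 0; t < T; ++t) X.col(t) = emb.row(words[t] - 1).t();
    LstmCache cf, cb;
    lstm_forward(Wf, Uf, bf.col(0), X, false, cf);
    lstm_forward(Wb, Ub, bb.col(0), X, true, cb);
    arma::mat HH = arma::join_cols(cf.h, cb.h);
    arma::mat em = (Wo * HH).t();
    em.each_row() += bo.col(0).t();

    List fb = crf_forward_backward_cpp(em, trans);
    double logZ = fb["logZ"];
    arma::mat marg = fb["marginals"];
    arma::mat etr = fb["expected_transitions"];

    // gold path score and count subtraction
    double gscore = trans(L, gold[0] - 1) + em(0, gold[0] - 1);
    arma::mat dTr = etr;
    dTr(L, gold[0] - 1) -= 1.0;
    for (int t = 1; t < T; ++t) {
      gscore += trans(gold[t - 1] - 1, gold[t] - 1) + em(t, gold[t] - 1);
      dTr(gold[t - 1] - 1, gold[t] - 1) -= 1.0;
    }
    gscore += trans(gold[T - 1] - 1, L + 1);
    dTr(gold[T - 1] - 1, L + 1) -= 1.0;
    total_loss += logZ - gscore;

    arma::mat dE = marg; // T x L
    for (int t = 0; t < T; ++t) dE(t, gold[t] - 1) -= 1.0;

    // output layer grads
    G[7] += dE.t() * HH.t();          // gWo
    G[8].col(0) += arma::sum(dE, 0).t(); // gbo
    G[9] += dTr;                      // gtrans
    arma::mat dHH = Wo.t() * dE.t();  // 2H x T
    arma::vec gbf(4 * H, arma::fill::zeros), gbb(4 * H, arma::fill::zeros);
    arma::mat dXf = lstm_backward(Wf, Uf, X, false, cf,
                                  dHH.rows(0, H - 1), G[1], G[2], gbf);
    arma::mat dXb = lstm_backward(Wb, Ub, X, true, cb,
                                  dHH.rows(H, 2 * H - 1), G[4], G[5], gbb);
    G[3].col(0) += gbf; G[6].col(0) += gbb;
    arma::mat dX = dXf + dXb;
    for (int t = 0; t < T; ++t)
      G[0].row(words[t] - 1) += dX.col(t).t();

    if (++in_batch == batch_size || oi == order.size() - 1) {
      ++step;
      for (int k = 0; k < 10; ++k) {
        G[k] /= in_batch;
        adam_update(P[k], M[k], V[k], G[k], lr, beta1, beta2, eps, step);
        G[k].zeros();
      }
      in_batch = 0;
    }
  }

  List outP(10), outM(10), outV(10);
  CharacterVector nm(10);
  for (int k = 0; k < 10; ++k) {
    outP[k] = P[k]; outM[k] = M[k]; outV[k] = V[k]; nm[k] = keys[k];
  }
  outP.attr("names") = nm; outM.attr("names") = nm; outV.attr("names") = nm;
  int nsent = order.size();
  return List::create(_["params"] = outP, _["m"] = outM, _["v"] = outV,
                      _["loss"] = total_loss / std::max(1, nsent),
                      _["step"] = step);
}
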