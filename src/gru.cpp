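// Batched single-layer GRU language model over token sequences.
// Parameters live in an R list of matrices; all randomness comes from R's
// RNG so that set.seed() in R governs sampling bit-for-bit.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct GruParams {
  arma::mat E;                       // V x De token embeddings
  arma::mat Wz, Wr, Wh;              // De x H
  arma::mat Uz, Ur, Uh;              // H x H
  arma::rowvec bz, br, bh;           // H
  arma::mat Wo;                      // H x V
  arma::rowvec bo;                   // V
};

static GruParams unpack(const List& p) {
  GruParams g;
  g.E  = as<arma::mat>(p["E"]);
  g.Wz = as<arma::mat>(p["Wz"]); g.Wr = as<arma::mat>(p["Wr"]); g.Wh = as<arma::mat>(p["Wh"]);
  g.Uz = as<arma::mat>(p["Uz"]); g.Ur = as<arma::mat>(p["Ur"]); g.Uh = as<arma::mat>(p["Uh"]);
  g.bz = as<arma::rowvec>(p["bz"]); g.br = as<arma::rowvec>(p["br"]); g.bh = as<arma::rowvec>(p["bh"]);
  g.Wo = as<arma::mat>(p["Wo"]); g.bo = as<arma::rowvec>(p["bo"]);
  return g;
}

static inline arma::mat sigmoid(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// row-wise log-softmax, numerically stable. The first vocabulary entry is
// the start marker by package convention; it is never a legal next token,
// so its logit is masked out and the distribution normalizes over the
// remaining tokens.
static arma::mat log_softmax_rows(const arma::mat& logits_in) {
  arma::mat logits = logits_in;
  logits.col(0).fill(-1e30);
  arma::vec m = arma::max(logits, 1);
  arma::mat shifted = logits.each_col() - m;
  arma::vec lse = arma::log(arma::sum(arma::exp(shifted), 1));
  return shifted.each_col() - lse;
}

// Sequence log-likelihood and (optionally) the gradient of
//   L = sum_b seqw[b] * (-log p(sequence_b))
// X is B x T of 1-based token ids (0 = padding); each row is
// START t1 ... tk END; len gives the full row length including both markers.
// [[Rcpp::export]]
List cpp_gru_logprob_grad(List params, IntegerMatrix X, IntegerVector len,
                          NumericVector seqw, bool want_grad) {
  GruParams g = unpack(params);
  const int B = X.nrow(), T = X.ncol();
  const int H = g.Uz.n_rows, De = g.E.n_cols, V = g.E.n_rows;

  arma::mat h(B, H, arma::fill::zeros);
  arma::vec lp(B, arma::fill::zeros);

  std::vector<arma::mat> s_x, s_z, s_r, s_c, s_hprev, s_dlogits;
  std::vector<arma::vec> s_mask;
  std::vector<std::vector<int>> s_tok;

  GruParams gr;  // gradient accumulators
  if (want_grad) {
    gr.E.zeros(V, De);
    gr.Wz.zeros(De, H); gr.Wr.zeros(De, H); gr.Wh.zeros(De, H);
    gr.Uz.zeros(H, H);  gr.Ur.zeros(H, H);  gr.Uh.zeros(H, H);
    gr.bz.zeros(H); gr.br.zeros(H); gr.bh.zeros(H);
    gr.Wo.zeros(H, V); gr.bo.zeros(V);
  }

  for (int t = 0; t < T - 1; ++t) {
    arma::vec mask(B, arma::fill::zeros);
    std::vector<int> toks(B, 0);
    arma::mat x(B, De, arma::fill::zeros);
    bool any_active = false;
    for (int b = 0; b < B; ++b) {
      if (t + 1 < len[b]) {                  // target X(b, t+1) exists
        mask(b) = 1.0; any_active = true;
        toks[b] = X(b, t);                   // input token (1-based)
        x.row(b) = g.E.row(toks[b] - 1);
      }
    }
    if (!any_active) break;

    arma::mat z = sigmoid(x * g.Wz + h * g.Uz + arma::repmat(g.bz, B, 1));
    arma::mat r = sigmoid(x * g.Wr + h * g.Ur + arma::repmat(g.br, B, 1));
    arma::mat c = arma::tanh(x * g.Wh + (r % h) * g.Uh + arma::repmat(g.bh, B, 1));
    arma::mat hnew = (1.0 - z) % h + z % c;
    arma::mat hprev = h;
    arma::mat hdiff = hnew - hprev;
    h = hprev + hdiff.each_col() % mask;            // inactive rows keep state

    arma::mat logits = h * g.Wo + arma::repmat(g.bo, B, 1);
    arma::mat logp = log_softmax_rows(logits);

    arma::mat dlogits;
    if (want_grad) dlogits.set_size(B, V);
    for (int b = 0; b < B; ++b) {
      if (mask(b) > 0.5) {
        int tgt = X(b, t + 1) - 1;
        lp(b) += logp(b, tgt);
        if (want_grad) {
          dlogits.row(b) = seqw[b] * arma::exp(logp.row(b));
          dlogits(b, tgt) -= seqw[b];
        }
      } else if (want_grad) {
        dlogits.row(b).zeros();
      }
    }
    if (want_grad) {
      s_x.push_back(x); s_z.push_back(z); s_r.push_back(r); s_c.push_back(c);
      s_hprev.push_back(hprev); s_mask.push_back(mask); s_tok.push_back(toks);
      s_dlogits.push_back(dlogits);
    }
  }

  List out = List::create(Named("lp") = NumericVector(lp.begin(), lp.end()));
  if (!want_grad) return out;

  const int S = (int)s_x.size();
  arma::mat dh(B, H, arma::fill::zeros);
  for (int t = S - 1; t >= 0; --t) {
    const arma::mat &x = s_x[t], &z = s_z[t], &r = s_r[t], &c = s_c[t], &hprev = s_hprev[t];
    const arma::vec& mask = s_mask[t];
    // state after this step feeds the output layer of this step
    arma::mat hdiff = (1.0 - z) % hprev + z % c - hprev;
    arma::mat hcur = hprev + hdiff.each_col() % mask;
    gr.Wo += hcur.t() * s_dlogits[t];
    gr.bo += arma::sum(s_dlogits[t], 0);
    dh += s_dlogits[t] * g.Wo.t();

    arma::mat dh_act  = dh.each_col() % mask;
    arma::mat dh_skip = dh - dh_act;                 // flows through unchanged state

    arma::mat dc = dh_act % z;
    arma::mat da = dc % (1.0 - c % c);
    gr.Wh += x.t() * da;
    gr.Uh += (r % hprev).t() * da;
    gr.bh += arma::sum(da, 0);
    arma::mat drh = da * g.Uh.t();
    arma::mat dr = drh % hprev;
    arma::mat dhprev = drh % r + dh_act % (1.0 - z);

    arma::mat dz = dh_act % (c - hprev);
    arma::mat daz = dz % z % (1.0 - z);
    gr.Wz += x.t() * daz; gr.Uz += hprev.t() * daz; gr.bz += arma::sum(daz, 0);
    dhprev += daz * g.Uz.t();

    arma::mat dar = dr % r % (1.0 - r);
    gr.Wr += x.t() * dar; gr.Ur += hprev.t() * dar; gr.br += arma::sum(dar, 0);
    dhprev += dar * g.Ur.t();

    arma::mat dx = da * g.Wh.t() + daz * g.Wz.t() + dar * g.Wr.t();
    for (int b = 0; b < B; ++b)
      if (mask(b) > 0.5) gr.E.row(s_tok[t][b] - 1) += dx.row(b);

    dh = dhprev + dh_skip;
  }

  out["grad"] = List::create(
    Named("E") = gr.E, Named("Wz") = gr.Wz, Named("Wr") = gr.Wr, Named("Wh") = gr.Wh,
    Named("Uz") = gr.Uz, Named("Ur") = gr.Ur, Named("Uh") = gr.Uh,
    Named("bz") = gr.bz, Named("br") = gr.br, Named("bh") = gr.bh,
    Named("Wo") = gr.Wo, Named("bo") = gr.bo);
  return out;
}

// Ancestral sampling of n sequences. Sampling uses logits/temperature;
// the returned log-probs are always evaluated at temperature 1.
// Returns X (n x max_len, 1-based ids, 0-padded), lp, len, terminated.
// [[Rcpp::export]]
List cpp_gru_sample(List params, int n, int max_len, double temperature,
                    int start_id, int end_id) {
  GruParams g = unpack(params);
  const int H = g.Uz.n_rows, De = g.E.n_cols, V = g.E.n_rows;

  IntegerMatrix X(n, max_len);
  NumericVector lp(n);
  IntegerVector len(n);
  LogicalVector terminated(n);
  arma::mat h(n, H, arma::fill::zeros);
  std::vector<bool> active(n, true);
  for (int b = 0; b < n; ++b) { X(b, 0) = start_id; len[b] = 1; }

  GetRNGstate();
  for (int t = 1; t < max_len; ++t) {
    bool any = false;
    arma::mat x(n, De, arma::fill::zeros);
    for (int b = 0; b < n; ++b)
      if (active[b]) { x.row(b) = g.E.row(X(b, t - 1) - 1); any = true; }
    if (!any) break;

    arma::mat z = sigmoid(x * g.Wz + h * g.Uz + arma::repmat(g.bz, n, 1));
    arma::mat r = sigmoid(x * g.Wr + h * g.Ur + arma::repmat(g.br, n, 1));
    arma::mat c = arma::tanh(x * g.Wh + (r % h) * g.Uh + arma::repmat(g.bh, n, 1));
    arma::mat hnew = (1.0 - z) % h + z % c;
    for (int b = 0; b < n; ++b) if (active[b]) h.row(b) = hnew.row(b);

    arma::mat logits = h * g.Wo + arma::repmat(g.bo, n, 1);
    arma::mat logp1 = log_softmax_rows(logits);
    arma::mat logpT = log_softmax_rows(logits / temperature);

    for (int b = 0; b < n; ++b) {
      if (!active[b]) continue;
      double u = unif_rand(), acc = 0.0;
      int pick = V - 1;
      for (int v = 0; v < V; ++v) {
        acc += std::exp(logpT(b, v));
        if (u <= acc) { pick = v; break; }
      }
      X(b, t) = pick + 1;
      lp[b] += logp1(b, pick);
      len[b] = t + 1;
      if (pick + 1 == end_id) { active[b] = false; terminated[b] = true; }
    }
  }
  PutRNGstate();

  return List::create(Named("X") = X, Named("lp") = lp,
                      Named("len") = len, Named("terminated") = terminated);
}
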