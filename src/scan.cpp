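#include <Rcpp.h>
using namespace Rcpp;

// Poisson log-likelihood ratio of a circular zone under the conditional
// scan model: D*log(D/E) + (C-D)*log((C-D)/(C-E)) with E = U*C/N, and 0
// when D <= E (one-sided high-risk indicator). Conventions 0*log(0/x)=0.
static inline double zone_llr(double D, double E, double C) {
  if (D <= E || D <= 0.0) return 0.0;
  double llr = D * std::log(D / E);
  if (C - D > 0.0) llr += (C - D) * std::log((C - D) / (C - E));
  return llr;
}

// Best zone per centre over nested distance-ordered prefixes.
// ord: H x H integer matrix (0-based), row i = centre i then other
//      districts by increasing distance; mlen: number of admissible
//      members per centre under the population cap.
// [[Rcpp::export]]
List scan_best_zones(const IntegerMatrix& ord, const IntegerVector& mlen,
                     const NumericVector& pop, const IntegerVector& cases,
                     double C, double N) {
  int H = ord.nrow();
  NumericVector best_llr(H);
  IntegerVector best_j(H);
  for (int i = 0; i < H; ++i) {
    double U = 0.0, D = 0.0, best = 0.0;
    int bj = 1;
    for (int j = 0; j < mlen[i]; ++j) {
      int d = ord(i, j);
      U += pop[d];
      D += cases[d];
      double llr = zone_llr(D, U * C / N, C);
      if (llr > best) { best = llr; bj = j + 1; }
    }
    best_llr[i] = best;
    best_j[i] = bj;           // zone size achieving the centre's max LLR
  }
  return List::create(_["llr"] = best_llr, _["size"] = best_j);
}

// Max scan statistic for n_mc conditional-multinomial null replicates:
// C cases dropped on districts with probabilities u_i / N.
// [[Rcpp::export]]
NumericVector scan_null_max(const IntegerMatrix& ord,
                            const IntegerVector& mlen,
                            const NumericVector& pop, int C, double N,
                            int n_mc) {
  int H = ord.nrow();
  NumericVector prob(H);
  for (int i = 0; i < H; ++i) prob[i] = pop[i] / N;
  NumericVector out(n_mc);
  IntegerVector draw(H);
  RNGScope scope;
  for (int r = 0; r < n_mc; ++r) {
    rmultinom(C, prob.begin(), H, draw.begin());
    double maxllr = 0.0;
    for (int i = 0; i < H; ++i) {
      double U = 0.0, D = 0.0;
      for (int j = 0; j < mlen[i]; ++j) {
        int d = ord(i, j);
        U += pop[d];
        D += draw[d];
        double llr = zone_llr(D, U * C / N, (double)C);
        if (llr > maxllr) maxllr = llr;
      }
    }
    out[r] = maxllr;
  }
  return out;
}
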