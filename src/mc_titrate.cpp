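#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte Carlo over protonation microstates.
//
// Sites carry contiguous blocks of global microstate indices
// (site_offset[s] .. site_offset[s]+site_nms[s]-1, 0-based).  esingle is the
// pH-specific singleton energy of every global microstate (kcal/mol); W is
// the pairwise interaction matrix (kcal/mol, zero within a site's own
// block).  One sweep = n_sites attempted moves; a move is either a
// single-site microstate change or, with probability pair_prob, a
// simultaneous change of a strongly coupled site pair.  Populations are
// accumulated once per sweep after burn-in; standard errors come from batch
// means over nbatch equal batches.  Randomness is drawn from R's RNG so
// set.seed() makes runs exactly reproducible.
// [[Rcpp::export]]
List cpp_mc_titrate(IntegerVector site_offset, IntegerVector site_nms,
                    NumericVector esingle, NumericMatrix W, double kT,
                    int sweeps, int burnin, int nbatch,
                    IntegerMatrix pairs, double pair_prob,
                    IntegerVector start_state) {
  const int ns = site_offset.size();
  const int ng = esingle.size();
  const int npairs = pairs.nrow();
  std::vector<int> cur(ns);      // local microstate index per site
  std::vector<int> gcur(ns);     // global microstate index per site
  for (int s = 0; s < ns; ++s) {
    cur[s] = start_state[s];
    gcur[s] = site_offset[s] + cur[s];
  }
  const double beta = 1.0 / kT;

  // energy change for moving site s to local state b (given current state)
  auto dE_single = [&](int s, int b) {
    const int ga = gcur[s];
    const int gb = site_offset[s] + b;
    double d = esingle[gb] - esingle[ga];
    for (int t = 0; t < ns; ++t) {
      if (t == s) continue;
      d += W(gb, gcur[t]) - W(ga, gcur[t]);
    }
    return d;
  };

  long accepted = 0, attempted = 0;
  std::vector<double> counts(ng, 0.0);
  NumericMatrix batch(nbatch, ng);
  const int per_batch = std::max(1, sweeps / nbatch);

  for (int sweep = 0; sweep < burnin + sweeps; ++sweep) {
    for (int mv = 0; mv < ns; ++mv) {
      const bool do_pair = (npairs > 0) && (unif_rand() < pair_prob);
      if (!do_pair) {
        const int s = (int)(unif_rand() * ns);
        if (site_nms[s] < 2) continue;
        int b = (int)(unif_rand() * (site_nms[s] - 1));
        if (b >= cur[s]) ++b;
        const double d = dE_single(s, b);
        ++attempted;
        if (d <= 0.0 || unif_rand() < std::exp(-beta * d)) {
          cur[s] = b;
          gcur[s] = site_offset[s] + b;
          ++accepted;
        }
      } else {
        const int pr = (int)(unif_rand() * npairs);
        const int s1 = pairs(pr, 0), s2 = pairs(pr, 1);
        int b1 = (int)(unif_rand() * (site_nms[s1] - 1));
        if (b1 >= cur[s1]) ++b1;
        int b2 = (int)(unif_rand() * (site_nms[s2] - 1));
        if (b2 >= cur[s2]) ++b2;
        const int ga1 = gcur[s1], ga2 = gcur[s2];
        const int gb1 = site_offset[s1] + b1, gb2 = site_offset[s2] + b2;
        double d = esingle[gb1] - esingle[ga1] + esingle[gb2] - esingle[ga2];
        for (int t = 0; t < ns; ++t) {
          if (t == s1 || t == s2) continue;
          d += W(gb1, gcur[t]) - W(ga1, gcur[t]);
          d += W(gb2, gcur[t]) - W(ga2, gcur[t]);
        }
        d += W(gb1, gb2) - W(ga1, ga2);
        ++attempted;
        if (d <= 0.0 || unif_rand() < std::exp(-beta * d)) {
          cur[s1] = b1; gcur[s1] = site_offset[s1] + b1;
          cur[s2] = b2; gcur[s2] = site_offset[s2] + b2;
          ++accepted;
        }
      }
    }
    if (sweep >= burnin) {
      const int sw = sweep - burnin;
      const int bi = std::min(nbatch - 1, sw / per_batch);
      for (int s = 0; s < ns; ++s) {
        counts[gcur[s]] += 1.0;
        batch(bi, gcur[s]) += 1.0;
      }
    }
  }

  NumericVector pops(ng), se(ng);
  for (int g = 0; g < ng; ++g) pops[g] = counts[g] / sweeps;
  // batch means -> standard error of the mean
  for (int g = 0; g < ng; ++g) {
    double mean = 0.0;
    std::vector<double> bm(nbatch);
    for (int b = 0; b < nbatch; ++b) {
      const int nsw = (b == nbatch - 1) ? (sweeps - per_batch * (nbatch - 1))
                                        : per_batch;
      bm[b] = batch(b, g) / std::max(1, nsw);
      mean += bm[b];
    }
    mean /= nbatch;
    double var = 0.0;
    for (int b = 0; b < nbatch; ++b)
      var += (bm[b] - mean) * (bm[b] - mean);
    var /= (nbatch - 1);
    se[g] = std::sqrt(var / nbatch);
  }
  return List::create(_["pops"] = pops, _["se"] = se,
                      _["acceptance"] = attempted > 0
                        ? (double)accepted / attempted : 0.0);
}
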