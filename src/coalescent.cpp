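#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// Single-locus structured coalescent under an ms-style demographic model
// (no intra-locus recombination).  Times are in units of 4*N0 generations,
// sizes relative to N0, migration rates M = 4*N0*m: a lineage in i moves to
// j (backwards in time) at rate M_ij per unit time.  Events, sorted by time:
//   type 0: set size of population i to x
//   type 1: set migration rate from i to j (backwards) to x
//   type 2: join - lineages of population i move into j, migration rates
//           involving i are zeroed (ms -ej semantics)
// Mutations are dropped on the realised genealogy at rate theta per unit
// branch length (branch lengths in 4*N0 generations, theta = 4*N0*mu*L;
// infinite sites), so E[S] = theta * a_{n-1} for a constant-size single
// population. Each mutation yields one SNP row of per-population derived
// allele counts.
//
// Per-population B multipliers (bmat row) rescale every size of that
// population, including sizes set by later epoch-change events; this is the
// "multiply the Ne estimates by the B score" device used to emulate
// background selection.

struct Node {
  double time;
  double blen;              // branch to parent, filled when merged
  std::vector<int> popcnt;  // descendant sample counts per population
};

// [[Rcpp::export(name = ".sim_loci_cpp")]]
List sim_loci_cpp(double theta,
                  IntegerVector sample_sizes,
                  NumericVector init_sizes,
                  NumericMatrix init_mig,
                  NumericMatrix events, // cols: time, type, i, j, x
                  NumericMatrix bmat,   // n_loci x npop
                  double seed) {
  const int npop = sample_sizes.size();
  const int nloci = bmat.nrow();
  if (bmat.ncol() != npop) stop("bmat must have one column per population");
  const int nev = events.nrow();
  const int ntot = sum(sample_sizes);
  if (ntot < 2) stop("need at least two sampled lineages");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> out_locus;
  std::vector<int> out_counts; // row-major npop per SNP

  std::vector<std::vector<int>> pops(npop);
  std::vector<double> sizes(npop);
  std::vector<double> mig(npop * npop);
  std::vector<Node> nodes;
  nodes.reserve(2 * ntot);

  for (int l = 0; l < nloci; ++l) {
    // reset state
    nodes.clear();
    for (int k = 0; k < npop; ++k) {
      pops[k].clear();
      sizes[k] = init_sizes[k] * bmat(l, k);
      for (int j = 0; j < npop; ++j) mig[k * npop + j] = init_mig(k, j);
    }
    for (int k = 0; k < npop; ++k)
      for (int s = 0; s < sample_sizes[k]; ++s) {
        Node nd; nd.time = 0.0; nd.blen = 0.0;
        nd.popcnt.assign(npop, 0); nd.popcnt[k] = 1;
        pops[k].push_back((int)nodes.size());
        nodes.push_back(std::move(nd));
      }

    double t = 0.0;
    int iev = 0;
    int nact = ntot;
    double ttot = 0.0;

    while (nact > 1) {
      // total event rate
      double rate = 0.0;
      for (int k = 0; k < npop; ++k) {
        double nk = (double)pops[k].size();
        if (nk >= 2) rate += nk * (nk - 1.0) / sizes[k];
        if (nk >= 1) {
          double mrow = 0.0;
          for (int j = 0; j < npop; ++j) if (j != k) mrow += mig[k * npop + j];
          rate += nk * mrow;
        }
      }
      double tnext = R_PosInf;
      if (rate > 0.0) {
        double u = unif(rng);
        if (u <= 0.0) u = 1e-300;
        tnext = t - std::log(u) / rate;
      }
      if (iev < nev && tnext >= events(iev, 0)) {
        // demographic event fires first
        t = events(iev, 0);
        int type = (int)events(iev, 1);
        int i = (int)events(iev, 2) - 1;
        int j = (int)events(iev, 3) - 1;
        double x = events(iev, 4);
        if (type == 0) {
          sizes[i] = x * bmat(l, i);
        } else if (type == 1) {
          mig[i * npop + j] = x;
        } else if (type == 2) {
          for (size_t q = 0; q < pops[i].size(); ++q) pops[j].push_back(pops[i][q]);
          pops[i].clear();
          for (int q = 0; q < npop; ++q) { mig[i * npop + q] = 0.0; mig[q * npop + i] = 0.0; }
        }
        ++iev;
        continue;
      }
      if (!R_finite(tnext)) {
        if (iev < nev) { // rates all zero but events remain: jump to next event
          t = events(iev, 0);
          continue;
        }
        stop("coalescent cannot complete: zero rates with %d lineages left "
             "(population not reachable from the root?)", nact);
      }
      t = tnext;
      // pick the event
      double u = unif(rng) * rate;
      double acc = 0.0;
      int done = 0;
      for (int k = 0; k < npop && !done; ++k) {
        double nk = (double)pops[k].size();
        if (nk >= 2) {
          double ck = nk * (nk - 1.0) / sizes[k];
          if (u < acc + ck) {
            // coalesce a random pair in k
            int a = (int)(unif(rng) * nk); if (a >= (int)nk) a = (int)nk - 1;
            int b = (int)(unif(rng) * (nk - 1)); if (b >= (int)nk - 1) b = (int)nk - 2;
            if (b >= a) ++b;
            int na = pops[k][a], nb = pops[k][b];
            Node par; par.time = t; par.blen = 0.0;
            par.popcnt.assign(npop, 0);
            for (int q = 0; q < npop; ++q)
              par.popcnt[q] = nodes[na].popcnt[q] + nodes[nb].popcnt[q];
            nodes[na].blen = t - nodes[na].time;
            nodes[nb].blen = t - nodes[nb].time;
            ttot += nodes[na].blen + nodes[nb].blen;
            // replace a by parent, drop b
            int pid = (int)nodes.size();
            nodes.push_back(std::move(par));
            pops[k][a] = pid;
            pops[k][b] = pops[k].back();
            pops[k].pop_back();
            --nact;
            done = 1;
            break;
          }
          acc += ck;
        }
        if (nk >= 1) {
          for (int j = 0; j < npop; ++j) {
            if (j == k) continue;
            double mk = nk * mig[k * npop + j];
            if (mk <= 0.0) continue;
            if (u < acc + mk) {
              int a = (int)(unif(rng) * nk); if (a >= (int)nk) a = (int)nk - 1;
              pops[j].push_back(pops[k][a]);
              pops[k][a] = pops[k].back();
              pops[k].pop_back();
              done = 1;
              break;
            }
            acc += mk;
          }
          if (done) break;
        }
      }
    }

    // drop mutations
    std::poisson_distribution<int> pois(theta * ttot);
    int S = ttot > 0 ? pois(rng) : 0;
    if (S > 0) {
      // cumulative branch lengths over all merged nodes
      std::vector<double> cum(nodes.size());
      double c = 0.0;
      for (size_t q = 0; q < nodes.size(); ++q) { c += nodes[q].blen; cum[q] = c; }
      for (int s = 0; s < S; ++s) {
        double u = unif(rng) * c;
        size_t lo = 0, hi = nodes.size() - 1;
        while (lo < hi) {
          size_t mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        out_locus.push_back(l + 1);
        for (int q = 0; q < npop; ++q) out_counts.push_back(nodes[lo].popcnt[q]);
      }
    }
  }

  int nsnp = (int)out_locus.size();
  IntegerMatrix counts(nsnp, npop);
  IntegerVector locus(nsnp);
  for (int s = 0; s < nsnp; ++s) {
    locus[s] = out_locus[s];
    for (int q = 0; q < npop; ++q) counts(s, q) = out_counts[(size_t)s * npop + q];
  }
  return List::create(_["locus"] = locus, _["counts"] = counts);
}
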