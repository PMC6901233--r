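#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Saitou-Nei neighbor-joining restricted to what the per-SNP scan needs:
// external (terminal) branch lengths for each taxon.  Ties at the
// join-selection step are broken by the lowest (i, j) index pair so scans
// are deterministic.  Internal branch lengths are computed but discarded.
//
// dist is a flattened upper-triangle (combn(K, 2) column order: (1,2),
// (1,3), ..., (K-1,K)), one row per SNP.  Returns one external branch per
// taxon per SNP, plus a topology code: for K = 4 the code 1/2/3 identifies
// which pair was joined first ((1,2)|(3,4) -> 1, (1,3)|(2,4) -> 2,
// (1,4)|(2,3) -> 3); for K = 3 the code is 0 (single topology); for K > 4
// the code is NA.

static const int MAXK = 16;

// NJ on a single K x K matrix held in d (row-major), writing external
// branch lengths into ext. Returns topology code.
static int nj_one(double *d, int K, double *ext) {
  // ids[i] > 0: active row i is original taxon ids[i]-1; 0: internal node
  int ids[MAXK];
  double D[MAXK * MAXK];
  for (int i = 0; i < K; ++i) ids[i] = i + 1;
  for (int i = 0; i < K * K; ++i) D[i] = d[i];
  int r = K;
  int first_i = -1, first_j = -1;

  while (r > 3) {
    double R[MAXK];
    for (int i = 0; i < r; ++i) {
      double s = 0.0;
      for (int k = 0; k < r; ++k) s += D[i * r + k];
      R[i] = s;
    }
    double qmin = R_PosInf;
    int bi = 0, bj = 1;
    for (int i = 0; i < r - 1; ++i) {
      for (int j = i + 1; j < r; ++j) {
        double q = (r - 2) * D[i * r + j] - R[i] - R[j];
        if (q < qmin - 1e-12) { qmin = q; bi = i; bj = j; }
      }
    }
    if (first_i < 0) { first_i = ids[bi]; first_j = ids[bj]; }
    double vi = 0.5 * D[bi * r + bj] + (R[bi] - R[bj]) / (2.0 * (r - 2));
    double vj = D[bi * r + bj] - vi;
    if (ids[bi] > 0) ext[ids[bi] - 1] = vi;
    if (ids[bj] > 0) ext[ids[bj] - 1] = vj;
    // distances from the new node u to every other active node
    double dn[MAXK];
    for (int k = 0; k < r; ++k)
      dn[k] = 0.5 * (D[bi * r + k] + D[bj * r + k] - D[bi * r + bj]);
    // compact: drop rows bi, bj, append u
    int map[MAXK];
    int m = 0;
    for (int k = 0; k < r; ++k) if (k != bi && k != bj) map[m++] = k;
    double D2[MAXK * MAXK];
    int r2 = r - 1;
    for (int a = 0; a < m; ++a) {
      for (int b = 0; b < m; ++b) D2[a * r2 + b] = D[map[a] * r + map[b]];
      D2[a * r2 + m] = dn[map[a]];
      D2[m * r2 + a] = dn[map[a]];
    }
    D2[m * r2 + m] = 0.0;
    int ids2[MAXK];
    for (int a = 0; a < m; ++a) ids2[a] = ids[map[a]];
    ids2[m] = 0;
    for (int i = 0; i < r2 * r2; ++i) D[i] = D2[i];
    for (int i = 0; i < r2; ++i) ids[i] = ids2[i];
    r = r2;
  }
  // three-point formula for the last three nodes
  double b0 = 0.5 * (D[0 * r + 1] + D[0 * r + 2] - D[1 * r + 2]);
  double b1 = 0.5 * (D[0 * r + 1] + D[1 * r + 2] - D[0 * r + 2]);
  double b2 = 0.5 * (D[0 * r + 2] + D[1 * r + 2] - D[0 * r + 1]);
  double bs[3] = {b0, b1, b2};
  for (int k = 0; k < 3; ++k)
    if (ids[k] > 0) ext[ids[k] - 1] = bs[k];

  if (K == 3) return 0;
  if (K == 4) {
    int a = first_i < first_j ? first_i : first_j;
    int b = first_i < first_j ? first_j : first_i;
    if (a == 1 && b == 2) return 1;
    if (a == 3 && b == 4) return 1;
    if (a == 1 && b == 3) return 2;
    if (a == 2 && b == 4) return 2;
    return 3;
  }
  return NA_INTEGER;
}

// [[Rcpp::export(name = ".nj_batch_cpp")]]
List nj_batch_cpp(NumericMatrix dist, int K) {
  if (K < 3 || K > MAXK) stop("K must be between 3 and %d", MAXK);
  int npair = K * (K - 1) / 2;
  if (dist.ncol() != npair)
    stop("dist must have K*(K-1)/2 columns");
  int n = dist.nrow();
  NumericMatrix ext(n, K);
  IntegerVector topo(n);
  double d[MAXK * MAXK];
  double e[MAXK];
  for (int s = 0; s < n; ++s) {
    int m = 0;
    for (int i = 0; i < K; ++i) d[i * K + i] = 0.0;
    for (int i = 0; i < K - 1; ++i) {
      for (int j = i + 1; j < K; ++j) {
        double v = dist(s, m++);
        if (!R_finite(v)) stop("non-finite distance at SNP %d", s + 1);
        d[i * K + j] = v;
        d[j * K + i] = v;
      }
    }
    topo[s] = nj_one(d, K, e);
    for (int i = 0; i < K; ++i) ext(s, i) = e[i];
  }
  return List::create(_["branches"] = ext, _["topology"] = topo);
}
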