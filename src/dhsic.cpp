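// d-variable HSIC statistic and its permutation null.
//
// The V-statistic form is
//   dHSIC = 1/n^2 sum_{i,j} prod_l K_l(i,j)
//         + prod_l (1/n^2 sum_{i,j} K_l(i,j))
//         - 2/n sum_i prod_l (1/n sum_j K_l(i,j))
// Permuting variable l's sample indices permutes K_l symmetrically, which
// leaves each kernel's grand mean and the multiset of its row means
// unchanged; only the first term and the pairing of row means need the
// permuted indices.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double dhsic_eval(const std::vector<const double *> &K,
                         const std::vector<std::vector<double>> &rowmean,
                         double t2, const std::vector<const int *> &perm,
                         int n, int d) {
  double t1 = 0.0;
  for (int i = 0; i < n; i++) {
    // diagonal
    double pd = 1.0;
    for (int l = 0; l < d; l++) {
      int pi = perm[l][i];
      pd *= K[l][pi + (R_xlen_t)n * pi];
    }
    t1 += pd;
    for (int j = i + 1; j < n; j++) {
      double p = 1.0;
      for (int l = 0; l < d; l++) {
        int pi = perm[l][i], pj = perm[l][j];
        p *= K[l][pi + (R_xlen_t)n * pj];
      }
      t1 += 2.0 * p;
    }
  }
  t1 /= (double)n * (double)n;
  double t3 = 0.0;
  for (int i = 0; i < n; i++) {
    double p = 1.0;
    for (int l = 0; l < d; l++) p *= rowmean[l][perm[l][i]];
    t3 += p;
  }
  t3 = 2.0 * t3 / n;
  return t1 + t2 - t3;
}

// [[Rcpp::export]]
List dhsic_perm_cpp(List Ks, int n_perm) {
  int d = Ks.size();
  std::vector<NumericMatrix> Kmats(d);
  std::vector<const double *> K(d);
  for (int l = 0; l < d; l++) {
    Kmats[l] = as<NumericMatrix>(Ks[l]);
    K[l] = Kmats[l].begin();
  }
  int n = Kmats[0].nrow();

  std::vector<std::vector<double>> rowmean(d, std::vector<double>(n, 0.0));
  double t2 = 1.0;
  for (int l = 0; l < d; l++) {
    double grand = 0.0;
    for (int j = 0; j < n; j++) {
      double s = 0.0;
      for (int i = 0; i < n; i++) s += K[l][i + (R_xlen_t)n * j];
      rowmean[l][j] = s / n;
      grand += s;
    }
    t2 *= grand / ((double)n * (double)n);
  }

  std::vector<std::vector<int>> identity(d, std::vector<int>(n));
  for (int l = 0; l < d; l++)
    for (int i = 0; i < n; i++) identity[l][i] = i;
  std::vector<const int *> pview(d);
  for (int l = 0; l < d; l++) pview[l] = identity[l].data();
  double stat = dhsic_eval(K, rowmean, t2, pview, n, d);

  NumericVector perms(n_perm);
  std::vector<std::vector<int>> pidx(d, std::vector<int>(n));
  for (int i = 0; i < n; i++) pidx[0][i] = i;  // variable 1 stays fixed
  for (int b = 0; b < n_perm; b++) {
    for (int l = 1; l < d; l++) {
      IntegerVector s = Rcpp::sample(n, n, false);  // uses R's RNG
      for (int i = 0; i < n; i++) pidx[l][i] = s[i] - 1;
    }
    for (int l = 0; l < d; l++) pview[l] = pidx[l].data();
    perms[b] = dhsic_eval(K, rowmean, t2, pview, n, d);
  }
  return List::create(Named("stat") = stat, Named("perms") = perms);
}
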