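#include <Rcpp.h>
using namespace Rcpp;

// Manly-Bejder within-sample permutation chain on group-by-individual
// incidence matrices. The only move is a 2x2 checkerboard swap inside a
// single period, which preserves every row total (group size) and column
// total (times identified per period). Because column totals are
// invariant, the half-weight denominator of each dyad,
// d_ab = (seen_a + seen_b)/2, is fixed along the chain and the HWI only
// changes through the joint-association counts X, which are maintained
// incrementally.

static inline bool joint_in_period(const IntegerMatrix &m, int a, int b) {
  int G = m.nrow();
  for (int g = 0; g < G; ++g) {
    if (m(g, a) && m(g, b)) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".perm_chain")]]
List perm_chain(List mats, IntegerVector seen, int n_save, int thin,
                int burnin, bool return_mats) {
  int P = mats.size();
  std::vector<IntegerMatrix> M(P);
  for (int p = 0; p < P; ++p) M[p] = clone(as<IntegerMatrix>(mats[p]));
  int N = M[0].ncol();

  // sampling weights: matrix size (rows x cols); periods with < 2 rows
  // can never flip and get weight 0
  std::vector<double> cw(P);
  double tot = 0.0;
  for (int p = 0; p < P; ++p) {
    int G = M[p].nrow();
    tot += (G >= 2) ? (double)G * N : 0.0;
    cw[p] = tot;
  }
  if (tot <= 0.0) stop("no period admits a checkerboard flip");

  // initial joint counts X
  IntegerMatrix X(N, N);
  for (int p = 0; p < P; ++p) {
    for (int a = 0; a < N; ++a) {
      for (int b = a + 1; b < N; ++b) {
        if (joint_in_period(M[p], a, b)) { X(a, b)++; X(b, a)++; }
      }
    }
  }

  NumericMatrix stats(n_save, 2);
  long long accepted = 0;
  long long steps = (long long)burnin + (long long)n_save * thin;
  int save_i = 0;
  long long next_save = burnin + thin;
  if (n_save == 0) next_save = -1;

  for (long long s = 1; s <= steps; ++s) {
    // choose period by weight
    double u = unif_rand() * tot;
    int p = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
    if (p >= P) p = P - 1;
    IntegerMatrix &m = M[p];
    int G = m.nrow();
    // two distinct rows, two distinct columns
    int r1 = (int)(unif_rand() * G); if (r1 == G) r1--;
    int r2 = (int)(unif_rand() * (G - 1)); if (r2 == G - 1) r2--;
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * N); if (c1 == N) c1--;
    int c2 = (int)(unif_rand() * (N - 1)); if (c2 == N - 1) c2--;
    if (c2 >= c1) c2++;

    int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    bool flip = (a == 1 && d == 1 && b == 0 && c == 0) ||
                (a == 0 && d == 0 && b == 1 && c == 1);
    if (flip) {
      // joint rows of the two affected columns, before
      std::vector<char> j1o(N), j2o(N);
      for (int e = 0; e < N; ++e) {
        j1o[e] = joint_in_period(m, c1, e);
        j2o[e] = joint_in_period(m, c2, e);
      }
      m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
      m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
      for (int e = 0; e < N; ++e) {
        if (e != c1 && e != c2) {
          int d1 = (int)joint_in_period(m, c1, e) - (int)j1o[e];
          if (d1) { X(c1, e) += d1; X(e, c1) += d1; }
          int d2 = (int)joint_in_period(m, c2, e) - (int)j2o[e];
          if (d2) { X(c2, e) += d2; X(e, c2) += d2; }
        }
      }
      int d12 = (int)joint_in_period(m, c1, c2) - (int)j1o[c2];
      if (d12) { X(c1, c2) += d12; X(c2, c1) += d12; }
      accepted++;
    }

    if (s == next_save) {
      // SD and CV of the HWI over all dyads
      double sum = 0.0, sumsq = 0.0;
      long long nd = 0;
      for (int i = 0; i < N; ++i) {
        for (int j = i + 1; j < N; ++j) {
          double den = 0.5 * (seen[i] + seen[j]);
          double h = den > 0 ? X(i, j) / den : 0.0;
          sum += h; sumsq += h * h; nd++;
        }
      }
      double mean = sum / nd;
      double var = (sumsq - nd * mean * mean) / (nd - 1);
      if (var < 0) var = 0;
      double sd = std::sqrt(var);
      stats(save_i, 0) = sd;
      stats(save_i, 1) = mean > 0 ? sd / mean : NA_REAL;
      save_i++;
      next_save += thin;
      if (save_i >= n_save) next_save = -1;
    }
  }

  List out = List::create(_["stats"] = stats, _["accepted"] = (double)accepted,
                          _["x"] = X);
  if (return_mats) {
    List fm(P);
    for (int p = 0; p < P; ++p) fm[p] = M[p];
    out["mats"] = fm;
  }
  return out;
}
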