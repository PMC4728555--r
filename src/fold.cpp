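#include <Rcpp.h>
using namespace Rcpp;

// Nested-structure thermodynamic engine over a simple per-pair energy
// model: Watson-Crick + GU wobble pairs, additive pair energies, no loop
// terms, minimum hairpin loop of 3 unpaired bases. Bases are encoded
// A=0, C=1, G=2, U=3. Energies in kcal/mol, RT in kcal/mol.

static const int HL = 3; // minimum hairpin loop length

static inline double pair_energy(int a, int b, const double *en) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return en[0]; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return en[1]; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return en[2]; // GU
  return NA_REAL;
}

// inside partition function over all intervals; blocked positions are
// forbidden from pairing (used for constrained/unpaired probabilities)
static NumericMatrix inside_Z(const IntegerVector &s, const double *en,
                              double RT, const LogicalVector &blocked) {
  int n = s.size();
  NumericMatrix Z(n + 2, n + 2);
  std::fill(Z.begin(), Z.end(), 1.0); // empty interval contributes 1
  for (int d = HL + 1; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      double val = Z(i + 1, j); // i unpaired
      if (!blocked[i - 1]) {
        for (int k = i + HL + 1; k <= j; ++k) {
          if (blocked[k - 1]) continue;
          double e = pair_energy(s[i - 1], s[k - 1], en);
          if (ISNA(e)) continue;
          double w = std::exp(-e / RT);
          val += w * Z(i + 1, k - 1) * Z(k + 1, j);
        }
      }
      Z(i, j) = val;
    }
  }
  return Z;
}

// [[Rcpp::export]]
double fold_Z_cpp(IntegerVector s, NumericVector en, double RT,
                  LogicalVector blocked) {
  int n = s.size();
  if (n == 0) return 1.0;
  NumericMatrix Z = inside_Z(s, en.begin(), RT, blocked);
  return Z(1, n);
}

// [[Rcpp::export]]
List fold_bpp_cpp(IntegerVector s, NumericVector en, double RT) {
  int n = s.size();
  const double *e = en.begin();
  LogicalVector blocked(n, false);
  NumericMatrix Z = inside_Z(s, e, RT, blocked);
  double Ztot = (n > 0) ? Z(1, n) : 1.0;

  NumericMatrix P(n, n), Zout(n + 2, n + 2);
  // exterior partition function for each admissible pair (i,j), computed
  // from the largest spans inward: the directly-enclosing pair (p,q), if
  // any, has a strictly larger span
  for (int d = n - 1; d >= HL + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      double eij = pair_energy(s[i - 1], s[j - 1], e);
      if (ISNA(eij)) continue;
      double val = Z(1, i - 1) * Z(j + 1, n);
      for (int p = 1; p <= i - 1; ++p) {
        for (int q = j + 1; q <= n; ++q) {
          double epq = pair_energy(s[p - 1], s[q - 1], e);
          if (ISNA(epq)) continue;
          double w = std::exp(-epq / RT);
          val += w * Zout(p, q) * Z(p + 1, i - 1) * Z(j + 1, q - 1);
        }
      }
      Zout(i, j) = val;
      double w = std::exp(-eij / RT);
      double pij = w * Z(i + 1, j - 1) * val / Ztot;
      P(i - 1, j - 1) = pij;
      P(j - 1, i - 1) = pij;
    }
  }
  return List::create(Named("Z") = Ztot, Named("p") = P);
}

// [[Rcpp::export]]
double fold_mfe_cpp(IntegerVector s, NumericVector en) {
  int n = s.size();
  if (n == 0) return 0.0;
  const double *e = en.begin();
  NumericMatrix E(n + 2, n + 2); // zero-initialized: empty structure
  for (int d = HL + 1; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      double best = E(i + 1, j);
      for (int k = i + HL + 1; k <= j; ++k) {
        double eik = pair_energy(s[i - 1], s[k - 1], e);
        if (ISNA(eik)) continue;
        double v = eik + E(i + 1, k - 1) + E(k + 1, j);
        if (v < best) best = v;
      }
      E(i, j) = best;
    }
  }
  return E(1, n);
}
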