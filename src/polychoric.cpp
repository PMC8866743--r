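// Polychoric correlation core: bivariate-normal CDF (Genz, 1993 algorithm),
// two-step maximum-likelihood pair estimation with thresholds fixed from the
// margins, and the full pairwise matrix loop.  C++ because the selection
// pipeline evaluates O(10^4) item pairs repeatedly (jackknife weights).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Genz's BVNU: P(X > dh, Y > dk) for standard bivariate normal, corr r.
// Direct translation of the published MATLAB/Fortran routine; max abs error
// ~5e-16 claimed, well below the 1e-4 oracle tolerance used in tests.
static double bvnu(double dh, double dk, double r) {
  if (!R_FINITE(dh) && dh > 0) return 0.0;
  if (!R_FINITE(dk) && dk > 0) return 0.0;
  if (!R_FINITE(dh) && dh < 0) return (!R_FINITE(dk) && dk < 0) ? 1.0 : phid(-dk);
  if (!R_FINITE(dk) && dk < 0) return phid(-dh);
  if (r == 0.0) return phid(-dh) * phid(-dk);

  static const double w3[3] = {0.1713244923791705, 0.3607615730481384, 0.4679139345726904};
  static const double x3[3] = {0.9324695142031522, 0.6612093864662647, 0.2386191860831970};
  static const double w6[6] = {0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
                               0.2031674267230659, 0.2334925365383547, 0.2491470458134029};
  static const double x6[6] = {0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
                               0.5873179542866171, 0.3678314989981802, 0.1252334085114692};
  static const double w10[10] = {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
                                 0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
                                 0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
                                 0.1527533871307259};
  static const double x10[10] = {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
                                 0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
                                 0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
                                 0.07652652113349733};
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { w = w3;  x = x3;  lg = 3; }
  else if (ar < 0.75) { w = w6;  x = x6;  lg = 6; }
  else                { w = w10; x = x10; lg = 10; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  const double twopi = 2.0 * M_PI;

  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < lg; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * twopi) + phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as), bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 + c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs), sp = std::sqrt(twopi) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b * (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * w[i] * std::exp(asr2) * (ep - sp);
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X <= a, Y <= b)
static inline double bvn_cdf_(double a, double b, double r) {
  return bvnu(-a, -b, r);
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
NumericVector bvn_cdf_cpp(NumericVector a, NumericVector b, NumericVector rho) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_cdf_(a[i], b[i], rho[i]);
  return out;
}

// Cell probabilities of an r x c table given row thresholds ta (length r-1),
// column thresholds tb (length c-1) and correlation rho.
static void cell_probs(const std::vector<double> &ta, const std::vector<double> &tb,
                       double rho, std::vector<double> &P) {
  int r = (int)ta.size() + 1, c = (int)tb.size() + 1;
  // cumulative CDF grid including +/- infinity borders
  std::vector<double> G((r + 1) * (c + 1));
  for (int i = 0; i <= r; i++) {
    for (int j = 0; j <= c; j++) {
      double av = (i == 0) ? R_NegInf : (i == r ? R_PosInf : ta[i - 1]);
      double bv = (j == 0) ? R_NegInf : (j == c ? R_PosInf : tb[j - 1]);
      double v;
      if (i == 0 || j == 0) v = 0.0;
      else if (i == r && j == c) v = 1.0;
      else if (i == r) v = phid(bv);
      else if (j == c) v = phid(av);
      else v = bvn_cdf_(av, bv, rho);
      G[i * (c + 1) + j] = v;
    }
  }
  P.assign(r * c, 0.0);
  for (int i = 1; i <= r; i++)
    for (int j = 1; j <= c; j++)
      P[(i - 1) * c + (j - 1)] = G[i * (c + 1) + j] - G[(i - 1) * (c + 1) + j] -
                                 G[i * (c + 1) + (j - 1)] + G[(i - 1) * (c + 1) + (j - 1)];
}

static double table_nll(const std::vector<double> &nij, const std::vector<double> &ta,
                        const std::vector<double> &tb, double rho) {
  std::vector<double> P;
  cell_probs(ta, tb, rho, P);
  double nll = 0.0;
  for (size_t i = 0; i < nij.size(); i++) {
    if (nij[i] > 0.0) nll -= nij[i] * std::log(std::max(P[i], 1e-300));
  }
  return nll;
}

// golden-section minimization of the pair NLL over rho in [lo, hi]
static double golden_rho(const std::vector<double> &nij, const std::vector<double> &ta,
                         const std::vector<double> &tb, double lo, double hi) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = table_nll(nij, ta, tb, x1), f2 = table_nll(nij, ta, tb, x2);
  for (int it = 0; it < 70; it++) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = table_nll(nij, ta, tb, x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = table_nll(nij, ta, tb, x2);
    }
    if (b - a < 1e-9) break;
  }
  return (a + b) / 2.0;
}

// Collapse zero-margin rows/cols of a contingency table into the adjacent
// lower category (first row/col collapses upward).  Returns collapsed table;
// sets collapsed=true if anything merged.
static void collapse_table(std::vector<double> &tab, int &r, int &c, bool &collapsed) {
  collapsed = false;
  // rows
  for (int i = 0; i < r;) {
    double rs = 0.0;
    for (int j = 0; j < c; j++) rs += tab[i * c + j];
    if (rs == 0.0 && r > 1) {
      int tgt = (i > 0) ? i - 1 : 1;  // merge into lower neighbour, first row merges up
      for (int j = 0; j < c; j++) tab[tgt * c + j] += tab[i * c + j];
      tab.erase(tab.begin() + i * c, tab.begin() + (i + 1) * c);
      r--; collapsed = true;
    } else i++;
  }
  // cols
  for (int j = 0; j < c;) {
    double cs = 0.0;
    for (int i = 0; i < r; i++) cs += tab[i * c + j];
    if (cs == 0.0 && c > 1) {
      int tgt = (j > 0) ? j - 1 : 1;
      for (int i = 0; i < r; i++) tab[i * c + tgt] += tab[i * c + j];
      for (int i = r - 1; i >= 0; i--) tab.erase(tab.begin() + i * c + j);
      c--; collapsed = true;
    } else j++;
  }
}

// thresholds from margins of a (collapsed) table: probit of cumulative props
static void margin_thresholds(const std::vector<double> &tab, int r, int c,
                              std::vector<double> &ta, std::vector<double> &tb, double &n) {
  std::vector<double> rm(r, 0.0), cm(c, 0.0);
  n = 0.0;
  for (int i = 0; i < r; i++)
    for (int j = 0; j < c; j++) { rm[i] += tab[i * c + j]; cm[j] += tab[i * c + j]; n += tab[i * c + j]; }
  ta.clear(); tb.clear();
  double cum = 0.0;
  for (int i = 0; i < r - 1; i++) { cum += rm[i]; ta.push_back(R::qnorm(cum / n, 0.0, 1.0, 1, 0)); }
  cum = 0.0;
  for (int j = 0; j < c - 1; j++) { cum += cm[j]; tb.push_back(R::qnorm(cum / n, 0.0, 1.0, 1, 0)); }
}

static double polychoric_table(std::vector<double> tab, int r, int c, bool &collapsed,
                               bool &degenerate) {
  collapse_table(tab, r, c, collapsed);
  degenerate = (r < 2 || c < 2);
  if (degenerate) return NA_REAL;
  std::vector<double> ta, tb;
  double n;
  margin_thresholds(tab, r, c, ta, tb, n);
  double rho = golden_rho(tab, ta, tb, -0.999, 0.999);
  // honor the clamp contract at the boundary
  if (rho > 0.999) rho = 0.999;
  if (rho < -0.999) rho = -0.999;
  return rho;
}

// [[Rcpp::export(name = ".polychoric_table_cpp")]]
List polychoric_table_cpp(NumericMatrix table) {
  int r = table.nrow(), c = table.ncol();
  std::vector<double> tab(r * c);
  for (int i = 0; i < r; i++)
    for (int j = 0; j < c; j++) tab[i * c + j] = table(i, j);
  bool collapsed = false, degenerate = false;
  double rho = polychoric_table(tab, r, c, collapsed, degenerate);
  return List::create(_["rho"] = rho, _["collapsed"] = collapsed,
                      _["degenerate"] = degenerate);
}

// Pairwise polychoric matrix.  X: integer matrix with categories 0..K-1,
// NA_INTEGER for missing.  Pairwise-complete observations.
// [[Rcpp::export(name = ".polychoric_matrix_cpp")]]
List polychoric_matrix_cpp(IntegerMatrix X, int K) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix R(p, p);
  IntegerMatrix npair(p, p);
  LogicalMatrix clog(p, p);
  R.fill_diag(1.0);
  std::vector<double> tab(K * K);
  for (int a = 0; a < p; a++) {
    npair(a, a) = n;
    for (int b = a + 1; b < p; b++) {
      std::fill(tab.begin(), tab.end(), 0.0);
      int m = 0;
      for (int i = 0; i < n; i++) {
        int xa = X(i, a), xb = X(i, b);
        if (xa == NA_INTEGER || xb == NA_INTEGER) continue;
        tab[xa * K + xb] += 1.0;
        m++;
      }
      bool collapsed = false, degenerate = false;
      double rho = (m > 0) ? polychoric_table(tab, K, K, collapsed, degenerate) : NA_REAL;
      R(a, b) = R(b, a) = rho;
      npair(a, b) = npair(b, a) = m;
      clog(a, b) = clog(b, a) = collapsed || degenerate;
    }
  }
  return List::create(_["R"] = R, _["npair"] = npair, _["collapse"] = clog);
}

// Per-item thresholds from full-sample margins (probit of cumulative
// proportions), with empty-category collapse mirrored by dropping the
// corresponding threshold.  Returns a list of numeric vectors.
// [[Rcpp::export(name = ".item_thresholds_cpp")]]
List item_thresholds_cpp(IntegerMatrix X, int K) {
  int n = X.nrow(), p = X.ncol();
  List out(p);
  for (int a = 0; a < p; a++) {
    std::vector<double> cnt(K, 0.0);
    double m = 0.0;
    for (int i = 0; i < n; i++) {
      int v = X(i, a);
      if (v == NA_INTEGER) continue;
      cnt[v] += 1.0; m += 1.0;
    }
    std::vector<double> tau;
    double cum = 0.0;
    for (int c = 0; c < K - 1; c++) {
      cum += cnt[c];
      double pr = cum / m;
      if (pr <= 0.0 || pr >= 1.0) continue;  // empty boundary: threshold dropped
      tau.push_back(R::qnorm(pr, 0.0, 1.0, 1, 0));
    }
    out[a] = NumericVector(tau.begin(), tau.end());
  }
  return out;
}
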