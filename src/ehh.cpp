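#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// EHH from a class assignment over carrier haplotypes:
// sum over classes of C(size, 2) / C(n, 2)
static double ehh_of_classes(const std::vector<int>& cls, int n_classes,
                             int n) {
  std::vector<int> count(n_classes, 0);
  for (size_t i = 0; i < cls.size(); ++i) count[cls[i]]++;
  double num = 0.0;
  for (int c = 0; c < n_classes; ++c)
    num += 0.5 * count[c] * (count[c] - 1.0);
  double den = 0.5 * n * (n - 1.0);
  return num / den;
}

// Refine the class assignment by the alleles of one marker column.
// Returns the new number of classes.
static int refine(std::vector<int>& cls, int& n_classes,
                  const IntegerMatrix& hap,
                  const std::vector<int>& rows, int marker) {
  std::unordered_map<long long, int> remap;
  int next_id = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    long long key = (long long)cls[i] * 2LL + hap(rows[i], marker);
    auto it = remap.find(key);
    if (it == remap.end()) {
      remap[key] = next_id;
      cls[i] = next_id++;
    } else {
      cls[i] = it->second;
    }
  }
  n_classes = next_id;
  return next_id;
}

// One-directional EHH decay from a core marker. Carriers are the rows
// whose core allele equals `allele`, or all rows when allele < 0 (the
// pooled, allele-agnostic convention used by XP-EHH). The curve starts at
// the core marker with EHH = 1 (the core itself does not partition) and is
// refined marker by marker outward until EHH < cutoff or the chromosome
// end; the stopping marker is included.
// [[Rcpp::export(name = ".ehh_side_cpp")]]
List ehh_side_cpp(IntegerMatrix hap, int core0, int allele, bool right,
                  double cutoff) {
  int n_sites = hap.ncol();
  if (core0 < 0 || core0 >= n_sites) stop("core index out of range");
  std::vector<int> rows;
  for (int r = 0; r < hap.nrow(); ++r) {
    if (allele < 0 || hap(r, core0) == allele) rows.push_back(r);
  }
  int n = rows.size();
  if (n < 2) {
    return List::create(_["markers"] = IntegerVector(0),
                        _["ehh"] = NumericVector(0),
                        _["n_carriers"] = n);
  }
  std::vector<int> markers;
  std::vector<double> ehh;
  markers.push_back(core0);
  ehh.push_back(1.0);
  std::vector<int> cls(n, 0);
  int n_classes = 1;
  int step = right ? 1 : -1;
  for (int m = core0 + step; m >= 0 && m < n_sites; m += step) {
    refine(cls, n_classes, hap, rows, m);
    double e = ehh_of_classes(cls, n_classes, n);
    markers.push_back(m);
    ehh.push_back(e);
    if (e < cutoff) break;
  }
  return List::create(_["markers"] = wrap(markers),
                      _["ehh"] = wrap(ehh),
                      _["n_carriers"] = n);
}

// Trapezoidal integral of one EHH side against bp positions.
static double integrate_side(IntegerMatrix& hap, NumericVector& positions,
                             int core0, int allele, bool right,
                             double cutoff) {
  int n_sites = hap.ncol();
  std::vector<int> rows;
  for (int r = 0; r < hap.nrow(); ++r) {
    if (allele < 0 || hap(r, core0) == allele) rows.push_back(r);
  }
  int n = rows.size();
  if (n < 2) return NA_REAL;
  std::vector<int> cls(n, 0);
  int n_classes = 1;
  double prev_e = 1.0;
  double prev_pos = positions[core0];
  double area = 0.0;
  int step = right ? 1 : -1;
  for (int m = core0 + step; m >= 0 && m < n_sites; m += step) {
    refine(cls, n_classes, hap, rows, m);
    double e = ehh_of_classes(cls, n_classes, n);
    double w = std::abs(positions[m] - prev_pos);
    area += w * 0.5 * (e + prev_e);
    prev_e = e;
    prev_pos = positions[m];
    if (e < cutoff) break;
  }
  return area;
}

// iHH at one core: left + right trapezoid integrals (bp units).
// [[Rcpp::export(name = ".ihh_cpp")]]
double ihh_cpp(IntegerMatrix hap, NumericVector positions, int core0,
               int allele, double cutoff) {
  if (core0 < 0 || core0 >= hap.ncol()) stop("core index out of range");
  double l = integrate_side(hap, positions, core0, allele, false, cutoff);
  double r = integrate_side(hap, positions, core0, allele, true, cutoff);
  if (ISNAN(l) || ISNAN(r)) return NA_REAL;
  return l + r;
}

// Pooled (allele-agnostic) iHH at every site for two groups sharing one
// site list; column 1 = group A, column 2 = group B.
// [[Rcpp::export(name = ".ihh_scan_cpp")]]
NumericMatrix ihh_scan_cpp(IntegerMatrix hapA, IntegerMatrix hapB,
                           NumericVector positions, double cutoff) {
  int n_sites = hapA.ncol();
  if (hapB.ncol() != n_sites) stop("site lists differ between groups");
  NumericMatrix out(n_sites, 2);
  for (int s = 0; s < n_sites; ++s) {
    out(s, 0) = ihh_cpp(hapA, positions, s, -1, cutoff);
    out(s, 1) = ihh_cpp(hapB, positions, s, -1, cutoff);
  }
  return out;
}
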