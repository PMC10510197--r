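#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Bulk scoring kernel: evaluates every (peptide, link site, delta) combination
// of the eligible index prefix against one processed spectrum and keeps the
// best-scoring combination per peptide.  Matching rule mirrors match_score():
// each theoretical ion may claim only its nearest in-tolerance peak (tie ->
// lower m/z), each peak at most one ion, contested peaks resolved by smaller
// distance then lower ion m/z.

struct Claim {
  double dist;
  double mz;
  int ion;
  int peak;
};

static inline int nearest_peak(const double* pm, int np, double mz,
                               double tol) {
  int lo = 0, hi = np;  // first index with pm[i] >= mz
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (pm[mid] < mz) lo = mid + 1; else hi = mid;
  }
  int best = -1;
  double bd = 0.0;
  if (lo < np) { best = lo; bd = pm[lo] - mz; }
  if (lo > 0) {
    double d = mz - pm[lo - 1];
    if (best < 0 || d <= bd) { best = lo - 1; bd = d; }  // tie -> lower m/z
  }
  if (best < 0 || bd > tol) return -1;
  return best;
}

// [[Rcpp::export(name = ".score_sites_kernel")]]
NumericMatrix score_sites_kernel(NumericVector peak_mz,
                                 NumericVector peak_int,
                                 NumericVector res_flat,
                                 IntegerVector pep_off,
                                 IntegerVector site_flat,
                                 IntegerVector site_off,
                                 NumericVector delta1,
                                 NumericVector delta2,
                                 double tol_ppm,
                                 int max_charge,
                                 double proton,
                                 double water) {
  const int npep = delta1.size();
  const bool two_deltas = delta2.size() > 0;
  const double* pm = peak_mz.begin();
  const double* pint = peak_int.begin();
  const int np = peak_mz.size();

  NumericMatrix out(npep, 5);  // score, site, delta_idx, matched, total_ions
  std::vector<double> prefix;
  std::vector<double> ion_mz;
  std::vector<bool> ion_cov;
  std::vector<Claim> claims;
  std::vector<int> stamp(np, -1);
  int token = 0;

  for (int p = 0; p < npep; ++p) {
    const int r0 = pep_off[p], r1 = pep_off[p + 1];
    const int n = r1 - r0;
    double best_score = -1.0;
    int best_site = NA_INTEGER, best_delta = NA_INTEGER, best_matched = 0;
    int total_ions = (n >= 2) ? 2 * (n - 1) * max_charge : 0;

    if (n >= 2) {
      prefix.assign(n + 1, 0.0);
      for (int i = 0; i < n; ++i) prefix[i + 1] = prefix[i] + res_flat[r0 + i];
      const double total_res = prefix[n];
      const int s0 = site_off[p], s1 = site_off[p + 1];
      const int ndelta = two_deltas ? 2 : 1;

      for (int si = s0; si < s1; ++si) {
        const int site = site_flat[si];
        for (int di = 0; di < ndelta; ++di) {
          const double d = (di == 0) ? delta1[p] : delta2[p];
          ion_mz.clear();
          for (int i = 1; i <= n - 1; ++i) {
            const double bneut = prefix[i] + ((site <= i - 1) ? d : 0.0);
            const double yneut = (total_res - prefix[n - i]) + water +
              ((site >= n - i) ? d : 0.0);
            for (int z = 1; z <= max_charge; ++z) {
              ion_mz.push_back((bneut + z * proton) / z);
              ion_mz.push_back((yneut + z * proton) / z);
            }
          }
          // collect nearest-peak claims
          claims.clear();
          for (size_t k = 0; k < ion_mz.size(); ++k) {
            const double mz = ion_mz[k];
            const int pk = nearest_peak(pm, np, mz, tol_ppm * 1e-6 * mz);
            if (pk >= 0) {
              Claim c;
              c.dist = std::abs(pm[pk] - mz);
              c.mz = mz;
              c.ion = (int)k;
              c.peak = pk;
              claims.push_back(c);
            }
          }
          std::sort(claims.begin(), claims.end(),
                    [](const Claim& a, const Claim& b) {
                      if (a.dist != b.dist) return a.dist < b.dist;
                      if (a.mz != b.mz) return a.mz < b.mz;
                      return a.ion < b.ion;
                    });
          ++token;
          double score = 0.0;
          int matched = 0;
          for (size_t k = 0; k < claims.size(); ++k) {
            const int pk = claims[k].peak;
            if (stamp[pk] != token) {
              stamp[pk] = token;
              score += pint[pk];
              ++matched;
            }
          }
          if (score > best_score) {
            best_score = score;
            best_site = site;
            best_delta = di + 1;
            best_matched = matched;
          }
        }
      }
    }

    if (best_score < 0) {
      // no fragment ions evaluated (length-1 peptide or no sites)
      best_score = 0.0;
      if (site_off[p + 1] > site_off[p]) {
        best_site = site_flat[site_off[p]];
        best_delta = 1;
      }
    }
    out(p, 0) = best_score < 0 ? 0.0 : best_score;
    out(p, 1) = best_site;
    out(p, 2) = best_delta;
    out(p, 3) = best_matched;
    out(p, 4) = total_ions;
  }
  return out;
}
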