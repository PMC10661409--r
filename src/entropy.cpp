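#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Template-matching counts for ApEn / SampEn.
//
// Both entropies count pairs of length-m templates whose Chebyshev
// (maximum-coordinate) distance is <= r.  The counting loops below visit,
// for each template i, only the templates j whose FIRST coordinate lies
// within r of template i's first coordinate (a necessary condition for a
// Chebyshev match), found by sorting the templates by first coordinate and
// sliding a two-pointer window.  This changes nothing about which pairs are
// counted, only how many are examined.

// Per-template match counts (self-match INCLUDED) for templates of length m
// among the first `nt` templates of series x; remaining coordinates checked
// explicitly.
static std::vector<long long> match_counts(const double* x, int nt, int m,
                                           double r) {
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<long long> cnt(nt, 0);
  int lo = 0;
  for (int a = 0; a < nt; ++a) {
    int i = ord[a];
    while (x[ord[lo]] < x[i] - r) ++lo;
    for (int b = lo; b < nt; ++b) {
      int j = ord[b];
      if (x[j] > x[i] + r) break;
      if (b < a) continue;  // each unordered pair visited once (b >= a)
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        cnt[i] += 1;
        if (j != i) cnt[j] += 1;
      }
    }
  }
  return cnt;
}

// phi^m(r) of the Pincus approximate-entropy construction: mean over the
// N - m + 1 templates of log(C_i / (N - m + 1)), self-matches included.
static double apen_phi(const double* x, int n, int m, double r) {
  int nt = n - m + 1;
  std::vector<long long> cnt = match_counts(x, nt, m, r);
  double acc = 0.0;
  for (int i = 0; i < nt; ++i)
    acc += std::log((double)cnt[i] / (double)nt);
  return acc / (double)nt;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for ApEn with m = %d", m);
  return apen_phi(REAL(x), n, m, r) - apen_phi(REAL(x), n, m + 1, r);
}

// Sample entropy: unordered template pairs i != j within r at lengths m and
// m + 1, both over the N - m templates of the Richman-Moorman construction
// (so both lengths use the same template set); self-matches excluded.
// Returns NA when no (m+1)-length pair matches.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for SampEn with m = %d", m);
  const double* x0 = REAL(x);
  int nt = n - m;
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x0[a] < x0[b]; });
  long long bm = 0, bm1 = 0;
  int lo = 0;
  for (int a = 0; a < nt; ++a) {
    int i = ord[a];
    while (x0[ord[lo]] < x0[i] - r) ++lo;
    for (int b = lo; b < nt; ++b) {
      int j = ord[b];
      if (x0[j] > x0[i] + r) break;
      if (b <= a) continue;  // unordered pairs, i != j
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x0[i + k] - x0[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        ++bm;
        if (std::fabs(x0[i + m] - x0[j + m]) <= r) ++bm1;
      }
    }
  }
  if (bm == 0 || bm1 == 0) return NA_REAL;
  return -std::log((double)bm1 / (double)bm);
}

// Permutation entropy of ordinal patterns of length n_order.  Each window
// maps to the permutation that sorts it ascending; ties broken by the
// earlier index first (stable sort).  Natural log, unnormalized.
// [[Rcpp::export(name = ".permen_cpp")]]
double permen_cpp(NumericVector x, int n_order) {
  int n = x.size();
  if (n < n_order) stop("series shorter than the ordinal pattern length");
  const double* p = REAL(x);
  int nw = n - n_order + 1;

  // pattern id = Lehmer-style mixed-radix code of the sorting permutation
  std::vector<int> idx(n_order);
  int npat = 1;
  for (int k = 2; k <= n_order; ++k) npat *= k;
  std::vector<double> counts(npat, 0.0);

  for (int w = 0; w < nw; ++w) {
    for (int k = 0; k < n_order; ++k) idx[k] = k;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return p[w + a] < p[w + b]; });
    int code = 0;
    for (int k = 0; k < n_order; ++k) {
      int smaller = 0;
      for (int l = k + 1; l < n_order; ++l)
        if (idx[l] < idx[k]) ++smaller;
      code = code * (n_order - k) + smaller;
    }
    counts[code] += 1.0;
  }

  double h = 0.0;
  for (int c = 0; c < npat; ++c) {
    if (counts[c] > 0) {
      double pr = counts[c] / (double)nw;
      h -= pr * std::log(pr);
    }
  }
  return h;
}
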