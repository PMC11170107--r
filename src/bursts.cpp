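#include <Rcpp.h>
using namespace Rcpp;

// Poisson Surprise of a window holding n spikes over span T at background rate
// `rate`: S = -log10 P(N >= n | N ~ Poisson(rate*T)).
static double surprise_log10(int n, double mu) {
  // upper tail on the log scale; n >= 1, mu > 0
  double logq = R::ppois((double)(n - 1), mu, 0, 1);
  return -logq / M_LN10;
}

struct Win {
  int i, j;      // 0-based spike indices, inclusive
  double s;      // surprise
  bool ok;
};

// Best (maximal-surprise) window inside t[lo..hi].  For a fixed spike count n
// the surprise is maximized exactly by the minimal-span window (the Poisson
// upper tail is increasing in T), so scanning spans per n gives the exact
// global optimum.  Ties: larger n wins, then earlier start.
// Since Q(n, mu) >= dpois(n, mu), -log10 dpois(n, mu) upper-bounds the
// surprise; the exact tail is evaluated only for n whose bound can beat the
// running best (exactness is unaffected, larger-n ties still win because
// candidates are visited in increasing n).
static Win best_window(const NumericVector& t, int lo, int hi,
                       double rate, int min_spikes) {
  Win best; best.ok = false; best.s = -1.0; best.i = -1; best.j = -1;
  int len = hi - lo + 1;
  if (len < min_spikes) return best;
  for (int n = min_spikes; n <= len; ++n) {
    double minspan = R_PosInf; int argi = -1;
    for (int i = lo; i + n - 1 <= hi; ++i) {
      double span = t[i + n - 1] - t[i];
      if (span < minspan) { minspan = span; argi = i; }
    }
    double mu = rate * minspan;
    if (best.ok) {
      double s_ub = -R::dpois((double)n, mu, 1) / M_LN10;
      if (s_ub < best.s) continue;
    }
    double s = surprise_log10(n, mu);
    if (!best.ok || s > best.s ||
        (s == best.s && (n > best.j - best.i + 1 ||
                         (n == best.j - best.i + 1 && argi < best.i)))) {
      best.ok = true; best.s = s; best.i = argi; best.j = argi + n - 1;
    }
  }
  return best;
}

// Greedy maximal non-overlapping burst extraction: take the best window of the
// segment; if its surprise clears the threshold, emit it and recurse on the
// flanking segments.  Returns a matrix with columns (i, j, surprise), 1-based.
// [[Rcpp::export(name = ".ls_burst_scan")]]
NumericMatrix ls_burst_scan(NumericVector t, double rate,
                            int min_spikes, double surprise_min) {
  std::vector<double> out_i, out_j, out_s;
  std::vector<std::pair<int,int> > stack;
  int nt = t.size();
  if (nt >= min_spikes && rate > 0) stack.push_back(std::make_pair(0, nt - 1));
  while (!stack.empty()) {
    std::pair<int,int> seg = stack.back(); stack.pop_back();
    Win w = best_window(t, seg.first, seg.second, rate, min_spikes);
    if (!w.ok || w.s < surprise_min) continue;
    out_i.push_back(w.i + 1);
    out_j.push_back(w.j + 1);
    out_s.push_back(w.s);
    if (w.i - seg.first >= min_spikes)
      stack.push_back(std::make_pair(seg.first, w.i - 1));
    if (seg.second - w.j >= min_spikes)
      stack.push_back(std::make_pair(w.j + 1, seg.second));
  }
  int nb = out_i.size();
  NumericMatrix res(nb, 3);
  for (int k = 0; k < nb; ++k) {
    res(k, 0) = out_i[k]; res(k, 1) = out_j[k]; res(k, 2) = out_s[k];
  }
  colnames(res) = CharacterVector::create("i", "j", "surprise");
  return res;
}

// Histogram of pairwise lags tb - ta restricted to [-max_lag, +max_lag),
// binned with width bin_s (first bin starts at -max_lag).  Both inputs sorted.
// [[Rcpp::export(name = ".xcorr_counts")]]
IntegerVector xcorr_counts(NumericVector ta, NumericVector tb,
                           double bin_s, double max_lag) {
  int nbins = (int)std::floor(2.0 * max_lag / bin_s + 0.5);
  IntegerVector counts(nbins);
  int nb = tb.size();
  int lo = 0;
  for (int a = 0; a < ta.size(); ++a) {
    double t0 = ta[a] - max_lag, t1 = ta[a] + max_lag;
    while (lo < nb && tb[lo] < t0) ++lo;
    for (int b = lo; b < nb && tb[b] < t1; ++b) {
      int bin = (int)std::floor((tb[b] - ta[a] + max_lag) / bin_s);
      if (bin >= 0 && bin < nbins) counts[bin]++;
    }
  }
  return counts;
}
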