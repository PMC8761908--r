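#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// LZ76 production (exhaustive-history) parsing word count c(n).
//
// A word starting at 0-based position l is extended while it occurs as a
// substring starting at some i < l (the occurrence may overlap the word
// itself); the first extension that breaks reproducibility closes the word.
// The final word counts even when it stays reproducible to the end.
//
// Implementation: suffix automaton of the whole string with the minimal end
// position of each state's occurrence set. The word s[l..l+m] is
// reproducible from the extended history iff some occurrence of it ends at
// or before l+m-1 (equivalently starts before l). Building the automaton is
// O(n) for a binary alphabet and the parse walk visits each symbol once.
// ---------------------------------------------------------------------------

namespace {

struct SuffixAutomaton {
  std::vector<int> len, link, minend;
  std::vector<std::array<int, 2>> nxt;
  int last, sz;

  void init(int maxn) {
    const int cap = 2 * maxn + 4;
    if ((int)len.size() < cap) {
      len.resize(cap); link.resize(cap); minend.resize(cap); nxt.resize(cap);
    }
    len[0] = 0; link[0] = -1; minend[0] = 1 << 30; nxt[0] = {-1, -1};
    last = 0; sz = 1;
  }

  void extend(int c, int pos) {
    const int cur = sz++;
    len[cur] = len[last] + 1; minend[cur] = pos; link[cur] = -1;
    nxt[cur] = {-1, -1};
    int p = last;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = link[p]; }
    if (p == -1) link[cur] = 0;
    else {
      const int q = nxt[p][c];
      if (len[p] + 1 == len[q]) link[cur] = q;
      else {
        const int cl = sz++;
        len[cl] = len[p] + 1; link[cl] = link[q]; nxt[cl] = nxt[q];
        minend[cl] = minend[q];
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = cl; p = link[p]; }
        link[q] = cl; link[cur] = cl;
      }
    }
    last = cur;
  }
};

SuffixAutomaton sam;
std::vector<int> sam_cnt, sam_order;

int lz76_core(const int* s, int n) {
  if (n <= 0) return 0;
  if (n == 1) return 1;
  sam.init(n);
  for (int i = 0; i < n; ++i) sam.extend(s[i], i);
  // propagate minimal end positions up the suffix-link tree
  // (counting sort by state length gives a topological order)
  if ((int)sam_cnt.size() < n + 2) sam_cnt.resize(n + 2);
  if ((int)sam_order.size() < sam.sz) sam_order.resize(sam.sz);
  std::fill(sam_cnt.begin(), sam_cnt.begin() + n + 2, 0);
  for (int v = 0; v < sam.sz; ++v) sam_cnt[sam.len[v]]++;
  for (int i = 1; i <= n + 1; ++i) sam_cnt[i] += sam_cnt[i - 1];
  for (int v = sam.sz - 1; v >= 0; --v) sam_order[--sam_cnt[sam.len[v]]] = v;
  for (int i = sam.sz - 1; i >= 1; --i) {
    const int v = sam_order[i];
    if (sam.link[v] >= 0 && sam.minend[v] < sam.minend[sam.link[v]])
      sam.minend[sam.link[v]] = sam.minend[v];
  }
  int c = 0, l = 0;
  while (l < n) {
    int m = 0, st = 0;
    while (l + m < n) {
      const int st2 = sam.nxt[st][s[l + m]];
      if (st2 < 0 || sam.minend[st2] > l + m - 1) break;
      st = st2; ++m;
    }
    ++c;
    if (m >= 1 && l + m >= n) break;  // final word, reproducible to the end
    l += m + 1;
  }
  return c;
}

}  // namespace

// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(IntegerVector s) {
  return lz76_core(INTEGER(s), s.size());
}

// ---------------------------------------------------------------------------
// Per-channel complexity
// ---------------------------------------------------------------------------

namespace {

// normalized LZC of one real segment (median binarization)
double seg_lzc(const double* x, int n, std::vector<double>& buf,
               std::vector<int>& bin) {
  std::copy(x, x + n, buf.begin());
  std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
  double med = buf[n / 2];
  if (n % 2 == 0) {
    const double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
    med = 0.5 * (lo + med);
  }
  for (int i = 0; i < n; ++i) bin[i] = x[i] > med ? 1 : 0;
  return lz76_core(bin.data(), n) * std::log2((double)n) / n;
}

// Kaspar-Schuster KC estimate of one real segment (difference binarization)
double seg_kc(const double* x, int n, std::vector<int>& bin) {
  const int m = n - 1;
  for (int i = 0; i < m; ++i) bin[i] = (x[i + 1] - x[i]) > 0 ? 1 : 0;
  return lz76_core(bin.data(), m) * std::log2((double)m) / m;
}

}  // namespace

// Per-channel complexity of one epoch: columns of X are channels.
// Row 1: normalized Lempel-Ziv complexity; row 2: Kolmogorov complexity
// estimate (difference method).
// [[Rcpp::export(name = ".epoch_complexity_cpp")]]
NumericMatrix epoch_complexity_cpp(NumericMatrix X) {
  const int n = X.nrow(), nch = X.ncol();
  if (n < 3) stop("epoch too short for complexity estimation");
  NumericMatrix out(2, nch);
  std::vector<double> buf(n);
  std::vector<int> bin(n);
  for (int ch = 0; ch < nch; ++ch) {
    const double* x = &X(0, ch);
    out(0, ch) = seg_lzc(x, n, buf, bin);
    out(1, ch) = seg_kc(x, n, bin);
  }
  return out;
}

// Batched per-epoch complexity over a whole recording. M is samples x
// channels (channel-contiguous columns), `starts` are 0-based start samples
// of the selected epochs, all of length `len`. When avg_ref is true the
// instantaneous cross-channel mean is subtracted before binarization
// (average reference). Returns per-estimator matrices (channels x epochs);
// estimators not requested come back as NULL.
// [[Rcpp::export(name = ".epochs_complexity_cpp")]]
List epochs_complexity_cpp(NumericMatrix M, IntegerVector starts, int len,
                           bool do_lzc, bool do_kc, bool avg_ref) {
  const int n = M.nrow(), nch = M.ncol(), nep = starts.size();
  if (len < 3) stop("epoch too short for complexity estimation");
  NumericMatrix lz(do_lzc ? nch : 0, do_lzc ? nep : 0);
  NumericMatrix kk(do_kc ? nch : 0, do_kc ? nep : 0);
  std::vector<double> buf(len), seg(len), chmean(len);
  std::vector<int> bin(len);
  for (int e = 0; e < nep; ++e) {
    const int s0 = starts[e];
    if (s0 < 0 || s0 + len > n) stop("epoch window out of range");
    if (avg_ref) {
      std::fill(chmean.begin(), chmean.end(), 0.0);
      for (int ch = 0; ch < nch; ++ch) {
        const double* x = &M(s0, ch);
        for (int i = 0; i < len; ++i) chmean[i] += x[i];
      }
      for (int i = 0; i < len; ++i) chmean[i] /= nch;
    }
    for (int ch = 0; ch < nch; ++ch) {
      const double* x = &M(s0, ch);
      for (int i = 0; i < len; ++i)
        seg[i] = x[i] - (avg_ref ? chmean[i] : 0.0);
      if (do_lzc) lz(ch, e) = seg_lzc(seg.data(), len, buf, bin);
      if (do_kc) kk(ch, e) = seg_kc(seg.data(), len, bin);
    }
  }
  return List::create(_["lzc"] = do_lzc ? (SEXP)lz : R_NilValue,
                      _["kc"] = do_kc ? (SEXP)kk : R_NilValue);
}

// ---------------------------------------------------------------------------
// Zero-phase forward-backward IIR filtering
// ---------------------------------------------------------------------------

namespace {

// Direct-form-II-transposed IIR filter with initial state zi * x0.
void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
              const double* x, double* y, int n,
              const std::vector<double>& zi, double x0) {
  const int nz = (int)b.size() - 1;
  std::vector<double> z(nz);
  for (int k = 0; k < nz; ++k) z[k] = zi[k] * x0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

void pad_coeffs(NumericVector b_, NumericVector a_, NumericVector zi_,
                std::vector<double>& b, std::vector<double>& a,
                std::vector<double>& zi) {
  const int nc = std::max(b_.size(), a_.size());
  b.assign(nc, 0.0); a.assign(nc, 0.0); zi.assign(nc - 1, 0.0);
  for (int i = 0; i < b_.size(); ++i) b[i] = b_[i];
  for (int i = 0; i < a_.size(); ++i) a[i] = a_[i];
  for (int i = 0; i < nc - 1; ++i) zi[i] = zi_[i];
}

}  // namespace

// Zero-phase forward-backward filtering of each column of X (samples x
// channels) with odd-reflection padding of length padlen and steady-state
// initial conditions zi (computed by the R-side companion-matrix solve).
// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericMatrix filtfilt_cpp(NumericVector b_, NumericVector a_,
                           NumericMatrix X, NumericVector zi_, int padlen) {
  const int n = X.nrow(), nch = X.ncol();
  std::vector<double> b, a, zi;
  pad_coeffs(b_, a_, zi_, b, a, zi);
  if (n <= padlen)
    stop("signal length must exceed the filter padding length (%d)", padlen);
  const int ne = n + 2 * padlen;
  std::vector<double> ext(ne), tmp(ne);
  NumericMatrix out(n, nch);
  for (int ch = 0; ch < nch; ++ch) {
    const double* x = &X(0, ch);
    for (int j = 0; j < padlen; ++j) ext[j] = 2.0 * x[0] - x[padlen - j];
    std::copy(x, x + n, ext.begin() + padlen);
    for (int j = 0; j < padlen; ++j)
      ext[padlen + n + j] = 2.0 * x[n - 1] - x[n - 2 - j];
    iir_pass(b, a, ext.data(), tmp.data(), ne, zi, ext[0]);
    std::reverse(tmp.begin(), tmp.end());
    iir_pass(b, a, tmp.data(), ext.data(), ne, zi, tmp[0]);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) out(i, ch) = ext[padlen + i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Synthetic EEG oscillator
// ---------------------------------------------------------------------------

// Sum of band oscillators with slowly drifting phase. For band b the
// instantaneous phase advances by 2*pi*freq[b]/fs plus a per-segment slope
// taken from drift_steps (one row per knot segment, radians per knot
// interval), linearly spread over knot_every samples.
// [[Rcpp::export(name = ".oscillator_cpp")]]
NumericVector oscillator_cpp(int n, double fs, NumericVector freq,
                             NumericVector amp, NumericVector phase0,
                             NumericMatrix drift_steps, int knot_every) {
  const int nb = freq.size();
  NumericVector out(n);
  for (int b = 0; b < nb; ++b) {
    double s = std::sin(phase0[b]), c = std::cos(phase0[b]);
    const double base = 2.0 * M_PI * freq[b] / fs;
    const double ab = amp[b];
    int i = 0, seg = 0;
    while (i < n) {
      const double inc =
          base + drift_steps(std::min(seg, drift_steps.nrow() - 1), b) / knot_every;
      const double si = std::sin(inc), ci = std::cos(inc);
      const int stop_i = std::min(n, i + knot_every);
      for (; i < stop_i; ++i) {
        out[i] += ab * s;
        const double s2 = s * ci + c * si;
        c = c * ci - s * si;
        s = s2;
      }
      ++seg;
    }
  }
  return out;
}
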