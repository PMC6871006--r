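#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ungapped window mapping against a subject sequence.
//
// Each query window is slid over every offset of the subject (and of its
// reverse complement); the offset with the fewest mismatches wins. The scan
// is exact: candidate offsets found from exact seed k-mer hits only tighten
// the branch-and-bound limit, they never replace the full scan. 'N' never
// matches anything, including itself.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// mismatches of q against s starting at offset, stop early past 'limit'
static int count_mm(const std::string& q, const std::string& s, size_t offset,
                    int limit) {
  int mm = 0;
  const size_t n = q.size();
  for (size_t i = 0; i < n; ++i) {
    char a = q[i], b = s[offset + i];
    if (a != b || a == 'N') {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

// best (minimum) mismatch count of q at any offset of s, or limit+1 if none
// is within 'limit'; ties resolved to the smallest offset.
static int best_hit(const std::string& q, const std::string& s, int limit) {
  const size_t n = q.size(), m = s.size();
  if (n > m || n == 0) return limit + 1;
  int best = limit + 1;

  // seed phase: exact hits of a few k-mers bound the full scan
  const size_t k = 16;
  if (n >= k) {
    size_t step = std::max(n / 8, k);
    for (size_t qi = 0; qi + k <= n; qi += step) {
      std::string seed = q.substr(qi, k);
      if (seed.find('N') != std::string::npos) continue;
      size_t pos = s.find(seed);
      int hits = 0;
      while (pos != std::string::npos && hits < 25) {
        if (pos >= qi && pos - qi + n <= m) {
          int mm = count_mm(q, s, pos - qi, best - 1);
          if (mm < best) best = mm;
        }
        pos = s.find(seed, pos + 1);
        ++hits;
      }
    }
  }
  if (best == 0) return 0;

  // exhaustive phase (branch-and-bound on current best)
  for (size_t off = 0; off + n <= m; ++off) {
    int mm = count_mm(q, s, off, best - 1);
    if (mm < best) {
      best = mm;
      if (best == 0) break;
    }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_map_windows(CharacterVector windows, std::string subject,
                          double min_identity) {
  std::string subject_rc = revcomp(subject);
  int nw = windows.size();
  IntegerVector wlen(nw), mism(nw);
  NumericVector ident(nw);
  LogicalVector aligned(nw);
  CharacterVector strand(nw);
  for (int i = 0; i < nw; ++i) {
    std::string w = as<std::string>(windows[i]);
    int n = (int)w.size();
    int limit = (int)std::floor((1.0 - min_identity / 100.0) * n);
    int fwd = best_hit(w, subject, limit);
    int rev = best_hit(w, subject_rc, limit);
    int best = std::min(fwd, rev);
    wlen[i] = n;
    if (best <= limit) {
      aligned[i] = true;
      mism[i] = best;
      ident[i] = 100.0 * (n - best) / n;
      strand[i] = (fwd <= rev) ? "+" : "-";
    } else {
      aligned[i] = false;
      mism[i] = NA_INTEGER;
      ident[i] = NA_REAL;
      strand[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["window_length"] = wlen, _["aligned"] = aligned,
                           _["mismatches"] = mism, _["identity"] = ident,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Longest terminal repeat: largest l in [min_len, floor(L/2)] such that the
// length-l prefix matches the length-l terminal block with <= max_mismatch
// mismatches. inverted = FALSE compares prefix vs suffix (direct repeat);
// inverted = TRUE compares prefix vs reverse complement of the suffix.
// [[Rcpp::export]]
int cpp_terminal_repeat(std::string seq, int min_len, int max_mismatch,
                        bool inverted) {
  const int L = (int)seq.size();
  const int lmax = L / 2;
  if (min_len < 1 || lmax < min_len) return 0;
  for (int l = lmax; l >= min_len; --l) {
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < l; ++i) {
      char a = seq[i];
      char b = inverted ? comp_base(seq[L - 1 - i]) : seq[L - l + i];
      if (a != b || a == 'N') {
        if (++mm > max_mismatch) { ok = false; break; }
      }
    }
    if (ok) return l;
  }
  return 0;
}
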