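#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost global alignment (Needleman-Wunsch under the Levenshtein
// objective): mismatch = 1, each gap base = 1, match = 0.  Computed inside a
// diagonal band that doubles until the optimal cost provably fits (Ukkonen),
// so the result is always the exact global optimum.  Deterministic
// traceback: diagonal preferred over target-gap (I) over query-gap (D).
// 'N' and any non-ACGT symbol never match anything (including itself);
// comparison is case-insensitive.

static inline int8_t code_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void push_op(std::string &cigar, int &run, char &op, char next) {
  if (op == next) { run++; return; }
  if (run > 0) { cigar += std::to_string(run); cigar += op; }
  op = next; run = 1;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string q, std::string t, double max_cells = 2e8) {
  const long n = (long)q.size(), m = (long)t.size();
  std::vector<int8_t> qc(n), tc(m);
  for (long i = 0; i < n; ++i) qc[i] = code_base(q[i]);
  for (long j = 0; j < m; ++j) tc[j] = code_base(t[j]);

  const int INF = 1 << 29;
  long d = std::max<long>(32, std::labs(m - n));
  std::vector<int> prev, cur;
  std::vector<uint8_t> tb; // 0 diag, 1 up (I, consumes q), 2 left (D)
  int cost = INF;
  long W = 0;

  for (;;) {
    if (d > n + m) d = n + m;
    W = 2 * d + 1;
    if ((double)(n + 1) * (double)W > max_cells)
      stop("alignment problem too large: %ld x %ld cells exceeds limit",
           (long)(n + 1), W);
    prev.assign(W, INF);
    cur.assign(W, INF);
    tb.assign((size_t)(n + 1) * W, 0);
    // row 0: j = off, all-deletion prefix
    for (long off = 0; off <= d && off <= m; ++off) {
      prev[off + d] = (int)off;
      tb[off + d] = 2;
    }
    for (long i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), INF);
      uint8_t *tbrow = &tb[(size_t)i * W];
      for (long off = -d; off <= d; ++off) {
        long j = i + off;
        if (j < 0 || j > m) continue;
        long idx = off + d;
        int best = INF; uint8_t dir = 0;
        if (j >= 1 && prev[idx] < INF) {
          int c = prev[idx] + ((qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ? 0 : 1);
          if (c < best) { best = c; dir = 0; }
        }
        if (off + 1 <= d && prev[idx + 1] < INF) {
          int c = prev[idx + 1] + 1; // up: consume query base
          if (c < best) { best = c; dir = 1; }
        }
        if (off - 1 >= -d && cur[idx - 1] < INF) {
          int c = cur[idx - 1] + 1; // left: consume target base
          if (c < best) { best = c; dir = 2; }
        }
        if (j == 0) { best = (int)i; dir = 1; }
        cur[idx] = best;
        tbrow[idx] = dir;
      }
      std::swap(prev, cur);
    }
    cost = prev[m - n + d];
    if (cost <= d || d >= n + m) break;
    d = std::max(2 * d, (long)cost);
  }

  // traceback from (n, m)
  long i = n, j = m;
  std::string rev_ops;
  rev_ops.reserve(n + m);
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * W + (j - i + d)];
    if (i > 0 && j > 0 && dir == 0) {
      rev_ops += (qc[i - 1] >= 0 && qc[i - 1] == tc[j - 1]) ? '=' : 'X';
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      rev_ops += 'I'; --i;
    } else {
      rev_ops += 'D'; --j;
    }
  }
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  std::string cigar; cigar.reserve(32);
  int run = 0; char op = 0;
  for (size_t k = rev_ops.size(); k-- > 0;) {
    char o = rev_ops[k];
    switch (o) {
      case '=': matches++; break;
      case 'X': mismatches++; break;
      case 'I': ins++; break;
      case 'D': del++; break;
    }
    push_op(cigar, run, op, o);
  }
  if (run > 0) { cigar += std::to_string(run); cigar += op; }
  int columns = matches + mismatches + ins + del;
  return List::create(_["cost"] = cost, _["matches"] = matches,
                      _["mismatches"] = mismatches, _["insertions"] = ins,
                      _["deletions"] = del, _["columns"] = columns,
                      _["cigar"] = cigar);
}
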