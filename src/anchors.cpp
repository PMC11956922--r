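#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <set>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Maximal exact match anchors seeded by k-mers that occur exactly once in
// each sequence (counting both strands of each).  Seeds are extended to
// maximal exact matches and deduplicated; both orientations are searched.
// Coordinates are 0-based half-open; minus-strand anchors report target
// coordinates on the forward strand.

static inline int code_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// count k-mers of s (forward scan only) into map
static void count_kmers(const std::string &s, int k,
                        std::unordered_map<uint64_t, int> &cnt,
                        std::unordered_map<uint64_t, int> *pos = nullptr) {
  if ((int)s.size() < k) return;
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code_base(s[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      cnt[kmer]++;
      if (pos) (*pos)[kmer] = (int)(i + 1 - k);
    }
  }
}

static bool match_at(const std::string &q, const std::string &t, long qi, long ti) {
  if (qi < 0 || ti < 0 || qi >= (long)q.size() || ti >= (long)t.size()) return false;
  int a = code_base(q[qi]), b = code_base(t[ti]);
  return a >= 0 && a == b;
}

// [[Rcpp::export(name = ".find_anchors_cpp")]]
DataFrame find_anchors_cpp(std::string q, std::string t, int k) {
  if (k < 8) stop("k must be >= 8 (spurious-match guard)");
  if (k > 31) stop("k must be <= 31");
  std::string qr = revcomp(q), tr = revcomp(t);

  std::unordered_map<uint64_t, int> cq, ct, posq, post_f, post_r;
  count_kmers(q, k, cq, &posq);
  count_kmers(qr, k, cq);
  count_kmers(t, k, ct, &post_f);
  count_kmers(tr, k, ct, &post_r);

  // collect maximal exact matches per orientation, dedupe on extended coords
  std::set<std::tuple<int, long, long>> seen; // strand(0/1), qstart, tstart(space coords)
  std::vector<long> qs, qe, ts, te;
  std::vector<std::string> strand;

  auto scan = [&](const std::string &tgt,
                  std::unordered_map<uint64_t, int> &post, bool minus) {
    if ((int)q.size() < k) return;
    uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    std::unordered_map<long, long> diag_end; // diagonal -> extended query end
    for (size_t i = 0; i < q.size(); ++i) {
      int c = code_base(q[i]);
      if (c < 0) { run = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      if (cq[kmer] != 1 || ct.count(kmer) == 0 || ct[kmer] != 1) continue;
      auto it = post.find(kmer);
      if (it == post.end()) continue;
      long q0 = (long)(i + 1 - k), t0 = (long)it->second;
      // seeds inside an already-extended match on this diagonal are redundant
      long diag = q0 - t0;
      auto de = diag_end.find(diag);
      if (de != diag_end.end() && q0 + k <= de->second) continue;
      // extend to maximal exact match in (q, tgt) space
      long a = q0, b = t0;
      while (match_at(q, tgt, a - 1, b - 1)) { --a; --b; }
      long a2 = q0 + k, b2 = t0 + k;
      while (match_at(q, tgt, a2, b2)) { ++a2; ++b2; }
      diag_end[diag] = a2;
      auto key = std::make_tuple(minus ? 1 : 0, a, b);
      if (seen.count(key)) continue;
      seen.insert(key);
      if (!minus) {
        qs.push_back(a); qe.push_back(a2); ts.push_back(b); te.push_back(b2);
        strand.push_back("+");
      } else {
        // map coords in revcomp(t) space back to forward target coords
        long m = (long)t.size();
        qs.push_back(a); qe.push_back(a2);
        ts.push_back(m - b2); te.push_back(m - b);
        strand.push_back("-");
      }
    }
  };

  scan(t, post_f, false);
  scan(tr, post_r, true);

  // sort by query position, then target
  std::vector<size_t> ord(qs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (qs[a] != qs[b]) return qs[a] < qs[b];
    return ts[a] < ts[b];
  });
  IntegerVector oqs(ord.size()), oqe(ord.size()), ots(ord.size()), ote(ord.size()),
      olen(ord.size());
  CharacterVector ostr(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    size_t j = ord[i];
    oqs[i] = (int)qs[j]; oqe[i] = (int)qe[j];
    ots[i] = (int)ts[j]; ote[i] = (int)te[j];
    olen[i] = (int)(qe[j] - qs[j]);
    ostr[i] = strand[j];
  }
  return DataFrame::create(_["qstart"] = oqs, _["qend"] = oqe, _["tstart"] = ots,
                           _["tend"] = ote, _["len"] = olen, _["strand"] = ostr,
                           _["stringsAsFactors"] = false);
}
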