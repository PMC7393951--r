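#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exact k-mer seeding plus ungapped extension of each query against a
// single target sequence, on both strands.  Shared by the fragment-based
// ANI engine (partial overlap allowed, min_frac < 1) and the internal
// competitive read mapper (full placement required, min_frac = 1).
// k-mers containing non-ACGT bases are never indexed or looked up.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void index_kmers(const std::string& seq, int k, KmerIndex& idx) {
  const int n = seq.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | b) & mask;
    if (++valid >= k) idx[kmer].push_back(i - k + 1);
  }
}

struct Best {
  double identity = -1.0;
  int olen = 0, matches = 0, strand = 0, tstart = 0;
};

static void scan_strand(const std::string& q, const std::string& target,
                        const KmerIndex& idx, int k, double min_frac,
                        int strand, Best& best) {
  const int qn = q.size(), tn = target.size();
  if (qn < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  std::vector<int> offsets;
  for (int i = 0; i < qn; ++i) {
    int b = base2bit(q[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | b) & mask;
    if (valid + 1 >= k) {
      KmerIndex::const_iterator it = idx.find(kmer);
      if (it != idx.end()) {
        int qpos = i - k + 1;
        for (int tpos : it->second) offsets.push_back(tpos - qpos);
      }
    }
    ++valid;
  }
  std::sort(offsets.begin(), offsets.end());
  offsets.erase(std::unique(offsets.begin(), offsets.end()), offsets.end());

  for (int off : offsets) {
    int ostart = std::max(0, off);
    int oend = std::min(tn, off + qn);
    int olen = oend - ostart;
    if (olen <= 0) continue;
    double frac = static_cast<double>(olen) / qn;
    if (frac < min_frac - 1e-12) continue;
    int matches = 0;
    const int qoff = ostart - off;
    for (int i = 0; i < olen; ++i)
      if (q[qoff + i] == target[ostart + i]) ++matches;
    double ident = 100.0 * matches / olen;
    bool better = ident > best.identity + 1e-12 ||
        (std::abs(ident - best.identity) <= 1e-12 &&
         (olen > best.olen ||
          (olen == best.olen &&
           (best.strand == 0 || strand > best.strand ||
            (strand == best.strand && ostart < best.tstart)))));
    if (better) {
      best.identity = ident;
      best.olen = olen;
      best.matches = matches;
      best.strand = strand;
      best.tstart = ostart;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_seed_extend(CharacterVector queries, std::string target,
                              int k, double min_frac) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  for (auto& c : target) c = toupper(c);
  KmerIndex idx;
  index_kmers(target, k, idx);

  const int nq = queries.size();
  NumericMatrix out(nq, 5);
  colnames(out) = CharacterVector::create("identity", "aligned_frac",
                                          "matches", "strand", "tstart");
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (auto& c : q) c = toupper(c);
    Best best;
    scan_strand(q, target, idx, k, min_frac, 1, best);
    scan_strand(revcomp_str(q), target, idx, k, min_frac, -1, best);
    if (best.strand == 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = NA_REAL; out(i, 4) = NA_REAL;
    } else {
      out(i, 0) = best.identity;
      out(i, 1) = static_cast<double>(best.olen) / q.size();
      out(i, 2) = best.matches;
      out(i, 3) = best.strand;
      out(i, 4) = best.tstart + 1;  // 1-based
    }
  }
  return out;
}
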