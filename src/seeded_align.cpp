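#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Ungapped best-hit read alignment against a small scaffold set, via
// pigeonhole seeding: a read with at most m mismatches must contain an
// exact k-mer match for any k <= floor(L / (m + 1)) taken from
// non-overlapping read segments. All placements at or below the per-read
// mismatch budget are therefore found; placements over budget are
// irrelevant (the caller records them as unaligned).

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N and friends never participate in seeds
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > kmer_map;

static void index_scaffolds(const std::vector<std::string>& scafs, int k,
                            kmer_map& idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < (int)scafs.size(); ++s) {
    const std::string& seq = scafs[s];
    uint64_t kmer = 0;
    int valid = 0;  // length of current run of ACGT ending at i
    for (int i = 0; i < (int)seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) idx[kmer].push_back(std::make_pair(s, i - k + 1));
    }
  }
}

// mismatches of read placed at scaffold position `start`, early exit > limit
static int hamming_at(const std::string& read, const std::string& scaf,
                      int start, int limit) {
  int mm = 0;
  const int L = (int)read.size();
  for (int i = 0; i < L; ++i) {
    char r = read[i], s = scaf[start + i];
    if (r != s || r == 'N') {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

struct Best {
  int mm, scaf, pos, strand;  // strand: 0 fwd, 1 rev
  Best() : mm(INT_MAX), scaf(INT_MAX), pos(INT_MAX), strand(0) {}
  // deterministic ordering: fewest mismatches, then first scaffold in
  // database order, then forward strand, then leftmost position
  bool better(int m, int s, int st, int p) const {
    if (m != mm) return m < mm;
    if (s != scaf) return s < scaf;
    if (st != strand) return st < strand;
    return p < pos;
  }
};

static void scan_strand(const std::string& read, int strand,
                        const std::vector<std::string>& scafs,
                        const kmer_map& idx, int k, int budget, Best& best) {
  const int L = (int)read.size();
  if (L < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int nseg = L / k;
  for (int seg = 0; seg < nseg; ++seg) {
    int off = seg * k;
    uint64_t kmer = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base2bits(read[off + i]);
      if (b < 0) { ok = false; break; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;
    kmer_map::const_iterator it = idx.find(kmer);
    if (it == idx.end()) continue;
    const std::vector<std::pair<int, int> >& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      int s = hits[h].first;
      int start = hits[h].second - off;
      if (start < 0 || start + L > (int)scafs[s].size()) continue;
      int limit = best.mm == INT_MAX ? budget : std::min(budget, best.mm);
      int mm = hamming_at(read, scafs[s], start, limit);
      if (mm <= budget && best.better(mm, s, strand, start)) {
        best.mm = mm; best.scaf = s; best.strand = strand; best.pos = start;
      }
    }
  }
}

// [[Rcpp::export(name = ".seeded_align")]]
List seeded_align(CharacterVector reads, CharacterVector scaffolds,
                  IntegerVector max_mm, int k) {
  const int n = reads.size();
  if (max_mm.size() != n) stop("max_mm must have one entry per read");
  if (k < 1 || k > 32) stop("seed length k must be in 1..32");

  std::vector<std::string> scafs(scaffolds.size());
  for (int s = 0; s < scaffolds.size(); ++s)
    scafs[s] = as<std::string>(scaffolds[s]);

  kmer_map idx;
  index_scaffolds(scafs, k, idx);

  IntegerVector out_mm(n), out_scaf(n);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int L = (int)fwd.size();
    std::string rev(L, 'N');
    for (int j = 0; j < L; ++j) rev[j] = comp(fwd[L - 1 - j]);

    Best best;
    scan_strand(fwd, 0, scafs, idx, k, max_mm[i], best);
    scan_strand(rev, 1, scafs, idx, k, max_mm[i], best);

    if (best.mm == INT_MAX) {
      out_mm[i] = NA_INTEGER;
      out_scaf[i] = NA_INTEGER;
    } else {
      out_mm[i] = best.mm;
      out_scaf[i] = best.scaf + 1;  // 1-based for R
    }
  }
  return List::create(_["mismatches"] = out_mm, _["scaffold"] = out_scaf);
}
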