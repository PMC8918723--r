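// Seed-and-extend aligner core used by builtinAlign().
//
// The pseudo-genome already contains both converted strands of every
// chromosome, so alignment is forward-only: mate 1 is matched as given and
// mate 2 is reverse-complemented by the R wrapper before it reaches this
// code.  Seeds are exact k-mers taken from the read start at a fixed stride;
// each seed hit proposes a diagonal which is scored by ungapped mismatch
// counting over the full read.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Cand {
  int chrom;  // 0-based pseudo-chromosome index
  int pos;    // 0-based leftmost
  int mm;     // mismatch count
};

inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

void buildIndex(const std::vector<std::string>& seqs, int k, KmerIndex& idx) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < seqs.size(); ++c) {
    const std::string& s = seqs[c];
    if ((int)s.size() < k) continue;
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = baseCode(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }  // N breaks the window
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        idx[kmer].push_back(((uint64_t)c << 32) | (uint64_t)(i + 1 - k));
    }
  }
}

// Mismatches of read placed at ref[start, start+len); N never matches.
int countMismatch(const std::string& ref, long start, const std::string& read,
                  int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char r = read[i];
    if (r == 'N' || r != ref[start + i]) {
      if (++mm > maxmm) return mm;
    }
  }
  return mm;
}

void gatherCandidates(const std::string& read, const KmerIndex& idx,
                      const std::vector<std::string>& seqs, int k, int stride,
                      int maxmm, size_t maxHitsPerKmer,
                      std::vector<Cand>& out) {
  const int len = (int)read.size();
  if (len < k) return;
  std::unordered_set<uint64_t> seen;
  for (int off = 0; off + k <= len; off += stride) {
    uint64_t kmer = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = baseCode(read[off + j]);
      if (b < 0) { ok = false; break; }
      kmer = (kmer << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    KmerIndex::const_iterator it = idx.find(kmer);
    if (it == idx.end()) continue;
    if (it->second.size() > maxHitsPerKmer) continue;  // repeat seed, skip
    for (size_t h = 0; h < it->second.size(); ++h) {
      const int chrom = (int)(it->second[h] >> 32);
      const long pos = (long)(it->second[h] & 0xffffffffULL);
      const long start = pos - off;
      if (start < 0 || start + len > (long)seqs[chrom].size()) continue;
      const uint64_t key = ((uint64_t)chrom << 40) | (uint64_t)start;
      if (!seen.insert(key).second) continue;
      int mm = countMismatch(seqs[chrom], start, read, maxmm);
      if (mm <= maxmm) {
        Cand c = { chrom, (int)start, mm };
        out.push_back(c);
      }
    }
  }
}

inline uint64_t splitmix(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

inline int scaledMaxMM(double per100, int len) {
  int mm = (int)std::floor(per100 * (double)len / 100.0);
  return mm < 0 ? 0 : mm;
}

}  // namespace

// Align reads against the pseudo-genome.  reads2 (already reverse
// complemented) triggers paired-end FR pairing on the same pseudo-chromosome.
// Returns 0-based positions; chrom 0 means unmapped.
// [[Rcpp::export(name = ".cppAlign")]]
List cppAlign(CharacterVector reads1, Nullable<CharacterVector> reads2,
              CharacterVector chromSeqs, int k, int stride,
              double maxMismatchPer100, int maxInsert, bool uniqueOnly,
              int seed, int indexOffset, int maxHitsPerKmer) {
  const int n = reads1.size();
  std::vector<std::string> seqs(chromSeqs.size());
  for (int i = 0; i < chromSeqs.size(); ++i)
    seqs[i] = as<std::string>(chromSeqs[i]);

  KmerIndex idx;
  buildIndex(seqs, k, idx);

  const bool paired = reads2.isNotNull();
  CharacterVector r2;
  if (paired) {
    r2 = reads2.get();
    if (r2.size() != n) stop("mate vectors differ in length");
  }

  IntegerVector chromOut(n, 0), pos1Out(n, NA_INTEGER), pos2Out(n, NA_INTEGER),
      mmOut(n, NA_INTEGER);
  LogicalVector multiOut(n, false);

  std::vector<Cand> c1, c2;
  for (int i = 0; i < n; ++i) {
    c1.clear();
    const std::string s1 = as<std::string>(reads1[i]);
    const int max1 = scaledMaxMM(maxMismatchPer100, (int)s1.size());
    gatherCandidates(s1, idx, seqs, k, stride, max1, (size_t)maxHitsPerKmer, c1);

    if (!paired) {
      int best = max1 + 1, nbest = 0;
      std::vector<int> ties;
      for (size_t a = 0; a < c1.size(); ++a) {
        if (c1[a].mm < best) { best = c1[a].mm; nbest = 1; ties.clear(); ties.push_back((int)a); }
        else if (c1[a].mm == best) { ++nbest; ties.push_back((int)a); }
      }
      if (nbest == 0) continue;
      if (nbest > 1) {
        multiOut[i] = true;
        if (uniqueOnly) continue;
      }
      // tie-break from (seed, global read index): invariant to chunking
      int pick = ties[(int)(splitmix((uint64_t)seed * 2654435761ULL +
                                     (uint64_t)(indexOffset + i)) %
                            ties.size())];
      chromOut[i] = c1[pick].chrom + 1;
      pos1Out[i] = c1[pick].pos;
      mmOut[i] = c1[pick].mm;
      continue;
    }

    c2.clear();
    const std::string s2 = as<std::string>(r2[i]);
    const int len2 = (int)s2.size();
    const int max2 = scaledMaxMM(maxMismatchPer100, len2);
    gatherCandidates(s2, idx, seqs, k, stride, max2, (size_t)maxHitsPerKmer, c2);
    if (c1.empty() || c2.empty()) continue;

    int best = max1 + max2 + 1;
    std::vector<std::pair<int, int> > ties;
    for (size_t a = 0; a < c1.size(); ++a) {
      for (size_t b = 0; b < c2.size(); ++b) {
        if (c1[a].chrom != c2[b].chrom) continue;
        const long p1 = c1[a].pos, p2 = c2[b].pos;
        if (p2 < p1) continue;                       // FR orientation
        const long frag = p2 + len2 - p1;
        if (frag <= 0 || frag > maxInsert) continue;
        const int score = c1[a].mm + c2[b].mm;
        if (score < best) { best = score; ties.clear(); }
        if (score == best) ties.push_back(std::make_pair((int)a, (int)b));
      }
    }
    if (ties.empty()) continue;
    if (ties.size() > 1) {
      multiOut[i] = true;
      if (uniqueOnly) continue;
    }
    const size_t pick =
        (size_t)(splitmix((uint64_t)seed * 2654435761ULL +
                          (uint64_t)(indexOffset + i)) % ties.size());
    const Cand& a = c1[ties[pick].first];
    const Cand& b = c2[ties[pick].second];
    chromOut[i] = a.chrom + 1;
    pos1Out[i] = a.pos;
    pos2Out[i] = b.pos;
    mmOut[i] = a.mm + b.mm;
  }

  return List::create(_["chrom"] = chromOut, _["pos1"] = pos1Out,
                      _["pos2"] = pos2Out, _["mm"] = mmOut,
                      _["multi"] = multiOut);
}
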