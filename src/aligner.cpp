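// Ungapped, end-to-end, mismatch-bounded alignment of short reads against
// a small target set (junction database, transcriptome, or genome).
//
// Strategy: pigeonhole seeding. A placement with <= v mismatches must
// contain at least one of v+1 non-overlapping read segments matched
// exactly (N counts as a mismatch, so an exactly matching segment is
// N-free on both sides). All w-mers of all targets are indexed in a
// sorted array; candidate placements found through any segment are
// verified by full Hamming count with early exit.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

static const int CODE_N = 4;
static const int CODE_BAD = 5;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return CODE_N;
    default: return CODE_BAD;
  }
}

static std::vector<uint8_t> encode(const char *s, R_xlen_t n, bool *ok) {
  std::vector<uint8_t> out(n);
  *ok = true;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c == CODE_BAD) *ok = false;
    out[i] = (uint8_t)c;
  }
  return out;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &s) {
  std::vector<uint8_t> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t c = s[s.size() - 1 - i];
    out[i] = (c < 4) ? (uint8_t)(3 - c) : c;
  }
  return out;
}

// key of the w-mer starting at p, or UINT64_MAX if it contains N
static inline uint64_t kmer_key(const std::vector<uint8_t> &s, size_t p, int w) {
  uint64_t key = 0;
  for (int k = 0; k < w; ++k) {
    uint8_t c = s[p + k];
    if (c >= 4) return UINT64_MAX;
    key = (key << 2) | c;
  }
  return key;
}

struct SeedIndex {
  // sorted (key, target<<32|pos) pairs over every w-mer of every target
  std::vector<std::pair<uint64_t, uint64_t>> entries;
  int w;
};

static SeedIndex build_index(const std::vector<std::vector<uint8_t>> &targets, int w) {
  SeedIndex idx;
  idx.w = w;
  size_t total = 0;
  for (const auto &t : targets)
    if ((int)t.size() >= w) total += t.size() - w + 1;
  idx.entries.reserve(total);
  for (size_t t = 0; t < targets.size(); ++t) {
    const auto &seq = targets[t];
    if ((int)seq.size() < w) continue;
    for (size_t p = 0; p + w <= seq.size(); ++p) {
      uint64_t key = kmer_key(seq, p, w);
      if (key != UINT64_MAX)
        idx.entries.emplace_back(key, ((uint64_t)t << 32) | (uint64_t)p);
    }
  }
  std::sort(idx.entries.begin(), idx.entries.end());
  return idx;
}

static inline int hamming_leq(const std::vector<uint8_t> &read,
                              const std::vector<uint8_t> &target,
                              size_t offset, int vmax) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    uint8_t a = read[i], b = target[offset + i];
    if (a != b || a >= 4) {
      if (++mm > vmax) return vmax + 1;
    }
  }
  return mm;
}

struct Hit {
  int target;
  int offset;
  bool minus;
  int mm;
};

// Enumerate all placements of one (already strand-resolved) read with
// mismatches <= v; appends to hits, dedups via seen.
static void place_one(const std::vector<uint8_t> &read,
                      const std::vector<std::vector<uint8_t>> &targets,
                      const SeedIndex &idx, int v, bool minus,
                      std::vector<Hit> &hits,
                      std::unordered_set<uint64_t> &seen) {
  const int w = idx.w;
  const int nseg = v + 1;
  const size_t len = read.size();
  for (int s = 0; s < nseg; ++s) {
    size_t p = (size_t)s * w;
    if (p + w > len) break;
    uint64_t key = kmer_key(read, p, w);
    if (key == UINT64_MAX) continue;
    auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(),
                               std::make_pair(key, (uint64_t)0));
    for (auto it = lo; it != idx.entries.end() && it->first == key; ++it) {
      uint64_t packed = it->second;
      int t = (int)(packed >> 32);
      long long tp = (long long)(packed & 0xffffffffULL);
      long long o = tp - (long long)p;
      if (o < 0 || (size_t)(o + len) > targets[t].size()) continue;
      uint64_t sig = ((uint64_t)t << 33) | ((uint64_t)o << 1) | (minus ? 1 : 0);
      if (!seen.insert(sig).second) continue;
      int mm = hamming_leq(read, targets[t], (size_t)o, v);
      if (mm <= v) hits.push_back(Hit{t, (int)o, minus, mm});
    }
  }
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(CharacterVector reads, CharacterVector targets,
                     int v, bool unique_only, bool both_strands,
                     bool any_hit_mode) {
  const R_xlen_t nt = targets.size();
  std::vector<std::vector<uint8_t>> tg(nt);
  for (R_xlen_t t = 0; t < nt; ++t) {
    bool ok;
    const char *s = CHAR(STRING_ELT(targets, t));
    tg[t] = encode(s, LENGTH(STRING_ELT(targets, t)), &ok);
    if (!ok) stop("target %d contains non-ACGTN characters", (int)t + 1);
  }

  // seed width from the shortest read so pigeonhole covers every read
  size_t min_len = SIZE_MAX;
  const R_xlen_t nr = reads.size();
  for (R_xlen_t r = 0; r < nr; ++r) {
    size_t l = (size_t)LENGTH(STRING_ELT(reads, r));
    if (l < min_len) min_len = l;
  }
  if (nr == 0 || min_len == SIZE_MAX || min_len == 0)
    stop("no reads to align");
  int w = (int)(min_len / (size_t)(v + 1));
  if (w > 31) w = 31;
  if (w < 1) stop("reads too short for %d mismatches", v);

  SeedIndex idx = build_index(tg, w);

  std::vector<int> out_read, out_target, out_offset, out_mm;
  std::vector<int> out_minus;
  LogicalVector any_hit(any_hit_mode ? nr : 0);

  std::vector<Hit> hits;
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t r = 0; r < nr; ++r) {
    bool ok;
    const char *s = CHAR(STRING_ELT(reads, r));
    std::vector<uint8_t> rd = encode(s, LENGTH(STRING_ELT(reads, r)), &ok);
    if (!ok) stop("read %d contains non-ACGTN characters", (int)r + 1);
    hits.clear();
    seen.clear();
    place_one(rd, tg, idx, v, false, hits, seen);
    if (both_strands)
      place_one(revcomp(rd), tg, idx, v, true, hits, seen);
    if (any_hit_mode) {
      any_hit[r] = !hits.empty();
      continue;
    }
    if (hits.empty()) continue;
    int best = v + 1;
    for (const Hit &h : hits) if (h.mm < best) best = h.mm;
    int nbest = 0;
    for (const Hit &h : hits) if (h.mm == best) ++nbest;
    if (unique_only && nbest > 1) continue;
    for (const Hit &h : hits) {
      if (h.mm != best) continue;
      out_read.push_back((int)r + 1);
      out_target.push_back(h.target + 1);
      out_offset.push_back(h.offset);
      out_minus.push_back(h.minus ? 1 : 0);
      out_mm.push_back(h.mm);
    }
  }

  if (any_hit_mode) return List::create(Named("any_hit") = any_hit);
  return List::create(
    Named("read") = wrap(out_read),
    Named("target") = wrap(out_target),
    Named("offset") = wrap(out_offset),
    Named("minus") = wrap(out_minus),
    Named("mismatches") = wrap(out_mm)
  );
}
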