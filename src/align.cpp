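#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Ungapped substitution-only alignment of short reads (>= 24 nt) against a
// small set of reference sequences. Two entry points share one hit record
// layout: cpp_align_seed (12-mer pigeonhole seeds, production path) and
// cpp_align_brute (exhaustive position scan, test oracle). Hits are emitted
// as parallel vectors (read index, reference index, 0-based start, strand,
// mismatches); ordering is canonicalized on the R side.

namespace {

const int SEED_LEN = 12;

struct Hit {
  int read;   // 0-based read index
  int ref;    // 0-based reference index
  int start;  // 0-based start on reference
  int strand; // +1 / -1
  int mm;
};

char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

bool has_n(const std::string& s) {
  return s.find_first_not_of("ACGT") != std::string::npos;
}

// Hamming distance with early exit once max_mm is exceeded; -1 = over budget.
int hamming_capped(const std::string& ref, int start, const std::string& read,
                   int max_mm) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    if (ref[start + i] != read[i]) {
      if (++mm > max_mm) return -1;
    }
  }
  return mm;
}

// 2-bit encode a 12-mer; -1 if any non-ACGT base.
long long encode_kmer(const std::string& s, int pos) {
  long long v = 0;
  for (int i = 0; i < SEED_LEN; ++i) {
    int b;
    switch (s[pos + i]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: return -1;
    }
    v = (v << 2) | b;
  }
  return v;
}

typedef std::unordered_map<long long, std::vector<std::pair<int, int>>> KmerIndex;

KmerIndex build_index(const std::vector<std::string>& refs) {
  KmerIndex idx;
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < SEED_LEN) continue;
    for (int p = 0; p + SEED_LEN <= (int)s.size(); ++p) {
      long long k = encode_kmer(s, p);
      if (k >= 0) idx[k].push_back({(int)r, p});
    }
  }
  return idx;
}

void scan_strand_seeded(const KmerIndex& idx,
                        const std::vector<std::string>& refs,
                        const std::string& read, int read_i, int strand,
                        int max_mm, std::vector<Hit>& out) {
  int L = (int)read.size();
  if (L < SEED_LEN) return;
  // Pigeonhole: with <= 1 substitution, at least one of two disjoint 12-mer
  // seeds is exact. Reads enter the pipeline at >= 24 nt so both seeds exist;
  // shorter reads fall back to a single seed and max_mm = 0 correctness only,
  // which the R wrapper guards against.
  std::vector<int> seed_pos;
  seed_pos.push_back(0);
  if (max_mm > 0 && L >= 2 * SEED_LEN) seed_pos.push_back(SEED_LEN);
  std::vector<std::pair<int, int>> cand; // (ref, start) candidates
  for (int sp : seed_pos) {
    long long k = encode_kmer(read, sp);
    if (k < 0) continue;
    auto it = idx.find(k);
    if (it == idx.end()) continue;
    for (auto& rp : it->second) {
      int start = rp.second - sp;
      if (start < 0) continue;
      if (start + L > (int)refs[rp.first].size()) continue;
      cand.push_back({rp.first, start});
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (auto& c : cand) {
    int mm = hamming_capped(refs[c.first], c.second, read, max_mm);
    if (mm >= 0) out.push_back({read_i, c.first, c.second, strand, mm});
  }
}

void scan_strand_brute(const std::vector<std::string>& refs,
                       const std::string& read, int read_i, int strand,
                       int max_mm, std::vector<Hit>& out) {
  int L = (int)read.size();
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    int last = (int)s.size() - L;
    for (int p = 0; p <= last; ++p) {
      int mm = hamming_capped(s, p, read, max_mm);
      if (mm >= 0) out.push_back({read_i, (int)r, p, strand, mm});
    }
  }
}

DataFrame hits_to_df(std::vector<Hit>& hits) {
  // Canonical order: read, then reference, start, strand (+ before -), mm.
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.read != b.read) return a.read < b.read;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.start != b.start) return a.start < b.start;
    if (a.strand != b.strand) return a.strand > b.strand;
    return a.mm < b.mm;
  });
  int n = (int)hits.size();
  IntegerVector read(n), ref(n), start(n), strand(n), mm(n);
  for (int i = 0; i < n; ++i) {
    read[i] = hits[i].read + 1;
    ref[i] = hits[i].ref + 1;
    start[i] = hits[i].start;
    strand[i] = hits[i].strand;
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["read"] = read, _["ref"] = ref,
                           _["start"] = start, _["strand"] = strand,
                           _["mismatches"] = mm);
}

DataFrame align_impl(CharacterVector reads, CharacterVector refs_in,
                     int max_mm, bool both_strands, bool report_all,
                     bool brute) {
  std::vector<std::string> refs(refs_in.size());
  for (int i = 0; i < refs_in.size(); ++i) refs[i] = as<std::string>(refs_in[i]);
  KmerIndex idx;
  if (!brute) idx = build_index(refs);
  std::vector<Hit> all;
  for (int i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    if (has_n(fwd)) continue; // N-containing reads dropped upstream as well
    std::vector<Hit> hits;
    if (brute) {
      scan_strand_brute(refs, fwd, i, +1, max_mm, hits);
      if (both_strands) scan_strand_brute(refs, revcomp(fwd), i, -1, max_mm, hits);
    } else {
      scan_strand_seeded(idx, refs, fwd, i, +1, max_mm, hits);
      if (both_strands) scan_strand_seeded(idx, refs, revcomp(fwd), i, -1, max_mm, hits);
    }
    if (!report_all && !hits.empty()) {
      auto best = std::min_element(
          hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
            if (a.ref != b.ref) return a.ref < b.ref;
            if (a.start != b.start) return a.start < b.start;
            if (a.strand != b.strand) return a.strand > b.strand;
            return a.mm < b.mm;
          });
      hits = {*best};
    }
    all.insert(all.end(), hits.begin(), hits.end());
  }
  return hits_to_df(all);
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_align_seed(CharacterVector reads, CharacterVector refs,
                         int max_mm, bool both_strands, bool report_all) {
  return align_impl(reads, refs, max_mm, both_strands, report_all, false);
}

// [[Rcpp::export]]
DataFrame cpp_align_brute(CharacterVector reads, CharacterVector refs,
                          int max_mm, bool both_strands, bool report_all) {
  return align_impl(reads, refs, max_mm, both_strands, report_all, true);
}
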