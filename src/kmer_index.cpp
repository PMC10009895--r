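#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// k-mer index over a small transcriptome: canonical (min of forward and
// reverse-complement) 2-bit encodings mapped to interned transcript sets.
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, int32_t> kmap;  // canonical k-mer -> class id
  std::vector<std::vector<int32_t> > classes;  // class id -> sorted 0-based tx
};

inline int code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return -1;
    default: return -2;  // invalid character
  }
}

// Calls f(canonical_code) for every k-mer made only of A/C/G/T; runs are
// reset at N. Sets *bad_char and stops early on any other character.
template <typename F>
void each_canonical_kmer(const std::string& seq, int k, bool* bad_char, F f) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = code_of(seq[i]);
    if (b == -2) { *bad_char = true; return; }
    if (b == -1) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(fwd < rc ? fwd : rc);
  }
}

}  // namespace

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector ids, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  // collect, per k-mer, the (sorted, unique) transcripts containing it
  std::unordered_map<uint64_t, std::vector<int32_t> > tmp;
  for (int t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    if ((int)s.size() < k)
      stop("transcript '" + as<std::string>(ids[t]) +
           "' is shorter than k = " + std::to_string(k));
    bool bad = false;
    each_canonical_kmer(s, k, &bad, [&](uint64_t code) {
      std::vector<int32_t>& v = tmp[code];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
    if (bad)
      stop("transcript '" + as<std::string>(ids[t]) +
           "' contains characters outside A/C/G/T/N");
  }
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  std::map<std::vector<int32_t>, int32_t> interned;
  for (std::unordered_map<uint64_t, std::vector<int32_t> >::iterator it =
           tmp.begin();
       it != tmp.end(); ++it) {
    std::map<std::vector<int32_t>, int32_t>::iterator hit =
        interned.find(it->second);
    int32_t cid;
    if (hit == interned.end()) {
      cid = (int32_t)idx->classes.size();
      idx->classes.push_back(it->second);
      interned.insert(std::make_pair(it->second, cid));
    } else {
      cid = hit->second;
    }
    idx->kmap.insert(std::make_pair(it->first, cid));
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".kmer_index_n_kmers")]]
double kmer_index_n_kmers(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return (double)p->kmap.size();
}

// Transcript sets (1-based indices) for query k-mer strings; integer(0) for
// k-mers absent from the index or containing non-ACGT characters.
// [[Rcpp::export(name = ".kmer_index_lookup")]]
List kmer_index_lookup(SEXP xp, CharacterVector kmers) {
  XPtr<KmerIndex> p(xp);
  int k = p->k;
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    IntegerVector res(0);
    if ((int)s.size() == k) {
      bool bad = false;
      bool seen = false;
      uint64_t code = 0;
      each_canonical_kmer(s, k, &bad, [&](uint64_t c) { code = c; seen = true; });
      if (!bad && seen) {
        std::unordered_map<uint64_t, int32_t>::iterator it = p->kmap.find(code);
        if (it != p->kmap.end()) {
          const std::vector<int32_t>& cls = p->classes[it->second];
          res = IntegerVector(cls.size());
          for (size_t j = 0; j < cls.size(); ++j) res[j] = cls[j] + 1;
        }
      }
    }
    out[i] = res;
  }
  return out;
}

// Pseudoalign reads: a read's compatibility set is the intersection of the
// transcript sets of its indexed k-mers (absent k-mers skipped); empty
// intersection or no indexed k-mer leaves the read unassigned.
// [[Rcpp::export(name = ".pseudoalign_cpp")]]
List pseudoalign_cpp(SEXP xp, CharacterVector reads) {
  XPtr<KmerIndex> p(xp);
  int k = p->k;
  std::map<std::vector<int32_t>, double> counts;
  double unassigned = 0;
  std::vector<int32_t> cur, scratch;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    bool bad = false, any = false, empty = false;
    cur.clear();
    each_canonical_kmer(s, k, &bad, [&](uint64_t code) {
      if (empty) return;
      std::unordered_map<uint64_t, int32_t>::iterator it = p->kmap.find(code);
      if (it == p->kmap.end()) return;  // skip k-mers absent from the index
      const std::vector<int32_t>& cls = p->classes[it->second];
      if (!any) {
        cur = cls;
        any = true;
      } else {
        scratch.clear();
        std::set_intersection(cur.begin(), cur.end(), cls.begin(), cls.end(),
                              std::back_inserter(scratch));
        cur.swap(scratch);
        if (cur.empty()) empty = true;
      }
    });
    if (bad)
      stop("read " + std::to_string(r + 1) +
           " contains characters outside A/C/G/T/N");
    if (!any || empty || cur.empty()) {
      unassigned += 1;
    } else {
      counts[cur] += 1;
    }
  }
  int n = (int)counts.size();
  List ecs(n);
  NumericVector cnt(n);
  int i = 0;
  for (std::map<std::vector<int32_t>, double>::iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    IntegerVector v(it->first.size());
    for (size_t j = 0; j < it->first.size(); ++j) v[j] = it->first[j] + 1;
    ecs[i] = v;
    cnt[i] = it->second;
  }
  return List::create(_["ec"] = ecs, _["count"] = cnt,
                      _["unassigned"] = unassigned);
}
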