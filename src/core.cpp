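#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit nucleotide encoding; -1 for anything not ACGT (case-insensitive).
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) c = complement(c);
  return out;
}

// Maximal exact matches between ref and qry seeded by shared k-mers.
// unique_ref = true keeps only seeds whose k-mer occurs exactly once in the
// reference (MUM-like); false allows up to max_hits occurrences (MEM-like).
// Coordinates are 0-based; matches are maximal by construction (extended in
// both directions until mismatch or sequence end).
// [[Rcpp::export(name = ".find_anchors_fwd_cpp")]]
DataFrame find_anchors_fwd_cpp(std::string ref, std::string qry, int k,
                               int min_len, bool unique_ref, int max_hits) {
  const int64_t nr = (int64_t)ref.size(), nq = (int64_t)qry.size();
  std::vector<int64_t> out_r, out_q, out_l;
  if (nr < k || nq < k) {
    return DataFrame::create(_["ref_start"] = NumericVector(0),
                             _["qry_start"] = NumericVector(0),
                             _["length"] = NumericVector(0));
  }
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index reference k-mers
  std::unordered_map<uint64_t, std::vector<int64_t>> idx;
  idx.reserve((size_t)nr);
  {
    uint64_t h = 0; int run = 0;
    for (int64_t i = 0; i < nr; ++i) {
      int b = base2bit(ref[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto &v = idx[h];
        if ((int)v.size() <= max_hits) v.push_back(i - k + 1);
      }
    }
  }

  // per-diagonal coverage to avoid re-extending seeds inside a found match
  std::unordered_map<int64_t, int64_t> diag_cov;
  std::unordered_set<uint64_t> seen;

  uint64_t h = 0; int run = 0;
  for (int64_t j = 0; j < nq; ++j) {
    int b = base2bit(qry[j]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    int64_t qpos = j - k + 1;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    const std::vector<int64_t> &hits = it->second;
    if (unique_ref && hits.size() != 1) continue;
    if ((int)hits.size() > max_hits) continue;
    for (int64_t rpos : hits) {
      int64_t diag = rpos - qpos;
      auto dc = diag_cov.find(diag);
      if (dc != diag_cov.end() && qpos + k <= dc->second) continue;
      // extend left
      int64_t ri = rpos, qi = qpos;
      while (ri > 0 && qi > 0 && base2bit(ref[ri - 1]) >= 0 &&
             ref[ri - 1] == qry[qi - 1]) { --ri; --qi; }
      // extend right
      int64_t re = rpos + k, qe = qpos + k;
      while (re < nr && qe < nq && base2bit(ref[re]) >= 0 &&
             ref[re] == qry[qe]) { ++re; ++qe; }
      diag_cov[diag] = qe;
      int64_t len = re - ri;
      if (len < min_len) continue;
      uint64_t key = ((uint64_t)(uint32_t)(int32_t)(diag) << 32) ^
                     (uint64_t)(uint32_t)ri;
      if (!seen.insert(key).second) continue;
      out_r.push_back(ri); out_q.push_back(qi); out_l.push_back(len);
    }
  }
  return DataFrame::create(
      _["ref_start"] = NumericVector(out_r.begin(), out_r.end()),
      _["qry_start"] = NumericVector(out_q.begin(), out_q.end()),
      _["length"] = NumericVector(out_l.begin(), out_l.end()));
}

// Count read k-mer hits against a dictionary of allele-distinctive k-mers.
// kmers[i] belongs to group[i] (1-based); a k-mer seen (in either strand
// orientation) in a read increments its group's count. K-mers shared by two
// different groups are dropped from the dictionary (not distinctive).
// [[Rcpp::export(name = ".count_kmer_hits_cpp")]]
IntegerVector count_kmer_hits_cpp(CharacterVector reads, CharacterVector kmers,
                                  IntegerVector group, int n_groups, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, int> dict;  // kmer hash -> group (0 = dead)
  dict.reserve(kmers.size() * 2);

  auto hash_of = [&](const std::string &s) -> int64_t {
    if ((int)s.size() != k) return -1;
    uint64_t h = 0;
    for (int i = 0; i < k; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) return -1;
      h = (h << 2) | (uint64_t)b;
    }
    return (int64_t)(h & mask);
  };

  auto insert_kmer = [&](uint64_t h, int g) {
    auto it = dict.find(h);
    if (it == dict.end()) dict[h] = g;
    else if (it->second != g) it->second = 0;  // ambiguous across groups
  };

  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    int64_t h = hash_of(s);
    if (h < 0) continue;
    int g = group[i];
    insert_kmer((uint64_t)h, g);
    int64_t hrc = hash_of(revcomp_cpp(s));
    if (hrc >= 0) insert_kmer((uint64_t)hrc, g);
  }

  IntegerVector counts(n_groups);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t h = 0; int run = 0;
    for (const char *p = s; *p; ++p) {
      int b = base2bit(*p);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      auto it = dict.find(h);
      if (it != dict.end() && it->second > 0) counts[it->second - 1]++;
    }
  }
  return counts;
}

// Apply iid substitution errors at rate err per base, using R's RNG so the
// result is reproducible under set.seed().
// [[Rcpp::export(name = ".mutate_reads_cpp")]]
CharacterVector mutate_reads_cpp(CharacterVector reads, double err) {
  if (err <= 0) return reads;
  static const char *alt[4] = {"CGT", "AGT", "ACT", "ACG"};
  CharacterVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    int n_err = (int)R::rbinom((double)s.size(), err);
    for (int e = 0; e < n_err; ++e) {
      int pos = (int)(R::unif_rand() * s.size());
      if (pos >= (int)s.size()) pos = (int)s.size() - 1;
      int b = base2bit(s[pos]);
      if (b < 0) continue;
      int pick = (int)(R::unif_rand() * 3);
      if (pick > 2) pick = 2;
      s[pos] = alt[b][pick];
    }
    out[i] = s;
  }
  return out;
}
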