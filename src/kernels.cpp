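#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or other ambiguity
  }
}

// pack a k-mer (k <= 31) into a 64-bit integer; false if it contains an
// ambiguous base (such k-mers are ignored, matching the forward-strand,
// exact-string k-mer model documented for the normalizer)
static inline bool pack_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static void distinct_kmers(const char *s, int len, int k,
                           std::unordered_set<uint64_t> &out) {
  out.clear();
  for (int p = 0; p + k <= len; ++p) {
    uint64_t v;
    if (pack_kmer(s + p, k, v)) out.insert(v);
  }
}

// Streaming digital normalization: a read is saved as a putative allele
// iff the number of its distinct k-mers absent from the index is at least
// novelty_fraction * (its distinct k-mer count). Saving a read adds all
// its k-mers to the index. Reads shorter than k get NA (skipped).
// [[Rcpp::export]]
List dnr_stream_cpp(CharacterVector reads, int k,
                    double novelty_fraction) {
  std::unordered_set<uint64_t> index;
  std::unordered_set<uint64_t> rk;
  R_xlen_t n = reads.size();
  LogicalVector saved(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int)strlen(s);
    if (len < k) { saved[i] = NA_LOGICAL; continue; }
    distinct_kmers(s, len, k, rk);
    int total = (int)rk.size();
    if (total == 0) { saved[i] = NA_LOGICAL; continue; }
    int novel = 0;
    for (uint64_t v : rk) if (!index.count(v)) ++novel;
    // >= half (or the configured fraction), integer boundary via epsilon
    bool keep = ((double)novel + 1e-9) >= novelty_fraction * (double)total;
    if (keep) for (uint64_t v : rk) index.insert(v);
    saved[i] = keep;
  }
  return List::create(_["saved"] = saved,
                      _["index_size"] = (double)index.size());
}

// k-mers of the current saved-allele set (for index-consistency checks)
// [[Rcpp::export]]
double count_distinct_kmers_cpp(CharacterVector seqs, int k) {
  std::unordered_set<uint64_t> all;
  std::unordered_set<uint64_t> rk;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    distinct_kmers(s, (int)strlen(s), k, rk);
    for (uint64_t v : rk) all.insert(v);
  }
  return (double)all.size();
}

// Lenient end-gap-free matcher: reads are restriction-anchored so the only
// alignment considered is offset 0 over the shared prefix. Candidate
// alleles are found through shared k-mer seeds; the best hit is the allele
// with the fewest substitutions if that count is <= max_mm, ties broken by
// the lowest allele index (callers pass alleles sorted by allele_id).
// [[Rcpp::export]]
List match_reads_cpp(CharacterVector reads, CharacterVector alleles,
                     int k, int max_mm) {
  std::unordered_map<uint64_t, std::vector<int> > seed;
  int A = alleles.size();
  std::unordered_set<uint64_t> ks;
  for (int a = 0; a < A; ++a) {
    const char *s = CHAR(STRING_ELT(alleles, a));
    distinct_kmers(s, (int)strlen(s), k, ks);
    for (uint64_t v : ks) seed[v].push_back(a);
  }
  R_xlen_t n = reads.size();
  IntegerVector best(n), mm(n);
  std::vector<char> seen(A, 0);
  std::vector<int> cand;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int)strlen(s);
    cand.clear();
    for (int p = 0; p + k <= len; ++p) {
      uint64_t v;
      if (!pack_kmer(s + p, k, v)) continue;
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = seed.find(v);
      if (it == seed.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        int a = it->second[j];
        if (!seen[a]) { seen[a] = 1; cand.push_back(a); }
      }
    }
    std::sort(cand.begin(), cand.end());
    int ba = -1, bm = max_mm + 1;
    for (size_t j = 0; j < cand.size(); ++j) {
      int a = cand[j];
      seen[a] = 0;
      const char *t = CHAR(STRING_ELT(alleles, a));
      int L = std::min(len, (int)strlen(t));
      int d = 0;
      for (int p = 0; p < L && d < bm; ++p) if (s[p] != t[p]) ++d;
      if (d < bm) { bm = d; ba = a; }
    }
    if (ba >= 0 && bm <= max_mm) { best[i] = ba + 1; mm[i] = bm; }
    else { best[i] = NA_INTEGER; mm[i] = NA_INTEGER; }
  }
  return List::create(_["allele"] = best, _["mismatches"] = mm);
}

// Per-base substitution errors using R's RNG (so set.seed() governs it)
// [[Rcpp::export]]
CharacterVector perturb_reads_cpp(CharacterVector reads, double error_rate) {
  RNGScope scope;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    buf.assign(CHAR(STRING_ELT(reads, i)));
    for (size_t p = 0; p < buf.size(); ++p) {
      if (unif_rand() < error_rate) {
        int b = base_code(buf[p]);
        if (b < 0) continue;
        int off = 1 + (int)(unif_rand() * 3.0);
        if (off > 3) off = 3;
        buf[p] = BASES[(b + off) & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}

static inline char BASES_CHR(int b) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  return B[b];
}

// Minimal pileup caller. Reads are anchored at position 1 of their
// assigned reference allele. Per position and sample: missing if depth <
// min_depth; heterozygous (top two bases) if the second-most-common base
// reaches het_min_fraction of the sample depth; else homozygous for the
// majority base (ties by base order A<C<G<T). A position is emitted as a
// biallelic site when exactly two distinct bases occur across the called
// genotypes; >2 distinct bases is counted as triallelic and dropped.
// gt codes: 0 = missing, 1 = ref hom, 2 = het, 3 = alt hom
// [[Rcpp::export]]
List pileup_call_cpp(CharacterVector reads, IntegerVector allele_of,
                     IntegerVector sample_of, int n_alleles, int n_samples,
                     IntegerVector allele_len, int min_depth,
                     double het_min_fraction) {
  R_xlen_t n = reads.size();
  std::vector< std::vector<int> > by_allele(n_alleles);
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = allele_of[i];
    if (a == NA_INTEGER) continue;
    by_allele[a - 1].push_back((int)i);
  }
  std::vector<int> site_allele, site_pos, n_tri(1, 0);
  std::vector<char> site_ref, site_alt;
  std::vector<int> gt_rows;   // n_samples entries per site
  std::vector<int> dp_rows;
  std::vector<int> cnt;       // 4 * L * S scratch
  std::vector<int> scall;     // per-sample called pair: b1*4+b2 (-1 missing)
  for (int a = 0; a < n_alleles; ++a) {
    const std::vector<int> &idx = by_allele[a];
    if (idx.empty()) continue;
    int L = allele_len[a];
    cnt.assign((size_t)4 * L * n_samples, 0);
    for (size_t j = 0; j < idx.size(); ++j) {
      int i = idx[j];
      const char *s = CHAR(STRING_ELT(reads, i));
      int len = std::min((int)strlen(s), L);
      int smp = sample_of[i] - 1;
      for (int p = 0; p < len; ++p) {
        int b = base_code(s[p]);
        if (b >= 0) cnt[((size_t)p * n_samples + smp) * 4 + b]++;
      }
    }
    for (int p = 0; p < L; ++p) {
      scall.assign(n_samples, -1);
      int allele_mask = 0;
      int tot[4] = {0, 0, 0, 0};
      for (int smp = 0; smp < n_samples; ++smp) {
        const int *c = &cnt[((size_t)p * n_samples + smp) * 4];
        int depth = c[0] + c[1] + c[2] + c[3];
        for (int b = 0; b < 4; ++b) tot[b] += c[b];
        if (depth < min_depth) continue;
        int b1 = 0;
        for (int b = 1; b < 4; ++b) if (c[b] > c[b1]) b1 = b;
        int b2 = -1;
        for (int b = 0; b < 4; ++b)
          if (b != b1 && (b2 < 0 || c[b] > c[b2])) b2 = b;
        bool het = c[b2] > 0 &&
          ((double)c[b2] + 1e-9) >= het_min_fraction * (double)depth;
        if (het) {
          int lo = std::min(b1, b2), hi = std::max(b1, b2);
          scall[smp] = lo * 4 + hi;
          allele_mask |= (1 << lo) | (1 << hi);
        } else {
          scall[smp] = b1 * 4 + b1;
          allele_mask |= (1 << b1);
        }
      }
      int n_distinct = 0;
      for (int b = 0; b < 4; ++b) if (allele_mask & (1 << b)) ++n_distinct;
      if (n_distinct < 2) continue;
      if (n_distinct > 2) { n_tri[0]++; continue; }
      int ba = -1, bb = -1;
      for (int b = 0; b < 4; ++b)
        if (allele_mask & (1 << b)) { if (ba < 0) ba = b; else bb = b; }
      // ref = overall-majority of the two site alleles, ties by base order
      int rb = (tot[bb] > tot[ba]) ? bb : ba;
      int ab = (rb == ba) ? bb : ba;
      site_allele.push_back(a + 1);
      site_pos.push_back(p + 1);
      site_ref.push_back(BASES_CHR(rb));
      site_alt.push_back(BASES_CHR(ab));
      for (int smp = 0; smp < n_samples; ++smp) {
        const int *c = &cnt[((size_t)p * n_samples + smp) * 4];
        dp_rows.push_back(c[0] + c[1] + c[2] + c[3]);
        int sc = scall[smp];
        if (sc < 0) { gt_rows.push_back(0); continue; }
        int x = sc / 4, y = sc % 4;
        if (x != y) gt_rows.push_back(2);
        else if (x == rb) gt_rows.push_back(1);
        else gt_rows.push_back(3);
      }
    }
  }
  int ns = (int)site_allele.size();
  IntegerMatrix gt(ns, n_samples), dp(ns, n_samples);
  for (int i = 0; i < ns; ++i)
    for (int smp = 0; smp < n_samples; ++smp) {
      gt(i, smp) = gt_rows[(size_t)i * n_samples + smp];
      dp(i, smp) = dp_rows[(size_t)i * n_samples + smp];
    }
  CharacterVector refv(ns), altv(ns);
  for (int i = 0; i < ns; ++i) {
    refv[i] = std::string(1, site_ref[i]);
    altv[i] = std::string(1, site_alt[i]);
  }
  return List::create(
    _["allele"] = wrap(site_allele), _["pos"] = wrap(site_pos),
    _["ref"] = refv, _["alt"] = altv, _["gt"] = gt, _["dp"] = dp,
    _["n_triallelic"] = n_tri[0]);
}

// Greedy reference deduplication: alleles are visited in decreasing
// support order (ties by index); an allele within max_mm substitutions
// of an already-kept allele (candidates found through shared k-mers)
// is mapped onto the closest keeper, ties to the lowest keeper index;
// otherwise it becomes a keeper itself. Returns the keeper row (1-based)
// for every allele.
// [[Rcpp::export]]
IntegerVector dedup_alleles_cpp(CharacterVector seqs, NumericVector support,
                                int k, int max_mm) {
  int n = seqs.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (support[a] != support[b]) return support[a] > support[b];
    return a < b;
  });
  std::unordered_map<uint64_t, std::vector<int> > seed;
  std::unordered_set<uint64_t> ks;
  IntegerVector keeper(n);
  std::vector<char> seen(n, 0);
  std::vector<int> cand;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = (int)strlen(s);
    cand.clear();
    for (int p = 0; p + k <= len; ++p) {
      uint64_t v;
      if (!pack_kmer(s + p, k, v)) continue;
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = seed.find(v);
      if (it == seed.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        int a = it->second[j];
        if (!seen[a]) { seen[a] = 1; cand.push_back(a); }
      }
    }
    std::sort(cand.begin(), cand.end());
    int ba = -1, bm = max_mm + 1;
    for (size_t j = 0; j < cand.size(); ++j) {
      int a = cand[j];
      seen[a] = 0;
      const char *t = CHAR(STRING_ELT(seqs, a));
      int L = std::min(len, (int)strlen(t));
      int d = 0;
      for (int p = 0; p < L && d < bm; ++p) if (s[p] != t[p]) ++d;
      if (d < bm) { bm = d; ba = a; }
    }
    if (ba >= 0 && bm <= max_mm) {
      keeper[i] = ba + 1;
    } else {
      keeper[i] = i + 1;
      distinct_kmers(s, len, k, ks);
      for (uint64_t v : ks) seed[v].push_back(i);
    }
  }
  return keeper;
}

// Center-star representative among weighted unique sequences: the sequence
// minimizing the multiplicity-weighted total Hamming distance to all
// cluster members, ties broken by the lexicographically smallest sequence.
// [[Rcpp::export]]
List csr_center_cpp(CharacterVector useqs, NumericVector counts) {
  int m = useqs.size();
  std::vector<double> tot(m, 0.0);
  for (int i = 0; i < m; ++i) {
    const char *si = CHAR(STRING_ELT(useqs, i));
    int li = (int)strlen(si);
    for (int j = i + 1; j < m; ++j) {
      const char *sj = CHAR(STRING_ELT(useqs, j));
      int L = std::min(li, (int)strlen(sj));
      int d = 0;
      for (int p = 0; p < L; ++p) if (si[p] != sj[p]) ++d;
      tot[i] += (double)d * counts[j];
      tot[j] += (double)d * counts[i];
    }
  }
  int best = 0;
  for (int i = 1; i < m; ++i) {
    if (tot[i] < tot[best] ||
        (tot[i] == tot[best] &&
         strcmp(CHAR(STRING_ELT(useqs, i)), CHAR(STRING_ELT(useqs, best))) < 0))
      best = i;
  }
  return List::create(_["index"] = best + 1, _["total_distance"] = tot[best]);
}

// Pairwise independence G / (2 ln 10) over the code contingency table of
// shared non-missing individuals. codes: markers x individuals, 0 =
// missing, categories 1..ncat. Degenerate tables (one effective row or
// column) get LOD 0.
// [[Rcpp::export]]
NumericMatrix pairwise_lod_cpp(IntegerMatrix codes, int ncat) {
  int M = codes.nrow(), N = codes.ncol();
  NumericMatrix lod(M, M);
  std::vector<int> tab(ncat * ncat);
  const double two_ln10 = 2.0 * std::log(10.0);
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      std::fill(tab.begin(), tab.end(), 0);
      int n = 0;
      for (int s = 0; s < N; ++s) {
        int a = codes(i, s), b = codes(j, s);
        if (a > 0 && b > 0) { tab[(a - 1) * ncat + (b - 1)]++; ++n; }
      }
      double G = 0.0;
      if (n > 0) {
        std::vector<int> rs(ncat, 0), cs(ncat, 0);
        int nr = 0, nc = 0;
        for (int a = 0; a < ncat; ++a)
          for (int b = 0; b < ncat; ++b) {
            rs[a] += tab[a * ncat + b];
            cs[b] += tab[a * ncat + b];
          }
        for (int a = 0; a < ncat; ++a) if (rs[a] > 0) ++nr;
        for (int b = 0; b < ncat; ++b) if (cs[b] > 0) ++nc;
        if (nr >= 2 && nc >= 2) {
          for (int a = 0; a < ncat; ++a)
            for (int b = 0; b < ncat; ++b) {
              int o = tab[a * ncat + b];
              if (o > 0)
                G += 2.0 * o * std::log((double)o * n /
                                        ((double)rs[a] * cs[b]));
            }
          if (G < 0) G = 0;  // numerical guard
        }
      }
      lod(i, j) = lod(j, i) = G / two_ln10;
    }
  }
  return lod;
}

// Pairwise similarity: fraction of individuals, among those non-missing in
// both markers, with identical codes. NaN when no shared individuals.
// [[Rcpp::export]]
NumericMatrix pairwise_similarity_cpp(IntegerMatrix codes) {
  int M = codes.nrow(), N = codes.ncol();
  NumericMatrix sim(M, M);
  for (int i = 0; i < M; ++i) {
    sim(i, i) = 1.0;
    for (int j = i + 1; j < M; ++j) {
      int shared = 0, eq = 0;
      for (int s = 0; s < N; ++s) {
        int a = codes(i, s), b = codes(j, s);
        if (a > 0 && b > 0) { ++shared; if (a == b) ++eq; }
      }
      double v = shared > 0 ? (double)eq / shared : R_NaN;
      sim(i, j) = sim(j, i) = v;
    }
  }
  return sim;
}
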