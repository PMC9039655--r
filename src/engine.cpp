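// Seed-and-extend alignment engines.
//
// Two search primitives back the package:
//  * a k-mer seed index + full-length ungapped Hamming mapper with a
//    uniqueness margin (read mapping; disjoint seeds give a pigeonhole
//    guarantee of finding every locus within the mismatch budget when
//    max mismatches < floor(read_len / k));
//  * a word-seeded local hit scan used for probe-efficacy scoring and
//    unmapped-read attribution (every query offset is seeded, so the hit
//    set equals the exhaustive "placement contains an exact word" oracle).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bit(char c) {
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
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// Seed index over a multi-chromosome genome
// ---------------------------------------------------------------------------

struct SeedIndex {
  std::string genome;                  // concatenated chromosomes
  std::vector<uint64_t> chrom_start;   // global offset of each chromosome
  std::vector<uint64_t> chrom_end;
  std::vector<std::string> chrom_name;
  int k;
  std::vector<uint64_t> keys;          // sorted k-mer codes
  std::vector<uint64_t> pos;           // global positions, parallel to keys
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  uint64_t off = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    idx->chrom_start.push_back(off);
    idx->chrom_end.push_back(off + s.size());
    idx->chrom_name.push_back(as<std::string>(names[i]));
    idx->genome += s;
    off += s.size();
  }
  const std::string& g = idx->genome;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<std::pair<uint64_t, uint64_t>> ent;
  for (size_t c = 0; c < idx->chrom_start.size(); ++c) {
    uint64_t lo = idx->chrom_start[c], hi = idx->chrom_end[c];
    if (hi - lo < (uint64_t)k) continue;
    uint64_t code = 0; int run = 0;
    for (uint64_t p = lo; p < hi; ++p) {
      int b = base2bit(g[p]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) ent.emplace_back(code, p - k + 1);
    }
  }
  std::sort(ent.begin(), ent.end());
  idx->keys.reserve(ent.size());
  idx->pos.reserve(ent.size());
  for (auto& e : ent) { idx->keys.push_back(e.first); idx->pos.push_back(e.second); }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)idx->keys.size(),
                      _["chrom"] = wrap(idx->chrom_name),
                      _["length"] = NumericVector(idx->chrom_end.begin(), idx->chrom_end.end()) -
                                    NumericVector(idx->chrom_start.begin(), idx->chrom_start.end()));
}

// [[Rcpp::export]]
NumericVector cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base2bit(c);
    if (b < 0) return NumericVector(0);
    code = (code << 2) | (uint64_t)b;
  }
  auto lo = std::lower_bound(idx->keys.begin(), idx->keys.end(), code);
  auto hi = std::upper_bound(idx->keys.begin(), idx->keys.end(), code);
  NumericVector out(hi - lo);
  for (R_xlen_t i = 0; lo + i != hi; ++i) out[i] = (double)idx->pos[(lo - idx->keys.begin()) + i];
  return out;
}

static int hamming_at(const std::string& g, uint64_t start, const std::string& q) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i)
    if (g[start + i] != q[i]) ++mm;
  return mm;
}

// Map each read independently (mates are paired on the R side).
// Returns one row per read: status 0 = unmapped, 1 = unique, 2 = multimapped.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, double max_mismatch_frac,
                        int unique_margin) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  const std::string& g = idx->genome;
  R_xlen_t n = reads.size();
  IntegerVector status(n), chrom(n, NA_INTEGER), mism(n, NA_INTEGER),
      naccept(n, 0), strand(n, NA_INTEGER);
  NumericVector start(n, NA_REAL);

  for (R_xlen_t r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    if (len < k) { status[r] = 0; continue; }
    int thresh = (int)std::floor(max_mismatch_frac * len + 1e-6);
    std::string rev = revcomp(fwd);
    // candidate loci: (global start, strand 0/1)
    std::vector<std::pair<uint64_t, int>> cand;
    for (int sdi = 0; sdi < 2; ++sdi) {
      const std::string& q = sdi == 0 ? fwd : rev;
      for (int off = 0; off + k <= len; off += k) {
        uint64_t code = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bit(q[off + j]);
          if (b < 0) { ok = false; break; }
          code = (code << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto lo = std::lower_bound(idx->keys.begin(), idx->keys.end(), code);
        auto hi = std::upper_bound(idx->keys.begin(), idx->keys.end(), code);
        for (auto it = lo; it != hi; ++it) {
          uint64_t p = idx->pos[it - idx->keys.begin()];
          if (p < (uint64_t)off) continue;
          cand.emplace_back(p - off, sdi);
        }
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    int best_mm = len + 1, second_mm = len + 1, n_acc = 0;
    uint64_t best_start = 0; int best_strand = 0, best_chrom = -1;
    for (auto& cs : cand) {
      uint64_t s = cs.first;
      // must lie fully inside one chromosome
      int ci = -1;
      {
        auto it = std::upper_bound(idx->chrom_start.begin(), idx->chrom_start.end(), s);
        ci = (int)(it - idx->chrom_start.begin()) - 1;
      }
      if (ci < 0 || s + (uint64_t)len > idx->chrom_end[ci]) continue;
      const std::string& q = cs.second == 0 ? fwd : rev;
      int mm = hamming_at(g, s, q);
      if (mm > thresh) continue;
      ++n_acc;
      if (mm < best_mm) {
        second_mm = best_mm;
        best_mm = mm; best_start = s; best_strand = cs.second; best_chrom = ci;
      } else if (mm < second_mm) {
        second_mm = mm;
      }
    }
    naccept[r] = n_acc;
    if (n_acc == 0) { status[r] = 0; continue; }
    bool uniq = (n_acc == 1) || (second_mm - best_mm >= unique_margin);
    status[r] = uniq ? 1 : 2;
    chrom[r] = best_chrom + 1;
    start[r] = (double)(best_start - idx->chrom_start[best_chrom]);
    strand[r] = best_strand;
    mism[r] = best_mm;
  }
  return DataFrame::create(_["status"] = status, _["chrom_idx"] = chrom,
                           _["start"] = start, _["strand"] = strand,
                           _["mismatches"] = mism, _["n_candidates"] = naccept,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Word-seeded local hit scan (probe efficacy / attribution)
// ---------------------------------------------------------------------------

// A hit is a full-diagonal placement of the query on the target (clipped at
// target bounds) that (a) shares at least one exact `word`-length match with
// the target at the implied offset, (b) covers >= min_cov of the query, and
// (c) has matches / query_len >= min_identity. Both strands are searched.
// [[Rcpp::export]]
DataFrame cpp_local_hits(CharacterVector queries, CharacterVector targets,
                         double min_identity, double min_cov, int word) {
  if (word < 4 || word > 15) stop("word_size must be between 4 and 15");
  const uint64_t mask = (1ULL << (2 * word)) - 1;

  std::vector<int> out_query, out_target, out_matches, out_winlen;
  std::vector<double> out_start;
  std::vector<int> out_strand;

  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    std::string tg = as<std::string>(targets[t]);
    int64_t tlen = (int64_t)tg.size();
    if (tlen < word) continue;
    // counting-sort word index of the target
    size_t nbuck = (size_t)1 << (2 * word);
    std::vector<uint32_t> cnt(nbuck + 1, 0);
    std::vector<int64_t> codes(tlen - word + 1, -1);
    {
      uint64_t code = 0; int run = 0;
      for (int64_t p = 0; p < tlen; ++p) {
        int b = base2bit(tg[p]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= word) { codes[p - word + 1] = (int64_t)code; ++cnt[code + 1]; }
      }
    }
    for (size_t i = 1; i <= nbuck; ++i) cnt[i] += cnt[i - 1];
    std::vector<uint32_t> posv(codes.size() > 0 ? cnt[nbuck] : 0);
    {
      std::vector<uint32_t> fill(cnt.begin(), cnt.end() - 1);
      for (size_t p = 0; p < codes.size(); ++p)
        if (codes[p] >= 0) posv[fill[codes[p]]++] = (uint32_t)p;
    }

    for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
      std::string fwd = as<std::string>(queries[qi]);
      int qlen = (int)fwd.size();
      if (qlen < word) continue;
      std::string rev = revcomp(fwd);
      for (int sdi = 0; sdi < 2; ++sdi) {
        const std::string& q = sdi == 0 ? fwd : rev;
        std::vector<int64_t> starts;
        for (int off = 0; off + word <= qlen; ++off) {
          uint64_t code = 0; bool ok = true;
          for (int j = 0; j < word; ++j) {
            int b = base2bit(q[off + j]);
            if (b < 0) { ok = false; break; }
            code = (code << 2) | (uint64_t)b;
          }
          if (!ok) continue;
          for (uint32_t ii = cnt[code]; ii < cnt[code + 1]; ++ii)
            starts.push_back((int64_t)posv[ii] - off);
        }
        std::sort(starts.begin(), starts.end());
        starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
        for (int64_t s : starts) {
          int64_t ws = std::max(s, (int64_t)0);
          int64_t we = std::min(s + qlen, tlen);
          int winlen = (int)(we - ws);
          if (winlen <= 0) continue;
          if ((double)winlen + 1e-9 < min_cov * qlen) continue;
          int matches = 0;
          for (int64_t p = ws; p < we; ++p)
            if (tg[p] == q[p - s]) ++matches;
          if ((double)matches + 1e-9 < min_identity * qlen) continue;
          out_query.push_back((int)qi + 1);
          out_target.push_back((int)t + 1);
          out_start.push_back((double)ws);
          out_strand.push_back(sdi);
          out_matches.push_back(matches);
          out_winlen.push_back(winlen);
        }
      }
    }
  }
  return DataFrame::create(_["query_idx"] = wrap(out_query),
                           _["target_idx"] = wrap(out_target),
                           _["tstart"] = wrap(out_start),
                           _["strand"] = wrap(out_strand),
                           _["matches"] = wrap(out_matches),
                           _["win_len"] = wrap(out_winlen),
                           _["stringsAsFactors"] = false);
}
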