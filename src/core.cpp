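#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index: postings stored as flat arrays keyed by sorted unique k-mers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_postings(CharacterVector refs, int k, int step) {
  std::vector<std::pair<std::string, std::pair<int,int> > > entries;
  for (R_xlen_t t = 0; t < refs.size(); ++t) {
    std::string s = as<std::string>(refs[t]);
    if ((int)s.size() < k) continue;
    for (int off = 0; off + k <= (int)s.size(); off += step)
      entries.push_back(std::make_pair(s.substr(off, k),
                                       std::make_pair((int)t, off)));
  }
  std::sort(entries.begin(), entries.end());
  int n = entries.size();
  std::vector<std::string> keys;
  std::vector<int> key_start;
  IntegerVector post_target(n), post_offset(n);
  for (int i = 0; i < n; ++i) {
    if (i == 0 || entries[i].first != entries[i-1].first) {
      keys.push_back(entries[i].first);
      key_start.push_back(i);
    }
    post_target[i] = entries[i].second.first;
    post_offset[i] = entries[i].second.second;
  }
  key_start.push_back(n);
  return List::create(_["keys"] = wrap(keys),
                      _["key_start"] = wrap(key_start),
                      _["post_target"] = post_target,
                      _["post_offset"] = post_offset);
}

// Compact banded global-in-read DP without traceback: edit distance between
// `read` and the reference segment beginning at `start`, minimised over
// segment lengths within the band (exact for distances <= max_edit).
// `scratch` is caller-owned reusable storage.
static int banded_edit_fast(const std::string &read, const std::string &ref,
                            int start, int max_edit,
                            std::vector<int> &scratch) {
  const int L = (int)read.size();
  const int tmax = std::min(L + max_edit, (int)ref.size() - start);
  if (tmax < std::max(0, L - max_edit)) return INT_MAX;
  const int w = 2 * max_edit + 1;
  const int INF = 1 << 28;
  scratch.assign((size_t)(L + 1) * w, INF);
  // row i holds j in [i - max_edit, i + max_edit]; band slot b = j - i + max_edit
  auto at = [&](int i, int b) -> int& { return scratch[(size_t)i * w + b]; };
  for (int j = 0; j <= std::min(max_edit, tmax); ++j) at(0, j + max_edit) = j;
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, i - max_edit), jhi = std::min(tmax, i + max_edit);
    for (int j = jlo; j <= jhi; ++j) {
      int b = j - i + max_edit;
      int best = INF;
      if (j > 0) {
        int d = at(i - 1, b);          // (i-1, j-1) is same slot in row i-1
        if (d < INF) best = d + (read[i-1] == ref[start + j - 1] ? 0 : 1);
      }
      if (b + 1 < w) {                 // (i-1, j) -> read insertion
        int d = at(i - 1, b + 1);
        if (d < INF && d + 1 < best) best = d + 1;
      }
      if (b > 0) {                     // (i, j-1) -> deletion from read
        int d = at(i, b - 1);
        if (d < INF && d + 1 < best) best = d + 1;
      }
      at(i, b) = best;
    }
  }
  int bestd = INF;
  for (int j = std::max(0, L - max_edit); j <= tmax; ++j) {
    int d = at(L, j - L + max_edit);
    if (d < bestd) bestd = d;
  }
  return bestd > max_edit ? INT_MAX : bestd;
}

// Banded global-in-read DP over a full (small) matrix, with traceback for
// CIGAR output.  Same contract as banded_edit_fast.
static int banded_edit(const std::string &read, const std::string &ref,
                       int start, int max_edit, std::string *cigar) {
  const int L = (int)read.size();
  const int tmax0 = std::min(L + max_edit, (int)ref.size() - start);
  if (tmax0 < std::max(0, L - max_edit)) return INT_MAX;
  const int tmax = tmax0;
  const int INF = 1 << 28;
  // full (L+1) x (tmax+1) matrix, only band cells filled
  std::vector<int> D((size_t)(L + 1) * (tmax + 1), INF);
  auto at = [&](int i, int j) -> int& { return D[(size_t)i * (tmax + 1) + j]; };
  for (int j = 0; j <= std::min(max_edit, tmax); ++j) at(0, j) = j;
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, i - max_edit), jhi = std::min(tmax, i + max_edit);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF;
      if (j > 0 && at(i-1, j-1) < INF) {
        int c = at(i-1, j-1) + (read[i-1] == ref[start + j - 1] ? 0 : 1);
        if (c < best) best = c;
      }
      if (at(i-1, j) < INF && at(i-1, j) + 1 < best) best = at(i-1, j) + 1; // read ins
      if (j > 0 && at(i, j-1) < INF && at(i, j-1) + 1 < best) best = at(i, j-1) + 1; // del
      at(i, j) = best;
    }
  }
  int bestj = -1, bestd = INF;
  for (int j = std::max(0, L - max_edit); j <= tmax; ++j)
    if (at(L, j) < bestd) { bestd = at(L, j); bestj = j; }
  if (bestd > max_edit) return INT_MAX;
  if (cigar) {
    // traceback from (L, bestj)
    std::string ops;
    int i = L, j = bestj;
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 && at(i-1, j-1) < INF &&
          at(i, j) == at(i-1, j-1) + (read[i-1] == ref[start + j - 1] ? 0 : 1)) {
        ops.push_back('M'); --i; --j;
      } else if (i > 0 && at(i-1, j) < INF && at(i, j) == at(i-1, j) + 1) {
        ops.push_back('I'); --i;
      } else {
        ops.push_back('D'); --j;
      }
    }
    std::reverse(ops.begin(), ops.end());
    std::string cg; int run = 0; char cur = 0;
    for (char o : ops) {
      if (o == cur) { ++run; }
      else { if (run) cg += std::to_string(run) + cur; cur = o; run = 1; }
    }
    if (run) cg += std::to_string(run) + cur;
    *cigar = cg;
  }
  return bestd;
}

struct Hit { int target; int start; char strand; int edit; std::string cigar; };

typedef std::unordered_map<uint64_t, std::pair<int,int> > KMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default:  return -1;
  }
}

// 2-bit packed encoding of a k-mer (k <= 31); returns false on non-ACGT
static bool pack_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static void align_one(const std::string &read, const KMap &kmap,
                      const IntegerVector &post_target,
                      const IntegerVector &post_offset,
                      const std::vector<std::string> &refs,
                      int k, int max_edit, bool want_cigar,
                      std::vector<Hit> &out, std::vector<int> &scratch) {
  const int L = (int)read.size();
  if (L < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const char strands[2] = {'+', '-'};
  for (int si = 0; si < 2; ++si) {
    const std::string q = (si == 0) ? read : revcomp(read);
    // candidate starts per target from seed diagonals, expanded +- max_edit
    std::unordered_map<long long, char> seen; // (target<<32)|start
    std::vector<std::pair<int,int> > cand;
    uint64_t kv = 0;
    int valid = 0; // consecutive ACGT bases accumulated
    for (int pos = 0; pos < L; ++pos) {
      int c = base_code(q[pos]);
      if (c < 0) { valid = 0; continue; }
      kv = ((kv << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      int off = pos - k + 1;
      KMap::const_iterator it = kmap.find(kv);
      if (it == kmap.end()) continue;
      for (int p = it->second.first; p < it->second.second; ++p) {
        int tgt = post_target[p];
        int implied = post_offset[p] - off;
        for (int s = implied - max_edit; s <= implied + max_edit; ++s) {
          if (s < 0 || s >= (int)refs[tgt].size()) continue;
          long long key = ((long long)tgt << 32) | (unsigned int)s;
          if (seen.insert(std::make_pair(key, 1)).second)
            cand.push_back(std::make_pair(tgt, s));
        }
      }
    }
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int tgt = cand[ci].first, s = cand[ci].second;
      int d;
      std::string cg;
      if (want_cigar) d = banded_edit(q, refs[tgt], s, max_edit, &cg);
      else d = banded_edit_fast(q, refs[tgt], s, max_edit, scratch);
      if (d <= max_edit) {
        Hit h; h.target = tgt; h.start = s;
        h.strand = strands[si]; h.edit = d; h.cigar = cg;
        out.push_back(h);
      }
    }
  }
}

static KMap make_kmap(const CharacterVector &keys,
                      const IntegerVector &key_start, int k) {
  KMap kmap;
  kmap.reserve(keys.size() * 2);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t kv;
    std::string s = as<std::string>(keys[i]);
    if (!pack_kmer(s.c_str(), k, kv)) continue;
    kmap[kv] = std::make_pair(key_start[i], key_start[i + 1]);
  }
  return kmap;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads,
                          CharacterVector keys, IntegerVector key_start,
                          IntegerVector post_target, IntegerVector post_offset,
                          CharacterVector ref_seqs,
                          int k, int max_edit, bool want_cigar) {
  auto kmap = make_kmap(keys, key_start, k);
  std::vector<std::string> refs(ref_seqs.size());
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    refs[i] = as<std::string>(ref_seqs[i]);
  std::vector<int> o_read, o_target, o_start, o_edit;
  std::vector<std::string> o_strand, o_cigar;
  std::vector<int> scratch;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::vector<Hit> hits;
    align_one(as<std::string>(reads[r]), kmap, post_target, post_offset,
              refs, k, max_edit, want_cigar, hits, scratch);
    for (auto &h : hits) {
      o_read.push_back((int)r + 1);
      o_target.push_back(h.target + 1);
      o_start.push_back(h.start);
      o_edit.push_back(h.edit);
      o_strand.push_back(std::string(1, h.strand));
      o_cigar.push_back(h.cigar);
    }
  }
  return DataFrame::create(_["read"] = wrap(o_read),
                           _["target"] = wrap(o_target),
                           _["tstart"] = wrap(o_start),
                           _["strand"] = wrap(o_strand),
                           _["edit"] = wrap(o_edit),
                           _["cigar"] = wrap(o_cigar),
                           _["stringsAsFactors"] = false);
}

// Pair-level alignment: for each pair report whether a proper placement
// exists (same target, opposite strands, insert within bounds, each mate
// within max_edit) and the minimal-summed-edit target set.
// [[Rcpp::export]]
List cpp_align_pairs(CharacterVector mate1, CharacterVector mate2,
                     CharacterVector keys, IntegerVector key_start,
                     IntegerVector post_target, IntegerVector post_offset,
                     CharacterVector ref_seqs, CharacterVector ref_names,
                     int k, int max_edit,
                     int insert_min, int insert_max) {
  auto kmap = make_kmap(keys, key_start, k);
  std::vector<int> scratch;
  std::vector<std::string> refs(ref_seqs.size());
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    refs[i] = as<std::string>(ref_seqs[i]);
  R_xlen_t n = mate1.size();
  LogicalVector proper(n);
  IntegerVector best_target(n, NA_INTEGER), summed_edit(n, NA_INTEGER);
  IntegerVector start1(n, NA_INTEGER), start2(n, NA_INTEGER);
  IntegerVector edit1(n, NA_INTEGER), edit2(n, NA_INTEGER);
  CharacterVector strand1(n, NA_STRING);
  CharacterVector tied(n, NA_STRING);
  LogicalVector ambiguous(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(mate1[i]);
    std::string r2 = as<std::string>(mate2[i]);
    std::vector<Hit> h1, h2;
    align_one(r1, kmap, post_target, post_offset, refs, k, max_edit, false, h1,
              scratch);
    align_one(r2, kmap, post_target, post_offset, refs, k, max_edit, false, h2,
              scratch);
    int L1 = (int)r1.size(), L2 = (int)r2.size();
    int bestsum = INT_MAX; int btgt = -1, bs1 = -1, bs2 = -1, be1 = -1, be2 = -1;
    char bstr = 0;
    std::unordered_set<int> tiedset;
    for (auto &a : h1) for (auto &b : h2) {
      if (a.target != b.target || a.strand == b.strand) continue;
      int lo = std::min(a.start, b.start);
      int hi = std::max(a.start + L1, b.start + L2);
      int ins = hi - lo;
      if (ins < insert_min || ins > insert_max) continue;
      int sum = a.edit + b.edit;
      if (sum < bestsum) {
        bestsum = sum; tiedset.clear(); tiedset.insert(a.target);
        btgt = a.target; bs1 = a.start; bs2 = b.start;
        be1 = a.edit; be2 = b.edit; bstr = a.strand;
      } else if (sum == bestsum) {
        tiedset.insert(a.target);
        // deterministic tie-break within equal target: smaller (name, start)
        if (a.target == btgt) {
          if (std::min(a.start, b.start) < std::min(bs1, bs2)) {
            bs1 = a.start; bs2 = b.start; be1 = a.edit; be2 = b.edit;
            bstr = a.strand;
          }
        } else {
          std::string cur = as<std::string>(ref_names[btgt]);
          std::string alt = as<std::string>(ref_names[a.target]);
          if (alt < cur) {
            btgt = a.target; bs1 = a.start; bs2 = b.start;
            be1 = a.edit; be2 = b.edit; bstr = a.strand;
          }
        }
      }
    }
    if (bestsum < INT_MAX) {
      proper[i] = true;
      best_target[i] = btgt + 1;
      summed_edit[i] = bestsum;
      start1[i] = bs1; start2[i] = bs2; edit1[i] = be1; edit2[i] = be2;
      strand1[i] = std::string(1, bstr);
      std::vector<int> tv(tiedset.begin(), tiedset.end());
      std::vector<std::string> tn;
      for (int t : tv) tn.push_back(as<std::string>(ref_names[t]));
      std::sort(tn.begin(), tn.end());
      std::string joined;
      for (size_t j = 0; j < tn.size(); ++j) {
        if (j) joined += ",";
        joined += tn[j];
      }
      tied[i] = joined;
      ambiguous[i] = tiedset.size() > 1;
    } else {
      proper[i] = false;
      ambiguous[i] = false;
    }
  }
  return List::create(_["proper"] = proper, _["target"] = best_target,
                      _["summed_edit"] = summed_edit,
                      _["start1"] = start1, _["start2"] = start2,
                      _["edit1"] = edit1, _["edit2"] = edit2,
                      _["strand1"] = strand1,
                      _["tied_targets"] = tied, _["ambiguous"] = ambiguous);
}

// ---------------------------------------------------------------------------
// rRNA filter: end-to-end Hamming scan, either strand, any offset
// ---------------------------------------------------------------------------

static bool hamming_at(const std::string &read, const std::string &ref,
                       int s, int max_mm) {
  const int L = (int)read.size();
  if (s < 0 || s + L > (int)ref.size()) return false;
  int mm = 0;
  for (int i = 0; i < L; ++i)
    if (read[i] != ref[s + i] && ++mm > max_mm) return false;
  return true;
}

static bool hamming_brute(const std::string &read,
                          const std::vector<std::string> &refs, int max_mm) {
  for (size_t r = 0; r < refs.size(); ++r) {
    const int R = (int)refs[r].size(), L = (int)read.size();
    for (int s = 0; s + L <= R; ++s)
      if (hamming_at(read, refs[r], s, max_mm)) return true;
  }
  return false;
}

static const int RRNA_SEED = 10;
typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > SeedIndex;

// Seeded scan: with <= max_mm mismatches over a read split into max_mm + 1
// disjoint chunks, one chunk is mismatch-free (pigeonhole), so its leading
// seed q-mer occurs exactly in the reference at the implied offset. Reads
// too short for full-length chunks of the seed size fall back to the brute
// scan, which is the same contract.
static bool hamming_seeded(const std::string &read,
                           const std::vector<std::string> &refs,
                           const SeedIndex &sidx, int max_mm) {
  const int L = (int)read.size();
  const int c = max_mm + 1;
  const int chunk = L / c;
  if (chunk < RRNA_SEED) return hamming_brute(read, refs, max_mm);
  for (int i = 0; i < c; ++i) {
    int cs = i * chunk;
    uint64_t kv;
    if (!pack_kmer(read.c_str() + cs, RRNA_SEED, kv)) continue;
    SeedIndex::const_iterator it = sidx.find(kv);
    if (it == sidx.end()) continue;
    for (size_t p = 0; p < it->second.size(); ++p) {
      int r = it->second[p].first;
      int s = it->second[p].second - cs;
      if (hamming_at(read, refs[r], s, max_mm)) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_hamming_hits(CharacterVector reads, CharacterVector rrna,
                               int max_mm) {
  std::vector<std::string> refs(rrna.size());
  SeedIndex sidx;
  for (R_xlen_t i = 0; i < rrna.size(); ++i) {
    refs[i] = as<std::string>(rrna[i]);
    const std::string &s = refs[i];
    for (int p = 0; p + RRNA_SEED <= (int)s.size(); ++p) {
      uint64_t kv;
      if (pack_kmer(s.c_str() + p, RRNA_SEED, kv))
        sidx[kv].push_back(std::make_pair((int)i, p));
    }
  }
  LogicalVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    out[i] = hamming_seeded(rd, refs, sidx, max_mm) ||
             hamming_seeded(revcomp(rd), refs, sidx, max_mm);
  }
  return out;
}

// ---------------------------------------------------------------------------
// adapter + sliding-window quality trimming (Phred+33 quality strings)
// returns the retained length of each read (from its 5' end)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector seqs, CharacterVector quals,
                               std::string adapter, double mismatch_frac,
                               int min_overlap, int q_threshold, int window) {
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  const int A = (int)adapter.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int L = (int)s.size();
    // 1) adapter: leftmost position where the read suffix matches an adapter
    //    prefix within the mismatch fraction (overlap >= min_overlap)
    int cut = L;
    if (A > 0) {
      for (int p = 0; p <= L - min_overlap; ++p) {
        int ov = std::min(L - p, A);
        int allowed = (int)(mismatch_frac * ov);
        int mm = 0; bool ok = true;
        for (int j = 0; j < ov; ++j) {
          if (s[p + j] != adapter[j] && ++mm > allowed) { ok = false; break; }
        }
        if (ok) { cut = p; break; }
      }
    }
    L = cut;
    // 2) sliding-window quality clip: first window with mean < threshold
    if (window > 0 && L >= window) {
      for (int p = 0; p + window <= L; ++p) {
        int sum = 0;
        for (int j = 0; j < window; ++j) sum += (int)q[p + j] - 33;
        if ((double)sum / window < q_threshold) { L = p; break; }
      }
    }
    out[i] = L;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps (protein scoring)
// ---------------------------------------------------------------------------

static std::vector<int> encode_protein(const std::string &s,
                                       const int *lut, bool &ok) {
  std::vector<int> v(s.size());
  ok = true;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    if (c < 0) { ok = false; return v; }
    v[i] = c;
  }
  return v;
}

static void make_lut(const CharacterVector &alphabet, int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (R_xlen_t i = 0; i < alphabet.size(); ++i) {
    std::string a = as<std::string>(alphabet[i]);
    lut[(unsigned char)a[0]] = (int)i;
  }
}

// single-pair SW with traceback: returns score, alignment length, identities
// [[Rcpp::export]]
List cpp_sw_pair(std::string a, std::string b, IntegerMatrix subst,
                 CharacterVector alphabet, int gap_open, int gap_extend) {
  int lut[256]; make_lut(alphabet, lut);
  bool oka, okb;
  std::vector<int> ea = encode_protein(a, lut, oka);
  std::vector<int> eb = encode_protein(b, lut, okb);
  if (!oka || !okb) stop("sequence contains a character absent from the substitution matrix alphabet");
  int m = (int)ea.size(), n = (int)eb.size();
  const int NEG = -(1 << 28);
  std::vector<int> H((m+1)*(n+1), 0), E((m+1)*(n+1), NEG), F((m+1)*(n+1), NEG);
  auto idx = [&](int i, int j) { return (size_t)i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[idx(i,j)] = std::max(E[idx(i,j-1)] - gap_extend,
                             H[idx(i,j-1)] - gap_open - gap_extend);
      F[idx(i,j)] = std::max(F[idx(i-1,j)] - gap_extend,
                             H[idx(i-1,j)] - gap_open - gap_extend);
      int diag = H[idx(i-1,j-1)] + subst(ea[i-1], eb[j-1]);
      int h = std::max(0, std::max(diag, std::max(E[idx(i,j)], F[idx(i,j)])));
      H[idx(i,j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback for identity
  int i = bi, j = bj, ident = 0, alen = 0;
  while (i > 0 && j > 0 && H[idx(i,j)] > 0) {
    int h = H[idx(i,j)];
    if (h == H[idx(i-1,j-1)] + subst(ea[i-1], eb[j-1])) {
      if (ea[i-1] == eb[j-1]) ++ident;
      ++alen; --i; --j;
    } else if (h == E[idx(i,j)]) {
      while (j > 0 && E[idx(i,j)] != H[idx(i,j-1)] - gap_open - gap_extend &&
             E[idx(i,j)] == E[idx(i,j-1)] - gap_extend) { --j; ++alen; }
      --j; ++alen;
    } else if (h == F[idx(i,j)]) {
      while (i > 0 && F[idx(i,j)] != H[idx(i-1,j)] - gap_open - gap_extend &&
             F[idx(i,j)] == F[idx(i-1,j)] - gap_extend) { --i; ++alen; }
      --i; ++alen;
    } else break;
  }
  return List::create(_["score"] = best, _["align_length"] = alen,
                      _["identities"] = ident);
}

// all-vs-all SW raw scores (no traceback), queries x subjects
// [[Rcpp::export]]
IntegerMatrix cpp_sw_matrix(CharacterVector queries, CharacterVector subjects,
                            IntegerMatrix subst, CharacterVector alphabet,
                            int gap_open, int gap_extend) {
  int lut[256]; make_lut(alphabet, lut);
  int nq = (int)queries.size(), ns = (int)subjects.size();
  std::vector<std::vector<int> > eq(nq), es(ns);
  bool ok;
  for (int i = 0; i < nq; ++i) {
    eq[i] = encode_protein(as<std::string>(queries[i]), lut, ok);
    if (!ok) stop("query %d contains a character absent from the matrix alphabet", i + 1);
  }
  for (int j = 0; j < ns; ++j) {
    es[j] = encode_protein(as<std::string>(subjects[j]), lut, ok);
    if (!ok) stop("subject %d contains a character absent from the matrix alphabet", j + 1);
  }
  IntegerMatrix out(nq, ns);
  const int NEG = -(1 << 28);
  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int> &a = eq[qi];
    int m = (int)a.size();
    for (int sj = 0; sj < ns; ++sj) {
      const std::vector<int> &b = es[sj];
      int n = (int)b.size();
      // rolling rows
      std::vector<int> Hp(n + 1, 0), H(n + 1, 0), Ep(n + 1, NEG), E(n + 1, NEG);
      std::vector<int> Fp(n + 1, NEG), F(n + 1, NEG);
      int best = 0;
      for (int i = 1; i <= m; ++i) {
        H[0] = 0; E[0] = NEG; F[0] = NEG;
        for (int j = 1; j <= n; ++j) {
          E[j] = std::max(E[j-1] - gap_extend, H[j-1] - gap_open - gap_extend);
          F[j] = std::max(Fp[j] - gap_extend, Hp[j] - gap_open - gap_extend);
          int diag = Hp[j-1] + subst(a[i-1], b[j-1]);
          int h = std::max(0, std::max(diag, std::max(E[j], F[j])));
          H[j] = h;
          if (h > best) best = h;
        }
        std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
      }
      out(qi, sj) = best;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
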