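// Low-level sequence kernels: MinHash sketching, suffix-array MUM finding,
// k-mer repeat masking, banded affine alignment, seed-and-extend read
// mapping, and pileup accumulation. All coordinates are 0-based half-open;
// R wrappers convert to 1-based reporting.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// splitmix64: fixed, seedless 64-bit mixer; reproducible across platforms
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ------------------------------------------------------------------ MinHash

// Bottom-s sketch of canonical k-mers. Hash values are the top 53 bits of
// splitmix64 of the 2-bit-packed canonical k-mer, exactly representable as
// doubles. k <= 31.
// [[Rcpp::export(name = ".cpp_minhash")]]
NumericVector cpp_minhash(CharacterVector seqs, int k, int s) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::unordered_set<uint64_t> seen;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string seq = as<std::string>(seqs[si]);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bit(seq[i]);
      if (b < 0) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rev);
        seen.insert(splitmix64(canon) >> 11);
      }
    }
  }
  std::vector<uint64_t> all(seen.begin(), seen.end());
  std::sort(all.begin(), all.end());
  size_t keep = std::min((size_t)s, all.size());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)all[i];
  return out;
}

// ----------------------------------------------------- suffix array + MUMs

// Suffix array by prefix doubling (O(n log^2 n)); adequate at genome sizes
// this tool targets.
static void build_sa(const std::string& s, std::vector<int>& sa,
                     std::vector<int>& rank_out) {
  int n = (int)s.size();
  sa.resize(n);
  std::vector<int> r(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; r[i] = (unsigned char)s[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + len < n ? r[a + len] : -1;
      int rb = b + len < n ? r[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    r = tmp;
    if (r[sa[n - 1]] == n - 1) break;
  }
  rank_out = r;
}

// Kasai LCP: lcp[i] = lcp(sa[i-1], sa[i])
static void build_lcp(const std::string& s, const std::vector<int>& sa,
                      const std::vector<int>& rank, std::vector<int>& lcp) {
  int n = (int)s.size();
  lcp.assign(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
}

// Maximal unique matches between ref and qry (forward strand): exact
// matches of length >= minlen occurring exactly once in each sequence and
// extendable in neither direction. Classical adjacent-suffix scan on the
// SA+LCP of "ref#qry". N never matches: ref N -> 'X', qry N -> 'Y'.
// [[Rcpp::export(name = ".cpp_find_mums")]]
DataFrame cpp_find_mums(std::string ref, std::string qry, int minlen) {
  int n1 = (int)ref.size();
  for (auto& c : ref) if (base2bit(c) < 0) c = 'X';
  for (auto& c : qry) if (base2bit(c) < 0) c = 'Y';
  std::string s = ref + "#" + qry;
  int n = (int)s.size();
  std::vector<int> sa, rank, lcp;
  build_sa(s, sa, rank);
  build_lcp(s, sa, rank, lcp);
  std::vector<int> rs, qs, ln;
  for (int i = 1; i < n; ++i) {
    int a = sa[i - 1], b = sa[i];
    bool a_ref = a < n1, b_ref = b < n1;
    if (a_ref == b_ref) continue;
    int L = lcp[i];
    if (L < minlen) continue;
    // uniqueness: no outer neighbor shares a prefix of length >= L
    if (i >= 2 && lcp[i - 1] >= L) continue;
    if (i + 1 < n && lcp[i + 1] >= L) continue;
    int rpos = a_ref ? a : b;
    int qpos = a_ref ? b - n1 - 1 : a - n1 - 1;
    // left-maximality
    if (rpos > 0 && qpos > 0 && ref[rpos - 1] == qry[qpos - 1]) continue;
    rs.push_back(rpos); qs.push_back(qpos); ln.push_back(L);
  }
  // sort by ref_start
  std::vector<int> ord(rs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return rs[a] < rs[b]; });
  IntegerVector R(ord.size()), Q(ord.size()), L(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    R[i] = rs[ord[i]]; Q[i] = qs[ord[i]]; L[i] = ln[ord[i]];
  }
  return DataFrame::create(_["ref_start"] = R, _["qry_start"] = Q, _["length"] = L);
}

// ------------------------------------------------------------ repeat mask

// A position is repeat-masked iff it lies in a window of length minlen
// whose canonical minlen-mer occurs >= 2 times over all contigs (forward
// occurrences of the k-mer or its reverse complement). Any off-diagonal
// exact self-match of length >= minlen is a union of such windows.
// [[Rcpp::export(name = ".cpp_repeat_mask")]]
List cpp_repeat_mask(CharacterVector contigs, int minlen) {
  std::unordered_map<std::string, int> counts;
  std::vector<std::string> seqs(contigs.size());
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    seqs[ci] = as<std::string>(contigs[ci]);
    const std::string& seq = seqs[ci];
    if ((int)seq.size() < minlen) continue;
    for (size_t i = 0; i + minlen <= seq.size(); ++i) {
      std::string w = seq.substr(i, minlen);
      bool ok = true;
      for (char c : w) if (base2bit(c) < 0) { ok = false; break; }
      if (!ok) continue;
      std::string rc = revcomp(w);
      counts[w < rc ? w : rc] += 1;
    }
  }
  List out(contigs.size());
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const std::string& seq = seqs[ci];
    LogicalVector m(seq.size(), false);
    if ((int)seq.size() >= minlen) {
      for (size_t i = 0; i + minlen <= seq.size(); ++i) {
        std::string w = seq.substr(i, minlen);
        bool ok = true;
        for (char c : w) if (base2bit(c) < 0) { ok = false; break; }
        if (!ok) continue;
        std::string rc = revcomp(w);
        if (counts[w < rc ? w : rc] >= 2)
          for (int j = 0; j < minlen; ++j) m[i + j] = true;
      }
    }
    out[ci] = m;
  }
  return out;
}

// ------------------------------------------- banded affine global aligner

static const int NEG = -1000000000;

// Global alignment of a (ref) vs b (qry) with affine gaps inside a band
// around the corner-to-corner diagonal. Opening a gap costs open + extend.
// Returns per-column op string over {=, X, D, I}: D consumes ref only
// (deletion in qry), I consumes qry only.
// [[Rcpp::export(name = ".cpp_banded_global")]]
List cpp_banded_global(std::string a, std::string b, int band_pad,
                       int match, int mismatch, int gap_open, int gap_extend) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) {
    std::string ops(n, 'D'); ops.append(m, 'I');
    int sc = (n + m > 0) ? gap_open + gap_extend * (n + m) : 0;
    return List::create(_["score"] = sc, _["ops"] = ops);
  }
  int lo = std::min(0, m - n) - band_pad;       // band on d = j - i
  int hi = std::max(0, m - n) + band_pad;
  int w = hi - lo + 1;
  // DP layers: M (aligned pair), X (gap in b, consumes a), Y (gap in a)
  std::vector<int> M((size_t)(n + 1) * w, NEG), X = M, Y = M;
  std::vector<uint8_t> tbM((size_t)(n + 1) * w, 0), tbX = tbM, tbY = tbM;
  auto idx = [&](int i, int j) { return (size_t)i * w + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };
  M[idx(0, 0)] = 0;
  for (int j = 1; j <= m && inband(0, j); ++j) {
    Y[idx(0, j)] = gap_open + gap_extend * j;
    tbY[idx(0, j)] = (j == 1) ? 0 : 2;          // 0: from M, 2: extend Y
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = idx(i, j);
      if (j == 0) {
        X[c] = gap_open + gap_extend * i;
        tbX[c] = (i == 1) ? 0 : 1;              // 1: extend X
        continue;
      }
      // M from diagonal
      if (inband(i - 1, j - 1)) {
        size_t d = idx(i - 1, j - 1);
        int best = M[d]; uint8_t t = 0;
        if (X[d] > best) { best = X[d]; t = 1; }
        if (Y[d] > best) { best = Y[d]; t = 2; }
        if (best > NEG / 2) {
          bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N' && b[j - 1] != 'N';
          M[c] = best + (eq ? match : mismatch);
          tbM[c] = t;
        }
      }
      // X from above (consume a)
      if (inband(i - 1, j)) {
        size_t u = idx(i - 1, j);
        int op = (M[u] > NEG / 2) ? M[u] + gap_open + gap_extend : NEG;
        int ex = (X[u] > NEG / 2) ? X[u] + gap_extend : NEG;
        if (op >= ex) { X[c] = op; tbX[c] = 0; } else { X[c] = ex; tbX[c] = 1; }
      }
      // Y from left (consume b)
      if (inband(i, j - 1)) {
        size_t l = idx(i, j - 1);
        int op = (M[l] > NEG / 2) ? M[l] + gap_open + gap_extend : NEG;
        int ex = (Y[l] > NEG / 2) ? Y[l] + gap_extend : NEG;
        if (op >= ex) { Y[c] = op; tbY[c] = 0; } else { Y[c] = ex; tbY[c] = 2; }
      }
    }
  }
  size_t e = idx(n, m);
  int best = M[e]; int layer = 0;
  if (X[e] > best) { best = X[e]; layer = 1; }
  if (Y[e] > best) { best = Y[e]; layer = 2; }
  if (best <= NEG / 2) stop("band too narrow for global alignment");
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = idx(i, j);
    if (layer == 0) {
      bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N' && b[j - 1] != 'N';
      ops.push_back(eq ? '=' : 'X');
      layer = tbM[c]; --i; --j;
    } else if (layer == 1) {
      ops.push_back('D'); layer = tbX[c]; --i;
    } else {
      ops.push_back('I'); layer = tbY[c]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = ops);
}

// ---------------------------------------------------------- read mapping

struct SemiHit { int score; int ref_start; std::string ops; bool ok; };

// Semi-global: read fully aligned, free leading/trailing ref overhang.
// Band around read-vs-window diagonal.
static SemiHit semiglobal(const std::string& win, const std::string& read,
                          int band_pad, int match, int mismatch,
                          int gap_open, int gap_extend) {
  int n = (int)win.size(), m = (int)read.size();
  SemiHit out; out.ok = false;
  if (m == 0 || n == 0) return out;
  // path stays near diagonal j ~= i - pad_offset; we band on j - i in
  // [-(n - m) - band_pad, band_pad] which covers all ref start offsets
  int lo = -(n - m) - band_pad, hi = band_pad;
  if (n < m) { lo = -band_pad; hi = (m - n) + band_pad; }
  int w = hi - lo + 1;
  if (w < 1) return out;
  std::vector<int> M((size_t)(n + 1) * w, NEG), X = M, Y = M;
  std::vector<uint8_t> tbM((size_t)(n + 1) * w, 0), tbX = tbM, tbY = tbM;
  auto idx = [&](int i, int j) { return (size_t)i * w + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };
  for (int i = 0; i <= n; ++i)
    if (inband(i, 0)) M[idx(i, 0)] = 0;        // free ref prefix
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + lo), jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = idx(i, j);
      if (inband(i - 1, j - 1)) {
        size_t d = idx(i - 1, j - 1);
        int best = M[d]; uint8_t t = 0;
        if (X[d] > best) { best = X[d]; t = 1; }
        if (Y[d] > best) { best = Y[d]; t = 2; }
        if (best > NEG / 2) {
          bool eq = (win[i - 1] == read[j - 1]) && win[i - 1] != 'N' && read[j - 1] != 'N';
          M[c] = best + (eq ? match : mismatch);
          tbM[c] = t;
        }
      }
      if (inband(i - 1, j)) {
        size_t u = idx(i - 1, j);
        int op = (M[u] > NEG / 2) ? M[u] + gap_open + gap_extend : NEG;
        int ex = (X[u] > NEG / 2) ? X[u] + gap_extend : NEG;
        if (op >= ex) { X[c] = op; tbX[c] = 0; } else { X[c] = ex; tbX[c] = 1; }
      }
      if (inband(i, j - 1)) {
        size_t l = idx(i, j - 1);
        int op = (M[l] > NEG / 2) ? M[l] + gap_open + gap_extend : NEG;
        int ex = (Y[l] > NEG / 2) ? Y[l] + gap_extend : NEG;
        if (op >= ex) { Y[c] = op; tbY[c] = 0; } else { Y[c] = ex; tbY[c] = 2; }
      }
    }
  }
  // free ref suffix: best cell at j == m over all i
  int besti = -1, best = NEG, layer = 0;
  for (int i = 0; i <= n; ++i) {
    if (!inband(i, m)) continue;
    size_t c = idx(i, m);
    if (M[c] > best) { best = M[c]; besti = i; layer = 0; }
    if (X[c] > best) { best = X[c]; besti = i; layer = 1; }
    if (Y[c] > best) { best = Y[c]; besti = i; layer = 2; }
  }
  if (besti < 0 || best <= NEG / 2) return out;
  std::string ops;
  int i = besti, j = m;
  while (j > 0 || (layer == 1 && i > 0)) {
    size_t c = idx(i, j);
    if (layer == 0) {
      if (M[c] == 0 && j == 0) break;
      bool eq = (win[i - 1] == read[j - 1]) && win[i - 1] != 'N' && read[j - 1] != 'N';
      ops.push_back(eq ? '=' : 'X');
      layer = tbM[c]; --i; --j;
    } else if (layer == 1) {
      ops.push_back('D'); layer = tbX[c]; --i;
    } else {
      ops.push_back('I'); layer = tbY[c]; --j;
    }
    if (j == 0 && layer == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  out.score = best; out.ref_start = i; out.ops = ops; out.ok = true;
  return out;
}

// Map reads against a reference string by unique-best seed-and-extend.
// Returns one row per read: ref_start (0-based; -1 unmapped), strand
// (+1/-1), score, identity, ops. Ties across distinct loci, or identity
// below min_identity, leave the read unmapped.
// [[Rcpp::export(name = ".cpp_map_reads")]]
List cpp_map_reads(CharacterVector reads, std::string ref, int seed_k,
                   int max_seed_hits, double min_identity, int band_pad,
                   int match, int mismatch, int gap_open, int gap_extend) {
  int n = (int)ref.size();
  // seed index: packed k-mer -> positions (seed_k <= 15 => 30 bits)
  if (seed_k < 8 || seed_k > 15) stop("seed_k must be in [8, 15]");
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    uint64_t fwd = 0; int valid = 0;
    const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(ref[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_k) index[fwd].push_back(i - seed_k + 1);
    }
  }
  R_xlen_t nr = reads.size();
  IntegerVector ref_start(nr, -1), strand(nr, 0), score(nr, NA_INTEGER);
  NumericVector identity(nr, NA_REAL);
  CharacterVector ops(nr, NA_STRING);
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
  for (R_xlen_t r = 0; r < nr; ++r) {
    std::string fwd_read = as<std::string>(reads[r]);
    int m = (int)fwd_read.size();
    if (m < seed_k) continue;
    struct Cand { int diag; int votes; int strand; };
    std::vector<Cand> cands;
    for (int st = 0; st < 2; ++st) {
      std::string rd = st == 0 ? fwd_read : revcomp(fwd_read);
      std::unordered_map<int, int> votes;
      uint64_t h = 0; int valid = 0;
      for (int i = 0; i < m; ++i) {
        int b = base2bit(rd[i]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid >= seed_k) {
          auto it = index.find(h);
          if (it == index.end()) continue;
          if ((int)it->second.size() > max_seed_hits) continue;
          int qpos = i - seed_k + 1;
          for (int rp : it->second) votes[rp - qpos] += 1;
        }
      }
      if (votes.empty()) continue;
      // merge diagonals within band_pad into clusters
      std::vector<std::pair<int, int>> dv(votes.begin(), votes.end());
      std::sort(dv.begin(), dv.end());
      int cd = dv[0].first, cv = dv[0].second, cbest = dv[0].first, cbv = dv[0].second;
      for (size_t i = 1; i <= dv.size(); ++i) {
        if (i < dv.size() && dv[i].first - dv[i - 1].first <= band_pad) {
          cv += dv[i].second;
          if (dv[i].second > cbv) { cbv = dv[i].second; cbest = dv[i].first; }
        } else {
          cands.push_back({cbest, cv, st == 0 ? 1 : -1});
          if (i < dv.size()) {
            cd = cbest = dv[i].first; cv = cbv = dv[i].second;
          }
        }
      }
      (void)cd;
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.votes > b.votes; });
    size_t ncand = std::min(cands.size(), (size_t)8);
    int best = NEG, second = NEG, best_start = -1, best_strand = 0;
    std::string best_ops;
    for (size_t c = 0; c < ncand; ++c) {
      int d = cands[c].diag;
      int w0 = std::max(0, d - band_pad);
      int w1 = std::min(n, d + m + band_pad);
      if (w1 - w0 < seed_k) continue;
      std::string win = ref.substr(w0, w1 - w0);
      std::string rd = cands[c].strand == 1 ? fwd_read : revcomp(fwd_read);
      SemiHit h = semiglobal(win, rd, band_pad, match, mismatch, gap_open, gap_extend);
      if (!h.ok) continue;
      int start = w0 + h.ref_start;
      if (h.score > best) {
        // same-locus re-hit (overlapping cluster) does not demote to tie
        if (best_start >= 0 &&
            (best_strand != cands[c].strand || std::abs(start - best_start) > m / 2))
          second = best;
        best = h.score; best_start = start; best_strand = cands[c].strand;
        best_ops = h.ops;
      } else if (h.score > second &&
                 (best_strand != cands[c].strand || std::abs(start - best_start) > m / 2)) {
        second = h.score;
      }
    }
    if (best_start < 0 || best == second) continue;   // unmapped: tie or no hit
    int nmatch = 0, ncol = 0;
    for (char o : best_ops) { if (o == '=') ++nmatch; ++ncol; }
    double ident = ncol > 0 ? (double)nmatch / ncol : 0.0;
    if (ident < min_identity) continue;
    ref_start[r] = best_start; strand[r] = best_strand;
    score[r] = best; identity[r] = ident; ops[r] = best_ops;
  }
  return List::create(_["ref_start"] = ref_start, _["strand"] = strand,
                      _["score"] = score, _["identity"] = identity,
                      _["ops"] = ops);
}

// -------------------------------------------------------------- pileup

// Accumulate per-position base counts from read alignments. Reads are
// passed already strand-resolved (sequence as aligned to the forward
// reference). '=' and 'X' contribute the read base; 'D' consumes reference
// without contributing; 'I' consumes read only.
// [[Rcpp::export(name = ".cpp_pileup")]]
IntegerMatrix cpp_pileup(int ref_len, IntegerVector ref_start,
                         CharacterVector seqs, CharacterVector ops) {
  IntegerMatrix counts(4, ref_len);
  for (R_xlen_t a = 0; a < ref_start.size(); ++a) {
    if (ref_start[a] == NA_INTEGER || ref_start[a] < 0) continue;
    std::string sq = as<std::string>(seqs[a]);
    std::string op = as<std::string>(ops[a]);
    int i = ref_start[a], j = 0;
    for (char o : op) {
      if (o == '=' || o == 'X') {
        if (i >= ref_len) stop("alignment extends past reference end");
        int b = base2bit(sq[j]);
        if (b >= 0) counts(b, i) += 1;
        ++i; ++j;
      } else if (o == 'D') {
        ++i;
      } else if (o == 'I') {
        ++j;
      }
    }
  }
  return counts;
}

// Seed index summary for show()/diagnostics: number of indexed seed
// positions and how many distinct seeds exceed max_hits (repetitive).
// [[Rcpp::export(name = ".cpp_seed_stats")]]
List cpp_seed_stats(std::string ref, int seed_k, int max_hits) {
  std::unordered_map<uint64_t, int> counts;
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
  uint64_t fwd = 0; int valid = 0; long n_pos = 0;
  for (size_t i = 0; i < ref.size(); ++i) {
    int b = base2bit(ref[i]);
    if (b < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++valid >= seed_k) { counts[fwd] += 1; ++n_pos; }
  }
  long n_rep = 0;
  for (auto& kv : counts) if (kv.second > max_hits) ++n_rep;
  return List::create(_["n_positions"] = (double)n_pos,
                      _["n_distinct"] = (double)counts.size(),
                      _["n_repetitive"] = (double)n_rep);
}

// Paint alignment blocks onto a per-reference-position call track.
// Blocks are applied in the given order; positions already claimed by an
// earlier (higher-priority) block are never overwritten. States written:
// the query base for =/X columns ('N' if either side is not ACGT), '-'
// for D columns (deletion in query). 'I' consumes query only. Unclaimed
// positions end as '\0' and are returned as '-' (unaligned), with a
// separate logical marking claimed-aligned positions.
// [[Rcpp::export(name = ".cpp_paint_track")]]
List cpp_paint_track(std::string ref, IntegerVector block_start,
                     CharacterVector block_qry, CharacterVector block_ops) {
  int n = (int)ref.size();
  std::string track(n, '\0');
  for (R_xlen_t b = 0; b < block_start.size(); ++b) {
    std::string q = as<std::string>(block_qry[b]);
    std::string op = as<std::string>(block_ops[b]);
    int i = block_start[b], j = 0;
    for (char o : op) {
      if (o == '=' || o == 'X') {
        if (i >= 0 && i < n && track[i] == '\0') {
          char qc = q[j];
          bool ok = base2bit(qc) >= 0 && base2bit(ref[i]) >= 0;
          track[i] = ok ? qc : 'N';
        }
        ++i; ++j;
      } else if (o == 'D') {
        if (i >= 0 && i < n && track[i] == '\0') track[i] = '-';
        ++i;
      } else if (o == 'I') {
        ++j;
      }
    }
  }
  LogicalVector aligned(n);
  long n_aligned = 0;
  for (int i = 0; i < n; ++i) {
    if (track[i] == '\0') { track[i] = '-'; aligned[i] = false; }
    else if (track[i] == '-') aligned[i] = false;
    else { aligned[i] = true; ++n_aligned; }
  }
  return List::create(_["track"] = track, _["aligned"] = aligned,
                      _["n_aligned"] = (double)n_aligned);
}

// ----------------------------------------------------- hamming differences

// Pairwise differing-column counts over a base matrix (rows = samples),
// optionally restricted to a column subset. Used for SNP matrices and
// p-distances; columns are assumed unambiguous bases.
// [[Rcpp::export(name = ".cpp_pair_diffs")]]
IntegerMatrix cpp_pair_diffs(CharacterVector rows, IntegerVector cols) {
  int ns = (int)rows.size();
  std::vector<std::string> s(ns);
  for (int i = 0; i < ns; ++i) s[i] = as<std::string>(rows[i]);
  IntegerMatrix out(ns, ns);
  for (int i = 0; i < ns; ++i)
    for (int j = i + 1; j < ns; ++j) {
      int d = 0;
      if (cols.size() == 0) {
        for (size_t c = 0; c < s[i].size(); ++c) if (s[i][c] != s[j][c]) ++d;
      } else {
        for (R_xlen_t k = 0; k < cols.size(); ++k) {
          int c = cols[k] - 1;
          if (s[i][c] != s[j][c]) ++d;
        }
      }
      out(i, j) = d; out(j, i) = d;
    }
  return out;
}
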