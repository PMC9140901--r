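// Low-level alignment primitives shared by the repeat scanners, the
// homology search and the read classifier.  All coordinates crossing the
// R boundary are 1-based inclusive.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// Exact k-mer matches of `ref` inside `query`.
// Returns a two-column matrix (query position, ref position), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(const std::string& query, const std::string& ref,
                            int k) {
  int nq = query.size(), nr = ref.size();
  if (k < 1 || k > 31 || nr < k || nq < k) return IntegerMatrix(0, 2);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  uint64_t mask = (1ULL << (2 * k)) - 1, key = 0;
  int run = 0;
  for (int i = 0; i < nr; ++i) {
    int c = b2i(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  std::vector<int> qpos, rpos;
  key = 0; run = 0;
  for (int i = 0; i < nq; ++i) {
    int c = b2i(query[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::unordered_map<uint64_t, std::vector<int>>::iterator it = idx.find(key);
      if (it != idx.end())
        for (size_t h = 0; h < it->second.size(); ++h) {
          qpos.push_back(i - k + 2);
          rpos.push_back(it->second[h] + 1);
        }
    }
  }
  IntegerMatrix out(qpos.size(), 2);
  for (size_t i = 0; i < qpos.size(); ++i) {
    out(i, 0) = qpos[i];
    out(i, 1) = rpos[i];
  }
  return out;
}

// Apply point edits to a sequence: substitutions at sub_pos (1-based,
// replacement characters in sub_base), deletions at del_pos, and
// single-base insertions after ins_pos (characters in ins_base).
// Randomness lives in the R caller so the R seed governs everything.
// [[Rcpp::export]]
std::string cpp_apply_edits(std::string s, IntegerVector sub_pos,
                            CharacterVector sub_base, IntegerVector del_pos,
                            IntegerVector ins_pos, CharacterVector ins_base) {
  int n = s.size();
  for (int i = 0; i < sub_pos.size(); ++i) {
    int p = sub_pos[i] - 1;
    if (p >= 0 && p < n) s[p] = CHAR(STRING_ELT(sub_base, i))[0];
  }
  if (del_pos.size() == 0 && ins_pos.size() == 0) return s;
  std::vector<char> del(n, 0);
  std::vector<char> ins(n, 0);
  for (int i = 0; i < del_pos.size(); ++i) {
    int p = del_pos[i] - 1;
    if (p >= 0 && p < n) del[p] = 1;
  }
  for (int i = 0; i < ins_pos.size(); ++i) {
    int p = ins_pos[i] - 1;
    if (p >= 0 && p < n) ins[p] = CHAR(STRING_ELT(ins_base, i))[0];
  }
  std::string out;
  out.reserve(n + ins_pos.size());
  for (int i = 0; i < n; ++i) {
    if (!del[i]) out.push_back(s[i]);
    if (ins[i]) out.push_back(ins[i]);
  }
  return out;
}

// Batch form of cpp_seed_hits: one reference index shared by all queries,
// query positions sampled every `stride` bases.  Returns a list of
// two-column matrices (query position, ref position), 1-based.
// [[Rcpp::export]]
List cpp_seed_hits_batch(CharacterVector queries, const std::string& ref,
                         int k, int stride) {
  int nr = ref.size(), nq = queries.size();
  List out(nq);
  if (k < 1 || k > 31 || nr < k) {
    for (int q = 0; q < nq; ++q) out[q] = IntegerMatrix(0, 2);
    return out;
  }
  if (stride < 1) stride = 1;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  uint64_t mask = (1ULL << (2 * k)) - 1, key = 0;
  int run = 0;
  for (int i = 0; i < nr; ++i) {
    int c = b2i(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  for (int q = 0; q < nq; ++q) {
    std::string query = as<std::string>(queries[q]);
    int n = query.size();
    std::vector<int> qpos, rpos;
    key = 0; run = 0;
    for (int i = 0; i < n; ++i) {
      int c = b2i(query[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (run++ >= k - 1 && (i % stride == 0)) {
        std::unordered_map<uint64_t, std::vector<int>>::iterator it =
            idx.find(key);
        if (it != idx.end())
          for (size_t h = 0; h < it->second.size(); ++h) {
            qpos.push_back(i - k + 2);
            rpos.push_back(it->second[h] + 1);
          }
      }
    }
    IntegerMatrix m(qpos.size(), 2);
    for (size_t i = 0; i < qpos.size(); ++i) {
      m(i, 0) = qpos[i];
      m(i, 1) = rpos[i];
    }
    out[q] = m;
  }
  return out;
}

// Fitting (semi-global) alignment: the whole of `pattern` against any
// substring of `text`; unit match/mismatch/gap scores steer the path,
// identity is matches / alignment columns.
// [[Rcpp::export]]
List cpp_fit_align(const std::string& pattern, const std::string& text) {
  int m = pattern.size(), n = text.size();
  if (m == 0 || n == 0)
    return List::create(_["matches"] = 0, _["columns"] = m > n ? m : n,
                        _["identity"] = 0.0, _["t_start"] = 0, _["t_end"] = 0);
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<signed char> tb((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) prev[j] = 0;  // free leading text
  for (int i = 1; i <= m; ++i) {
    cur[0] = -i;
    tb[(size_t)i * (n + 1)] = 1;
    for (int j = 1; j <= n; ++j) {
      int sd = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 1 : -1);
      int su = prev[j] - 1;
      int sl = cur[j - 1] - 1;
      int best = sd;
      signed char t = 0;
      if (su > best) { best = su; t = 1; }
      if (sl > best) { best = sl; t = 2; }
      cur[j] = best;
      tb[(size_t)i * (n + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int bestj = 0, bests = prev[0];
  for (int j = 1; j <= n; ++j)
    if (prev[j] > bests) { bests = prev[j]; bestj = j; }
  int i = m, j = bestj, matches = 0, cols = 0;
  while (i > 0) {
    signed char t = tb[(size_t)i * (n + 1) + j];
    if (t == 0) {
      if (pattern[i - 1] == text[j - 1]) ++matches;
      --i; --j; ++cols;
    } else if (t == 1) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  double ident = cols > 0 ? (double)matches / cols : 0.0;
  return List::create(_["matches"] = matches, _["columns"] = cols,
                      _["identity"] = ident, _["t_start"] = j + 1,
                      _["t_end"] = bestj);
}

// Word-seeded ungapped extension between two sequences (self-comparison when
// query and subject are the same molecule, possibly doubled for circularity).
// exact = TRUE extends only through identical bases (identity 1 mode);
// otherwise an X-drop extension (+1 match, -mismatch_pen mismatch) is used and
// endpoints are trimmed back to the best-scoring matches.
// skip_diag_mod > 0 drops hits whose diagonal (spos - qpos) is 0 modulo that
// value (self-diagonals of a doubled circular molecule).
// [[Rcpp::export]]
DataFrame cpp_seed_extend(const std::string& query, const std::string& subject,
                          int word, int min_len, double min_identity,
                          bool exact, int skip_diag_mod,
                          int mismatch_pen, int xdrop) {
  int nq = query.size(), ns = subject.size();
  std::vector<int> q_s, q_e, s_s, s_e, nmatch;
  if (nq < word || ns < word)
    return DataFrame::create(_["q_start"] = q_s, _["q_end"] = q_e,
                             _["s_start"] = s_s, _["s_end"] = s_e,
                             _["matches"] = nmatch);
  // 2-bit index of subject words (word <= 12 keeps the table small)
  size_t nbuck = (size_t)1 << (2 * word);
  std::vector<std::vector<int>> idx(nbuck);
  uint64_t mask = ((uint64_t)1 << (2 * word)) - 1, key = 0;
  int run = 0;
  for (int i = 0; i < ns; ++i) {
    int c = b2i(subject[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= word) idx[key].push_back(i - word + 1);
  }
  std::unordered_map<long long, int> covered;  // diag -> last covered q end
  key = 0; run = 0;
  for (int qp = 0; qp < nq; ++qp) {
    int c = b2i(query[qp]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < word) continue;
    int q0 = qp - word + 1;
    const std::vector<int>& occ = idx[key];
    for (size_t h = 0; h < occ.size(); ++h) {
      int s0 = occ[h];
      long long diag = (long long)s0 - q0;
      if (skip_diag_mod > 0 && diag % skip_diag_mod == 0) continue;
      std::unordered_map<long long, int>::iterator cv = covered.find(diag);
      if (cv != covered.end() && q0 <= cv->second) continue;
      int ql = q0, qr = q0 + word - 1;
      int sl = s0, sr = s0 + word - 1;
      int mm = 0;  // mismatches inside reported segment
      if (exact) {
        while (ql > 0 && sl > 0 && query[ql - 1] == subject[sl - 1] &&
               b2i(query[ql - 1]) >= 0) { --ql; --sl; }
        while (qr + 1 < nq && sr + 1 < ns &&
               query[qr + 1] == subject[sr + 1] && b2i(query[qr + 1]) >= 0) {
          ++qr; ++sr;
        }
      } else {
        // leftwards X-drop
        int sc = 0, best = 0, bi = ql, bs = sl, bmm = 0, curmm = 0;
        int i2 = ql, j2 = sl;
        while (i2 > 0 && j2 > 0) {
          --i2; --j2;
          bool m = (query[i2] == subject[j2]) && b2i(query[i2]) >= 0;
          sc += m ? 1 : -mismatch_pen;
          if (!m) ++curmm;
          if (sc > best) { best = sc; bi = i2; bs = j2; bmm = curmm; }
          if (best - sc > xdrop) break;
        }
        ql = bi; sl = bs; mm += bmm;
        // rightwards X-drop
        sc = 0; best = 0;
        int bj = qr, bt = sr; bmm = 0; curmm = 0;
        i2 = qr; j2 = sr;
        while (i2 + 1 < nq && j2 + 1 < ns) {
          ++i2; ++j2;
          bool m = (query[i2] == subject[j2]) && b2i(query[i2]) >= 0;
          sc += m ? 1 : -mismatch_pen;
          if (!m) ++curmm;
          if (sc > best) { best = sc; bj = i2; bt = j2; bmm = curmm; }
          if (best - sc > xdrop) break;
        }
        qr = bj; sr = bt; mm += bmm;
      }
      int len = qr - ql + 1;
      double ident = (double)(len - mm) / len;
      covered[diag] = qr;
      if (len >= min_len && ident >= min_identity) {
        q_s.push_back(ql + 1); q_e.push_back(qr + 1);
        s_s.push_back(sl + 1); s_e.push_back(sr + 1);
        nmatch.push_back(len - mm);
      }
    }
  }
  return DataFrame::create(_["q_start"] = q_s, _["q_end"] = q_e,
                           _["s_start"] = s_s, _["s_end"] = s_e,
                           _["matches"] = nmatch);
}

// Score of aligning `text` against an endlessly repeated `consensus`
// (free starting phase, whole text consumed).  Used to validate tandem
// repeat arrays under the match/mismatch/indel scoring convention.
// [[Rcpp::export]]
List cpp_periodic_score(const std::string& text, const std::string& consensus,
                        int match, int mismatch, int indel) {
  int n = text.size(), p = consensus.size();
  const int NEG = -1000000000;
  if (n == 0 || p == 0) return List::create(_["score"] = 0);
  std::vector<int> prev(p), cur(p);
  for (int j = 0; j < p; ++j) prev[j] = 0;  // free start phase
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j < p; ++j) cur[j] = NEG;
    for (int j = 0; j < p; ++j) {
      int jn = (j + 1) % p;
      int sc = prev[j] + (text[i - 1] == consensus[j] ? match : -mismatch);
      if (sc > cur[jn]) cur[jn] = sc;
      int si = prev[j] - indel;  // insertion in the array
      if (si > cur[j]) cur[j] = si;
    }
    // deletions advance the phase without consuming text; relax twice
    // around the ring (a full-period deletion never pays)
    for (int r = 0; r < 2; ++r)
      for (int j = 0; j < p; ++j) {
        int jn = (j + 1) % p;
        if (cur[j] != NEG && cur[j] - indel > cur[jn]) cur[jn] = cur[j] - indel;
      }
    std::swap(prev, cur);
  }
  int best = NEG;
  for (int j = 0; j < p; ++j)
    if (prev[j] > best) best = prev[j];
  return List::create(_["score"] = best);
}
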