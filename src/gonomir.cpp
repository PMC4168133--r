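#include <Rcpp.h>
using namespace Rcpp;

// Ungapped substring scan: every placement of `query` inside each reference
// with at most `max_mismatch` substitutions. Offsets are 1-based.
// [[Rcpp::export]]
DataFrame cpp_match_scan(std::string query, CharacterVector refs,
                         int max_mismatch) {
  std::vector<int> ref_idx, offset, mism;
  const int qlen = (int)query.size();
  for (int r = 0; r < refs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(refs, r));
    int rlen = (int)LENGTH(STRING_ELT(refs, r));
    for (int off = 0; off + qlen <= rlen; ++off) {
      int mm = 0;
      for (int k = 0; k < qlen; ++k) {
        if (s[off + k] != query[k] && ++mm > max_mismatch) break;
      }
      if (mm <= max_mismatch) {
        ref_idx.push_back(r + 1);
        offset.push_back(off + 1);
        mism.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["offset"] = offset,
                           _["mismatches"] = mism);
}

// Best hit per query against a reference set. References must be supplied in
// the desired tie-break order (fewest mismatches first, then reference order,
// then offset). Returns 0 for ref_idx when there is no hit.
// [[Rcpp::export]]
List cpp_best_hits(CharacterVector queries, CharacterVector refs,
                   int max_mismatch) {
  int nq = queries.size(), nr = refs.size();
  IntegerVector ref_idx(nq, 0), offset(nq, NA_INTEGER), mism(nq, NA_INTEGER);
  std::vector<const char *> rs(nr);
  std::vector<int> rl(nr);
  for (int r = 0; r < nr; ++r) {
    rs[r] = CHAR(STRING_ELT(refs, r));
    rl[r] = (int)LENGTH(STRING_ELT(refs, r));
  }
  for (int q = 0; q < nq; ++q) {
    const char *qs = CHAR(STRING_ELT(queries, q));
    int qlen = (int)LENGTH(STRING_ELT(queries, q));
    int best_mm = max_mismatch + 1, best_r = 0, best_off = 0;
    for (int r = 0; r < nr && best_mm > 0; ++r) {
      for (int off = 0; off + qlen <= rl[r]; ++off) {
        int mm = 0;
        const char *s = rs[r] + off;
        for (int k = 0; k < qlen; ++k) {
          if (s[k] != qs[k] && ++mm >= best_mm) break;
        }
        if (mm < best_mm) {
          best_mm = mm; best_r = r + 1; best_off = off + 1;
          if (best_mm == 0) break;
        }
      }
    }
    if (best_r > 0) {
      ref_idx[q] = best_r; offset[q] = best_off; mism[q] = best_mm;
    }
  }
  return List::create(_["ref_idx"] = ref_idx, _["offset"] = offset,
                      _["mismatches"] = mism);
}

// Leftmost 3' adapter placement: scan every start position, align the adapter
// prefix overlapping the read end (overlap >= min_overlap), accept at most
// max_mismatch substitutions. Returns insert length, or -1 when no placement
// is found.
// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                               int max_mismatch, int min_overlap) {
  int n = reads.size(), alen = (int)adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    int found = -1;
    for (int st = 0; st <= len - min_overlap; ++st) {
      int L = std::min(alen, len - st);
      int mm = 0;
      for (int k = 0; k < L; ++k) {
        if (s[st + k] != adapter[k] && ++mm > max_mismatch) break;
      }
      if (mm <= max_mismatch) { found = st; break; }
    }
    out[i] = found;
  }
  return out;
}

static inline bool can_pair(char a, char b) {
  // Watson-Crick plus G:U wobble, DNA alphabet (T stands for U).
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Nussinov maximum base-pairing with a minimum hairpin loop, deterministic
// traceback (outermost compatible pair first). Returns the dot-bracket
// structure and the pair count.
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop) {
  int n = (int)seq.size();
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(seq[i], seq[k])) {
          int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                  (k < j ? dp[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  int pairs = 0;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (dp[i][j] == dp[i + 1][j]) {  // prefer leaving i unpaired only if forced
      bool paired = false;
      for (int k = j; k >= i + min_loop + 1; --k) {
        if (can_pair(seq[i], seq[k])) {
          int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                  (k < j ? dp[k + 1][j] : 0);
          if (v == dp[i][j]) {
            db[i] = '('; db[k] = ')'; ++pairs;
            if (k < j) stack.push_back(std::make_pair(k + 1, j));
            stack.push_back(std::make_pair(i + 1, k - 1));
            paired = true;
            break;
          }
        }
      }
      if (!paired) stack.push_back(std::make_pair(i + 1, j));
    } else {
      for (int k = j; k >= i + min_loop + 1; --k) {
        if (can_pair(seq[i], seq[k])) {
          int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                  (k < j ? dp[k + 1][j] : 0);
          if (v == dp[i][j]) {
            db[i] = '('; db[k] = ')'; ++pairs;
            if (k < j) stack.push_back(std::make_pair(k + 1, j));
            stack.push_back(std::make_pair(i + 1, k - 1));
            break;
          }
        }
      }
    }
  }
  return List::create(_["structure"] = db, _["pairs"] = pairs,
                      _["max_pairs"] = n > 1 ? dp[0][n - 1] : 0);
}
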