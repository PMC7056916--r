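// Compiled core: suffix-array construction, LCP, sparse sampling, and
// MEM enumeration between a query and the indexed representative text.
//
// Text layout: member sequences concatenated, each followed by a '$'
// terminator (including the last). Terminators sort below all nucleotides
// and are pairwise distinct in effect: during suffix sorting each
// terminator receives a unique initial rank ordered by position, so no
// suffix comparison ever crosses a terminator.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

static const char TERM = '$';

static inline bool is_nuc(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// match semantics for MEMs: N never matches anything (including N),
// terminators never match.
static inline bool ch_match(char a, char b) { return a == b && is_nuc(a); }

// Initial ranks: terminators get unique ranks 0..(t-1) by position;
// nucleotides rank t + code, code in ASCII order A < C < G < N < T.
static void initial_ranks(const std::string& s, std::vector<int>& r) {
  const int n = (int)s.size();
  r.assign(n, 0);
  int nterm = 0;
  for (int i = 0; i < n; ++i)
    if (s[i] == TERM) ++nterm;
  int t = 0;
  for (int i = 0; i < n; ++i) {
    char c = s[i];
    if (c == TERM) {
      r[i] = t++;
    } else {
      int code;
      switch (c) {
        case 'A': code = 0; break;
        case 'C': code = 1; break;
        case 'G': code = 2; break;
        case 'N': code = 3; break;
        case 'T': code = 4; break;
        default: stop("invalid character in index text: '%c'", c);
      }
      r[i] = nterm + code;
    }
  }
}

// Full suffix array by prefix doubling with counting sort, O(n log n).
static void build_full_sa(const std::string& s, std::vector<int>& sa,
                          std::vector<int>& isa, std::vector<int>& init_rank) {
  const int n = (int)s.size();
  initial_ranks(s, init_rank);
  std::vector<int> r = init_rank, tmp(n), cnt, sa2(n);
  sa.resize(n);

  // initial sort by rank
  int maxr = 0;
  for (int i = 0; i < n; ++i) maxr = std::max(maxr, r[i]);
  cnt.assign(maxr + 2, 0);
  for (int i = 0; i < n; ++i) cnt[r[i] + 1]++;
  for (size_t i = 1; i < cnt.size(); ++i) cnt[i] += cnt[i - 1];
  for (int i = 0; i < n; ++i) sa[cnt[r[i]]++] = i;

  for (int k = 1;; k <<= 1) {
    // sa2: order by second key (r[i+k], absent = smallest)
    int p = 0;
    for (int i = n - k; i < n; ++i) sa2[p++] = i;
    for (int i = 0; i < n; ++i)
      if (sa[i] >= k) sa2[p++] = sa[i] - k;
    // stable counting sort of sa2 by first key r[]
    cnt.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) cnt[r[i] + 1]++;
    for (int i = 1; i <= n; ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) sa[cnt[r[sa2[i]]]++] = sa2[i];
    // re-rank
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      int ka = a + k < n ? r[a + k] : -1;
      int kb = b + k < n ? r[b + k] : -1;
      tmp[b] = tmp[a] + ((r[a] != r[b] || ka != kb) ? 1 : 0);
    }
    r = tmp;
    if (r[sa[n - 1]] == n - 1) break;
  }
  isa = r;
}

// Kasai LCP; character equality on initial ranks so distinct terminators
// never compare equal (N == N counts: the LCP array describes the plain
// lexicographic structure of the text).
static void kasai_lcp(const std::vector<int>& sa, const std::vector<int>& isa,
                      const std::vector<int>& init_rank, std::vector<int>& lcp) {
  const int n = (int)sa.size();
  lcp.assign(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    int ri = isa[i];
    if (ri > 0) {
      int j = sa[ri - 1];
      while (i + h < n && j + h < n && init_rank[i + h] == init_rank[j + h]) ++h;
      lcp[ri] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
}

// [[Rcpp::export]]
List cpp_build_index(std::string text, int K) {
  if (K < 1) stop("sparse step K must be >= 1");
  const int n = (int)text.size();
  std::vector<int> sa, isa, init_rank, lcp;
  build_full_sa(text, sa, isa, init_rank);
  kasai_lcp(sa, isa, init_rank, lcp);

  // sparse sampling: keep positions p with p %% K == 0, excluding
  // terminator positions (their suffixes can never start a match); LCP
  // between consecutive sampled entries = min of full LCPs in between.
  std::vector<int> ssa, slcp;
  ssa.reserve(n / K + 1);
  slcp.reserve(n / K + 1);
  int cur = INT_MAX;
  bool first = true;
  for (int i = 0; i < n; ++i) {
    if (i > 0) cur = std::min(cur, lcp[i]);
    if (sa[i] % K == 0 && text[sa[i]] != TERM) {
      ssa.push_back(sa[i]);
      slcp.push_back(first ? 0 : cur);
      first = false;
      cur = INT_MAX;
    }
  }
  return List::create(_["sa"] = wrap(ssa), _["lcp"] = wrap(slcp));
}

// Top-down narrowing search of `pat` in the sampled SA.
// On return: [tlo,thi) = interval of the longest match, mlen its length;
// [dlo,dhi) = interval at depth exactly `min_len` (or empty if unreached).
struct SearchRes {
  int dlo, dhi, tlo, thi, mlen;
};

static void narrow(const std::string& text, const std::vector<int>& sa, int lo,
                   int hi, int d, char c, int& nlo, int& nhi) {
  int l = lo, r = hi;
  while (l < r) {
    int m = l + (r - l) / 2;
    if (text[sa[m] + d] < c)
      l = m + 1;
    else
      r = m;
  }
  nlo = l;
  r = hi;
  while (l < r) {
    int m = l + (r - l) / 2;
    if (text[sa[m] + d] <= c)
      l = m + 1;
    else
      r = m;
  }
  nhi = l;
}

static SearchRes sa_search(const std::string& text, const std::vector<int>& sa,
                           const char* pat, int plen, int min_len) {
  SearchRes res{-1, -1, 0, (int)sa.size(), 0};
  int lo = 0, hi = (int)sa.size(), d = 0;
  while (d < plen) {
    char c = pat[d];
    if (!is_nuc(c)) break;  // N (or anything non-ACGT) never matches
    int nlo, nhi;
    narrow(text, sa, lo, hi, d, c, nlo, nhi);
    if (nlo >= nhi) break;
    lo = nlo;
    hi = nhi;
    ++d;
    if (d == min_len) {
      res.dlo = lo;
      res.dhi = hi;
    }
  }
  res.tlo = lo;
  res.thi = hi;
  res.mlen = d;
  return res;
}

// [[Rcpp::export]]
List cpp_search_longest(std::string text, IntegerVector sa_in,
                        std::string pattern, int min_len) {
  std::vector<int> sa(sa_in.begin(), sa_in.end());
  SearchRes r =
      sa_search(text, sa, pattern.c_str(), (int)pattern.size(), min_len);
  return List::create(_["d_lo"] = r.dlo, _["d_hi"] = r.dhi, _["t_lo"] = r.tlo,
                      _["t_hi"] = r.thi, _["match_len"] = r.mlen);
}

// Enumerate all MEMs of length >= L between `query` and the indexed text.
// Sampled SA over the reference; every query position is searched once.
// For each candidate sampled match the true left-maximal start is
// recovered by scanning at most K characters left (findL); a candidate
// whose scan runs K full matching characters belongs to a MEM whose
// canonical (leftmost in-MEM) sample is another entry, and is skipped —
// each MEM is therefore emitted exactly once.
// member_starts/member_lens describe the concatenation; candidates lying
// on members shorter than min_member_len are discarded during collection.
// [[Rcpp::export]]
IntegerMatrix cpp_find_mems(std::string text, IntegerVector sa_in,
                            IntegerVector lcp_in, int K, std::string query,
                            int L, IntegerVector member_starts,
                            IntegerVector member_lens, int min_member_len) {
  if (K < 1) stop("sparse step K must be >= 1");
  if (L < K)
    stop("minimum MEM length L (%d) must be >= sparse step K (%d): "
         "matches shorter than the sparse step would require the scanning "
         "recovery path, which is not implemented",
         L, K);
  std::vector<int> sa(sa_in.begin(), sa_in.end());
  std::vector<int> lcp(lcp_in.begin(), lcp_in.end());
  const int minmatch = L - K + 1;
  const int m = (int)query.size();
  const char* q = query.c_str();
  const int nmem = (int)member_starts.size();

  std::vector<int> out;  // triples: text_pos, query_pos, len

  auto member_index = [&](int p) {
    // last member with start <= p
    int lo = 0, hi = nmem - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (member_starts[mid] <= p)
        lo = mid;
      else
        hi = mid - 1;
    }
    return lo;
  };

  auto candidate = [&](int i, int ml, int j) {
    int p = sa[i];
    if (min_member_len > 0 && member_lens[member_index(p)] < min_member_len)
      return;
    // findL: recover left-maximal start, at most K characters
    int t = 0, rp = p, qp = j;
    while (t < K && rp > 0 && qp > 0 && ch_match(text[rp - 1], q[qp - 1])) {
      --rp;
      --qp;
      ++t;
    }
    if (t == K) return;  // non-canonical sample for this MEM
    int len = t + ml;
    if (len >= L) {
      out.push_back(rp);
      out.push_back(qp);
      out.push_back(len);
    }
  };

  for (int j = 0; j < m; ++j) {
    SearchRes r = sa_search(text, sa, q + j, m - j, minmatch);
    if (r.mlen < minmatch) continue;
    for (int i = r.tlo; i < r.thi; ++i) candidate(i, r.mlen, j);
    // walk outward from the longest-match interval; running min of LCP
    // gives the exact match length of each neighbouring entry
    int run = INT_MAX;
    for (int i = r.tlo - 1; i >= r.dlo; --i) {
      run = std::min(run, lcp[i + 1]);
      if (run < minmatch) break;
      candidate(i, run, j);
    }
    run = INT_MAX;
    for (int i = r.thi; i < r.dhi; ++i) {
      run = std::min(run, lcp[i]);
      if (run < minmatch) break;
      candidate(i, run, j);
    }
  }

  int nr = (int)out.size() / 3;
  IntegerMatrix res(nr, 3);
  for (int i = 0; i < nr; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  colnames(res) = CharacterVector::create("text_pos", "query_pos", "length");
  return res;
}

// Ungapped x-drop extension along one flank (vectors already ordered
// outward from the seed edge). Stops once the running score falls more
// than `xdrop` below the best seen; keeps the first best-scoring prefix.
// [[Rcpp::export]]
List cpp_xdrop_ungapped(std::string a, std::string b, int match, int mismatch,
                        int xdrop) {
  const int n = (int)std::min(a.size(), b.size());
  int best = 0, best_at = 0, best_matches = 0, score = 0, matches = 0;
  for (int i = 0; i < n; ++i) {
    if (ch_match(a[i], b[i])) {
      score += match;
      ++matches;
    } else {
      score += mismatch;
    }
    if (score > best) {
      best = score;
      best_at = i + 1;
      best_matches = matches;
    }
    if (best - score > xdrop) break;
  }
  return List::create(_["steps"] = best_at, _["matches"] = best_matches,
                      _["score"] = best);
}

// Gapped (affine) banded x-drop extension of one flank. a = representative
// flank, b = query flank, both ordered outward from the seed edge.
// DP over rows i (a) and columns j (b), band |i-j| <= band; rows stop when
// every live cell has dropped more than xdrop below the global best.
// Returns the endpoint with maximal score, ties broken by more matches,
// then fewer total steps (i+j), then smaller i.
// [[Rcpp::export]]
List cpp_xdrop_gapped(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend, int xdrop) {
  const int la = (int)a.size(), lb = (int)b.size();
  const long NEG = LONG_MIN / 4;
  int band = (int)((xdrop + (-gap_open)) / std::max(1, -gap_extend)) + 2;

  // three-state affine DP: M (last col aligned), X (gap in b / step in a),
  // Y (gap in a / step in b); parallel match-count tables
  int width = std::min(lb, la + band) + 1;
  std::vector<long> M(width, NEG), X(width, NEG), Y(width, NEG);
  std::vector<long> Mc(width, 0), Xc(width, 0), Yc(width, 0);

  long best = 0;
  int best_i = 0, best_j = 0;
  long best_matches = 0;

  // row 0: gaps in a (consume b only)
  M[0] = 0;
  for (int j = 1; j < width && j <= band && j <= lb; ++j) {
    Y[j] = (long)gap_open + (long)(j - 1) * gap_extend;
    if (best - std::max(M[0], Y[j]) > xdrop) {
      Y[j] = NEG;
    }
  }

  std::vector<long> Mp, Xp, Yp, Mcp, Xcp, Ycp;
  for (int i = 1; i <= la; ++i) {
    Mp = M; Xp = X; Yp = Y; Mcp = Mc; Xcp = Xc; Ycp = Yc;
    std::fill(M.begin(), M.end(), NEG);
    std::fill(X.begin(), X.end(), NEG);
    std::fill(Y.begin(), Y.end(), NEG);
    int jlo = std::max(0, i - band), jhi = std::min(lb, i + band);
    bool alive = false;
    for (int j = jlo; j <= jhi; ++j) {
      // X: gap in b, from row i-1 same column
      if (j < (int)X.size()) {
        long fromM = (Mp[j] == NEG) ? NEG : Mp[j] + gap_open;
        long fromX = (Xp[j] == NEG) ? NEG : Xp[j] + gap_extend;
        if (fromM >= fromX) { X[j] = fromM; Xc[j] = Mcp[j]; }
        else { X[j] = fromX; Xc[j] = Xcp[j]; }
      }
      // Y: gap in a, from same row j-1
      if (j > 0) {
        long fromM = (M[j - 1] == NEG) ? NEG : M[j - 1] + gap_open;
        long fromY = (Y[j - 1] == NEG) ? NEG : Y[j - 1] + gap_extend;
        if (fromM >= fromY) { Y[j] = fromM; Yc[j] = Mc[j - 1]; }
        else { Y[j] = fromY; Yc[j] = Yc[j - 1]; }
      }
      // M: diagonal, from row i-1 col j-1
      if (j > 0) {
        long d = std::max(std::max(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
        if (!(i == 1 && j == 1) && d == NEG) {
          // unreachable
        } else {
          long dc;
          if (Mp[j - 1] >= Xp[j - 1] && Mp[j - 1] >= Yp[j - 1]) dc = Mcp[j - 1];
          else if (Xp[j - 1] >= Yp[j - 1]) dc = Xcp[j - 1];
          else dc = Ycp[j - 1];
          if (d != NEG) {
            bool hit = ch_match(a[i - 1], b[j - 1]);
            M[j] = d + (hit ? match : mismatch);
            Mc[j] = dc + (hit ? 1 : 0);
          }
        }
      }
      // x-drop pruning and best tracking (alignment endpoints in any state)
      long cell = std::max(std::max(M[j], X[j]), Y[j]);
      if (cell == NEG) continue;
      if (best - cell > xdrop) {
        M[j] = X[j] = Y[j] = NEG;
        continue;
      }
      alive = true;
      long cm;
      if (M[j] >= X[j] && M[j] >= Y[j]) cm = Mc[j];
      else if (X[j] >= Y[j]) cm = Xc[j];
      else cm = Yc[j];
      bool better = cell > best ||
                    (cell == best &&
                     (cm > best_matches ||
                      (cm == best_matches &&
                       (i + j < best_i + best_j ||
                        (i + j == best_i + best_j && i < best_i)))));
      if (better) {
        best = cell;
        best_matches = cm;
        best_i = i;
        best_j = j;
      }
    }
    if (!alive) break;
  }
  return List::create(_["steps_a"] = best_i, _["steps_b"] = best_j,
                      _["matches"] = (double)best_matches,
                      _["score"] = (double)best);
}
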