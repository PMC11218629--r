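// Native long-read local alignment core: fixed-k anchor seeding, collinear
// chaining, per-gap dynamic programming, ungapped x-drop end extension, and a
// layout consensus caller used by the greedy OLC assembler.
//
// All interval coordinates exchanged with R are 0-based, half-open.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = compl_base(s[i]);
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index of the reference
// ---------------------------------------------------------------------------

struct RefIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int32_t>> pos;
};

static void build_index(const std::string &ref, int k, RefIndex &idx) {
  idx.k = k;
  idx.pos.clear();
  if ((int)ref.size() < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t key = 0;
  int run = 0;
  for (size_t i = 0; i < ref.size(); ++i) {
    int v = b2i(ref[i]);
    if (v < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)v) & mask;
    if (++run >= k) idx.pos[key].push_back((int32_t)(i - k + 1));
  }
}

struct Anchor { int32_t q, r; };

static void collect_anchors(const std::string &q, const RefIndex &idx,
                            int max_hits, std::vector<Anchor> &out) {
  out.clear();
  const int k = idx.k;
  if ((int)q.size() < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t key = 0;
  int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int v = b2i(q[i]);
    if (v < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)v) & mask;
    if (++run >= k) {
      auto it = idx.pos.find(key);
      if (it != idx.pos.end() && (int)it->second.size() <= max_hits) {
        int32_t qp = (int32_t)(i - k + 1);
        for (int32_t rp : it->second) out.push_back({qp, rp});
      }
    }
  }
}

// ---------------------------------------------------------------------------
// collinear chaining (minimap2-style windowed DP)
// ---------------------------------------------------------------------------

static std::vector<std::vector<int>> chain_anchors(std::vector<Anchor> &A,
                                                   int k, int max_gap) {
  std::vector<std::vector<int>> chains;
  int n = (int)A.size();
  if (n == 0) return chains;
  std::sort(A.begin(), A.end(), [](const Anchor &a, const Anchor &b) {
    return a.q != b.q ? a.q < b.q : a.r < b.r;
  });
  std::vector<double> score(n, (double)k);
  std::vector<int> prev(n, -1);
  const int W = 80;
  for (int i = 1; i < n; ++i) {
    for (int j = i - 1; j >= 0 && j >= i - W; --j) {
      int dq = A[i].q - A[j].q;
      if (dq > max_gap) break;  // sorted by q: earlier j only further away
      if (dq <= 0) continue;
      int dr = A[i].r - A[j].r;
      if (dr <= 0 || dr > max_gap) continue;
      int dd = dq > dr ? dq - dr : dr - dq;
      if (dd > max_gap) continue;
      double sc = score[j] + std::min(std::min(k, dq), dr) - 0.05 * dd;
      if (sc > score[i]) { score[i] = sc; prev[i] = j; }
    }
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return score[a] > score[b]; });
  std::vector<char> used(n, 0);
  for (int oi : order) {
    if (used[oi]) continue;
    std::vector<int> ch;
    int cur = oi;
    while (cur >= 0 && !used[cur]) { ch.push_back(cur); used[cur] = 1; cur = prev[cur]; }
    std::reverse(ch.begin(), ch.end());
    chains.push_back(std::move(ch));
  }
  return chains;
}

// ---------------------------------------------------------------------------
// per-gap global DP (match +1, mismatch -1, gap -1), optional op emission
// ops: 'M' match, 'X' mismatch, 'I' base present in query only,
//      'D' base present in reference only
// ---------------------------------------------------------------------------

struct AlnStats { long matches = 0, cols = 0; };

static void align_segment(const std::string &q, int qs, int qe,
                          const std::string &r, int rs, int re,
                          AlnStats &st, std::string *ops) {
  int n = qe - qs, m = re - rs;
  if (n <= 0 && m <= 0) return;
  if (n <= 0) { st.cols += m; if (ops) ops->append(m, 'D'); return; }
  if (m <= 0) { st.cols += n; if (ops) ops->append(n, 'I'); return; }
  if ((long)n * (long)m > 4000000L) {
    // degenerate (should not occur with bounded chain gaps): crude columns
    int mn = std::min(n, m), mx = std::max(n, m);
    st.cols += mx;
    if (ops) { ops->append(mn, 'X'); ops->append(mx - mn, n > m ? 'I' : 'D'); }
    return;
  }
  std::vector<int> sc((size_t)(n + 1) * (m + 1));
  std::vector<char> tb((size_t)(n + 1) * (m + 1));
  auto at = [&](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { sc[at(0, j)] = -j; tb[at(0, j)] = 'D'; }
  for (int i = 0; i <= n; ++i) { sc[at(i, 0)] = -i; tb[at(i, 0)] = 'I'; }
  for (int i = 1; i <= n; ++i) {
    char qc = q[qs + i - 1];
    for (int j = 1; j <= m; ++j) {
      bool match = (qc == r[rs + j - 1]) && b2i(qc) >= 0;
      int diag = sc[at(i - 1, j - 1)] + (match ? 1 : -1);
      int up   = sc[at(i - 1, j)] - 1;
      int left = sc[at(i, j - 1)] - 1;
      int best = diag; char op = match ? 'M' : 'X';
      if (up > best)   { best = up;   op = 'I'; }
      if (left > best) { best = left; op = 'D'; }
      sc[at(i, j)] = best;
      tb[at(i, j)] = op;
    }
  }
  std::string rev;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    char op = tb[at(i, j)];
    rev.push_back(op);
    st.cols++;
    if (op == 'M') { st.matches++; i--; j--; }
    else if (op == 'X') { i--; j--; }
    else if (op == 'I') i--;
    else j--;
  }
  if (ops) { std::reverse(rev.begin(), rev.end()); ops->append(rev); }
}

// ---------------------------------------------------------------------------
// chain -> full alignment (+ gapped free-end extension at both ends)
// ---------------------------------------------------------------------------

struct ChainAln {
  int qs = 0, qe = 0, rs = 0, re = 0;
  long matches = 0, cols = 0;
  std::string ops;
};

// free-end extension DP over windows a (query side) and b (reference side):
// global-prefix scoring (match +1, mismatch -1, gap -1), the best-scoring
// cell anywhere wins.  Returns how far each side advanced; appends ops (in
// forward window orientation) and updates stats.
static void extend_dp(const std::string &a, const std::string &b,
                      AlnStats &st, std::string *ops, int &adv_a, int &adv_b) {
  int n = (int)a.size(), m = (int)b.size();
  adv_a = 0; adv_b = 0;
  if (n == 0 || m == 0) return;
  std::vector<int> sc((size_t)(n + 1) * (m + 1));
  std::vector<char> tb((size_t)(n + 1) * (m + 1));
  auto at = [&](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int j = 0; j <= m; ++j) { sc[at(0, j)] = -j; tb[at(0, j)] = 'D'; }
  for (int i = 0; i <= n; ++i) { sc[at(i, 0)] = -i; tb[at(i, 0)] = 'I'; }
  for (int i = 1; i <= n; ++i) {
    char ac = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      bool match = (ac == b[j - 1]) && b2i(ac) >= 0;
      int diag = sc[at(i - 1, j - 1)] + (match ? 1 : -1);
      int up   = sc[at(i - 1, j)] - 1;
      int left = sc[at(i, j - 1)] - 1;
      int v = diag; char op = match ? 'M' : 'X';
      if (up > v)   { v = up;   op = 'I'; }
      if (left > v) { v = left; op = 'D'; }
      sc[at(i, j)] = v;
      tb[at(i, j)] = op;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (bi == 0 && bj == 0) return;
  std::string rev;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    char op = tb[at(i, j)];
    rev.push_back(op);
    st.cols++;
    if (op == 'M') { st.matches++; i--; j--; }
    else if (op == 'X') { i--; j--; }
    else if (op == 'I') i--;
    else j--;
  }
  if (ops) { std::reverse(rev.begin(), rev.end()); ops->append(rev); }
  adv_a = bi; adv_b = bj;
}

static ChainAln align_chain(const std::string &q, const std::string &r,
                            const std::vector<Anchor> &A,
                            const std::vector<int> &ch, int k, bool want_ops) {
  ChainAln out;
  int qa = A[ch[0]].q, ra = A[ch[0]].r;
  out.qs = qa; out.rs = ra;
  for (size_t t = 0; t < ch.size(); ++t) {
    int qi = A[ch[t]].q, ri = A[ch[t]].r;
    int dq = qi - qa, dr = ri - ra;
    if (dq < 0 || dr < 0) {
      if (dq == dr) {  // same-diagonal overlap with previous anchor
        int add = qi + k - qa;
        if (add > 0) {
          out.matches += add; out.cols += add;
          if (want_ops) out.ops.append(add, 'M');
          qa += add; ra += add;
        }
      }
      continue;
    }
    AlnStats st;
    align_segment(q, qa, qi, r, ra, ri, st, want_ops ? &out.ops : nullptr);
    out.matches += st.matches; out.cols += st.cols;
    out.matches += k; out.cols += k;
    if (want_ops) out.ops.append(k, 'M');
    qa = qi + k; ra = ri + k;
  }
  out.qe = qa; out.re = ra;

  const int W = 256;  // extension window; iterated while it stays saturated
  // right extension
  for (;;) {
    int wq = std::min(W, (int)q.size() - out.qe);
    int wr = std::min(W, (int)r.size() - out.re);
    if (wq == 0 || wr == 0) break;
    AlnStats st;
    std::string ext;
    int da = 0, db = 0;
    extend_dp(q.substr(out.qe, wq), r.substr(out.re, wr), st,
              want_ops ? &ext : nullptr, da, db);
    if (da == 0 && db == 0) break;
    out.matches += st.matches; out.cols += st.cols;
    if (want_ops) out.ops.append(ext);
    out.qe += da; out.re += db;
    if (da < wq && db < wr) break;  // did not saturate the window
  }
  // left extension: run the same DP on reversed windows
  for (;;) {
    int wq = std::min(W, out.qs);
    int wr = std::min(W, out.rs);
    if (wq == 0 || wr == 0) break;
    std::string aq = q.substr(out.qs - wq, wq);
    std::string br = r.substr(out.rs - wr, wr);
    std::reverse(aq.begin(), aq.end());
    std::reverse(br.begin(), br.end());
    AlnStats st;
    std::string ext;
    int da = 0, db = 0;
    extend_dp(aq, br, st, want_ops ? &ext : nullptr, da, db);
    if (da == 0 && db == 0) break;
    out.matches += st.matches; out.cols += st.cols;
    if (want_ops) {
      std::reverse(ext.begin(), ext.end());
      out.ops.insert(0, ext);
    }
    out.qs -= da; out.rs -= db;
    if (da < wq && db < wr) break;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: local matches of one query against one reference, both strands
// ---------------------------------------------------------------------------

struct MatchRow {
  int qstart, qend, rstart, rend;
  char strand;
  long matches, cols;
};

static void matches_one_strand(const std::string &qs_seq, const RefIndex &idx,
                               const std::string &ref, int k, int max_gap,
                               int max_hits, std::vector<MatchRow> &rows,
                               char strand, int qlen) {
  std::vector<Anchor> A;
  collect_anchors(qs_seq, idx, max_hits, A);
  if (A.empty()) return;
  auto chains = chain_anchors(A, k, max_gap);
  for (auto &ch : chains) {
    int span = A[ch.back()].q + k - A[ch[0]].q;
    if (span < 2 * k) continue;  // single spurious anchors
    ChainAln ca = align_chain(qs_seq, ref, A, ch, k, false);
    MatchRow row;
    row.strand = strand;
    row.rstart = ca.rs; row.rend = ca.re;
    row.matches = ca.matches; row.cols = ca.cols;
    if (strand == '+') { row.qstart = ca.qs; row.qend = ca.qe; }
    else { row.qstart = qlen - ca.qe; row.qend = qlen - ca.qs; }
    rows.push_back(row);
  }
}

static DataFrame rows_to_df(std::vector<MatchRow> &rows, int min_len,
                            double min_identity,
                            const std::vector<int> *qidx = nullptr,
                            const std::vector<int> *qidx_src = nullptr) {
  std::vector<int> keep;
  for (size_t i = 0; i < rows.size(); ++i) {
    const MatchRow &m = rows[i];
    double ident = m.cols > 0 ? 100.0 * (double)m.matches / (double)m.cols : 0.0;
    if (m.qend - m.qstart >= min_len && ident >= min_identity) keep.push_back((int)i);
  }
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    int qa = qidx_src ? (*qidx_src)[a] : 0, qb = qidx_src ? (*qidx_src)[b] : 0;
    if (qa != qb) return qa < qb;
    return rows[a].qstart < rows[b].qstart;
  });
  int n = (int)keep.size();
  IntegerVector qi(n), qs(n), qe(n), rs(n), re(n);
  NumericVector mt(n), al(n), id(n);
  CharacterVector st(n);
  for (int i = 0; i < n; ++i) {
    const MatchRow &m = rows[keep[i]];
    qi[i] = qidx_src ? (*qidx_src)[keep[i]] + 1 : 1;
    qs[i] = m.qstart; qe[i] = m.qend; rs[i] = m.rstart; re[i] = m.rend;
    mt[i] = (double)m.matches; al[i] = (double)m.cols;
    id[i] = m.cols > 0 ? 100.0 * (double)m.matches / (double)m.cols : 0.0;
    st[i] = m.strand == '+' ? "+" : "-";
  }
  return DataFrame::create(
    _["query"] = qi, _["qstart"] = qs, _["qend"] = qe,
    _["rstart"] = rs, _["rend"] = re, _["strand"] = st,
    _["matches"] = mt, _["aln_len"] = al, _["identity"] = id,
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_local_matches_batch(CharacterVector queries, std::string ref,
                                  int k = 15, int min_len = 100,
                                  double min_identity = 80.0,
                                  int max_gap = 500, int max_hits = 50) {
  RefIndex idx;
  build_index(ref, k, idx);
  std::vector<MatchRow> rows;
  std::vector<int> src;
  for (int qn = 0; qn < queries.size(); ++qn) {
    std::string q = as<std::string>(queries[qn]);
    int qlen = (int)q.size();
    size_t before = rows.size();
    matches_one_strand(q, idx, ref, k, max_gap, max_hits, rows, '+', qlen);
    std::string rc = revcomp(q);
    matches_one_strand(rc, idx, ref, k, max_gap, max_hits, rows, '-', qlen);
    for (size_t i = before; i < rows.size(); ++i) src.push_back(qn);
  }
  return rows_to_df(rows, min_len, min_identity, nullptr, &src);
}

// ---------------------------------------------------------------------------
// exported: layout consensus over a draft backbone
// ---------------------------------------------------------------------------

// For every fragment: best single chain vs the draft (both strands).  Votes:
// per draft column counts for A/C/G/T/del; insertion strings keyed by the
// draft position they precede.  A column's call is the majority symbol
// (ties -> alphabetical base; deletion only on strict majority).  An
// insertion is emitted when its most frequent string is supported by more
// than half of the fragments covering the junction.

// [[Rcpp::export]]
List cpp_consensus(std::string draft, CharacterVector frags,
                   int k = 15, int min_len = 500, double min_identity = 80.0,
                   int max_gap = 500, int max_hits = 50) {
  RefIndex idx;
  build_index(draft, k, idx);
  int L = (int)draft.size();
  std::vector<std::array<long, 5>> votes((size_t)L, {0, 0, 0, 0, 0});
  std::map<int, std::map<std::string, int>> ins_votes;
  std::map<int, int> ins_cov;  // fragments spanning each junction

  int nf = frags.size();
  LogicalVector mapped(nf);
  NumericVector aligned(nf);
  IntegerVector rstart(nf), rend(nf);
  CharacterVector strand(nf);

  for (int f = 0; f < nf; ++f) {
    std::string fs = as<std::string>(frags[f]);
    ChainAln best;
    char best_strand = '+';
    bool have = false;
    for (int s = 0; s < 2; ++s) {
      std::string oriented = s == 0 ? fs : revcomp(fs);
      std::vector<Anchor> A;
      collect_anchors(oriented, idx, max_hits, A);
      if (A.empty()) continue;
      auto chains = chain_anchors(A, k, max_gap);
      for (auto &ch : chains) {
        int span = A[ch.back()].q + k - A[ch[0]].q;
        if (span < 2 * k) continue;
        ChainAln ca = align_chain(oriented, draft, A, ch, k, true);
        double ident = ca.cols > 0 ? 100.0 * ca.matches / ca.cols : 0.0;
        if (ca.qe - ca.qs < min_len || ident < min_identity) continue;
        if (!have || ca.matches > best.matches) {
          best = ca; best_strand = s == 0 ? '+' : '-'; have = true;
        }
        break;  // chains are score-ordered; first passing chain is the best
      }
    }
    mapped[f] = have;
    if (!have) { aligned[f] = 0; rstart[f] = NA_INTEGER; rend[f] = NA_INTEGER; strand[f] = NA_STRING; continue; }
    aligned[f] = (double)(best.re - best.rs);
    rstart[f] = best.rs; rend[f] = best.re;
    strand[f] = best_strand == '+' ? "+" : "-";

    std::string oriented = best_strand == '+' ? fs : revcomp(fs);
    int qpos = best.qs, rpos = best.rs;
    std::string pending_ins;
    for (char op : best.ops) {
      if (op == 'I') { pending_ins.push_back(oriented[qpos]); qpos++; continue; }
      if (!pending_ins.empty()) {
        ins_votes[rpos][pending_ins]++;
        pending_ins.clear();
      }
      if (op == 'M' || op == 'X') {
        int v = b2i(oriented[qpos]);
        if (v >= 0 && rpos < L) votes[rpos][v]++;
        qpos++; rpos++;
      } else {  // 'D'
        if (rpos < L) votes[rpos][4]++;
        rpos++;
      }
    }
    if (!pending_ins.empty()) ins_votes[rpos][pending_ins]++;
    for (int j = best.rs + 1; j < best.re; ++j) ins_cov[j]++;
  }

  std::string cons;
  cons.reserve(L + 64);
  IntegerVector depth(L);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int p = 0; p <= L; ++p) {
    auto iv = ins_votes.find(p);
    if (iv != ins_votes.end()) {
      int cov = 0;
      auto ic = ins_cov.find(p);
      if (ic != ins_cov.end()) cov = ic->second;
      const std::string *best_s = nullptr;
      int best_n = 0;
      for (auto &kv : iv->second)
        if (kv.second > best_n) { best_n = kv.second; best_s = &kv.first; }
      if (best_s && 2 * best_n > cov && cov > 0) cons.append(*best_s);
    }
    if (p == L) break;
    long d = votes[p][0] + votes[p][1] + votes[p][2] + votes[p][3] + votes[p][4];
    depth[p] = (int)d;
    if (d == 0) { cons.push_back(draft[p]); continue; }
    int bi = 0;
    for (int b = 1; b < 4; ++b) if (votes[p][b] > votes[p][bi]) bi = b;
    if (votes[p][4] > votes[p][bi]) continue;  // strict majority deletion
    cons.push_back(bases[bi]);
  }

  return List::create(
    _["consensus"] = cons, _["depth"] = depth, _["mapped"] = mapped,
    _["aligned_bases"] = aligned, _["rstart"] = rstart, _["rend"] = rend,
    _["strand"] = strand);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
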