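// Seed-and-extend anchor discovery between chromosome sequences:
// exact maximal matches (MEMs) or mismatch-tolerant gapless anchors,
// plus the per-fragment best-hit scan used by fragment-based ANI.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

// Exact k-mer position index of `t` (no canonicalization; strands are
// scanned separately). Seeds containing non-ACGT bases are skipped.
static void index_kmers(const std::string& t, int k,
                        std::unordered_map<uint64_t, std::vector<int> >& idx) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t h = 0;
  int valid = 0;
  for (size_t i = 0; i < t.size(); ++i) {
    int b = b2(t[i]);
    if (b < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++valid >= k) idx[h].push_back((int)(i + 1 - k));
  }
}

struct Anchor { int qs, qe, ts, te, matches; };

// One-orientation anchor scan of q against t. mode 0 = exact MEM,
// mode 1 = gapless X-drop extension with mismatches.
static void scan_anchors(const std::string& q, const std::string& t,
                         int min_anchor, int mode, int seed_k,
                         double min_identity, int xdrop, int max_hits,
                         std::vector<Anchor>& out) {
  const int ql = (int)q.size(), tl = (int)t.size();
  if (ql < seed_k || tl < seed_k) return;
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(tl);
  index_kmers(t, seed_k, idx);
  // per-diagonal query end already covered by a reported anchor
  std::unordered_map<int64_t, int> covered;

  const uint64_t mask = (seed_k < 32) ? ((1ULL << (2 * seed_k)) - 1) : ~0ULL;
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < ql; ++i) {
    int b = b2(q[i]);
    if (b < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++valid < seed_k) continue;
    int qp = i + 1 - seed_k;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    const std::vector<int>& hits = it->second;
    if ((int)hits.size() > max_hits) continue;
    for (int tp : hits) {
      int64_t diag = (int64_t)qp - (int64_t)tp;
      auto cv = covered.find(diag);
      if (cv != covered.end() && qp + seed_k <= cv->second) continue;
      int qs, qe, ts, te, matches;
      if (mode == 0) {
        // maximal exact extension
        int l = 0;
        while (qp - l - 1 >= 0 && tp - l - 1 >= 0 && q[qp - l - 1] == t[tp - l - 1]) ++l;
        int r = seed_k;
        while (qp + r < ql && tp + r < tl && q[qp + r] == t[tp + r]) ++r;
        qs = qp - l; qe = qp + r; ts = tp - l; te = tp + r;
        matches = qe - qs;
      } else {
        // X-drop: +1 match, -2 mismatch, trim to the maximum-score point
        int score = seed_k, best = seed_k;
        int bqe = qp + seed_k, m = seed_k, bm = seed_k;
        for (int x = qp + seed_k, y = tp + seed_k; x < ql && y < tl; ++x, ++y) {
          if (q[x] == t[y]) { ++score; ++m; } else score -= 2;
          if (score > best) { best = score; bqe = x + 1; bm = m; }
          if (best - score > xdrop) break;
        }
        int bqs = qp, lm = 0, blm = 0;
        score = best; int best2 = best;
        for (int x = qp - 1, y = tp - 1; x >= 0 && y >= 0; --x, --y) {
          if (q[x] == t[y]) { ++score; ++lm; } else score -= 2;
          if (score > best2) { best2 = score; bqs = x; blm = lm; }
          if (best2 - score > xdrop) break;
        }
        qs = bqs; qe = bqe; ts = (int)(qs - diag); te = (int)(qe - diag);
        matches = bm + blm;
      }
      int len = qe - qs;
      covered[diag] = std::max(cv == covered.end() ? 0 : cv->second, qe);
      if (len >= min_anchor &&
          (mode == 0 || (double)matches / len >= min_identity)) {
        Anchor a; a.qs = qs; a.qe = qe; a.ts = ts; a.te = te; a.matches = matches;
        out.push_back(a);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_anchors(const std::string& query, const std::string& target,
                           int min_anchor, int mode, int seed_k,
                           double min_identity, int xdrop, int max_hits) {
  std::vector<Anchor> fwd, rev;
  scan_anchors(query, target, min_anchor, mode, seed_k, min_identity, xdrop,
               max_hits, fwd);
  std::string trc = revcomp(target);
  scan_anchors(query, trc, min_anchor, mode, seed_k, min_identity, xdrop,
               max_hits, rev);
  const int tl = (int)target.size();
  int n = (int)(fwd.size() + rev.size());
  IntegerVector qs(n), qe(n), ts(n), te(n), len(n);
  NumericVector ident(n);
  CharacterVector strand(n);
  int o = 0;
  for (const Anchor& a : fwd) {
    qs[o] = a.qs + 1; qe[o] = a.qe + 1; ts[o] = a.ts + 1; te[o] = a.te + 1;
    len[o] = a.qe - a.qs; ident[o] = (double)a.matches / (a.qe - a.qs);
    strand[o] = "+"; ++o;
  }
  for (const Anchor& a : rev) {
    // map [ts,te) on the reverse complement back to forward coordinates
    qs[o] = a.qs + 1; qe[o] = a.qe + 1;
    ts[o] = tl - a.te + 1; te[o] = tl - a.ts + 1;
    len[o] = a.qe - a.qs; ident[o] = (double)a.matches / (a.qe - a.qs);
    strand[o] = "-"; ++o;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["tstart"] = ts, _["tend"] = te,
                           _["strand"] = strand, _["length"] = len,
                           _["identity"] = ident,
                           _["stringsAsFactors"] = false);
}

// Best gapless placement of each consecutive query fragment in the target
// (both strands), seeded by shared k-mers voting for diagonals.
// Returns, per fragment: best identity, aligned fraction, and the midpoint
// of the matched target interval in forward coordinates (for reciprocity).
// [[Rcpp::export]]
DataFrame cpp_fragment_hits(const std::string& query, const std::string& target,
                            int fragment_len, int seed_k, int top_diags,
                            int min_votes) {
  const int ql = (int)query.size(), tl = (int)target.size();
  const int nf = ql / fragment_len;
  std::unordered_map<uint64_t, std::vector<int> > idx_f, idx_r;
  idx_f.reserve(tl); idx_r.reserve(tl);
  index_kmers(target, seed_k, idx_f);
  std::string trc = revcomp(target);
  index_kmers(trc, seed_k, idx_r);

  NumericVector best_id(nf, NA_REAL), aligned_frac(nf, 0.0), tmid(nf, NA_REAL);
  const uint64_t mask = (seed_k < 32) ? ((1ULL << (2 * seed_k)) - 1) : ~0ULL;

  for (int f = 0; f < nf; ++f) {
    const int fs = f * fragment_len;
    for (int strand = 0; strand < 2; ++strand) {
      const std::unordered_map<uint64_t, std::vector<int> >& idx =
        strand == 0 ? idx_f : idx_r;
      std::unordered_map<int64_t, int> votes;
      uint64_t h = 0; int valid = 0;
      for (int i = fs; i < fs + fragment_len; ++i) {
        int b = b2(query[i]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid < seed_k) continue;
        auto it = idx.find(h);
        if (it == idx.end()) continue;
        if ((int)it->second.size() > 64) continue;
        int qp = i + 1 - seed_k;
        for (int tp : it->second) votes[(int64_t)qp - tp] += 1;
      }
      if (votes.empty()) continue;
      std::vector<std::pair<int, int64_t> > ranked;
      ranked.reserve(votes.size());
      for (auto& kv : votes) ranked.push_back(std::make_pair(kv.second, kv.first));
      std::sort(ranked.begin(), ranked.end(),
                [](const std::pair<int, int64_t>& a, const std::pair<int, int64_t>& b) {
                  return a.first > b.first || (a.first == b.first && a.second < b.second);
                });
      int nd = std::min((int)ranked.size(), top_diags);
      for (int d = 0; d < nd; ++d) {
        if (ranked[d].first < min_votes) break;
        int64_t diag = ranked[d].second;
        // fragment [fs, fs+L) maps to [fs - diag, fs + L - diag) on this strand
        int a0 = (int)std::max((int64_t)fs - diag, (int64_t)0);
        int a1 = (int)std::min((int64_t)fs + fragment_len - diag, (int64_t)tl);
        if (a1 <= a0) continue;
        int m = 0;
        const std::string& tt = strand == 0 ? target : trc;
        for (int y = a0; y < a1; ++y) {
          int x = (int)(y + diag);
          if (query[x] == tt[y]) ++m;
        }
        double frac = (double)(a1 - a0) / fragment_len;
        double id = (double)m / (a1 - a0);
        if (R_IsNA(best_id[f]) || id * frac > best_id[f] * aligned_frac[f]) {
          best_id[f] = id;
          aligned_frac[f] = frac;
          double mid = 0.5 * (a0 + a1);
          tmid[f] = strand == 0 ? mid : (double)tl - mid;
        }
      }
    }
  }
  return DataFrame::create(_["fragment"] = seq_len(nf),
                           _["best_identity"] = best_id,
                           _["aligned_frac"] = aligned_frac,
                           _["tmid"] = tmid);
}
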