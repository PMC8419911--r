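// Core string algorithms: approximate junction search (Myers bit-parallel),
// end-free affine-gap alignment (Gotoh), k-mer amplicon classification, and
// the per-base read error model. Coordinates are 0-based half-open throughout.
#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return 4;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Myers (1999) bit-parallel approximate search, pattern length <= 64.
// Text-prefix-free ("HW") mode: reports end positions (inclusive) where the
// full pattern matches a text infix with edit distance <= k.
// ---------------------------------------------------------------------------
static void myers_search(const std::string& pat, const std::string& txt, int k,
                         std::vector<std::pair<int, int> >& out,
                         bool anchored = false) {
  // anchored = false: pattern matches any text infix ending at j ("HW").
  // anchored = true: the match must start at text position 0 ("SHW");
  // leading text gaps then cost 1 each (horizontal boundary input +1).
  const int m = (int)pat.size();
  if (m < 1 || m > 64) stop("pattern length must be in [1, 64]");
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int c = base_code(pat[i]);
    if (c < 4) Peq[c] |= (1ULL << i);
  }
  uint64_t Pv = ~0ULL, Mv = 0;
  int score = m;
  const uint64_t mask = 1ULL << (m - 1);
  for (size_t j = 0; j < txt.size(); ++j) {
    int c = base_code(txt[j]);
    uint64_t Eq = (c < 4) ? Peq[c] : 0;
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    int delta = (Ph & mask) ? 1 : ((Mh & mask) ? -1 : 0);
    score += delta;
    Ph <<= 1; Mh <<= 1;
    if (anchored) Ph |= 1ULL;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
    if (score <= k) out.push_back(std::make_pair((int)j, score));
  }
}

// Exact start position for a hit ending at `end_incl` with distance <= d:
// search the reversed pattern in the reversed candidate window.
static int myers_hit_start(const std::string& pat, const std::string& txt,
                           int end_incl, int d, int* d_out) {
  const int m = (int)pat.size();
  int lo = std::max(0, end_incl + 1 - m - d);
  std::string win = txt.substr(lo, end_incl + 1 - lo);
  std::string rwin(win.rbegin(), win.rend());
  std::string rpat(pat.rbegin(), pat.rend());
  std::vector<std::pair<int, int> > cand;
  myers_search(rpat, rwin, d, cand, /*anchored=*/true);
  int best_d = INT_MAX, best_e = -1;
  for (size_t i = 0; i < cand.size(); ++i) {
    if (cand[i].second < best_d ||
        (cand[i].second == best_d && cand[i].first > best_e)) {
      best_d = cand[i].second;
      best_e = cand[i].first;
    }
  }
  if (best_e < 0) { *d_out = d; return end_incl + 1 - m; }  // defensive
  *d_out = best_d;
  return end_incl - best_e;
}

// Approximate occurrences of `adapter` (both orientations) in `read`.
// Overlapping candidates are resolved greedily by lowest edit distance,
// ties by leftmost start. Returns a matrix with columns
// start, end (0-based half-open), edits, strand (0 = forward, 1 = reverse).
// [[Rcpp::export]]
IntegerMatrix cpp_find_junctions(std::string read, std::string adapter,
                                 double max_edit_fraction) {
  const int m = (int)adapter.size();
  if (m < 10) stop("junction adapter must be at least 10 nt");
  if (m > 64) stop("junction adapter longer than 64 nt is not supported");
  if (max_edit_fraction < 0 || max_edit_fraction >= 0.5)
    stop("max_edit_fraction must be in [0, 0.5)");
  const int k = (int)std::floor(max_edit_fraction * m);

  struct Hit { int start, end, edits, strand; };
  std::vector<Hit> hits;
  for (int strand = 0; strand < 2; ++strand) {
    std::string pat = strand == 0 ? adapter : revcomp(adapter);
    if (strand == 1 && pat == adapter) break;  // palindromic adapter
    std::vector<std::pair<int, int> > cand;
    myers_search(pat, read, k, cand);
    // one occurrence produces a run of in-budget end positions; keep only the
    // best (lowest distance, then leftmost) end per run. Runs from distinct
    // occurrences are separated by at least a monomer, far more than m/2.
    std::vector<std::pair<int, int> > winners;
    int last_j = -1000000;
    for (size_t i = 0; i < cand.size(); ++i) {
      if (!winners.empty() && cand[i].first - last_j <= m / 2) {
        if (cand[i].second < winners.back().second) winners.back() = cand[i];
      } else {
        winners.push_back(cand[i]);
      }
      last_j = cand[i].first;
    }
    for (size_t i = 0; i < winners.size(); ++i) {
      int d2 = winners[i].second;
      int start = myers_hit_start(pat, read, winners[i].first,
                                  winners[i].second, &d2);
      Hit h; h.start = start; h.end = winners[i].first + 1;
      h.edits = d2; h.strand = strand;
      hits.push_back(h);
    }
  }
  // greedy non-overlapping selection: lowest edit distance, then leftmost
  std::vector<int> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (hits[a].edits != hits[b].edits) return hits[a].edits < hits[b].edits;
    if (hits[a].start != hits[b].start) return hits[a].start < hits[b].start;
    return hits[a].strand < hits[b].strand;
  });
  std::vector<int> kept;
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    const Hit& h = hits[ord[oi]];
    bool clash = false;
    for (size_t kj = 0; kj < kept.size(); ++kj) {
      const Hit& g = hits[kept[kj]];
      if (h.start < g.end && g.start < h.end) { clash = true; break; }
    }
    if (!clash) kept.push_back(ord[oi]);
  }
  std::sort(kept.begin(), kept.end(), [&](int a, int b) {
    return hits[a].start < hits[b].start;
  });
  IntegerMatrix out((int)kept.size(), 4);
  for (size_t i = 0; i < kept.size(); ++i) {
    out((int)i, 0) = hits[kept[i]].start;
    out((int)i, 1) = hits[kept[i]].end;
    out((int)i, 2) = hits[kept[i]].edits;
    out((int)i, 3) = hits[kept[i]].strand;
  }
  colnames(out) = CharacterVector::create("start", "end", "edits", "strand");
  return out;
}

// ---------------------------------------------------------------------------
// Gotoh affine-gap alignment, free end gaps in both sequences; the query is
// fully consumed unless the reference is exhausted first ("global-local").
// A gap of length L costs gap_open + L * gap_extend.
// ---------------------------------------------------------------------------
struct AlnResult {
  int score, ref_start, ref_end, q_start, q_end, n_match, n_col;
  std::vector<int> obs;   // per ref position in [ref_start, ref_end): 0..3 base, 4 del
  std::vector<int> ins;   // ref anchor positions with an insertion-after event
};

static const int NEG = INT_MIN / 4;

static void align_overlap(const std::string& q, const std::string& r,
                          int match, int mismatch, int gap_open, int gap_extend,
                          AlnResult& res) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<int> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)), F((n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
  for (int i = 1; i <= n; ++i) { H[i * W] = 0; E[i * W] = NEG; F[i * W] = NEG; }
  std::vector<int> qc(n), rc(m);
  for (int i = 0; i < n; ++i) qc[i] = base_code(q[i]);
  for (int j = 0; j < m; ++j) rc[j] = base_code(r[j]);
  for (int i = 1; i <= n; ++i) {
    const int* Hp = &H[(i - 1) * W];
    int* Hc = &H[i * W];
    int* Ec = &E[i * W];
    int* Fc = &F[i * W];
    const int* Fp = &F[(i - 1) * W];
    for (int j = 1; j <= m; ++j) {
      int e = std::max(Ec[j - 1] - gap_extend, Hc[j - 1] - gap_open - gap_extend);
      int f = std::max(Fp[j] - gap_extend, Hp[j] - gap_open - gap_extend);
      int s = (qc[i - 1] == rc[j - 1] && qc[i - 1] < 4) ? match : -mismatch;
      int h = Hp[j - 1] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      Ec[j] = e; Fc[j] = f; Hc[j] = h;
    }
  }
  // best cell on last row (query consumed) or last column (ref consumed)
  // prefer the largest ref column on score ties (consume ref rather than end
  // with a free-trailing insertion run: canonical, matches textbook traceback)
  int bi = n, bj = 0, best = H[n * W];
  for (int j = 1; j <= m; ++j) if (H[n * W + j] >= best) { best = H[n * W + j]; bj = j; }
  for (int i = 1; i < n; ++i) if (H[i * W + m] > best) { best = H[i * W + m]; bi = i; bj = m; }

  res.score = best;
  res.ref_end = bj; res.q_end = bi;
  res.n_match = 0; res.n_col = 0;
  res.obs.assign(m, -1);
  res.ins.clear();

  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in query/deletion), 2 = F (insertion)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[i * W + j];
      if (h == E[i * W + j]) { state = 1; continue; }
      if (h == F[i * W + j]) { state = 2; continue; }
      res.obs[j - 1] = qc[i - 1] < 4 ? qc[i - 1] : 5;  // 5 = ambiguous base, not counted
      ++res.n_col;
      if (qc[i - 1] == rc[j - 1] && qc[i - 1] < 4) ++res.n_match;
      --i; --j;
    } else if (state == 1) {           // ref base consumed, no query base: deletion
      res.obs[j - 1] = 4;
      ++res.n_col;
      int e = E[i * W + j];
      bool ext = (j >= 2) && (e == E[i * W + j - 1] - gap_extend);
      --j;
      if (!ext) state = 0;
    } else {                           // query base consumed, no ref base: insertion
      ++res.n_col;
      int f = F[i * W + j];
      bool ext = (i >= 2) && (f == F[(i - 1) * W + j] - gap_extend);
      --i;
      if (!ext) {
        state = 0;
        // one event per contiguous insertion run, anchored after ref pos j-1
        res.ins.push_back(j - 1);
      }
    }
  }
  res.ref_start = j; res.q_start = i;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string query, std::string ref, int match, int mismatch,
                    int gap_open, int gap_extend) {
  AlnResult res;
  align_overlap(query, ref, match, mismatch, gap_open, gap_extend, res);
  IntegerVector obs(res.obs.begin() + res.ref_start, res.obs.begin() + res.ref_end);
  return List::create(
    _["score"] = res.score,
    _["ref_start"] = res.ref_start, _["ref_end"] = res.ref_end,
    _["q_start"] = res.q_start, _["q_end"] = res.q_end,
    _["n_match"] = res.n_match, _["n_col"] = res.n_col,
    _["identity"] = res.n_col > 0 ? (double)res.n_match / res.n_col : 0.0,
    _["obs"] = obs, _["ins"] = wrap(res.ins));
}

// ---------------------------------------------------------------------------
// Batch alignment of segments against panel amplicons.
// Candidate (amplicon, strand) pairs are screened by shared 11-mers, then the
// top candidates are aligned with the affine aligner; ties between different
// amplicons are discarded as ambiguous. Reverse-strand segments are aligned as
// their reverse complement against the forward reference so that all reported
// coordinates and pileup events are in amplicon space.
// ---------------------------------------------------------------------------
static const int KMER = 11;

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector segments, CharacterVector refs,
                     int match, int mismatch, int gap_open, int gap_extend,
                     double min_identity, bool return_events) {
  const int nref = (int)refs.size();
  if (nref < 1) stop("panel must contain at least one amplicon");
  if (2 * nref > 64) stop("at most 32 amplicons are supported");
  std::vector<std::string> rseq(nref);
  for (int r = 0; r < nref; ++r) rseq[r] = as<std::string>(refs[r]);

  // k-mer -> bitmask over (ref, strand) pairs; pair index = 2*ref + strand
  std::unordered_map<uint32_t, uint64_t> kmap;
  kmap.reserve(2048 * nref);
  for (int r = 0; r < nref; ++r) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? rseq[r] : revcomp(rseq[r]);
      uint32_t km = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c >= 4) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & ((1U << (2 * KMER)) - 1);
        if (++run >= KMER) kmap[km] |= (1ULL << (2 * r + strand));
      }
    }
  }

  const R_xlen_t nseg = segments.size();
  IntegerVector out_ref(nseg, NA_INTEGER);
  IntegerVector out_strand(nseg, NA_INTEGER);
  IntegerVector out_score(nseg, NA_INTEGER);
  NumericVector out_ident(nseg, NA_REAL);
  IntegerVector out_rstart(nseg, NA_INTEGER), out_rend(nseg, NA_INTEGER);
  CharacterVector out_status(nseg);
  List out_obs(return_events ? nseg : 0), out_ins(return_events ? nseg : 0);

  std::vector<int> counts(2 * nref);
  for (R_xlen_t si = 0; si < nseg; ++si) {
    std::string seg = as<std::string>(segments[si]);
    const int L = (int)seg.size();
    std::fill(counts.begin(), counts.end(), 0);
    int nkmer = 0;
    {
      uint32_t km = 0; int run = 0;
      for (int i = 0; i < L; ++i) {
        int c = base_code(seg[i]);
        if (c >= 4) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & ((1U << (2 * KMER)) - 1);
        if (++run >= KMER) {
          ++nkmer;
          std::unordered_map<uint32_t, uint64_t>::const_iterator it = kmap.find(km);
          if (it != kmap.end()) {
            uint64_t msk = it->second;
            while (msk) {
              int b = __builtin_ctzll(msk);
              ++counts[b];
              msk &= msk - 1;
            }
          }
        }
      }
    }
    std::vector<int> cand;
    int c1 = 0;
    for (int p = 0; p < 2 * nref; ++p) if (counts[p] > c1) c1 = counts[p];
    if (nkmer == 0 || c1 == 0) {
      // no informative k-mers: brute-force all pairs for small panels
      if (nref <= 8 && L >= 5) {
        for (int p = 0; p < 2 * nref; ++p) cand.push_back(p);
      } else {
        out_status[si] = "no_kmer_match";
        continue;
      }
    } else {
      int margin = std::max(3, c1 / 4);
      for (int p = 0; p < 2 * nref; ++p)
        if (counts[p] >= c1 - margin) cand.push_back(p);
      std::sort(cand.begin(), cand.end(), [&](int a, int b) {
        return counts[a] > counts[b];
      });
      if (cand.size() > 6) cand.resize(6);
    }

    std::string seg_rc;
    AlnResult best, second;
    int best_pair = -1, second_pair = -1;
    best.score = NEG; second.score = NEG;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int p = cand[ci], r = p / 2, strand = p % 2;
      const std::string* qp = &seg;
      if (strand == 1) {
        if (seg_rc.empty()) seg_rc = revcomp(seg);
        qp = &seg_rc;
      }
      AlnResult res;
      align_overlap(*qp, rseq[r], match, mismatch, gap_open, gap_extend, res);
      if (res.score > best.score) {
        second = best; second_pair = best_pair;
        best = res; best_pair = p;
      } else if (res.score > second.score) {
        second = res; second_pair = p;
      }
    }
    if (best_pair < 0) { out_status[si] = "unaligned"; continue; }
    if (second_pair >= 0 && second.score == best.score &&
        second_pair / 2 != best_pair / 2) {
      out_status[si] = "ambiguous";
      continue;
    }
    double ident = best.n_col > 0 ? (double)best.n_match / best.n_col : 0.0;
    if (ident < min_identity) {
      out_status[si] = "low_identity";
      out_ident[si] = ident;
      continue;
    }
    // spurious short overlaps of unrelated sequence can score positive with
    // high local identity; require at least half the segment to align
    if (best.q_end - best.q_start < 0.5 * L) {
      out_status[si] = "low_aligned_fraction";
      out_ident[si] = ident;
      continue;
    }
    out_ref[si] = best_pair / 2 + 1;
    out_strand[si] = best_pair % 2;
    out_score[si] = best.score;
    out_ident[si] = ident;
    out_rstart[si] = best.ref_start;
    out_rend[si] = best.ref_end;
    out_status[si] = "aligned";
    if (return_events) {
      IntegerVector obs(best.obs.begin() + best.ref_start,
                        best.obs.begin() + best.ref_end);
      out_obs[si] = obs;
      out_ins[si] = wrap(best.ins);
    }
  }
  List out = List::create(
    _["amplicon"] = out_ref, _["strand"] = out_strand, _["score"] = out_score,
    _["identity"] = out_ident, _["ref_start"] = out_rstart,
    _["ref_end"] = out_rend, _["status"] = out_status);
  if (return_events) { out["obs"] = out_obs; out["ins"] = out_ins; }
  return out;
}

// Shared-k-mer classification only: best amplicon per segment (strand folded
// in), NA when no k-mer is shared. Used for pre-downsampling assignment.
// [[Rcpp::export]]
IntegerVector cpp_classify_kmer(CharacterVector segments, CharacterVector refs) {
  const int nref = (int)refs.size();
  if (nref < 1) stop("panel must contain at least one amplicon");
  if (2 * nref > 64) stop("at most 32 amplicons are supported");
  std::vector<std::string> rseq(nref);
  for (int r = 0; r < nref; ++r) rseq[r] = as<std::string>(refs[r]);
  // flat direct-addressed table over all 4^11 k-mers (33 MB, transient):
  // classification runs over ~1e5 segments per sample, so lookup speed wins
  std::vector<uint64_t> kmap(1U << (2 * KMER), 0);
  for (int r = 0; r < nref; ++r) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? rseq[r] : revcomp(rseq[r]);
      uint32_t km = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c >= 4) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & ((1U << (2 * KMER)) - 1);
        if (++run >= KMER) kmap[km] |= (1ULL << (2 * r + strand));
      }
    }
  }
  const R_xlen_t nseg = segments.size();
  IntegerVector out(nseg, NA_INTEGER);
  std::vector<int> counts(nref);
  for (R_xlen_t si = 0; si < nseg; ++si) {
    const char* seg = CHAR(STRING_ELT(segments, si));
    const int L = (int)LENGTH(STRING_ELT(segments, si));
    std::fill(counts.begin(), counts.end(), 0);
    uint32_t km = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = base_code(seg[i]);
      if (c >= 4) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint32_t)c) & ((1U << (2 * KMER)) - 1);
      if (++run >= KMER) {
        uint64_t msk = kmap[km];
        while (msk) {
          int b = __builtin_ctzll(msk);
          ++counts[b / 2];
          msk &= msk - 1;
        }
      }
    }
    int best = -1, bc = 0;
    for (int r = 0; r < nref; ++r)
      if (counts[r] > bc) { bc = counts[r]; best = r; }
    if (best >= 0 && bc >= 3) out[si] = best + 1;  // require >= 3 shared k-mers
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-base error model: independent substitution / insertion / deletion at the
// configured rates; the deletion rate is multiplied inside homopolymer runs of
// length >= 3 (capped so per-base event probability stays < 1). Uses R's RNG,
// so results are reproducible under set.seed().
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector seqs, double p_sub, double p_ins,
                                 double p_del, double hp_mult) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  std::string buf;
  std::vector<int> runlen;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    const int n = (int)s.size();
    runlen.assign(n, 1);
    // length of the homopolymer run each position belongs to
    int start = 0;
    for (int i = 1; i <= n; ++i) {
      if (i == n || s[i] != s[start]) {
        for (int j = start; j < i; ++j) runlen[j] = i - start;
        start = i;
      }
    }
    buf.clear();
    buf.reserve((size_t)(n * (1.0 + p_ins) + 8));
    for (int i = 0; i < n; ++i) {
      double pd = runlen[i] >= 3 ? p_del * hp_mult : p_del;
      double tot = p_sub + p_ins + pd;
      if (tot > 0.95) { pd *= 0.95 / tot; }
      double u = unif_rand();
      if (u < p_sub) {
        int orig = base_code(s[i]);
        int b = (int)(unif_rand() * 3.0);
        if (b > 2) b = 2;
        if (orig < 4) b = (orig + 1 + b) % 4; // any base != orig
        buf.push_back(BASES[b]);
      } else if (u < p_sub + p_ins) {
        buf.push_back(s[i]);
        int b = (int)(unif_rand() * 4.0);
        if (b > 3) b = 3;
        buf.push_back(BASES[b]);
      } else if (u < p_sub + p_ins + pd) {
        // deleted
      } else {
        buf.push_back(s[i]);
      }
    }
    out[si] = buf;
  }
  return out;
}
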