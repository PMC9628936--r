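#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    }
  }
  return r;
}

// 2-bit k-mer set of a sequence; k-mers containing non-ACGT are skipped.
static std::unordered_set<uint64_t> kmer_set(const std::string& s, int k) {
  std::unordered_set<uint64_t> out;
  const int n = (int)s.size();
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.insert(kmer);
  }
  return out;
}

static int kmer_hits(const std::string& s, const std::unordered_set<uint64_t>& ref,
                     int k) {
  const int n = (int)s.size();
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0, hits = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k && ref.count(kmer)) ++hits;
  }
  return hits;
}

// Banded local (Smith-Waterman) alignment with affine gaps; first gap base
// costs `gap_open`, each further base `gap_ext` (both positive penalties).
// Tracks the query start of the best local path so query coverage can be
// reported without a traceback matrix.
struct SWResult { int score, qstart, qend; };

static SWResult sw_affine(const std::vector<int>& q, const std::vector<int>& r,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int band) {
  const int n = (int)q.size(), m = (int)r.size();
  const int NEG = -1000000000;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  std::vector<int> Hs(m + 1, 1), Fs(m + 1, 1);
  SWResult best{0, 1, 0};
  const int extra = std::max(0, m - n);
  for (int i = 1; i <= n; ++i) {
    int lo = 1, hi = m;
    if (band > 0) { lo = std::max(1, i - band); hi = std::min(m, i + band + extra); }
    int diagH = (lo > 1) ? 0 : H[lo - 1];            // H(i-1, lo-1) before overwrite
    int diagS = (lo > 1) ? i : Hs[lo - 1];
    if (lo > 1) { H[lo - 1] = 0; Hs[lo - 1] = i; }    // outside band: restart
    int curE = NEG, curEs = i;
    for (int j = lo; j <= hi; ++j) {
      int upH = H[j], upHs = Hs[j];                   // H(i-1, j)
      // E: gap in query (consume ref)
      int e_open = H[j - 1] - gap_open;               // H(i, j-1) already this row
      int e_ext = curE - gap_ext;
      if (e_open >= e_ext) { curE = e_open; curEs = Hs[j - 1]; }
      else { curE = e_ext; }
      // F: gap in ref (consume query)
      int f_open = upH - gap_open;
      int f_ext = F[j] - gap_ext;
      if (f_open >= f_ext) { F[j] = f_open; Fs[j] = upHs; }
      else { F[j] = f_ext; }
      // H
      int s = (q[i - 1] == r[j - 1]) ? match : -mismatch;
      int h_diag = diagH + s;
      int h_diagS = (diagH == 0) ? i : diagS;
      int h = 0, hs = i + 1;
      if (h_diag > h) { h = h_diag; hs = h_diagS; }
      if (curE > h) { h = curE; hs = curEs; }
      if (F[j] > h) { h = F[j]; hs = Fs[j]; }
      diagH = upH; diagS = upHs;
      H[j] = h; Hs[j] = hs;
      if (h > best.score) { best.score = h; best.qstart = hs; best.qend = i; }
    }
    // cell just right of the band is read as up/diag by the next row;
    // treat it as a local restart
    if (band > 0 && hi + 1 <= m) { H[hi + 1] = 0; Hs[hi + 1] = i + 1; F[hi + 1] = NEG; }
  }
  return best;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    v[i] = (c < 0) ? -4 : c;  // non-ACGT never matches anything
  }
  return v;
}

// [[Rcpp::export]]
List sw_call_batch_cpp(CharacterVector reads, CharacterVector refs,
                       int match, int mismatch, int gap_open, int gap_ext,
                       int kmer, int top_k, int band) {
  const int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_fwd(n_refs);
  std::vector<std::vector<int>> ref_enc(n_refs);
  std::vector<std::unordered_set<uint64_t>> ref_kmers(n_refs);
  for (int r = 0; r < n_refs; ++r) {
    ref_fwd[r] = as<std::string>(refs[r]);
    ref_enc[r] = encode(ref_fwd[r]);
    ref_kmers[r] = kmer_set(ref_fwd[r], kmer);
  }
  IntegerVector out_ref(n_reads), out_strand(n_reads), out_score(n_reads),
      out_qs(n_reads), out_qe(n_reads), out_second(n_reads);
  LogicalVector out_tie(n_reads);
  NumericVector out_cov(n_reads);

  for (int i = 0; i < n_reads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    const int L = (int)fwd.size();
    std::vector<int> enc_f = encode(fwd), enc_r = encode(rev);

    // prescreen: shared-kmer count per (strand, ref)
    struct Cand { int ref, strand, hits; };
    std::vector<Cand> cands;
    cands.reserve(2 * n_refs);
    for (int r = 0; r < n_refs; ++r) {
      cands.push_back({r, 1, kmer_hits(fwd, ref_kmers[r], kmer)});
      cands.push_back({r, -1, kmer_hits(rev, ref_kmers[r], kmer)});
    }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand& a, const Cand& b) { return a.hits > b.hits; });
    int n_eval = (top_k > 0) ? std::min((int)cands.size(), 2 * top_k)
                             : (int)cands.size();

    int best_ref = -1, best_strand = 1, best_score = -1, best_qs = 1, best_qe = 0;
    std::vector<int> ref_best(n_refs, -1);
    for (int c = 0; c < n_eval; ++c) {
      const Cand& cd = cands[c];
      SWResult res = sw_affine(cd.strand > 0 ? enc_f : enc_r, ref_enc[cd.ref],
                               match, mismatch, gap_open, gap_ext, band);
      if (res.score > ref_best[cd.ref]) ref_best[cd.ref] = res.score;
      if (res.score > best_score ||
          (res.score == best_score && cd.ref < best_ref)) {
        best_ref = cd.ref; best_strand = cd.strand; best_score = res.score;
        best_qs = res.qstart; best_qe = res.qend;
      }
    }
    int second = -1;
    for (int r = 0; r < n_refs; ++r) {
      if (r != best_ref && ref_best[r] > second) second = ref_best[r];
    }
    out_ref[i] = best_ref + 1;
    out_strand[i] = best_strand;
    out_score[i] = best_score;
    out_qs[i] = best_qs; out_qe[i] = best_qe;
    out_cov[i] = (L > 0 && best_qe >= best_qs)
                     ? (double)(best_qe - best_qs + 1) / (double)L : 0.0;
    out_second[i] = second;
    out_tie[i] = (second == best_score);
  }
  return List::create(
      _["ref"] = out_ref, _["strand"] = out_strand, _["score"] = out_score,
      _["qstart"] = out_qs, _["qend"] = out_qe, _["coverage"] = out_cov,
      _["second_score"] = out_second, _["tie"] = out_tie);
}
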