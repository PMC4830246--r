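#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// NCBI BLOSUM62 over the alphabet ARNDCQEGHILKMFPSTWYVBZX*
static const int BLOSUM62[24][24] = {
{4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-2,-1,-1,-4},
{-1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-1,0,-1,-4},
{-2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,4,0,-1,-4},
{-2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,4,1,-1,-4},
{0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-1,-4},
{-1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,0,4,-1,-4},
{-1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,1,4,-1,-4},
{0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-1,-2,-1,-4},
{-2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,0,0,-1,-4},
{-1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-3,-3,-1,-4},
{-1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-4,-3,-1,-4},
{-1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,0,1,-1,-4},
{-1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-3,-1,-1,-4},
{-2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-3,-3,-1,-4},
{-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-2,-1,-1,-4},
{1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,0,0,-1,-4},
{0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-1,-1,-1,-4},
{-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-4,-2,-1,-4},
{-2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-3,-2,-1,-4},
{0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-3,-2,-1,-4},
{-2,-1,4,4,-3,0,1,-1,0,-3,-4,0,-3,-3,-2,0,-1,-4,-3,-3,4,0,-1,-4},
{-1,0,0,1,-3,4,4,-2,0,-3,-3,1,-1,-3,-1,0,-1,-2,-2,-2,0,4,-1,-4},
{-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-4},
{-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,1}
};

static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";

static inline int aa_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;  case 'D': return 3;
    case 'C': return 4;  case 'Q': return 5;  case 'E': return 6;  case 'G': return 7;
    case 'H': return 8;  case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14; case 'S': return 15;
    case 'T': return 16; case 'W': return 17; case 'Y': return 18; case 'V': return 19;
    case 'B': return 20; case 'Z': return 21; case 'X': return 22; case '*': return 23;
    case 'U': return 22; case 'O': return 22; case 'J': return 22;
    default:  return 22; // unknown -> X
  }
}

static std::vector<int> encode_aa(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = aa_code(s[i]);
  return v;
}

// score-only local alignment, affine gaps (gap of length k costs open + k * ext)
static int sw_protein_score(const std::vector<int> &a, const std::vector<int> &b,
                            int gap_open, int gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  const int NEG = -1000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // E: gap in a (horizontal)
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG); // F: gap in b (vertical)
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    const int *row = BLOSUM62[a[i - 1]];
    for (int j = 1; j <= n; ++j) {
      Ecur[j] = std::max(Ecur[j - 1] - gap_ext, Hcur[j - 1] - gap_open - gap_ext);
      Fcur[j] = std::max(Fprev[j] - gap_ext, Hprev[j] - gap_open - gap_ext);
      int h = Hprev[j - 1] + row[b[j - 1]];
      h = std::max(h, Ecur[j]);
      h = std::max(h, Fcur[j]);
      h = std::max(h, 0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

struct AlnStats {
  int score, qstart, qend, sstart, send;
  int length, matches, mismatches, gapopens, gaps;
  std::string qaln, saln;
};

// full SW with traceback; generic over a scoring callback
template <typename ScoreFun>
static AlnStats sw_traceback(const std::vector<int> &a, const std::vector<int> &b,
                             ScoreFun subst, int gap_open, int gap_ext,
                             const char *alph_a, const char *alph_b) {
  const int m = (int)a.size(), n = (int)b.size();
  AlnStats out{0, 0, 0, 0, 0, 0, 0, 0, 0, 0, "", ""};
  if (m == 0 || n == 0) return out;
  const int NEG = -1000000;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int idx = i * (n + 1) + j;
      E[idx] = std::max(E[idx - 1] - gap_ext, H[idx - 1] - gap_open - gap_ext);
      F[idx] = std::max(F[idx - (n + 1)] - gap_ext, H[idx - (n + 1)] - gap_open - gap_ext);
      int h = H[idx - (n + 1) - 1] + subst(a[i - 1], b[j - 1]);
      h = std::max(h, E[idx]);
      h = std::max(h, F[idx]);
      h = std::max(h, 0);
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  out.score = best;
  if (best == 0) return out;
  // traceback from (bi, bj)
  int i = bi, j = bj;
  std::string qa, sa;
  int state = 0; // 0 = H, 1 = E (gap in a / query), 2 = F (gap in b / subject)
  while (i > 0 && j > 0) {
    int idx = i * (n + 1) + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      int diag = H[idx - (n + 1) - 1] + subst(a[i - 1], b[j - 1]);
      if (H[idx] == diag) {
        qa.push_back(alph_a[a[i - 1]]);
        sa.push_back(alph_b[b[j - 1]]);
        if (a[i - 1] == b[j - 1]) out.matches++; else out.mismatches++;
        --i; --j;
      } else if (H[idx] == E[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in query: consume subject
      qa.push_back('-');
      sa.push_back(alph_b[b[j - 1]]);
      out.gaps++;
      bool opened = (E[idx] == H[idx - 1] - gap_open - gap_ext);
      if (opened) { out.gapopens++; state = 0; }
      --j;
    } else { // gap in subject: consume query
      qa.push_back(alph_a[a[i - 1]]);
      sa.push_back('-');
      out.gaps++;
      bool opened = (F[idx] == H[idx - (n + 1)] - gap_open - gap_ext);
      if (opened) { out.gapopens++; state = 0; }
      --i;
    }
  }
  out.qstart = i + 1; out.qend = bi;
  out.sstart = j + 1; out.send = bj;
  out.length = (int)qa.size();
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out.qaln = qa; out.saln = sa;
  return out;
}

static int blosum_sub(int x, int y) { return BLOSUM62[x][y]; }

// [[Rcpp::export]]
List cpp_sw_pair(std::string query, std::string subject, int gap_open, int gap_ext) {
  std::vector<int> a = encode_aa(query), b = encode_aa(subject);
  AlnStats st = sw_traceback(a, b, blosum_sub, gap_open, gap_ext, AA_ORDER, AA_ORDER);
  return List::create(
      _["score"] = st.score, _["qstart"] = st.qstart, _["qend"] = st.qend,
      _["sstart"] = st.sstart, _["send"] = st.send, _["length"] = st.length,
      _["matches"] = st.matches, _["mismatches"] = st.mismatches,
      _["gapopens"] = st.gapopens, _["gaps"] = st.gaps,
      _["qaln"] = st.qaln, _["saln"] = st.saln);
}

// Batch translated search: queries are translated frames, grouped per read.
// A 4-mer (over the 20 standard residues) prefilter selects candidate
// references; candidates are scored by Smith-Waterman and the best frame per
// (read, reference) pair is reported with full alignment statistics.
// [[Rcpp::export]]
DataFrame cpp_sw_search(CharacterVector frame_seqs, IntegerVector frame_read,
                        IntegerVector frame_label, CharacterVector ref_seqs,
                        int kmer, int min_shared, int gap_open, int gap_ext,
                        int min_frame_len) {
  const int nframe = frame_seqs.size();
  const int nref = ref_seqs.size();
  std::vector<std::vector<int>> refs(nref);
  for (int r = 0; r < nref; ++r) refs[r] = encode_aa(as<std::string>(ref_seqs[r]));

  // k-mer index over the 20-letter alphabet (kmers touching B/Z/X/* skipped)
  int tbl = 1;
  for (int i = 0; i < kmer; ++i) tbl *= 20;
  std::vector<std::vector<int>> index(tbl);
  for (int r = 0; r < nref; ++r) {
    const std::vector<int> &s = refs[r];
    int code = 0, valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      if (s[p] < 20) { code = (code * 20 + s[p]) % tbl; valid++; }
      else { code = 0; valid = 0; }
      if (valid >= kmer) {
        std::vector<int> &cell = index[code];
        if (cell.empty() || cell.back() != r) cell.push_back(r);
      }
    }
  }

  // best hit per (read, ref): keyed map
  struct Best { int score, frame_pos; };
  std::unordered_map<int64_t, Best> best;
  std::vector<int> cnt(nref, 0), touched;

  for (int f = 0; f < nframe; ++f) {
    std::string q = as<std::string>(frame_seqs[f]);
    if ((int)q.size() < min_frame_len) continue;
    std::vector<int> a = encode_aa(q);
    touched.clear();
    int code = 0, valid = 0;
    for (size_t p = 0; p < a.size(); ++p) {
      if (a[p] < 20) { code = (code * 20 + a[p]) % tbl; valid++; }
      else { code = 0; valid = 0; }
      if (valid >= kmer) {
        for (int r : index[code]) {
          if (cnt[r] == 0) touched.push_back(r);
          cnt[r]++;
        }
      }
    }
    int read = frame_read[f];
    for (int r : touched) {
      if (cnt[r] >= min_shared) {
        int sc = sw_protein_score(a, refs[r], gap_open, gap_ext);
        if (sc > 0) {
          int64_t key = (int64_t)read * nref + r;
          auto it = best.find(key);
          if (it == best.end() || sc > it->second.score)
            best[key] = Best{sc, f};
        }
      }
      cnt[r] = 0;
    }
  }

  // deterministic output order, then traceback each retained pair
  std::vector<int64_t> keys;
  keys.reserve(best.size());
  for (auto &kv : best) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  int nh = (int)keys.size();
  IntegerVector o_read(nh), o_ref(nh), o_frame(nh), o_score(nh), o_qs(nh),
      o_qe(nh), o_ss(nh), o_se(nh), o_len(nh), o_match(nh), o_mis(nh),
      o_go(nh), o_gaps(nh), o_framepos(nh);
  for (int h = 0; h < nh; ++h) {
    int64_t key = keys[h];
    int read = (int)(key / nref), r = (int)(key % nref);
    Best bs = best[key];
    std::vector<int> a = encode_aa(as<std::string>(frame_seqs[bs.frame_pos]));
    AlnStats st = sw_traceback(a, refs[r], blosum_sub, gap_open, gap_ext,
                               AA_ORDER, AA_ORDER);
    o_read[h] = read + 1;
    o_ref[h] = r + 1;
    o_frame[h] = frame_label[bs.frame_pos];
    o_framepos[h] = bs.frame_pos + 1;
    o_score[h] = st.score;
    o_qs[h] = st.qstart; o_qe[h] = st.qend;
    o_ss[h] = st.sstart; o_se[h] = st.send;
    o_len[h] = st.length; o_match[h] = st.matches; o_mis[h] = st.mismatches;
    o_go[h] = st.gapopens; o_gaps[h] = st.gaps;
  }
  return DataFrame::create(
      _["read"] = o_read, _["ref"] = o_ref, _["frame"] = o_frame,
      _["frame_pos"] = o_framepos, _["score"] = o_score, _["qstart"] = o_qs,
      _["qend"] = o_qe, _["sstart"] = o_ss, _["send"] = o_se,
      _["length"] = o_len, _["matches"] = o_match, _["mismatches"] = o_mis,
      _["gapopens"] = o_go, _["gaps"] = o_gaps,
      _["stringsAsFactors"] = false);
}

// ---------- nucleotide mapping (CLC-style: match +1, linear penalties) ------

static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N / other: mismatches everything
  }
}
static const char NT_ORDER[] = "ACGTN";

static std::vector<int> encode_nt(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = nt_code(s[i]);
  return v;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: c = 'N';
    }
  }
  return r;
}

// score-only SW with linear gap penalty and +1/-mismatch scoring
static int sw_nt_score(const std::vector<int> &a, const std::vector<int> &b,
                       int mismatch, int indel) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int sub = (a[i - 1] == b[j - 1] && a[i - 1] != 4) ? 1 : -mismatch;
      int h = Hprev[j - 1] + sub;
      h = std::max(h, Hprev[j] - indel);
      h = std::max(h, Hcur[j - 1] - indel);
      h = std::max(h, 0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Map each read against a set of nucleotide references, both strands.
// Reports the best (score; ties: forward strand, then lower reference index)
// local alignment per read with aligned strings for consensus building.
// [[Rcpp::export]]
DataFrame cpp_nt_map(CharacterVector reads, CharacterVector refs,
                     int mismatch, int indel) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::vector<int>> R(nf);
  for (int r = 0; r < nf; ++r) R[r] = encode_nt(as<std::string>(refs[r]));

  IntegerVector o_ref(nr), o_strand(nr), o_score(nr), o_qs(nr), o_qe(nr),
      o_ss(nr), o_se(nr), o_len(nr), o_match(nr), o_mis(nr), o_gaps(nr);
  CharacterVector o_qaln(nr), o_saln(nr);

  auto sub = [mismatch](int x, int y) {
    return (x == y && x != 4) ? 1 : -mismatch;
  };

  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    std::vector<int> af = encode_nt(fwd), ar = encode_nt(rev);
    int bscore = -1, bref = 0, bstrand = 1;
    for (int r = 0; r < nf; ++r) {
      int s1 = sw_nt_score(af, R[r], mismatch, indel);
      if (s1 > bscore) { bscore = s1; bref = r; bstrand = 1; }
      int s2 = sw_nt_score(ar, R[r], mismatch, indel);
      if (s2 > bscore) { bscore = s2; bref = r; bstrand = -1; }
    }
    const std::vector<int> &a = (bstrand == 1) ? af : ar;
    // linear gap penalty: open = 0, each gap base costs `indel`
    AlnStats st = sw_traceback(a, R[bref], sub, 0, indel, NT_ORDER, NT_ORDER);
    o_ref[i] = bref + 1; o_strand[i] = bstrand; o_score[i] = st.score;
    o_qs[i] = st.qstart; o_qe[i] = st.qend;
    o_ss[i] = st.sstart; o_se[i] = st.send;
    o_len[i] = st.length; o_match[i] = st.matches; o_mis[i] = st.mismatches;
    o_gaps[i] = st.gaps;
    o_qaln[i] = st.qaln; o_saln[i] = st.saln;
  }
  return DataFrame::create(
      _["ref"] = o_ref, _["strand"] = o_strand, _["score"] = o_score,
      _["qstart"] = o_qs, _["qend"] = o_qe, _["sstart"] = o_ss,
      _["send"] = o_se, _["length"] = o_len, _["matches"] = o_match,
      _["mismatches"] = o_mis, _["gaps"] = o_gaps, _["qaln"] = o_qaln,
      _["saln"] = o_saln, _["stringsAsFactors"] = false);
}
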