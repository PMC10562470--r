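#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide bitmasks: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'U': return 8;
    case 'M': return 3;  case 'R': return 5;  case 'W': return 9;  case 'S': return 6;
    case 'Y': return 10; case 'K': return 12; case 'V': return 7;  case 'H': return 11;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default:  return 0;
  }
}

static void mask_seq(const std::string& s, std::vector<int>& m) {
  m.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    m[i] = iupac_mask(s[i]);
    if (m[i] == 0) stop("non-IUPAC character '%s' at offset %d", std::string(1, s[i]), (int)(i + 1));
  }
}

// Score-only Smith-Waterman-Gotoh: no traceback bookkeeping, used to scan a
// read against a whole reference panel before aligning the winner in full.
// [[Rcpp::export(name = ".swg_score_cpp")]]
int swg_score_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int> am, bm;
  mask_seq(a, am); mask_seq(b, bm);
  const int n = am.size(), m = bm.size();
  const int open_cost = gap_open + gap_extend;
  std::vector<int> H(m + 1, 0), F(m + 1, INT_MIN / 4);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int hdiag = 0;  // H[i-1][j-1]
    int e = INT_MIN / 4;
    int hprev_j = H[0]; // H[i-1][j] rolling
    const int ai = am[i - 1];
    int* Hp = H.data();
    int* Fp = F.data();
    for (int j = 1; j <= m; ++j) {
      e = std::max(Hp[j - 1] - open_cost, e - gap_extend);
      const int f = std::max(Hp[j] - open_cost, Fp[j] - gap_extend);
      int h = hdiag + ((ai & bm[j - 1]) ? match : mismatch);
      h = std::max(h, std::max(e, f));
      if (h < 0) h = 0;
      hdiag = Hp[j];
      Hp[j] = h;
      Fp[j] = f;
      if (h > best) best = h;
    }
    (void)hprev_j;
  }
  return best;
}

// Direction byte layout (per DP cell):
//   bits 0-1: source of H  (0 = stop/zero, 1 = diagonal, 2 = F/up, 3 = E/left)
//   bit 2:    F extended an existing gap (1) vs opened from H (0)
//   bit 3:    E extended an existing gap (1) vs opened from H (0)
static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".swg_align_cpp")]]
List swg_align_cpp(std::string a, std::string b,
                   int match, int mismatch, int gap_open, int gap_extend,
                   bool traceback = true) {
  std::vector<int> am, bm;
  mask_seq(a, am); mask_seq(b, bm);
  const int n = am.size(), m = bm.size();
  const int open_cost = gap_open + gap_extend;

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Eprev;
  std::vector<int> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<unsigned char> dir;
  if (traceback) dir.assign((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Ecur = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      // E: gap in a (consume b[j])
      int e_open = Hcur[j - 1] - open_cost;
      int e_ext  = Ecur - gap_extend;
      if (e_ext > e_open) { Ecur = e_ext; d |= 8; } else Ecur = e_open;
      // F: gap in b (consume a[i])
      int f_open = Hprev[j] - open_cost;
      int f_ext  = Fprev[j] - gap_extend;
      if (f_ext > f_open) { Fcur[j] = f_ext; d |= 4; } else Fcur[j] = f_open;
      // H: best, preference diag > up(F) > left(E) > stop
      int diag = Hprev[j - 1] + ((am[i - 1] & bm[j - 1]) ? match : mismatch);
      int h = diag; unsigned char src = 1;
      if (Fcur[j] > h) { h = Fcur[j]; src = 2; }
      if (Ecur > h)    { h = Ecur;    src = 3; }
      if (h <= 0) { h = 0; src = 0; }
      Hcur[j] = h;
      if (traceback) dir[(size_t)i * (m + 1) + j] = d | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (!traceback || best == 0) {
    return List::create(_["score"] = best,
                        _["a_start"] = best ? bi - 1 : 0, _["a_end"] = bi,
                        _["b_start"] = best ? bj - 1 : 0, _["b_end"] = bj,
                        _["matches"] = 0, _["columns"] = 0,
                        _["gapped_a"] = "", _["gapped_b"] = "");
  }

  // traceback from (bi, bj) in state H
  std::string ga, gb;
  int i = bi, j = bj, matches = 0;
  int state = 0; // 0 = H, 1 = F, 2 = E
  while (true) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (state == 0) {
      int src = d & 3;
      if (src == 0) break;
      if (src == 1) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        if (am[i - 1] & bm[j - 1]) ++matches;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = (d & 4) ? 1 : 0;
      --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = (d & 8) ? 2 : 0;
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["matches"] = matches, _["columns"] = (int)ga.size(),
                      _["gapped_a"] = ga, _["gapped_b"] = gb);
}

// Global alignment (Needleman-Wunsch with affine gaps), same conventions and
// tie-breaking as the local aligner; used by the center-star MSA merge.
// [[Rcpp::export(name = ".nwg_align_cpp")]]
List nwg_align_cpp(std::string a, std::string b,
                   int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int> am, bm;
  mask_seq(a, am); mask_seq(b, bm);
  const int n = am.size(), m = bm.size();
  const int open_cost = gap_open + gap_extend;

  std::vector<int> Hprev(m + 1), Hcur(m + 1);
  std::vector<int> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);

  Hprev[0] = 0;
  for (int j = 1; j <= m; ++j) {
    Hprev[j] = -(gap_open + j * gap_extend);
    dir[j] = 3 | (j > 1 ? 8 : 0); // from E
  }
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = -(gap_open + i * gap_extend);
    dir[(size_t)i * (m + 1)] = 2 | (i > 1 ? 4 : 0); // from F
    int Ecur = NEG;
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      int e_open = Hcur[j - 1] - open_cost;
      int e_ext  = Ecur - gap_extend;
      if (e_ext > e_open) { Ecur = e_ext; d |= 8; } else Ecur = e_open;
      int f_open = Hprev[j] - open_cost;
      int f_ext  = Fprev[j] - gap_extend;
      if (f_ext > f_open) { Fcur[j] = f_ext; d |= 4; } else Fcur[j] = f_open;
      int diag = Hprev[j - 1] + ((am[i - 1] & bm[j - 1]) ? match : mismatch);
      int h = diag; unsigned char src = 1;
      if (Fcur[j] > h) { h = Fcur[j]; src = 2; }
      if (Ecur > h)    { h = Ecur;    src = 3; }
      Hcur[j] = h;
      dir[(size_t)i * (m + 1) + j] = d | src;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  int score = Hprev[m];

  std::string ga, gb;
  int i = n, j = m, matches = 0, state = 0;
  while (i > 0 || j > 0) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (state == 0) {
      int src = d & 3;
      if (src == 1) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        if (am[i - 1] & bm[j - 1]) ++matches;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = (d & 4) ? 1 : 0;
      --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = (d & 8) ? 2 : 0;
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = (int)ga.size(),
                      _["gapped_a"] = ga, _["gapped_b"] = gb);
}

// Degenerate-aware sliding scan of a primer core along one template strand.
// A position matches when the IUPAC sets intersect; mismatches must not exceed
// max_mismatch overall and must be zero within the 3'-terminal anchor (the
// last anchor3_len core positions). Returns a matrix: 0-based start, mismatches.
// [[Rcpp::export(name = ".scan_sites_cpp")]]
IntegerMatrix scan_sites_cpp(std::string tmpl, std::string core,
                             int max_mismatch, int anchor3_len) {
  std::vector<int> tm, cm;
  mask_seq(tmpl, tm); mask_seq(core, cm);
  const int n = tm.size(), k = cm.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + k <= n; ++s) {
    int mm = 0; bool ok = true;
    for (int p = 0; p < k; ++p) {
      if (!(tm[s + p] & cm[p])) {
        if (p >= k - anchor3_len) { ok = false; break; }
        if (++mm > max_mismatch)  { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(s); mms.push_back(mm); }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t r = 0; r < starts.size(); ++r) { out(r, 0) = starts[r]; out(r, 1) = mms[r]; }
  return out;
}
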