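#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Conversion-aware global affine-gap (Gotoh) alignment of a bisulfite read
// against an amplicon reference.
//
// Scoring: a gap of length k costs gap_open + k * gap_ext (the opening base
// pays gap_open + gap_ext).  Conversion-consistent pairs score `conv` like
// matches: mode "OT": reference C vs read C or T; mode "OB": reference G vs
// read G or A.
//
// band >= 0 restricts the DP to a corridor of half-width `band` around the
// length-difference-adjusted diagonal; band < 0 computes the full matrix.
// The corridor always contains the main diagonal, so a global path exists.

static const double NEG_INF = -1e18;

static inline double pair_score(char r, char q, int mode,
                                double match, double mismatch,
                                double conv) {
  if (mode == 0) {            // OT: C -> C/T
    if (r == 'C' && (q == 'C' || q == 'T')) return conv;
  } else {                    // OB: G -> G/A
    if (r == 'G' && (q == 'G' || q == 'A')) return conv;
  }
  return (r == q) ? match : mismatch;
}

static inline bool pair_matchlike(char r, char q, int mode) {
  if (r == q) return true;
  if (mode == 0) return r == 'C' && q == 'T';
  return r == 'G' && q == 'A';
}

struct Corridor {
  int m, lo_off, hi_off, W;
  Corridor(int n, int m_, int band) : m(m_) {
    if (band < 0) { lo_off = -1000000000; hi_off = 1000000000; }
    else {
      lo_off = std::min(0, m_ - n) - band;
      hi_off = std::max(0, m_ - n) + band;
    }
    W = std::min((long long)m_ + 1,
                 (long long)hi_off - lo_off + 1) + 2;
  }
  inline int lo(int i) const { return std::max(0, i + lo_off); }
  inline int hi(int i) const {
    return std::min(m, (hi_off > 500000000) ? m : i + hi_off);
  }
};

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string read, std::string strand,
                 double match, double mismatch,
                 double gap_open, double gap_ext, double conv,
                 int band, bool score_only) {
  const int n = ref.size(), m = read.size();
  const int mode = (strand == "OB") ? 1 : 0;
  Corridor C(n, m, band);
  const size_t W = C.W;
  const size_t NC = (size_t)(n + 1) * W;
  std::vector<double> M(NC, NEG_INF), X(NC, NEG_INF), Y(NC, NEG_INF);
  std::vector<unsigned char> tbM, tbX, tbY;
  if (!score_only) {
    tbM.assign(NC, 0); tbX.assign(NC, 0); tbY.assign(NC, 0);
  }
  // compact index: row i stores j in [lo(i), hi(i)] at i*W + (j - lo(i))
  std::vector<int> LO(n + 1);
  for (int i = 0; i <= n; ++i) LO[i] = C.lo(i);
  auto IDX = [&](int i, int j) { return (size_t)i * W + (j - LO[i]); };

  M[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= C.hi(0); ++j) {
    Y[IDX(0, j)] = gap_open + j * gap_ext;
    if (!score_only) tbY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const int lo = LO[i], hi = C.hi(i), plo = LO[i - 1], phi = C.hi(i - 1);
    if (lo == 0) {
      X[IDX(i, 0)] = gap_open + i * gap_ext;
      if (!score_only) tbX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = std::max(1, lo); j <= hi; ++j) {
      const size_t k = IDX(i, j);
      double Mu = NEG_INF, Xu = NEG_INF, Yu = NEG_INF;  // up (i-1, j)
      if (j >= plo && j <= phi) {
        const size_t ku = IDX(i - 1, j);
        Mu = M[ku]; Xu = X[ku]; Yu = Y[ku];
      }
      double Ml = NEG_INF, Xl = NEG_INF, Yl = NEG_INF;  // left (i, j-1)
      if (j - 1 >= lo) {
        const size_t kl = IDX(i, j - 1);
        Ml = M[kl]; Xl = X[kl]; Yl = Y[kl];
      }
      double Md = NEG_INF, Xd = NEG_INF, Yd = NEG_INF;  // diag (i-1, j-1)
      if (j - 1 >= plo && j - 1 <= phi) {
        const size_t kd = IDX(i - 1, j - 1);
        Md = M[kd]; Xd = X[kd]; Yd = Y[kd];
      }
      // X: gap in read (ref base vs -)
      double xo = Mu + gap_open + gap_ext;
      double xe = Xu + gap_ext;
      double xy = Yu + gap_open + gap_ext;
      unsigned char tx;
      double xv;
      if (xo >= xe && xo >= xy) { xv = xo; tx = 0; }
      else if (xe >= xy)        { xv = xe; tx = 1; }
      else                      { xv = xy; tx = 2; }
      X[k] = xv;
      // Y: gap in ref (read insertion)
      double yo = Ml + gap_open + gap_ext;
      double ye = Yl + gap_ext;
      double yx = Xl + gap_open + gap_ext;
      unsigned char ty;
      double yv;
      if (yo >= ye && yo >= yx) { yv = yo; ty = 0; }
      else if (ye >= yx)        { yv = ye; ty = 2; }
      else                      { yv = yx; ty = 1; }
      Y[k] = yv;
      // M: substitution
      double s = pair_score(ref[i - 1], read[j - 1], mode,
                            match, mismatch, conv);
      unsigned char tm;
      double mv;
      if (Md >= Xd && Md >= Yd) { mv = Md + s; tm = 0; }
      else if (Xd >= Yd)        { mv = Xd + s; tm = 1; }
      else                      { mv = Yd + s; tm = 2; }
      M[k] = mv;
      if (!score_only) { tbM[k] = tm; tbX[k] = tx; tbY[k] = ty; }
    }
  }
  const size_t kend = IDX(n, m);
  int state;
  double score;
  if (M[kend] >= X[kend] && M[kend] >= Y[kend]) { state = 0; score = M[kend]; }
  else if (X[kend] >= Y[kend])                  { state = 1; score = X[kend]; }
  else                                          { state = 2; score = Y[kend]; }
  if (score_only) return List::create(_["score"] = score);

  std::vector<int> ri, qi;
  ri.reserve(n + m); qi.reserve(n + m);
  int i = n, j = m, nmatch = 0;
  while (i > 0 || j > 0) {
    const size_t k = IDX(i, j);
    if (state == 0) {
      ri.push_back(i - 1); qi.push_back(j - 1);
      if (pair_matchlike(ref[i - 1], read[j - 1], mode)) ++nmatch;
      state = tbM[k]; --i; --j;
    } else if (state == 1) {
      ri.push_back(i - 1); qi.push_back(-1);
      state = tbX[k]; --i;
    } else {
      ri.push_back(-1); qi.push_back(j - 1);
      state = tbY[k]; --j;
    }
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(qi.begin(), qi.end());
  return List::create(_["score"] = score,
                      _["ref_offset"] = IntegerVector(ri.begin(), ri.end()),
                      _["read_offset"] = IntegerVector(qi.begin(), qi.end()),
                      _["n_match"] = nmatch,
                      _["n_cols"] = (int) ri.size());
}
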