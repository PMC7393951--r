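#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion.  A gap of length L costs gap_open + gap_ext * L (Biostrings
// penalty convention).  Traceback tie-break is fixed: prefer the match
// state, then a gap in the subject (vertical), then a gap in the query,
// so that identities are reproducible across co-optimal alignments.
//
// Two entry points: cpp_nw_batch computes score plus identity/coverage via
// traceback; cpp_nw_score_batch computes scores only with two rolling rows
// (the fast path for best-hit searches over many candidate pairs).

static const double NEG_INF = -1e18;

struct AlnStats {
  double score;
  int ncols;    // alignment length including gap columns
  int nmatch;   // identical aligned residue pairs
  int nboth;    // columns with residues in both sequences
};

// flat substitution matrix with plain-array access
struct SubMat {
  std::vector<double> s;
  int n;
  explicit SubMat(const IntegerMatrix& m) : s(m.nrow() * m.ncol()), n(m.nrow()) {
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < m.ncol(); ++j)
        s[i * n + j] = m(i, j);
  }
  inline double operator()(int a, int b) const { return s[a * n + b]; }
};

static AlnStats gotoh_align(const std::vector<int>& a,
                            const std::vector<int>& b,
                            const SubMat& sub, double go, double ge) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which state the max came from (0=M,1=X,2=Y)
  std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W), tY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(go + ge * i);
    tX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(go + ge * j);
    tY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      // M: diagonal
      {
        const int d = ij - W - 1;
        double best = M[d];
        unsigned char st = 0;
        if (X[d] > best) { best = X[d]; st = 1; }
        if (Y[d] > best) { best = Y[d]; st = 2; }
        M[ij] = best + sub(ai, b[j - 1]);
        tM[ij] = st;
      }
      // X: a[i-1] against a gap (vertical move)
      {
        const int u = ij - W;
        double best = M[u] - (go + ge);
        unsigned char st = 0;
        if (X[u] - ge > best) { best = X[u] - ge; st = 1; }
        if (Y[u] - (go + ge) > best) { best = Y[u] - (go + ge); st = 2; }
        X[ij] = best;
        tX[ij] = st;
      }
      // Y: b[j-1] against a gap (horizontal move)
      {
        const int l = ij - 1;
        double best = M[l] - (go + ge);
        unsigned char st = 0;
        if (X[l] - (go + ge) > best) { best = X[l] - (go + ge); st = 1; }
        if (Y[l] - ge > best) { best = Y[l] - ge; st = 2; }
        Y[ij] = best;
        tY[ij] = st;
      }
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  AlnStats st{score, 0, 0, 0};
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (state == 0) {
      ++st.ncols; ++st.nboth;
      if (a[i - 1] == b[j - 1]) ++st.nmatch;
      state = tM[ij]; --i; --j;
    } else if (state == 1) {
      ++st.ncols;
      state = tX[ij]; --i;
    } else {
      ++st.ncols;
      state = tY[ij]; --j;
    }
  }
  return st;
}

static double gotoh_score(const std::vector<int>& a, const std::vector<int>& b,
                          const SubMat& sub, double go, double ge,
                          std::vector<double>& buf) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  // two rolling rows for each of the three states
  if ((int)buf.size() < 6 * W) buf.resize(6 * W);
  double* Mp = &buf[0];       // previous row
  double* Xp = &buf[W];
  double* Yp = &buf[2 * W];
  double* Mc = &buf[3 * W];   // current row
  double* Xc = &buf[4 * W];
  double* Yc = &buf[5 * W];

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF; Yp[j] = -(go + ge * j);
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Xc[0] = -(go + ge * i);
    Yc[0] = NEG_INF;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = Mp[j - 1];
      if (Xp[j - 1] > d) d = Xp[j - 1];
      if (Yp[j - 1] > d) d = Yp[j - 1];
      Mc[j] = d + sub(ai, b[j - 1]);
      double x = Mp[j] - (go + ge);
      if (Xp[j] - ge > x) x = Xp[j] - ge;
      if (Yp[j] - (go + ge) > x) x = Yp[j] - (go + ge);
      Xc[j] = x;
      double y = Mc[j - 1] - (go + ge);
      if (Xc[j - 1] - (go + ge) > y) y = Xc[j - 1] - (go + ge);
      if (Yc[j - 1] - ge > y) y = Yc[j - 1] - ge;
      Yc[j] = y;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double best = Mp[m];
  if (Xp[m] > best) best = Xp[m];
  if (Yp[m] > best) best = Yp[m];
  return best;
}

static std::vector<int> encode_seq(const std::string& s,
                                   const std::vector<int>& lut,
                                   int fallback) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lut[static_cast<unsigned char>(s[i])];
    out[i] = (v >= 0) ? v : fallback;
    if (out[i] < 0) stop("character '%c' not in substitution alphabet", s[i]);
  }
  return out;
}

static std::vector<int> make_lut(const CharacterVector& alphabet) {
  std::vector<int> lut(256, -1);
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string ch = as<std::string>(alphabet[i]);
    if (ch.size() != 1) stop("alphabet entries must be single characters");
    lut[static_cast<unsigned char>(ch[0])] = i;
  }
  return lut;
}

// [[Rcpp::export]]
NumericMatrix cpp_nw_batch(CharacterVector a, CharacterVector b,
                           IntegerMatrix submat, CharacterVector alphabet,
                           double gap_open, double gap_ext) {
  const int np = a.size();
  if (b.size() != np) stop("a and b must have equal length");
  std::vector<int> lut = make_lut(alphabet);
  const int xidx = lut[static_cast<unsigned char>('X')];
  const SubMat sub(submat);

  NumericMatrix out(np, 5);
  colnames(out) = CharacterVector::create("score", "identity", "ncols",
                                          "nmatch", "nboth");
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]), sb = as<std::string>(b[p]);
    if (sa.empty() || sb.empty()) stop("empty sequence in alignment input");
    std::vector<int> ea = encode_seq(sa, lut, xidx);
    std::vector<int> eb = encode_seq(sb, lut, xidx);
    AlnStats st = gotoh_align(ea, eb, sub, gap_open, gap_ext);
    out(p, 0) = st.score;
    out(p, 1) = 100.0 * st.nmatch / st.ncols;
    out(p, 2) = st.ncols;
    out(p, 3) = st.nmatch;
    out(p, 4) = st.nboth;
  }
  return out;
}

// Score-only batch over index pairs into two sequence pools: sequences are
// encoded once, so a sequence appearing in many candidate pairs is not
// re-processed.  qi/si are 1-based indices into qs/ss.
// [[Rcpp::export]]
NumericVector cpp_nw_score_pairs(CharacterVector qs, CharacterVector ss,
                                 IntegerVector qi, IntegerVector si,
                                 IntegerMatrix submat,
                                 CharacterVector alphabet,
                                 double gap_open, double gap_ext) {
  if (qi.size() != si.size()) stop("qi and si must pair up");
  std::vector<int> lut = make_lut(alphabet);
  const int xidx = lut[static_cast<unsigned char>('X')];
  const SubMat sub(submat);

  std::vector<std::vector<int> > eq(qs.size()), es(ss.size());
  std::vector<bool> hq(qs.size(), false), hs(ss.size(), false);
  std::vector<double> buf;
  NumericVector out(qi.size());
  for (int p = 0; p < qi.size(); ++p) {
    const int i = qi[p] - 1, j = si[p] - 1;
    if (i < 0 || i >= qs.size() || j < 0 || j >= ss.size())
      stop("pair index out of range");
    if (!hq[i]) { eq[i] = encode_seq(as<std::string>(qs[i]), lut, xidx); hq[i] = true; }
    if (!hs[j]) { es[j] = encode_seq(as<std::string>(ss[j]), lut, xidx); hs[j] = true; }
    if (eq[i].empty() || es[j].empty()) stop("empty sequence in alignment input");
    out[p] = gotoh_score(eq[i], es[j], sub, gap_open, gap_ext, buf);
  }
  return out;
}
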