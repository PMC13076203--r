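#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Scalar affine-gap Smith-Waterman over a generic residue alphabet.
// Gap of length L costs gap_open + L * gap_ext (BLAST-style 11/1 convention).
// The DP fill keeps one rolling row for H plus a column array for F and
// records packed per-cell traceback bits, so the optimal local alignment can
// be recovered without storing the score matrices. Identities are counted on
// the traceback path only for residues flagged as unambiguous (ambiguity
// codes never count as identical even when equal).

namespace {

struct AlnResult {
  int score, identities, columns;
  int qstart, qend, tstart, tend; // 0-based half-open
  std::string qaln, taln;
};

// traceback byte per cell:
//   bits 0-1: H source (0 = zero/stop, 1 = diagonal, 2 = E, 3 = F)
//   bit 2: E extends a previous E (gap in query continues)
//   bit 3: F extends a previous F (gap in target continues)
const unsigned char H_DIAG = 1, H_E = 2, H_F = 3, E_EXT = 4, F_EXT = 8;
const int NEG_INF = -1000000000;

struct Scratch {
  std::vector<int> H, F;
  std::vector<unsigned char> tb;
};

AlnResult sw_one(const std::vector<int>& q, const std::vector<int>& t,
                 const int* sm, const std::vector<bool>& ident_ok,
                 int go, int ge, bool keep_aln,
                 const std::string& qs, const std::string& ts, Scratch& sc) {
  const int m = (int)q.size(), n = (int)t.size();
  const int gapfirst = go + ge;
  sc.H.assign(n + 1, 0);
  sc.F.assign(n + 1, NEG_INF);
  sc.tb.resize((size_t)m * n);
  int* H = sc.H.data();
  int* F = sc.F.data();

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* row = sm + 32 * q[i - 1];
    unsigned char* tbr = sc.tb.data() + (size_t)(i - 1) * n;
    int hdiag = H[0]; // H[i-1][0] = 0
    int e = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      const int htop = H[j]; // H[i-1][j]
      // E[i][j]: gap in query, from the left
      int e_open = H[j - 1] - gapfirst;
      int e_ext = e - ge;
      unsigned char bits = 0;
      if (e_ext > e_open) { e = e_ext; bits |= E_EXT; }
      else e = e_open;
      // F[i][j]: gap in target, from above
      int f_open = htop - gapfirst;
      int f_ext = F[j] - ge;
      int f;
      if (f_ext > f_open) { f = f_ext; bits |= F_EXT; }
      else f = f_open;
      F[j] = f;
      int d = hdiag + row[t[j - 1]];
      int h = d; unsigned char src = H_DIAG;
      if (e > h) { h = e; src = H_E; }
      if (f > h) { h = f; src = H_F; }
      if (h <= 0) { h = 0; src = 0; }
      tbr[j - 1] = bits | src;
      hdiag = htop;
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult r;
  r.score = best;
  r.identities = 0;
  r.columns = 0;
  if (best == 0) {
    r.qstart = r.qend = r.tstart = r.tend = 0;
    return r;
  }
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  std::string qa, ta;
  const unsigned char* tb = sc.tb.data();
  while (i > 0 && j > 0) {
    unsigned char cell = tb[(size_t)(i - 1) * n + (j - 1)];
    if (state == 0) {
      unsigned char src = cell & 3;
      if (src == 0) break;
      if (src == H_DIAG) {
        ++r.columns;
        if (q[i - 1] == t[j - 1] && ident_ok[q[i - 1]]) ++r.identities;
        if (keep_aln) { qa.push_back(qs[i - 1]); ta.push_back(ts[j - 1]); }
        --i; --j;
      } else if (src == H_E) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in query, consume target residue
      ++r.columns;
      if (keep_aln) { qa.push_back('-'); ta.push_back(ts[j - 1]); }
      state = (cell & E_EXT) ? 1 : 0;
      --j;
    } else { // gap in target, consume query residue
      ++r.columns;
      if (keep_aln) { qa.push_back(qs[i - 1]); ta.push_back('-'); }
      state = (cell & F_EXT) ? 2 : 0;
      --i;
    }
  }
  r.qstart = i; r.qend = bi;   // half-open on 0-based residues
  r.tstart = j; r.tend = bj;
  if (keep_aln) {
    r.qaln.assign(qa.rbegin(), qa.rend());
    r.taln.assign(ta.rbegin(), ta.rend());
  }
  return r;
}

std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    int c = lut[(unsigned char)s[k]];
    v[k] = c < 0 ? lut[(unsigned char)'X'] : c;
  }
  return v;
}

} // namespace

// [[Rcpp::export]]
List cc_sw_batch(CharacterVector query, CharacterVector target,
                 IntegerMatrix submat, std::string alphabet,
                 LogicalVector unambiguous, int gap_open, int gap_ext,
                 bool keep_aln) {
  const int np = query.size();
  if (target.size() != np) stop("query/target length mismatch");
  const int na = (int)alphabet.size();
  if (na > 32 || submat.nrow() != na || submat.ncol() != na) {
    stop("substitution matrix does not match the alphabet");
  }
  std::vector<int> lut(256, -1);
  for (int k = 0; k < na; ++k) lut[(unsigned char)alphabet[k]] = k;
  std::vector<bool> ident_ok(na);
  for (int k = 0; k < na; ++k) ident_ok[k] = unambiguous[k];
  // flat 32x32 substitution table for tight inner-loop access
  std::vector<int> sm(32 * 32, 0);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) sm[32 * a + b] = submat(a, b);

  Scratch scratch;
  IntegerVector score(np), identities(np), columns(np),
      qstart(np), qend(np), tstart(np), tend(np);
  CharacterVector qaln(np), taln(np);
  for (int p = 0; p < np; ++p) {
    std::string qs = as<std::string>(query[p]), ts = as<std::string>(target[p]);
    AlnResult r = sw_one(encode(qs, lut), encode(ts, lut), sm.data(), ident_ok,
                         gap_open, gap_ext, keep_aln, qs, ts, scratch);
    score[p] = r.score; identities[p] = r.identities; columns[p] = r.columns;
    // 1-based inclusive coordinates in the returned table
    qstart[p] = r.qstart + 1; qend[p] = r.qend;
    tstart[p] = r.tstart + 1; tend[p] = r.tend;
    if (keep_aln) { qaln[p] = r.qaln; taln[p] = r.taln; }
  }
  List out = List::create(
      _["score"] = score, _["identities"] = identities, _["columns"] = columns,
      _["qstart"] = qstart, _["qend"] = qend, _["tstart"] = tstart,
      _["tend"] = tend);
  if (keep_aln) { out["qaln"] = qaln; out["taln"] = taln; }
  return out;
}
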