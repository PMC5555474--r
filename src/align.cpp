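#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Gotoh affine-gap alignment with a packed one-byte-per-cell traceback.
// A gap of length L costs gap_open + L * gap_ext.
//
// Layers: M  = a[i] aligned to b[j]
//         GQ = gap in query a (consumes b[j])
//         GR = gap in reference b (consumes a[i])
// Tie-breaking is fixed: diagonal > gap-in-query > gap-in-reference,
// and open-from-M preferred over extend on equal score.
//
// Traceback byte layout:
//   bits 0-1: M predecessor (0 = M, 1 = GQ, 2 = GR, 3 = fresh start/local)
//   bit  2  : GQ predecessor (0 = open from M, 1 = extend)
//   bit  3  : GR predecessor (0 = open from M, 1 = extend)

static const int NEG_INF = -1073741824;  // large negative, safe from overflow

struct AlnResult {
  std::string ga, gb;
  int score;
  int a_start, a_end, b_start, b_end;  // 1-based inclusive; 0 when empty
};

static inline int subst(char x, char y, int match, int mismatch) {
  return (x == y) ? match : mismatch;
}

static AlnResult gotoh(const std::string& a, const std::string& b,
                       int match, int mismatch, int gap_open, int gap_ext,
                       bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  std::vector<int> Mprev(m + 1), Mcur(m + 1);
  std::vector<int> Qprev(m + 1), Qcur(m + 1);   // gap in query
  std::vector<int> Rprev(m + 1), Rcur(m + 1);   // gap in reference

  Mprev[0] = 0;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = local ? 0 : NEG_INF;
    Qprev[j] = local ? NEG_INF : -(gap_open + j * gap_ext);
    Rprev[j] = NEG_INF;
  }
  Qprev[0] = NEG_INF;
  Rprev[0] = NEG_INF;

  int best = 0, besti = 0, bestj = 0;  // local optimum tracker

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = local ? 0 : NEG_INF;
    Qcur[0] = NEG_INF;
    Rcur[0] = local ? NEG_INF : -(gap_open + i * gap_ext);
    uint8_t* row = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      // M layer: diagonal predecessor, preference M > GQ > GR (> start)
      int diag = Mprev[j - 1]; int dsel = 0;
      if (Qprev[j - 1] > diag) { diag = Qprev[j - 1]; dsel = 1; }
      if (Rprev[j - 1] > diag) { diag = Rprev[j - 1]; dsel = 2; }
      if (local && diag < 0) { diag = 0; dsel = 3; }
      Mcur[j] = diag + subst(a[i - 1], b[j - 1], match, mismatch);
      t |= (uint8_t)dsel;

      // GQ layer: consumes b[j], open-from-M preferred on tie
      int qo = Mcur[j - 1] == NEG_INF ? NEG_INF : Mcur[j - 1] - gap_open - gap_ext;
      int qe = Qcur[j - 1] == NEG_INF ? NEG_INF : Qcur[j - 1] - gap_ext;
      if (qo >= qe) { Qcur[j] = qo; } else { Qcur[j] = qe; t |= 4; }

      // GR layer: consumes a[i]
      int ro = Mprev[j] == NEG_INF ? NEG_INF : Mprev[j] - gap_open - gap_ext;
      int re = Rprev[j] == NEG_INF ? NEG_INF : Rprev[j] - gap_ext;
      if (ro >= re) { Rcur[j] = ro; } else { Rcur[j] = re; t |= 8; }

      row[j] = t;
      if (local && Mcur[j] > best) { best = Mcur[j]; besti = i; bestj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Qprev, Qcur); std::swap(Rprev, Rcur);
  }

  AlnResult res;
  int i, j, layer;  // layer: 0 = M, 1 = GQ, 2 = GR
  if (local) {
    res.score = best;
    if (best <= 0) {  // no positive-scoring pair
      res.a_start = res.a_end = res.b_start = res.b_end = 0;
      return res;
    }
    i = besti; j = bestj; layer = 0;
    res.a_end = besti; res.b_end = bestj;
  } else {
    // after the final swap, *prev holds row n
    int sc = Mprev[m]; layer = 0;
    if (Qprev[m] > sc) { sc = Qprev[m]; layer = 1; }
    if (Rprev[m] > sc) { sc = Rprev[m]; layer = 2; }
    res.score = sc;
    i = n; j = m;
    res.a_end = n; res.b_end = m;
  }

  std::string ga, gb;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (!local) {
      if (i == 0) layer = 1;       // only gap-in-query moves remain
      else if (j == 0) layer = 2;  // only gap-in-reference moves remain
    }
    if (layer == 0) {
      int dsel = t & 3;
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
      if (local && dsel == 3) break;  // fresh start: alignment begins here
      layer = dsel;
    } else if (layer == 1) {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      layer = (t & 4) ? 1 : 0;
      --j;
    } else {
      ga.push_back(a[i - 1]); gb.push_back('-');
      layer = (t & 8) ? 2 : 0;
      --i;
    }
    if (local && layer == 0 && (i == 0 || j == 0)) break;
  }
  res.a_start = local ? i + 1 : 1;
  res.b_start = local ? j + 1 : 1;
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  res.ga = ga; res.gb = gb;
  return res;
}

// [[Rcpp::export(name = ".cpp_align_global")]]
List cpp_align_global(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult r = gotoh(a, b, match, mismatch, gap_open, gap_ext, false);
  return List::create(_["query"] = r.ga, _["reference"] = r.gb,
                      _["score"] = r.score);
}

// [[Rcpp::export(name = ".cpp_align_local")]]
List cpp_align_local(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult r = gotoh(a, b, match, mismatch, gap_open, gap_ext, true);
  return List::create(_["query"] = r.ga, _["reference"] = r.gb,
                      _["score"] = r.score,
                      _["query_start"] = r.a_start, _["query_end"] = r.a_end,
                      _["ref_start"] = r.b_start, _["ref_end"] = r.b_end);
}
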