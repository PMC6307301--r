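#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Semi-global (end-gap-free) pairwise nucleotide alignment, affine gaps.
// Scoring: match +1, mismatch -1; a gap run of length L costs
// gap_open + (L-1) * gap_ext (defaults 2 and 1). Terminal overhangs are
// free and excluded from the identity denominator; internal gap columns
// count in it. Columns involving N never count as matches (they score
// as mismatches).
//
// Ties are resolved by a symmetric lexicographic objective: maximize
// score, then matches, then minimize aligned columns. Identity and
// overlap are read off the optimal value tuple, so the result is
// deterministic and invariant under swapping the two sequences.

struct Cell {
  double score;
  int matches;
  int columns;
  bool valid;
};

static inline bool better(const Cell &a, const Cell &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.columns < b.columns;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static const Cell INVALID = {0.0, 0, 0, false};

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap_open = 2.0, double gap_ext = 1.0) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) stop("sequences must be non-empty");

  // rolling rows over j = 0..lb for the three states:
  // M ends in an aligned pair, X in a gap in b (consumes a), Y in a gap
  // in a (consumes b); borders are free start points (value 0)
  std::vector<Cell> Mprev(lb + 1), Mcur(lb + 1), Xprev(lb + 1), Xcur(lb + 1),
      Yprev(lb + 1), Ycur(lb + 1);
  const Cell START = {0.0, 0, 0, true};
  for (int j = 0; j <= lb; ++j) { Mprev[j] = START; Xprev[j] = Yprev[j] = INVALID; }

  Cell best = INVALID;

  for (int i = 1; i <= la; ++i) {
    Mcur[0] = START; Xcur[0] = Ycur[0] = INVALID;
    const char ca = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const char cb = b[j - 1];
      const bool mt = (ca == cb) && is_acgt(ca) && is_acgt(cb);
      const double s = mt ? match : mismatch;
      // M from best of M/X/Y at (i-1, j-1)
      Cell pred = Mprev[j - 1];
      if (better(Xprev[j - 1], pred)) pred = Xprev[j - 1];
      if (better(Yprev[j - 1], pred)) pred = Yprev[j - 1];
      Cell m = INVALID;
      if (pred.valid) {
        m.valid = true;
        m.score = pred.score + s;
        m.matches = pred.matches + (mt ? 1 : 0);
        m.columns = pred.columns + 1;
      }
      Mcur[j] = m;
      // X: gap in b, consumes a[i]
      Cell xo = Mprev[j], xe = Xprev[j];
      if (xo.valid) { xo.score -= gap_open; xo.columns += 1; }
      if (xe.valid) { xe.score -= gap_ext; xe.columns += 1; }
      Xcur[j] = better(xo, xe) ? xo : xe;
      // Y: gap in a, consumes b[j]
      Cell yo = Mcur[j - 1], ye = Ycur[j - 1];
      if (yo.valid) { yo.score -= gap_open; yo.columns += 1; }
      if (ye.valid) { ye.score -= gap_ext; ye.columns += 1; }
      Ycur[j] = better(yo, ye) ? yo : ye;
      // endpoints: any M cell on the last row or last column
      if ((i == la || j == lb) && better(Mcur[j], best)) best = Mcur[j];
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (!best.valid || best.columns == 0) {
    return List::create(_["identity"] = 0.0, _["overlap"] = 0,
                        _["matches"] = 0, _["score"] = 0.0);
  }
  return List::create(_["identity"] = (double)best.matches / best.columns,
                      _["overlap"] = best.columns,
                      _["matches"] = best.matches,
                      _["score"] = best.score);
}
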