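#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded semi-global alignment (Gotoh affine gaps): the query is aligned
// globally, the reference locally (free leading/trailing reference skip), as
// needed when mapping short fragments inside near-full-length rRNA
// references. A gap of length L costs gap_open + L * gap_ext. Cells with
// |j - i - offset| > band are unreachable.
//
// States: M = query base aligned to reference base; X = query base against a
// gap (insertion in query relative to the reference); Y = reference base
// against a gap (deletion from the query).

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export]]
List banded_semiglobal_align(std::string query, std::string ref,
                             int band, int offset,
                             int match, int mismatch,
                             int gap_open, int gap_ext) {
  const int m = (int)query.size();
  const int n = (int)ref.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int go = gap_open + gap_ext;  // cost of the first gapped base
  const int ge = gap_ext;

  std::vector<int> M((m + 1) * (n + 1), NEG);
  std::vector<int> X((m + 1) * (n + 1), NEG);
  std::vector<int> Y((m + 1) * (n + 1), NEG);
  // traceback: predecessor state per cell/state (0=M, 1=X, 2=Y, 3=start)
  std::vector<signed char> tbM((m + 1) * (n + 1), -1);
  std::vector<signed char> tbX((m + 1) * (n + 1), -1);
  std::vector<signed char> tbY((m + 1) * (n + 1), -1);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  // row 0: alignment may start after skipping any reference prefix for free
  for (int j = 0; j <= n; ++j) {
    M[at(0, j)] = 0;
    tbM[at(0, j)] = 3;
  }

  for (int i = 1; i <= m; ++i) {
    long lo = (long)i + offset - band;
    long hi = (long)i + offset + band;
    int jlo = lo < 0 ? 0 : (int)lo;
    int jhi = hi > n ? n : (int)hi;
    if (jlo > jhi) continue;
    for (int j = jlo; j <= jhi; ++j) {
      // X: consume query base i against a gap
      {
        int fromM = M[at(i - 1, j)] == NEG ? NEG : M[at(i - 1, j)] - go;
        int fromX = X[at(i - 1, j)] == NEG ? NEG : X[at(i - 1, j)] - ge;
        int fromY = Y[at(i - 1, j)] == NEG ? NEG : Y[at(i - 1, j)] - go;
        int best = fromM; signed char tb = 0;
        if (fromX > best) { best = fromX; tb = 1; }
        if (fromY > best) { best = fromY; tb = 2; }
        if (best > NEG) { X[at(i, j)] = best; tbX[at(i, j)] = tb; }
      }
      if (j >= 1) {
        // Y: consume reference base j against a gap
        int fromM = M[at(i, j - 1)] == NEG ? NEG : M[at(i, j - 1)] - go;
        int fromY = Y[at(i, j - 1)] == NEG ? NEG : Y[at(i, j - 1)] - ge;
        int fromX = X[at(i, j - 1)] == NEG ? NEG : X[at(i, j - 1)] - go;
        int best = fromM; signed char tb = 0;
        if (fromY > best) { best = fromY; tb = 2; }
        if (fromX > best) { best = fromX; tb = 1; }
        if (best > NEG) { Y[at(i, j)] = best; tbY[at(i, j)] = tb; }
        // M: align query base i to reference base j
        int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
        int dM = M[at(i - 1, j - 1)];
        int dX = X[at(i - 1, j - 1)];
        int dY = Y[at(i - 1, j - 1)];
        int bestd = dM; signed char tb2 = 0;
        if (dX > bestd) { bestd = dX; tb2 = 1; }
        if (dY > bestd) { bestd = dY; tb2 = 2; }
        if (bestd > NEG) { M[at(i, j)] = bestd + s; tbM[at(i, j)] = tb2; }
      }
    }
  }

  // the trailing reference suffix is free: take the best cell in the last
  // row over states M and X (an alignment never usefully ends in Y)
  int best_j = -1, best_state = -1;
  int best_score = NEG;
  for (int j = 0; j <= n; ++j) {
    if (M[at(m, j)] > best_score) { best_score = M[at(m, j)]; best_j = j; best_state = 0; }
    if (X[at(m, j)] > best_score) { best_score = X[at(m, j)]; best_j = j; best_state = 1; }
  }
  if (best_j < 0 || best_score <= NEG)
    stop("no alignment found within the band; widen the band or reseed");

  // traceback
  std::string aq, ar;
  std::vector<std::string> ops;
  int i = m, j = best_j, state = best_state;
  while (!(i == 0)) {
    if (state == 0) {
      signed char tb = tbM[at(i, j)];
      if (tb == 3) break;  // start sentinel at row 0 only
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      ops.push_back(query[i - 1] == ref[j - 1] ? "match" : "mismatch");
      --i; --j; state = tb;
    } else if (state == 1) {
      signed char tb = tbX[at(i, j)];
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      ops.push_back("insertion");
      --i; state = tb;
    } else {
      signed char tb = tbY[at(i, j)];
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      ops.push_back("deletion");
      --j; state = tb;
    }
  }
  int ref_start = j;
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  std::reverse(ops.begin(), ops.end());

  return List::create(
    _["score"] = best_score,
    _["aligned_query"] = aq,
    _["aligned_ref"] = ar,
    _["ops"] = ops,
    _["query_start"] = 0,
    _["query_end"] = m,
    _["ref_start"] = ref_start,
    _["ref_end"] = best_j
  );
}
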