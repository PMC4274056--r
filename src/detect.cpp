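#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Descending multi-threshold region growing.
//
// For t = t_start, t_start - step, ..., t_min (the final round always runs at
// exactly t_min even if the step overshoots):
//   1. candidates = in-mask, unassigned pixels with intensity >= t
//   2. EXPANSION to a fixed point: synchronous dilation passes; a candidate
//      with at least one assigned neighbour joins the punctum of the
//      brightest adjacent assigned pixel (ties -> lowest label). Pixels
//      assigned in one pass can recruit neighbours in the next pass of the
//      same round.
//   3. FORMATION: remaining candidates are grouped into connected
//      components; components with >= min_size pixels become new puncta,
//      labelled in row-major order of each component's topmost-leftmost
//      pixel. Smaller components stay unassigned for later rounds.
//
// "Above threshold" is inclusive (>= t). Adjacency is 4- or 8-connectivity.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export(name = ".detect_puncta_cpp")]]
IntegerMatrix detect_puncta_cpp(IntegerMatrix channel, LogicalMatrix mask,
                                int t_start, int t_min, int step,
                                int min_size, int connectivity) {
  const int nr = channel.nrow(), nc = channel.ncol();
  IntegerMatrix labels(nr, nc); // 0 = unassigned
  int next_label = 1;

  int ndir;
  int dr[8], dc[8];
  if (connectivity == 8) {
    ndir = 8;
    for (int k = 0; k < 8; ++k) { dr[k] = DR8[k]; dc[k] = DC8[k]; }
  } else {
    ndir = 4;
    dr[0] = -1; dc[0] = 0; dr[1] = 1; dc[1] = 0;
    dr[2] = 0; dc[2] = -1; dr[3] = 0; dc[3] = 1;
  }

  std::vector<int> comp_stack;
  std::vector<unsigned char> cand(nr * nc, 0);
  std::vector<int> newlab(nr * nc);

  int t = t_start;
  bool last_round = false;
  while (true) {
    if (t <= t_min) { t = t_min; last_round = true; }

    // candidate mask for this round
    int ncand = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        bool c = mask(i, j) && labels(i, j) == 0 && channel(i, j) >= t;
        cand[i + j * nr] = c ? 1 : 0;
        if (c) ++ncand;
      }

    if (ncand > 0 && next_label > 1) {
      // EXPANSION: synchronous dilation passes until fixed point
      bool changed = true;
      while (changed) {
        changed = false;
        int nnew = 0;
        for (int j = 0; j < nc; ++j)
          for (int i = 0; i < nr; ++i) {
            if (!cand[i + j * nr]) continue;
            int best_lab = 0, best_int = -1;
            for (int k = 0; k < ndir; ++k) {
              int ii = i + dr[k], jj = j + dc[k];
              if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
              int lab = labels(ii, jj);
              if (lab == 0) continue;
              int v = channel(ii, jj);
              if (v > best_int || (v == best_int && lab < best_lab)) {
                best_int = v;
                best_lab = lab;
              }
            }
            if (best_lab > 0) {
              newlab[nnew * 2] = i + j * nr;
              newlab[nnew * 2 + 1] = best_lab;
              ++nnew;
            }
          }
        for (int m = 0; m < nnew; ++m) {
          int idx = newlab[m * 2];
          labels(idx % nr, idx / nr) = newlab[m * 2 + 1];
          cand[idx] = 0;
          changed = true;
        }
      }
    }

    // FORMATION: connected components of remaining candidates, scanned in
    // row-major order so the component seed is its topmost-leftmost pixel
    if (ncand > 0) {
      std::vector<unsigned char> seen(nr * nc, 0);
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) {
          int idx0 = i + j * nr;
          if (!cand[idx0] || seen[idx0]) continue;
          comp_stack.clear();
          comp_stack.push_back(idx0);
          seen[idx0] = 1;
          size_t head = 0;
          while (head < comp_stack.size()) {
            int idx = comp_stack[head++];
            int ci = idx % nr, cj = idx / nr;
            for (int k = 0; k < ndir; ++k) {
              int ii = ci + dr[k], jj = cj + dc[k];
              if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
              int nidx = ii + jj * nr;
              if (cand[nidx] && !seen[nidx]) {
                seen[nidx] = 1;
                comp_stack.push_back(nidx);
              }
            }
          }
          if ((int)comp_stack.size() >= min_size) {
            int lab = next_label++;
            for (size_t m = 0; m < comp_stack.size(); ++m) {
              int idx = comp_stack[m];
              labels(idx % nr, idx / nr) = lab;
              cand[idx] = 0;
            }
          }
          // sub-min_size components stay candidates in later rounds
        }
    }

    if (last_round) break;
    t -= step;
  }
  return labels;
}
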