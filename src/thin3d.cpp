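#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D curve thinning by sequential deletion of simple border points.
//
// A voxel is "simple" (deletable without changing topology) iff, in its
// 3x3x3 neighbourhood, (a) the foreground voxels form exactly one
// 26-connected component, and (b) the background voxels of the
// 18-neighbourhood form exactly one 6-connected component touching a face
// neighbour (Malandain & Bertrand characterisation). Endpoints (<= 1
// foreground 26-neighbour) are preserved so tubes thin to centrelines.
// Deletion is scheduled in six directional sub-iterations, with the simple
// test re-evaluated at deletion time, which keeps the skeleton centred and
// connectivity intact.

static const int NB = 27;

static inline int off(int dd, int dh, int dw) {
  return (dd + 1) + 3 * (dh + 1) + 9 * (dw + 1);
}

static void decode(int i, int& dd, int& dh, int& dw) {
  dd = i % 3 - 1; dh = (i / 3) % 3 - 1; dw = i / 9 - 1;
}

static int count26components(const int* nb) {
  int label[NB]; for (int i = 0; i < NB; ++i) label[i] = 0;
  int ncomp = 0;
  for (int i = 0; i < NB; ++i) {
    if (i == 13 || !nb[i] || label[i]) continue;
    ++ncomp;
    std::vector<int> stack(1, i);
    label[i] = ncomp;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cd, ch, cw; decode(cur, cd, ch, cw);
      for (int j = 0; j < NB; ++j) {
        if (j == 13 || !nb[j] || label[j]) continue;
        int jd, jh, jw; decode(j, jd, jh, jw);
        int a = std::abs(cd - jd), b = std::abs(ch - jh), c = std::abs(cw - jw);
        if (a <= 1 && b <= 1 && c <= 1) { label[j] = ncomp; stack.push_back(j); }
      }
    }
  }
  return ncomp;
}

static int count6componentsBg18(const int* nb) {
  // 6-components of background restricted to the 18-neighbourhood, counting
  // only components that include a face neighbour.
  int label[NB]; for (int i = 0; i < NB; ++i) label[i] = 0;
  int ncomp = 0;
  for (int i = 0; i < NB; ++i) {
    int id, ih, iw; decode(i, id, ih, iw);
    int nz = (id != 0) + (ih != 0) + (iw != 0);
    if (i == 13 || nz > 2 || nb[i] || label[i]) continue;
    if (nz != 1) continue;  // grow components from face neighbours only
    ++ncomp;
    std::vector<int> stack(1, i);
    label[i] = ncomp;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cd, ch, cw; decode(cur, cd, ch, cw);
      for (int j = 0; j < NB; ++j) {
        int jd, jh, jw; decode(j, jd, jh, jw);
        int jnz = (jd != 0) + (jh != 0) + (jw != 0);
        if (j == 13 || jnz > 2 || nb[j] || label[j]) continue;
        int a = std::abs(cd - jd) + std::abs(ch - jh) + std::abs(cw - jw);
        if (a == 1) { label[j] = ncomp; stack.push_back(j); }
      }
    }
  }
  return ncomp;
}

class Grid {
public:
  const int D, H, W;
  std::vector<int> v;
  Grid(IntegerVector mask, int D_, int H_, int W_) : D(D_), H(H_), W(W_), v(D_ * H_ * W_) {
    for (int i = 0; i < D * H * W; ++i) v[i] = mask[i] != 0;
  }
  inline int at(int d, int h, int w) const {
    if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) return 0;
    return v[d + D * (h + H * w)];
  }
  void neighborhood(int d, int h, int w, int* nb) const {
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh)
        for (int dd = -1; dd <= 1; ++dd)
          nb[off(dd, dh, dw)] = at(d + dd, h + dh, w + dw);
  }
};

static bool isSimple(const Grid& g, int d, int h, int w) {
  int nb[NB];
  g.neighborhood(d, h, w, nb);
  if (count26components(nb) != 1) return false;
  return count6componentsBg18(nb) == 1;
}

static int fgNeighbors26(const Grid& g, int d, int h, int w) {
  int n = 0;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (!dd && !dh && !dw) continue;
        n += g.at(d + dd, h + dh, w + dw);
      }
  return n;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask) {
  IntegerVector md = mask.attr("dim");
  const int D = md[0], H = md[1], W = md[2];
  Grid g(mask, D, H, W);

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<int> cand;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int d = 0; d < D; ++d) {
            if (!g.at(d, h, w)) continue;
            if (g.at(d + dirs[dir][0], h + dirs[dir][1], w + dirs[dir][2])) continue;
            if (fgNeighbors26(g, d, h, w) <= 1) continue;  // endpoint
            if (!isSimple(g, d, h, w)) continue;
            cand.push_back(d + D * (h + H * w));
          }
      for (size_t i = 0; i < cand.size(); ++i) {
        int d = cand[i] % D, h = (cand[i] / D) % H, w = cand[i] / (D * H);
        if (fgNeighbors26(g, d, h, w) <= 1) continue;
        if (!isSimple(g, d, h, w)) continue;
        g.v[cand[i]] = 0;
        changed = true;
      }
    }
  }

  IntegerVector out(D * H * W);
  for (int i = 0; i < D * H * W; ++i) out[i] = g.v[i];
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}
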