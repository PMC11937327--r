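#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact nearest-vertex search on the unit sphere.
//
// References are sorted by z once; each query walks outward from the
// closest z-slab and stops as soon as the remaining slab distance alone
// exceeds the best squared distance found.  Exact (no approximation);
// ties at exactly equal squared distance resolve to the lowest original
// reference index, matching the brute-force scan convention.
//
// Returns 1-based indices into the rows of V.
// [[Rcpp::export(name = ".nn_index_cpp")]]
IntegerVector nn_index_cpp(const NumericMatrix& Q, const NumericMatrix& V) {
  const int nq = Q.nrow(), nv = V.nrow();
  if (nv == 0) stop("reference vertex set is empty");
  std::vector<int> ord(nv);
  for (int j = 0; j < nv; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return V(a, 2) < V(b, 2); });
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int j = 0; j < nv; ++j) {
    const int o = ord[j];
    vx[j] = V(o, 0); vy[j] = V(o, 1); vz[j] = V(o, 2);
  }
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    int lo = 0, hi = nv;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (vz[mid] < qz) lo = mid + 1; else hi = mid;
    }
    double best = R_PosInf;
    int bi = nv;  // sentinel larger than any real index
    int up = lo, down = lo - 1;
    for (;;) {
      bool advanced = false;
      if (up < nv) {
        const double dz = vz[up] - qz;
        if (dz * dz <= best) {
          const double dx = vx[up] - qx, dy = vy[up] - qy;
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best || (d2 == best && ord[up] < bi)) { best = d2; bi = ord[up]; }
          ++up;
          advanced = true;
        }
      }
      if (down >= 0) {
        const double dz = vz[down] - qz;
        if (dz * dz <= best) {
          const double dx = vx[down] - qx, dy = vy[down] - qy;
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best || (d2 == best && ord[down] < bi)) { best = d2; bi = ord[down]; }
          --down;
          advanced = true;
        }
      }
      if (!advanced) break;
    }
    out[i] = bi + 1;
  }
  return out;
}
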