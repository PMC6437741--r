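#include <Rcpp.h>
using namespace Rcpp;

// Box-window sums with edge-replicating padding.
// Window is k x k (k odd) centred on each pixel; implemented with a
// summed-area table built over the replicate-padded matrix.
// [[Rcpp::export(name = ".box_sum_c")]]
NumericMatrix box_sum_c(NumericMatrix m, int k) {
  int nr = m.nrow(), nc = m.ncol();
  int p = k / 2;
  int pr = nr + 2 * p, pc = nc + 2 * p;
  // padded cumulative sums, (pr+1) x (pc+1) with leading zero row/col
  std::vector<double> sat((pr + 1) * (pc + 1), 0.0);
  for (int j = 0; j < pc; ++j) {
    int js = std::min(std::max(j - p, 0), nc - 1);
    for (int i = 0; i < pr; ++i) {
      int is = std::min(std::max(i - p, 0), nr - 1);
      double v = m(is, js);
      sat[(i + 1) + (j + 1) * (pr + 1)] =
        v + sat[i + (j + 1) * (pr + 1)] + sat[(i + 1) + j * (pr + 1)] -
        sat[i + j * (pr + 1)];
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = j, j1 = j + k;  // in padded coords: [j, j+k)
    for (int i = 0; i < nr; ++i) {
      int i0 = i, i1 = i + k;
      out(i, j) = sat[i1 + j1 * (pr + 1)] - sat[i0 + j1 * (pr + 1)] -
                  sat[i1 + j0 * (pr + 1)] + sat[i0 + j0 * (pr + 1)];
    }
  }
  return out;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Curvature div(grad(phi)/|grad(phi)|) by central differences with
// replicated edges; |grad(phi)| floored at `floor_mag`.
// [[Rcpp::export(name = ".curvature_c")]]
NumericMatrix curvature_c(NumericMatrix phi, double floor_mag) {
  int nr = phi.nrow(), nc = phi.ncol();
  NumericMatrix nx(nr, nc), ny(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      double gx = (phi(i, jp) - phi(i, jm)) / 2.0;  // x = column
      double gy = (phi(ip, j) - phi(im, j)) / 2.0;  // y = row
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag < floor_mag) mag = floor_mag;
      nx(i, j) = gx / mag;
      ny(i, j) = gy / mag;
    }
  }
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      out(i, j) = (nx(i, jp) - nx(i, jm)) / 2.0 + (ny(ip, j) - ny(im, j)) / 2.0;
    }
  }
  return out;
}

// One round of SLIC-style cluster assignment: for each cluster centre,
// scan a (2S)x(2S) neighbourhood and keep the per-pixel argmin of
// d = d_feature^2 + (compactness/S)^2 * d_xy^2 over clusters.
// feats: npix x nf (row-major pixel order matching R matrix layout,
// i.e. pixel index = i + j*nr), centres: K x (2+nf) as (row, col, feats).
// [[Rcpp::export(name = ".slic_assign_c")]]
IntegerMatrix slic_assign_c(NumericMatrix feats, NumericMatrix centres,
                            int nr, int nc, double S, double compactness) {
  int K = centres.nrow();
  int nf = feats.ncol();
  std::vector<double> best(nr * nc, R_PosInf);
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), NA_INTEGER);
  double wxy = (compactness / S) * (compactness / S);
  int R = (int)std::ceil(2.0 * S);
  for (int kcl = 0; kcl < K; ++kcl) {
    double cr = centres(kcl, 0), cc = centres(kcl, 1);
    int i0 = clampi((int)std::floor(cr - R), 0, nr - 1);
    int i1 = clampi((int)std::ceil(cr + R), 0, nr - 1);
    int j0 = clampi((int)std::floor(cc - R), 0, nc - 1);
    int j1 = clampi((int)std::ceil(cc + R), 0, nc - 1);
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        int idx = i + j * nr;
        double d = wxy * ((i - cr) * (i - cr) + (j - cc) * (j - cc));
        for (int f = 0; f < nf; ++f) {
          double df = feats(idx, f) - centres(kcl, 2 + f);
          d += df * df;
        }
        if (d < best[idx]) {
          best[idx] = d;
          lab(i, j) = kcl + 1;
        }
      }
    }
  }
  return lab;
}
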