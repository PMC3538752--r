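// [[Rcpp::depends(RcppArmadillo)]]
#include "dti_core.h"
using namespace Rcpp;

// Eigen-decomposition of a batch of tensors given as an N x 6 matrix
// (xx, yy, zz, xy, xz, yz).  Values N x 3 descending; vectors 3 x 3 x N with
// columns e1, e2, e3.
// [[Rcpp::export]]
List cpp_eigen_tensors(NumericMatrix T6) {
    int n = T6.nrow();
    NumericMatrix values(n, 3);
    NumericVector vectors(Dimension(3, 3, n));
    for (int r = 0; r < n; ++r) {
        Tens6 t = { T6(r, 0), T6(r, 1), T6(r, 2), T6(r, 3), T6(r, 4), T6(r, 5) };
        double lam[3], V[9];
        eig3sym(t, lam, V);
        for (int a = 0; a < 3; ++a) {
            values(r, a) = lam[a];
            for (int b = 0; b < 3; ++b) vectors[9 * r + 3 * a + b] = V[3 * a + b];
        }
    }
    return List::create(_["values"] = values, _["vectors"] = vectors);
}

// FA per tensor row (N x 6).
// [[Rcpp::export]]
NumericVector cpp_fa_tensors(NumericMatrix T6) {
    int n = T6.nrow();
    NumericVector fa(n);
    for (int r = 0; r < n; ++r) {
        Tens6 t = { T6(r, 0), T6(r, 1), T6(r, 2), T6(r, 3), T6(r, 4), T6(r, 5) };
        fa[r] = fa_of_tensor(t);
    }
    return fa;
}

// Trilinear interpolation of a tensor field at world-mm points (N x 3).
// Returns N x 6; rows outside the domain are NaN and flagged.
// [[Rcpp::export]]
List cpp_interp_tensor(NumericVector tens, IntegerVector dims,
                       NumericMatrix invAffine, NumericMatrix points) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = points.nrow();
    NumericMatrix out(n, 6);
    LogicalVector inside(n);
    const double* T = tens.begin();
    const double* invA = invAffine.begin();
    for (int r = 0; r < n; ++r) {
        Tens6 t;
        bool ok = interp_tensor(T, nx, ny, nz, invA,
                                points(r, 0), points(r, 1), points(r, 2), t);
        inside[r] = ok;
        const double* o = &t.xx;
        for (int c = 0; c < 6; ++c) out(r, c) = ok ? o[c] : NA_REAL;
    }
    return List::create(_["tensors"] = out, _["inside"] = inside);
}

// Min distance from each query point to a polyline (dense vertex set with
// segments between consecutive vertices); also the nearest vertex index
// (1-based) for tangent lookup.  Used by the phantom rasterizer.
// [[Rcpp::export]]
List cpp_polyline_distance(NumericMatrix points, NumericMatrix curve) {
    int n = points.nrow(), m = curve.nrow();
    NumericVector dist(n);
    IntegerVector nearest(n);
    for (int r = 0; r < n; ++r) {
        double px = points(r, 0), py = points(r, 1), pz = points(r, 2);
        double best = R_PosInf;
        int bestv = 1;
        for (int s = 0; s < m - 1; ++s) {
            double ax = curve(s, 0), ay = curve(s, 1), az = curve(s, 2);
            double bx = curve(s + 1, 0), by = curve(s + 1, 1), bz = curve(s + 1, 2);
            double ux = bx - ax, uy = by - ay, uz = bz - az;
            double uu = ux * ux + uy * uy + uz * uz;
            double t = 0.0;
            if (uu > 0) {
                t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / uu;
                if (t < 0) t = 0;
                if (t > 1) t = 1;
            }
            double dx = px - (ax + t * ux), dy = py - (ay + t * uy), dz = pz - (az + t * uz);
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (d < best) {
                best = d;
                bestv = (t < 0.5) ? s + 1 : s + 2;  // 1-based nearest vertex
            }
        }
        if (m == 1) {
            double dx = px - curve(0, 0), dy = py - curve(0, 1), dz = pz - curve(0, 2);
            best = std::sqrt(dx * dx + dy * dy + dz * dz);
            bestv = 1;
        }
        dist[r] = best;
        nearest[r] = bestv;
    }
    return List::create(_["distance"] = dist, _["nearest"] = nearest);
}
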