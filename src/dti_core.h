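#ifndef GSTRACT_DTI_CORE_H
#define GSTRACT_DTI_CORE_H

#include <RcppArmadillo.h>

// Symmetric diffusion tensor, 6 unique components.
struct Tens6 {
    double xx, yy, zz, xy, xz, yz;
};

// Tensor fields are stored as R arrays dim = (nx, ny, nz, 6), component
// order xx, yy, zz, xy, xz, yz.  Voxel centers sit at integer 0-based
// indices under the affine; the interpolable domain is [0, n-1] per axis.

inline long vidx(int i, int j, int k, int c, int nx, int ny, int nz) {
    return (long)i + (long)nx * ((long)j + (long)ny * ((long)k + (long)nz * (long)c));
}

// world -> continuous voxel coordinates via the inverse affine (col-major 4x4)
inline void world2voxel(const double* invA, double wx, double wy, double wz,
                        double& vx, double& vy, double& vz) {
    vx = invA[0] * wx + invA[4] * wy + invA[8]  * wz + invA[12];
    vy = invA[1] * wx + invA[5] * wy + invA[9]  * wz + invA[13];
    vz = invA[2] * wx + invA[6] * wy + invA[10] * wz + invA[14];
}

// Component-wise trilinear interpolation of the 6 unique components from the
// 8 surrounding voxel centers.  Returns false outside the center-to-center
// domain (trackers treat that as termination).
inline bool interp_tensor(const double* T, int nx, int ny, int nz,
                          const double* invA, double wx, double wy, double wz,
                          Tens6& out) {
    double vx, vy, vz;
    world2voxel(invA, wx, wy, wz, vx, vy, vz);
    if (!(vx >= 0.0 && vx <= nx - 1.0 &&
          vy >= 0.0 && vy <= ny - 1.0 &&
          vz >= 0.0 && vz <= nz - 1.0))
        return false;
    int i0 = (int)std::floor(vx), j0 = (int)std::floor(vy), k0 = (int)std::floor(vz);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = vx - i0, fy = vy - j0, fz = vz - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
    double* o = &out.xx;
    for (int c = 0; c < 6; ++c) {
        double c00 = T[vidx(i0, j0, k0, c, nx, ny, nz)] * (1 - fx) + T[vidx(i1, j0, k0, c, nx, ny, nz)] * fx;
        double c10 = T[vidx(i0, j1, k0, c, nx, ny, nz)] * (1 - fx) + T[vidx(i1, j1, k0, c, nx, ny, nz)] * fx;
        double c01 = T[vidx(i0, j0, k1, c, nx, ny, nz)] * (1 - fx) + T[vidx(i1, j0, k1, c, nx, ny, nz)] * fx;
        double c11 = T[vidx(i0, j1, k1, c, nx, ny, nz)] * (1 - fx) + T[vidx(i1, j1, k1, c, nx, ny, nz)] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        o[c] = c0 * (1 - fz) + c1 * fz;
    }
    return true;
}

// Eigen-decomposition, eigenvalues descending, eigenvectors as columns of V
// (col-major 3x3).  Degenerate spectra get an arbitrary orthonormal basis.
inline void eig3sym(const Tens6& t, double lam[3], double V[9]) {
    arma::mat33 D;
    D(0, 0) = t.xx; D(1, 1) = t.yy; D(2, 2) = t.zz;
    D(0, 1) = D(1, 0) = t.xy;
    D(0, 2) = D(2, 0) = t.xz;
    D(1, 2) = D(2, 1) = t.yz;
    arma::vec ev;
    arma::mat evec;
    arma::eig_sym(ev, evec, D);   // ascending
    for (int a = 0; a < 3; ++a) {
        lam[a] = ev(2 - a);
        for (int b = 0; b < 3; ++b) V[3 * a + b] = evec(b, 2 - a);
    }
}

// Fractional anisotropy from eigenvalues; negatives clamped to 0, result
// clipped to [0, 1]; all-zero spectrum returns 0 by convention.
inline double fa_from_lambda(double l1, double l2, double l3) {
    if (l1 < 0) l1 = 0;
    if (l2 < 0) l2 = 0;
    if (l3 < 0) l3 = 0;
    double ss = l1 * l1 + l2 * l2 + l3 * l3;
    if (ss <= 0) return 0.0;
    double m = (l1 + l2 + l3) / 3.0;
    double d1 = l1 - m, d2 = l2 - m, d3 = l3 - m;
    double fa = std::sqrt(1.5 * (d1 * d1 + d2 * d2 + d3 * d3) / ss);
    if (fa < 0) fa = 0;
    if (fa > 1) fa = 1;
    return fa;
}

inline double fa_of_tensor(const Tens6& t) {
    double lam[3], V[9];
    eig3sym(t, lam, V);
    return fa_from_lambda(lam[0], lam[1], lam[2]);
}

#endif
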