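// [[Rcpp::depends(RcppArmadillo)]]
#include "dti_core.h"
using namespace Rcpp;

// Deterministic trackers.  Both propagate bidirectionally from the seed at a
// fixed step length and terminate when FA drops below the threshold, on
// leaving the interpolable volume, or at max_steps per direction.
//
// SP: 4th-order Runge-Kutta integration of the major-eigenvector field.
// TD: v_out = normalize(Dhat * v_in), Dhat = D / lambda1.
//
// Eigenvector sign is flipped at every evaluation (including the four RK4
// stages) to keep a non-negative dot product with the incoming direction.

namespace {

struct FieldRef {
    const double* T;
    int nx, ny, nz;
    const double* invA;
};

// principal direction at x, sign-coherent with vprev; false if out of bounds
bool major_dir(const FieldRef& F, const double x[3], const double vprev[3],
               double out[3]) {
    Tens6 t;
    if (!interp_tensor(F.T, F.nx, F.ny, F.nz, F.invA, x[0], x[1], x[2], t))
        return false;
    double lam[3], V[9];
    eig3sym(t, lam, V);
    double dot = V[0] * vprev[0] + V[1] * vprev[1] + V[2] * vprev[2];
    double s = (dot < 0) ? -1.0 : 1.0;
    out[0] = s * V[0]; out[1] = s * V[1]; out[2] = s * V[2];
    return true;
}

bool fa_at(const FieldRef& F, const double x[3], double& fa) {
    Tens6 t;
    if (!interp_tensor(F.T, F.nx, F.ny, F.nz, F.invA, x[0], x[1], x[2], t))
        return false;
    fa = fa_of_tensor(t);
    return true;
}

bool step_sp(const FieldRef& F, const double x[3], const double vprev[3],
             double h, double dir[3]) {
    double k1[3], k2[3], k3[3], k4[3], xt[3];
    if (!major_dir(F, x, vprev, k1)) return false;
    for (int a = 0; a < 3; ++a) xt[a] = x[a] + 0.5 * h * k1[a];
    if (!major_dir(F, xt, k1, k2)) return false;
    for (int a = 0; a < 3; ++a) xt[a] = x[a] + 0.5 * h * k2[a];
    if (!major_dir(F, xt, k2, k3)) return false;
    for (int a = 0; a < 3; ++a) xt[a] = x[a] + h * k3[a];
    if (!major_dir(F, xt, k3, k4)) return false;
    double nv = 0;
    for (int a = 0; a < 3; ++a) {
        dir[a] = (k1[a] + 2 * k2[a] + 2 * k3[a] + k4[a]) / 6.0;
        nv += dir[a] * dir[a];
    }
    if (nv <= 0) return false;
    nv = std::sqrt(nv);
    double dot = 0;
    for (int a = 0; a < 3; ++a) {
        dir[a] /= nv;
        dot += dir[a] * vprev[a];
    }
    if (dot < 0)
        for (int a = 0; a < 3; ++a) dir[a] = -dir[a];
    return true;
}

bool step_td(const FieldRef& F, const double x[3], const double vprev[3],
             double dir[3]) {
    Tens6 t;
    if (!interp_tensor(F.T, F.nx, F.ny, F.nz, F.invA, x[0], x[1], x[2], t))
        return false;
    double lam[3], V[9];
    eig3sym(t, lam, V);
    if (lam[0] <= 0) return false;
    // D/lambda1 * vprev
    double vx = (t.xx * vprev[0] + t.xy * vprev[1] + t.xz * vprev[2]) / lam[0];
    double vy = (t.xy * vprev[0] + t.yy * vprev[1] + t.yz * vprev[2]) / lam[0];
    double vz = (t.xz * vprev[0] + t.yz * vprev[1] + t.zz * vprev[2]) / lam[0];
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nv <= 0) return false;
    dir[0] = vx / nv; dir[1] = vy / nv; dir[2] = vz / nv;
    return true;
}

// one directed half-track; returns points beyond the seed, in order
std::vector<double> half_track(const FieldRef& F, const double seed[3],
                               const double v0[3], double h, double faThr,
                               int maxSteps, int method) {
    std::vector<double> pts;
    double x[3] = { seed[0], seed[1], seed[2] };
    double vprev[3] = { v0[0], v0[1], v0[2] };
    for (int s = 0; s < maxSteps; ++s) {
        double dir[3];
        bool ok = (method == 0) ? step_sp(F, x, vprev, h, dir)
                                : step_td(F, x, vprev, dir);
        if (!ok) break;
        double xn[3] = { x[0] + h * dir[0], x[1] + h * dir[1], x[2] + h * dir[2] };
        double fa;
        if (!fa_at(F, xn, fa) || fa < faThr) break;
        pts.push_back(xn[0]); pts.push_back(xn[1]); pts.push_back(xn[2]);
        x[0] = xn[0]; x[1] = xn[1]; x[2] = xn[2];
        vprev[0] = dir[0]; vprev[1] = dir[1]; vprev[2] = dir[2];
    }
    return pts;
}

} // namespace

// Track one fiber per seed (N x 3 world mm).  method: 0 = SP, 1 = TD.
// Seeds with FA below the threshold yield an empty (0 x 3) fiber; fibers
// with fewer than 2 points are returned as such and filtered in R.
// [[Rcpp::export]]
List cpp_track(NumericVector tens, IntegerVector dims, NumericMatrix invAffine,
               NumericMatrix seeds, double step, double faThr, int maxSteps,
               int method) {
    FieldRef F = { tens.begin(), dims[0], dims[1], dims[2], invAffine.begin() };
    int n = seeds.nrow();
    List out(n);
    for (int r = 0; r < n; ++r) {
        double seed[3] = { seeds(r, 0), seeds(r, 1), seeds(r, 2) };
        double fa;
        Tens6 t;
        if (!fa_at(F, seed, fa) || fa < faThr ||
            !interp_tensor(F.T, F.nx, F.ny, F.nz, F.invA, seed[0], seed[1], seed[2], t)) {
            out[r] = NumericMatrix(0, 3);
            continue;
        }
        double lam[3], V[9];
        eig3sym(t, lam, V);
        double e1[3] = { V[0], V[1], V[2] };
        double e1n[3] = { -V[0], -V[1], -V[2] };
        std::vector<double> fwd = half_track(F, seed, e1, step, faThr, maxSteps, method);
        std::vector<double> bwd = half_track(F, seed, e1n, step, faThr, maxSteps, method);
        int nf = (int)fwd.size() / 3, nb = (int)bwd.size() / 3;
        NumericMatrix fib(nb + 1 + nf, 3);
        for (int i = 0; i < nb; ++i)        // backward half, reversed
            for (int a = 0; a < 3; ++a) fib(i, a) = bwd[3 * (nb - 1 - i) + a];
        for (int a = 0; a < 3; ++a) fib(nb, a) = seed[a];
        for (int i = 0; i < nf; ++i)
            for (int a = 0; a < 3; ++a) fib(nb + 1 + i, a) = fwd[3 * i + a];
        out[r] = fib;
    }
    return out;
}

// Single tensor-deflection direction map, exposed for unit-level checks.
// [[Rcpp::export]]
NumericVector cpp_td_direction(NumericVector tensor6, NumericVector vin) {
    Tens6 t = { tensor6[0], tensor6[1], tensor6[2], tensor6[3], tensor6[4], tensor6[5] };
    double lam[3], V[9];
    eig3sym(t, lam, V);
    if (lam[0] <= 0) stop("tensor has non-positive largest eigenvalue");
    double vx = (t.xx * vin[0] + t.xy * vin[1] + t.xz * vin[2]) / lam[0];
    double vy = (t.xy * vin[0] + t.yy * vin[1] + t.yz * vin[2]) / lam[0];
    double vz = (t.xz * vin[0] + t.yz * vin[1] + t.zz * vin[2]) / lam[0];
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nv <= 0) stop("deflected direction vanished");
    return NumericVector::create(vx / nv, vy / nv, vz / nv);
}
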