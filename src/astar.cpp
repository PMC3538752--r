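// [[Rcpp::depends(RcppArmadillo)]]
#include "dti_core.h"
#include <queue>
#include <unordered_map>
using namespace Rcpp;

// A* minimum-cost path search between two ROIs on a structured lattice.
// The state space is (node, arrival-offset) so the bending-angle constraint
// between adjacent segments is exact.  Edge cost combines the propagation
// probability of the tensor, the divergence from the principal diffusion
// direction and FA, accumulated over the segment length; edges whose
// midpoint FA falls below the threshold are forbidden.

namespace {

// cost = len * clamp(1 - p*d*FA, eps, 1); forbidden when midpoint FA < thr
inline double step_cost_core(const Tens6& t, const double v[3], double len,
                             double faThr, double eps, bool& forbidden) {
    double lam[3], V[9];
    eig3sym(t, lam, V);
    double fa = fa_from_lambda(lam[0], lam[1], lam[2]);
    if (fa < faThr) {
        forbidden = true;
        return R_PosInf;
    }
    forbidden = false;
    double p = 0.0, d = 1.0;
    if (lam[0] > 0) {
        double dvx = t.xx * v[0] + t.xy * v[1] + t.xz * v[2];
        double dvy = t.xy * v[0] + t.yy * v[1] + t.yz * v[2];
        double dvz = t.xz * v[0] + t.yz * v[1] + t.zz * v[2];
        double vDv = v[0] * dvx + v[1] * dvy + v[2] * dvz;
        p = (vDv - lam[2]) / lam[0];
        if (p < 0) p = 0;
        double cl = (lam[0] - lam[1]) / lam[0];
        double cp = (lam[1] - lam[2]) / lam[0];
        double cs = lam[2] / lam[0];
        if (cl >= cp && cl >= cs) {           // linear (ties -> linear)
            d = std::fabs(v[0] * V[0] + v[1] * V[1] + v[2] * V[2]);
        } else {                              // planar or spherical
            double ve3 = v[0] * V[6] + v[1] * V[7] + v[2] * V[8];
            double s = 1.0 - ve3 * ve3;
            d = std::sqrt(s > 0 ? s : 0.0);
        }
    }
    double u = 1.0 - p * d * fa;
    if (u < eps) u = eps;
    if (u > 1.0) u = 1.0;
    return len * u;
}

} // namespace

// Scalar step cost, exported so the R-level stepCost (and the independent
// shortest-path oracle in the tests) evaluate the identical arithmetic.
// [[Rcpp::export]]
double cpp_step_cost(NumericVector tensor6, NumericVector v, double len,
                     double faThr, double eps) {
    Tens6 t = { tensor6[0], tensor6[1], tensor6[2], tensor6[3], tensor6[4], tensor6[5] };
    double vv[3] = { v[0], v[1], v[2] };
    bool forbidden;
    double c = step_cost_core(t, vv, len, faThr, eps, forbidden);
    return forbidden ? R_PosInf : c;
}

// [[Rcpp::export]]
List cpp_astar(NumericVector tens, IntegerVector dims, NumericMatrix invAffine,
               NumericVector gorigin, double gspacing, IntegerVector gdims,
               IntegerMatrix offsets, NumericMatrix offDirs, NumericVector offLen,
               IntegerVector startNode, LogicalVector goalNode,
               NumericMatrix goalPts, LogicalVector expandable,
               double faThr, double cosBend, double eps, double maxExpansions) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double* T = tens.begin();
    const double* invA = invAffine.begin();
    const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
    const int M = offsets.nrow();
    const long nnodes = (long)gx * gy * gz;

    auto nodeOf = [&](int i, int j, int k) -> long {
        return (long)i + (long)gx * ((long)j + (long)gy * (long)k);
    };
    auto posOf = [&](long n, double out[3]) {
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        out[0] = gorigin[0] + gspacing * i;
        out[1] = gorigin[1] + gspacing * j;
        out[2] = gorigin[2] + gspacing * k;
    };

    // heuristic: eps * Euclidean distance to the nearest goal node
    std::vector<double> hcache((size_t)nnodes, -1.0);
    const int ng = goalPts.nrow();
    auto heur = [&](long n) -> double {
        double& hc = hcache[(size_t)n];
        if (hc >= 0) return hc;
        double p[3];
        posOf(n, p);
        double best = 0.0;
        if (ng > 0) {
            best = R_PosInf;
            for (int g = 0; g < ng; ++g) {
                double dx = p[0] - goalPts(g, 0), dy = p[1] - goalPts(g, 1),
                       dz = p[2] - goalPts(g, 2);
                double d = std::sqrt(dx * dx + dy * dy + dz * dz);
                if (d < best) best = d;
            }
        }
        hc = eps * best;
        return hc;
    };

    // state key: node * (M+1) + (arrival offset + 1); -1 = start (no arrival)
    auto keyOf = [&](long n, int aoff) -> long long {
        return (long long)n * (M + 1) + (aoff + 1);
    };

    std::unordered_map<long long, double> gScore;
    std::unordered_map<long long, long long> parent;

    struct QE {
        double f;
        long long order;
        long long key;
    };
    struct QCmp {
        bool operator()(const QE& a, const QE& b) const {
            if (a.f != b.f) return a.f > b.f;
            return a.order > b.order;   // FIFO tie-break
        }
    };
    std::priority_queue<QE, std::vector<QE>, QCmp> pq;
    long long counter = 0;

    long start = nodeOf(startNode[0], startNode[1], startNode[2]);
    long long skey = keyOf(start, -1);
    gScore[skey] = 0.0;
    pq.push({ heur(start), counter++, skey });

    long long goalKey = -1;
    double expansions = 0;

    while (!pq.empty()) {
        QE top = pq.top();
        pq.pop();
        long long key = top.key;
        long n = (long)(key / (M + 1));
        int aoff = (int)(key % (M + 1)) - 1;
        double g = gScore[key];
        if (top.f > g + heur(n) + 1e-12) continue;   // stale entry
        if (goalNode[n]) {
            goalKey = key;
            break;
        }
        if (++expansions > maxExpansions) break;
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        double p0[3];
        posOf(n, p0);
        for (int o = 0; o < M; ++o) {
            if (aoff >= 0) {   // bending-angle constraint between segments
                double dot = offDirs(aoff, 0) * offDirs(o, 0) +
                             offDirs(aoff, 1) * offDirs(o, 1) +
                             offDirs(aoff, 2) * offDirs(o, 2);
                if (dot < cosBend - 1e-12) continue;
            }
            long i2 = i + offsets(o, 0), j2 = j + offsets(o, 1), k2 = k + offsets(o, 2);
            if (i2 < 0 || i2 >= gx || j2 < 0 || j2 >= gy || k2 < 0 || k2 >= gz)
                continue;
            long n2 = nodeOf((int)i2, (int)j2, (int)k2);
            if (!expandable[n2]) continue;
            double p1[3] = { gorigin[0] + gspacing * i2,
                             gorigin[1] + gspacing * j2,
                             gorigin[2] + gspacing * k2 };
            double mid[3] = { 0.5 * (p0[0] + p1[0]), 0.5 * (p0[1] + p1[1]),
                              0.5 * (p0[2] + p1[2]) };
            Tens6 t;
            if (!interp_tensor(T, nx, ny, nz, invA, mid[0], mid[1], mid[2], t))
                continue;
            double v[3] = { offDirs(o, 0), offDirs(o, 1), offDirs(o, 2) };
            bool forbidden;
            double c = step_cost_core(t, v, offLen[o], faThr, eps, forbidden);
            if (forbidden) continue;
            long long key2 = keyOf(n2, o);
            double g2 = g + c;
            auto it = gScore.find(key2);
            if (it == gScore.end() || g2 < it->second) {
                gScore[key2] = g2;
                parent[key2] = key;
                pq.push({ g2 + heur(n2), counter++, key2 });
            }
        }
    }

    if (goalKey < 0)
        return List::create(_["found"] = false, _["expansions"] = expansions);

    std::vector<long> pathNodes;
    long long k = goalKey;
    while (true) {
        pathNodes.push_back((long)(k / (M + 1)));
        auto it = parent.find(k);
        if (it == parent.end()) break;
        k = it->second;
    }
    std::reverse(pathNodes.begin(), pathNodes.end());
    int np = (int)pathNodes.size();
    NumericMatrix pts(np, 3);
    IntegerMatrix nodes(np, 3);
    for (int r = 0; r < np; ++r) {
        long n = pathNodes[r];
        double p[3];
        posOf(n, p);
        pts(r, 0) = p[0]; pts(r, 1) = p[1]; pts(r, 2) = p[2];
        nodes(r, 0) = (int)(n % gx);
        nodes(r, 1) = (int)((n / gx) % gy);
        nodes(r, 2) = (int)(n / ((long)gx * gy));
    }
    return List::create(_["found"] = true, _["points"] = pts,
                        _["nodes"] = nodes, _["cost"] = gScore[goalKey],
                        _["expansions"] = expansions);
}
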