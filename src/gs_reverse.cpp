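// [[Rcpp::depends(RcppArmadillo)]]
#include "dti_core.h"
#include <queue>
#include <unordered_map>
using namespace Rcpp;

// Multi-goal reverse Dijkstra over the (node, arrival-offset) state space.
// One sweep from the goal set yields, for every start node, the same
// minimum-cost path a per-start A* search finds, with every edge cost
// evaluated once.  Edge costs and constraints are identical to cpp_astar:
// cost(n, o) is sampled at the midpoint of the segment leaving node n via
// offset o, edges with midpoint FA below the threshold are forbidden, and
// consecutive offsets must satisfy the bending-angle limit.

namespace {

inline double edge_cost_rev(const double* T, int nx, int ny, int nz,
                            const double* invA, const double p0[3],
                            const double p1[3], const double v[3],
                            double len, double faThr, double eps) {
    double mid[3] = { 0.5 * (p0[0] + p1[0]), 0.5 * (p0[1] + p1[1]),
                      0.5 * (p0[2] + p1[2]) };
    Tens6 t;
    if (!interp_tensor(T, nx, ny, nz, invA, mid[0], mid[1], mid[2], t))
        return R_PosInf;
    double lam[3], V[9];
    eig3sym(t, lam, V);
    double fa = fa_from_lambda(lam[0], lam[1], lam[2]);
    if (fa < faThr) return R_PosInf;
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
        if (cl >= cp && cl >= cs) {
            d = std::fabs(v[0] * V[0] + v[1] * V[1] + v[2] * V[2]);
        } else {
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

// Returns, per start node, found / cost / path points.
// [[Rcpp::export]]
List cpp_gs_reverse(NumericVector tens, IntegerVector dims,
                    NumericMatrix invAffine, NumericVector gorigin,
                    double gspacing, IntegerVector gdims,
                    IntegerMatrix offsets, NumericMatrix offDirs,
                    NumericVector offLen, IntegerMatrix startNodes,
                    LogicalVector goalNode, LogicalVector expandable,
                    double faThr, double cosBend, double eps,
                    double maxRelax) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double* T = tens.begin();
    const double* invA = invAffine.begin();
    const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
    const int M = offsets.nrow();

    auto nodeOf = [&](long i, long j, long k) -> long {
        return i + (long)gx * (j + (long)gy * k);
    };
    auto posOf = [&](long n, double out[3]) {
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        out[0] = gorigin[0] + gspacing * i;
        out[1] = gorigin[1] + gspacing * j;
        out[2] = gorigin[2] + gspacing * k;
    };
    // state key: node * M + arrival offset
    auto keyOf = [&](long n, int a) -> long long {
        return (long long)n * M + a;
    };

    // bending-compatible offset pairs, precomputed
    std::vector<std::vector<int> > compat(M);
    for (int a = 0; a < M; ++a)
        for (int b = 0; b < M; ++b) {
            double dot = offDirs(a, 0) * offDirs(b, 0) +
                         offDirs(a, 1) * offDirs(b, 1) +
                         offDirs(a, 2) * offDirs(b, 2);
            if (dot >= cosBend - 1e-12) compat[a].push_back(b);
        }

    // lazily allocated per-node state blocks: one hash lookup per node,
    // direct indexing over the M arrival offsets within a block
    std::unordered_map<long, int> nodeSlot;
    std::vector<double> distArena;
    std::vector<long long> parentArena;
    auto slotOf = [&](long n) -> int {
        auto it = nodeSlot.find(n);
        if (it != nodeSlot.end()) return it->second;
        int s = (int)(distArena.size() / M);
        nodeSlot.emplace(n, s);
        distArena.resize(distArena.size() + M, R_PosInf);
        parentArena.resize(parentArena.size() + M, -1LL);
        return s;
    };
    auto slotIfAny = [&](long n) -> int {
        auto it = nodeSlot.find(n);
        return it == nodeSlot.end() ? -1 : it->second;
    };

    auto edgeCost = [&](long n, int o) -> double {
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        long i2 = i + offsets(o, 0), j2 = j + offsets(o, 1), k2 = k + offsets(o, 2);
        if (i2 < 0 || i2 >= gx || j2 < 0 || j2 >= gy || k2 < 0 || k2 >= gz)
            return R_PosInf;
        if (!expandable[nodeOf(i2, j2, k2)]) return R_PosInf;
        double p0[3], p1[3];
        posOf(n, p0);
        posOf(nodeOf(i2, j2, k2), p1);
        double v[3] = { offDirs(o, 0), offDirs(o, 1), offDirs(o, 2) };
        return edge_cost_rev(T, nx, ny, nz, invA, p0, p1, v, offLen[o],
                             faThr, eps);
    };

    struct QE {
        double d;
        long long order;
        long long key;
    };
    struct QCmp {
        bool operator()(const QE& a, const QE& b) const {
            if (a.d != b.d) return a.d > b.d;
            return a.order > b.order;
        }
    };
    std::priority_queue<QE, std::vector<QE>, QCmp> pq;
    long long counter = 0;

    // seed every goal state at distance 0
    for (long n = 0; n < (long)goalNode.size(); ++n) {
        if (!goalNode[n]) continue;
        int s = slotOf(n);
        for (int a = 0; a < M; ++a) {
            distArena[(long long)s * M + a] = 0.0;
            pq.push({ 0.0, counter++, keyOf(n, a) });
        }
    }

    double relaxations = 0;
    while (!pq.empty()) {
        QE top = pq.top();
        pq.pop();
        long long key = top.key;
        long n = (long)(key / M);
        int a = (int)(key % M);
        int sn = slotIfAny(n);
        double d0 = distArena[(long long)sn * M + a];
        if (top.d > d0 + 1e-15) continue;   // stale entry
        // predecessor node n' = n - offset_a; forward edge (n', *) -> (n, a)
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        long ip = i - offsets(a, 0), jp = j - offsets(a, 1), kp = k - offsets(a, 2);
        if (ip < 0 || ip >= gx || jp < 0 || jp >= gy || kp < 0 || kp >= gz)
            continue;
        long np = nodeOf(ip, jp, kp);
        if (!expandable[np]) continue;
        double c = edgeCost(np, a);
        if (!R_FINITE(c)) continue;
        double nd = d0 + c;
        if (++relaxations > maxRelax) break;
        int sp = slotOf(np);
        double* dblock = &distArena[(long long)sp * M];
        long long* pblock = &parentArena[(long long)sp * M];
        const std::vector<int>& cb = compat[a];
        for (size_t bi = 0; bi < cb.size(); ++bi) {
            int b = cb[bi];
            if (nd < dblock[b]) {
                dblock[b] = nd;
                pblock[b] = key;
                pq.push({ nd, counter++, keyOf(np, b) });
            }
        }
    }

    // extract one optimal path per start node
    int ns = startNodes.nrow();
    List out(ns);
    for (int s = 0; s < ns; ++s) {
        long n = nodeOf(startNodes(s, 0), startNodes(s, 1), startNodes(s, 2));
        if (goalNode[n]) {
            out[s] = List::create(_["found"] = true, _["cost"] = 0.0,
                                  _["degenerate"] = true);
            continue;
        }
        // best first move: min over o of cost(s, o) + dist[(s + o, o)]
        double best = R_PosInf;
        int bestO = -1;
        for (int o = 0; o < M; ++o) {
            long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
            long i2 = i + offsets(o, 0), j2 = j + offsets(o, 1), k2 = k + offsets(o, 2);
            if (i2 < 0 || i2 >= gx || j2 < 0 || j2 >= gy || k2 < 0 || k2 >= gz)
                continue;
            int s2 = slotIfAny(nodeOf(i2, j2, k2));
            if (s2 < 0) continue;
            double dv = distArena[(long long)s2 * M + o];
            if (!R_FINITE(dv)) continue;
            double c = edgeCost(n, o);
            if (!R_FINITE(c)) continue;
            double tot = c + dv;
            if (tot < best) {
                best = tot;
                bestO = o;
            }
        }
        if (bestO < 0) {
            out[s] = List::create(_["found"] = false);
            continue;
        }
        std::vector<long> nodes;
        nodes.push_back(n);
        long i = n % gx, j = (n / gx) % gy, k = n / ((long)gx * gy);
        long long cur = keyOf(nodeOf(i + offsets(bestO, 0), j + offsets(bestO, 1),
                                     k + offsets(bestO, 2)), bestO);
        while (true) {
            long cn = (long)(cur / M);
            int ca = (int)(cur % M);
            int cs = slotIfAny(cn);
            nodes.push_back(cn);
            if (cs < 0) break;
            if (goalNode[cn] && distArena[(long long)cs * M + ca] == 0.0) break;
            long long pv = parentArena[(long long)cs * M + ca];
            if (pv < 0) break;
            cur = pv;
        }
        int np2 = (int)nodes.size();
        NumericMatrix pts(np2, 3);
        for (int r = 0; r < np2; ++r) {
            double p[3];
            posOf(nodes[r], p);
            pts(r, 0) = p[0]; pts(r, 1) = p[1]; pts(r, 2) = p[2];
        }
        out[s] = List::create(_["found"] = true, _["cost"] = best,
                              _["points"] = pts);
    }
    return out;
}
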