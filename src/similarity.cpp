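#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Closest-point machinery for fiber-pair and tract-pair similarity.
// All ties break toward the lower index for determinism.

namespace {

inline double dist3(const NumericMatrix& A, int i, const NumericMatrix& B, int j) {
    double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// index (0-based) of the point of B closest to A[i]
inline int nearest_index(const NumericMatrix& A, int i, const NumericMatrix& B) {
    int m = B.nrow(), best = 0;
    double bd = dist3(A, i, B, 0);
    for (int j = 1; j < m; ++j) {
        double d = dist3(A, i, B, j);
        if (d < bd) {
            bd = d;
            best = j;
        }
    }
    return best;
}

// duplicate-excluding closest-point relation between two point sets
std::set<std::pair<int, int> > closest_relation(const NumericMatrix& A,
                                                const NumericMatrix& B) {
    std::set<std::pair<int, int> > rel;
    for (int i = 0; i < A.nrow(); ++i)
        rel.insert(std::make_pair(i, nearest_index(A, i, B)));
    for (int j = 0; j < B.nrow(); ++j)
        rel.insert(std::make_pair(nearest_index(B, j, A), j));
    return rel;
}

double mcd_points(const NumericMatrix& A, const NumericMatrix& B) {
    std::set<std::pair<int, int> > rel = closest_relation(A, B);
    double s = 0;
    for (std::set<std::pair<int, int> >::const_iterator it = rel.begin();
         it != rel.end(); ++it)
        s += dist3(A, it->first, B, it->second);
    return s / (double)rel.size();
}

NumericMatrix reverse_rows(const NumericMatrix& B) {
    int m = B.nrow();
    NumericMatrix R(m, 3);
    for (int j = 0; j < m; ++j)
        for (int a = 0; a < 3; ++a) R(j, a) = B(m - 1 - j, a);
    return R;
}

struct TrimResult {
    int a0, a1, b0, b1;   // inclusive 0-based keep ranges
    bool reversed;        // B was reversed to establish end correspondence
    bool refusedA, refusedB;
};

// Pairwise trimming: at each end correspondence the closest point on the
// other fiber to each endpoint is found; if exactly one of the two is an
// interior point, the protruding segment beyond it (on the fiber that
// carries it) is removed.  Diverging ends (both interior) and coincident
// ends (both endpoints) are left alone, so at most one fiber is trimmed at
// each end.  Trims that would leave fewer than 2 points are refused.
TrimResult trim_core(const NumericMatrix& A, const NumericMatrix& Bin,
                     NumericMatrix& Bout) {
    int nA = A.nrow();
    TrimResult tr;
    tr.reversed = false;
    tr.refusedA = tr.refusedB = false;

    // orient B so that ends correspond (minimal summed endpoint distance)
    NumericMatrix B = Bin;
    int nB = B.nrow();
    double dFwd = dist3(A, 0, B, 0) + dist3(A, nA - 1, B, nB - 1);
    double dRev = dist3(A, 0, B, nB - 1) + dist3(A, nA - 1, B, 0);
    if (dRev < dFwd) {
        B = reverse_rows(Bin);
        tr.reversed = true;
    }

    tr.a0 = 0; tr.a1 = nA - 1; tr.b0 = 0; tr.b1 = nB - 1;

    // start end
    {
        int jB = nearest_index(A, 0, B);        // closest point on B to A's start
        int jA = nearest_index(B, 0, A);        // closest point on A to B's start
        bool intB = (jB != 0 && jB != nB - 1);
        bool intA = (jA != 0 && jA != nA - 1);
        if (intB != intA) {
            if (intB) tr.b0 = jB; else tr.a0 = jA;
        }
    }
    // far end
    {
        int jB = nearest_index(A, nA - 1, B);
        int jA = nearest_index(B, nB - 1, A);
        bool intB = (jB != 0 && jB != nB - 1);
        bool intA = (jA != 0 && jA != nA - 1);
        if (intB != intA) {
            if (intB) tr.b1 = jB; else tr.a1 = jA;
        }
    }

    if (tr.a1 - tr.a0 < 1) {   // would leave < 2 points: refuse
        tr.a0 = 0; tr.a1 = nA - 1;
        tr.refusedA = true;
    }
    if (tr.b1 - tr.b0 < 1) {
        tr.b0 = 0; tr.b1 = nB - 1;
        tr.refusedB = true;
    }
    Bout = B;
    return tr;
}

NumericMatrix slice_rows(const NumericMatrix& M, int r0, int r1) {
    NumericMatrix S(r1 - r0 + 1, 3);
    for (int r = r0; r <= r1; ++r)
        for (int a = 0; a < 3; ++a) S(r - r0, a) = M(r, a);
    return S;
}

double mcd_trimmed(const NumericMatrix& A, const NumericMatrix& B) {
    NumericMatrix Bo;
    TrimResult tr = trim_core(A, B, Bo);
    NumericMatrix At = slice_rows(A, tr.a0, tr.a1);
    NumericMatrix Bt = slice_rows(Bo, tr.b0, tr.b1);
    return mcd_points(At, Bt);
}

} // namespace

// [[Rcpp::export]]
List cpp_closest_pairs(NumericMatrix A, NumericMatrix B) {
    std::set<std::pair<int, int> > rel = closest_relation(A, B);
    int n = (int)rel.size();
    IntegerMatrix pairs(n, 2);
    NumericVector d(n);
    int r = 0;
    for (std::set<std::pair<int, int> >::const_iterator it = rel.begin();
         it != rel.end(); ++it, ++r) {
        pairs(r, 0) = it->first + 1;
        pairs(r, 1) = it->second + 1;
        d[r] = dist3(A, it->first, B, it->second);
    }
    return List::create(_["pairs"] = pairs, _["distance"] = d);
}

// [[Rcpp::export]]
double cpp_mean_closest_distance(NumericMatrix A, NumericMatrix B) {
    return mcd_points(A, B);
}

// [[Rcpp::export]]
List cpp_trim_pair(NumericMatrix A, NumericMatrix B) {
    NumericMatrix Bo;
    TrimResult tr = trim_core(A, B, Bo);
    return List::create(
        _["a"] = slice_rows(A, tr.a0, tr.a1),
        _["b"] = slice_rows(Bo, tr.b0, tr.b1),
        _["a_keep"] = IntegerVector::create(tr.a0 + 1, tr.a1 + 1),
        _["b_keep"] = IntegerVector::create(tr.b0 + 1, tr.b1 + 1),
        _["reversed"] = tr.reversed,
        _["refused"] = LogicalVector::create(tr.refusedA, tr.refusedB));
}

// [[Rcpp::export]]
double cpp_mcd_trimmed(NumericMatrix A, NumericMatrix B) {
    return mcd_trimmed(A, B);
}

// Tract-level similarity: each fiber of F paired with its closest fiber of
// G (trimmed mean closest-point distance) and vice versa; duplicate fiber
// pairs excluded; s_avg = mean, s_min = min over the relation.
// [[Rcpp::export]]
List cpp_tract_similarity(List F, List G) {
    int nf = F.size(), ng = G.size();
    NumericMatrix D(nf, ng);
    for (int i = 0; i < nf; ++i) {
        NumericMatrix fi = F[i];
        for (int j = 0; j < ng; ++j) {
            NumericMatrix gj = G[j];
            D(i, j) = mcd_trimmed(fi, gj);
        }
    }
    std::set<std::pair<int, int> > rel;
    for (int i = 0; i < nf; ++i) {
        int best = 0;
        for (int j = 1; j < ng; ++j)
            if (D(i, j) < D(i, best)) best = j;
        rel.insert(std::make_pair(i, best));
    }
    for (int j = 0; j < ng; ++j) {
        int best = 0;
        for (int i = 1; i < nf; ++i)
            if (D(i, j) < D(best, j)) best = i;
        rel.insert(std::make_pair(best, j));
    }
    int n = (int)rel.size();
    IntegerMatrix pairs(n, 2);
    NumericVector d(n);
    double s = 0, smin = R_PosInf;
    int r = 0;
    for (std::set<std::pair<int, int> >::const_iterator it = rel.begin();
         it != rel.end(); ++it, ++r) {
        pairs(r, 0) = it->first + 1;
        pairs(r, 1) = it->second + 1;
        d[r] = D(it->first, it->second);
        s += d[r];
        if (d[r] < smin) smin = d[r];
    }
    return List::create(_["s_avg"] = s / n, _["s_min"] = smin,
                        _["pairs"] = pairs, _["distance"] = d);
}
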