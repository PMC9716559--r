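#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Contact-map-overlap alignment by iterated double dynamic programming.
// Inner DP scores each residue pair (i in map A, j in map B) by the best
// monotone matching of their contact-neighbour offset profiles; the outer
// affine-gap DP (free terminal gaps) turns the similarity matrix into a
// monotone residue alignment. Refinement rounds rebuild the similarity from
// contacts that the previous alignment renders consistent.

// Monotone alignment of two neighbour-offset profiles; skips are free,
// matching offsets da and db contributes min(w) * exp(-(da-db)^2 / s2).
static double profile_score(const std::vector<int>& offA,
                            const std::vector<double>& wA,
                            const std::vector<int>& offB,
                            const std::vector<double>& wB,
                            double s2) {
    const int n = offA.size(), m = offB.size();
    if (n == 0 || m == 0) return 0.0;
    std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
    for (int a = 1; a <= n; ++a) {
        cur[0] = 0.0;
        for (int b = 1; b <= m; ++b) {
            const double d = offA[a - 1] - offB[b - 1];
            const double ms = std::min(wA[a - 1], wB[b - 1]) *
                              std::exp(-d * d / s2);
            cur[b] = std::max(std::max(prev[b], cur[b - 1]),
                              prev[b - 1] + ms);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

struct Neigh {
    std::vector<std::vector<int> > idx, off;
    std::vector<std::vector<double> > w;
};

static Neigh neighbours(const NumericMatrix& W) {
    const int L = W.nrow();
    Neigh nb;
    nb.idx.resize(L); nb.off.resize(L); nb.w.resize(L);
    for (int i = 0; i < L; ++i)
        for (int k = 0; k < L; ++k)
            if (W(i, k) > 0) {
                nb.idx[i].push_back(k);
                nb.off[i].push_back(k - i);
                nb.w[i].push_back(W(i, k));
            }
    return nb;
}

// Outer affine-gap DP (maximisation, free leading/trailing gaps).
// Returns the mapping as pairs of 0-based indices; diagonal moves are
// preferred on ties so identical maps align on the identity.
static void outer_dp(const NumericMatrix& S, double gapOpen, double gapExtend,
                     std::vector<std::pair<int, int> >& mapping) {
    const int n = S.nrow(), m = S.ncol();
    const double NEG = -1e18;
    NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
    for (int i = 0; i <= n; ++i)
        for (int j = 0; j <= m; ++j) { M(i, j) = NEG; Ix(i, j) = NEG; Iy(i, j) = NEG; }
    // best(i, j): best score of any state ending at (i, j); leading gaps free
    for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j) {
            double prev = 0.0;   // free start
            prev = std::max(prev, M(i - 1, j - 1));
            prev = std::max(prev, Ix(i - 1, j - 1));
            prev = std::max(prev, Iy(i - 1, j - 1));
            M(i, j) = S(i - 1, j - 1) + prev;
            Ix(i, j) = std::max(M(i - 1, j) + gapOpen,
                                Ix(i - 1, j) + gapExtend);
            Iy(i, j) = std::max(M(i, j - 1) + gapOpen,
                                Iy(i, j - 1) + gapExtend);
        }
    // free trailing gaps: end at the best M cell
    int bi = 0, bj = 0; double best = 0.0;
    for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
            if (M(i, j) > best + 1e-12) { best = M(i, j); bi = i; bj = j; }
    mapping.clear();
    if (bi == 0) return;
    int i = bi, j = bj, state = 0;   // 0 = M, 1 = Ix, 2 = Iy
    while (i > 0 && j > 0) {
        if (state == 0) {
            mapping.push_back(std::make_pair(i - 1, j - 1));
            const double prev = M(i, j) - S(i - 1, j - 1);
            if (std::fabs(prev) < 1e-9) break;   // free start reached
            if (std::fabs(M(i - 1, j - 1) - prev) < 1e-9) state = 0;
            else if (std::fabs(Ix(i - 1, j - 1) - prev) < 1e-9) state = 1;
            else state = 2;
            --i; --j;
        } else if (state == 1) {
            if (std::fabs(Ix(i, j) - (M(i - 1, j) + gapOpen)) < 1e-9)
                state = 0;
            --i;
        } else {
            if (std::fabs(Iy(i, j) - (M(i, j - 1) + gapOpen)) < 1e-9)
                state = 0;
            --j;
        }
    }
    std::reverse(mapping.begin(), mapping.end());
}

static double matched_weight(const NumericMatrix& WA, const NumericMatrix& WB,
                             const std::vector<std::pair<int, int> >& mapping,
                             int* nMatched) {
    double tot = 0.0; int cnt = 0;
    const int n = mapping.size();
    for (int a = 0; a < n; ++a)
        for (int b = a + 1; b < n; ++b) {
            const double wa = WA(mapping[a].first, mapping[b].first);
            const double wb = WB(mapping[a].second, mapping[b].second);
            if (wa > 0 && wb > 0) { tot += std::min(wa, wb); ++cnt; }
        }
    if (nMatched) *nMatched = cnt;
    return tot;
}

static double gap_penalty(const std::vector<std::pair<int, int> >& mapping,
                          double gapOpen, double gapExtend) {
    double gpen = 0.0;
    for (size_t k = 1; k < mapping.size(); ++k) {
        const int di = mapping[k].first - mapping[k - 1].first - 1;
        const int dj = mapping[k].second - mapping[k - 1].second - 1;
        if (di > 0) gpen += gapOpen + (di - 1) * gapExtend;
        if (dj > 0) gpen += gapOpen + (dj - 1) * gapExtend;
    }
    return gpen;
}

// Iterate consistency refinement from a given initial similarity, keeping
// the best mapping (by matched weight + gap penalty) seen in any round.
static void refine(const NumericMatrix& WA, const NumericMatrix& WB,
                   const Neigh& nA, const NumericMatrix& Sinit,
                   const NumericMatrix& S0, double gapOpen, double gapExtend,
                   int nIter, std::vector<std::pair<int, int> >& bestMap,
                   double& bestObj) {
    const int LA = WA.nrow(), LB = WB.nrow();
    NumericMatrix S = clone(Sinit);
    std::vector<std::pair<int, int> > mapping;
    for (int it = 0; it < nIter; ++it) {
        outer_dp(S, gapOpen, gapExtend, mapping);
        const double obj = matched_weight(WA, WB, mapping, 0) +
                           gap_penalty(mapping, gapOpen, gapExtend);
        if (obj > bestObj + 1e-12) { bestObj = obj; bestMap = mapping; }
        if (it + 1 == nIter) break;
        // rebuild similarity: contacts made consistent by current mapping
        std::vector<int> mapA(LA, -1);
        for (size_t k = 0; k < mapping.size(); ++k)
            mapA[mapping[k].first] = mapping[k].second;
        for (int i = 0; i < LA; ++i)
            for (int j = 0; j < LB; ++j) {
                double cons = 0.0;
                const std::vector<int>& nb = nA.idx[i];
                for (size_t t = 0; t < nb.size(); ++t) {
                    const int k = nb[t];
                    const int l = mapA[k];
                    if (l >= 0 && l != j && WB(j, l) > 0)
                        cons += std::min(WA(i, k), WB(j, l));
                }
                S(i, j) = cons + 0.1 * S0(i, j);
            }
    }
}

// Exact small-map search: depth-first enumeration of monotone mappings,
// maximising matched contact weight. Used by the aligner for maps of at
// most 10 residues, where enumeration is cheap and the heuristic's result
// must coincide with the optimum.
struct ExactState {
    const NumericMatrix* WA;
    const NumericMatrix* WB;
    std::vector<int> curA, curB, bestA, bestB;
    double best;
};

static void exact_rec(ExactState& st, int i0, int j0, double score) {
    if (score > st.best + 1e-12) {
        st.best = score;
        st.bestA = st.curA;
        st.bestB = st.curB;
    }
    const int LA = st.WA->nrow(), LB = st.WB->nrow();
    for (int i = i0; i < LA; ++i)
        for (int j = j0; j < LB; ++j) {
            double add = 0.0;
            for (size_t t = 0; t < st.curA.size(); ++t) {
                const double wa = (*st.WA)(st.curA[t], i);
                const double wb = (*st.WB)(st.curB[t], j);
                if (wa > 0 && wb > 0) add += std::min(wa, wb);
            }
            st.curA.push_back(i);
            st.curB.push_back(j);
            exact_rec(st, i + 1, j + 1, score + add);
            st.curA.pop_back();
            st.curB.pop_back();
        }
}

// [[Rcpp::export]]
List cpp_cmo_exact(NumericMatrix WA, NumericMatrix WB) {
    ExactState st;
    st.WA = &WA; st.WB = &WB; st.best = 0.0;
    exact_rec(st, 0, 0, 0.0);
    IntegerMatrix map(st.bestA.size(), 2);
    std::vector<std::pair<int, int> > mapping;
    for (size_t k = 0; k < st.bestA.size(); ++k) {
        map(k, 0) = st.bestA[k] + 1;
        map(k, 1) = st.bestB[k] + 1;
        mapping.push_back(std::make_pair(st.bestA[k], st.bestB[k]));
    }
    int nMatched = 0;
    const double mw = matched_weight(WA, WB, mapping, &nMatched);
    return List::create(_["mapping"] = map,
                        _["matchedWeight"] = mw,
                        _["matchedContacts"] = nMatched,
                        _["score"] = mw);
}

// [[Rcpp::export]]
List cpp_cmo_align(NumericMatrix WA, NumericMatrix WB, double gapOpen,
                   double gapExtend, int nIter, double sigma) {
    const int LA = WA.nrow(), LB = WB.nrow();
    const double s2 = 2.0 * sigma * sigma;
    Neigh nA = neighbours(WA), nB = neighbours(WB);

    // initial similarity from neighbour-profile alignment
    NumericMatrix S0(LA, LB);
    for (int i = 0; i < LA; ++i) {
        if (nA.off[i].empty()) continue;
        for (int j = 0; j < LB; ++j) {
            if (nB.off[j].empty()) continue;
            S0(i, j) = profile_score(nA.off[i], nA.w[i],
                                     nB.off[j], nB.w[j], s2);
        }
    }
    if (nIter < 1) nIter = 1;
    std::vector<std::pair<int, int> > bestMap;
    double bestObj = -1e18;
    // restart 1: neighbour-profile similarity
    refine(WA, WB, nA, S0, S0, gapOpen, gapExtend, nIter, bestMap, bestObj);
    // restart 2: near-diagonal band (suits maps of the same chain whose
    // register differs only locally, the register-error situation)
    if (LA == LB) {
        NumericMatrix Sb(LA, LB);
        for (int i = 0; i < LA; ++i)
            for (int j = 0; j < LB; ++j)
                if (std::abs(i - j) <= 10)
                    Sb(i, j) = 0.1 * S0(i, j) + 0.05;
        refine(WA, WB, nA, Sb, S0, gapOpen, gapExtend, nIter, bestMap,
               bestObj);
    }
    int nMatched = 0;
    const double mw = matched_weight(WA, WB, bestMap, &nMatched);
    const double gpen = gap_penalty(bestMap, gapOpen, gapExtend);
    IntegerMatrix map(bestMap.size(), 2);
    for (size_t k = 0; k < bestMap.size(); ++k) {
        map(k, 0) = bestMap[k].first + 1;
        map(k, 1) = bestMap[k].second + 1;
    }
    return List::create(_["mapping"] = map,
                        _["matchedWeight"] = mw,
                        _["matchedContacts"] = nMatched,
                        _["score"] = mw + gpen);
}
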