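#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Intermolecular duplex model: inter-strand pairs only, antiparallel,
// non-crossing; nearest-neighbor stacking for adjacent pairs; affine
// interior-loop/bulge penalty; terminal AU/GU penalty at both helix ends;
// no dangling ends; loops capped at MAXLOOP unpaired nt per side.
// All energies handled in integer centi-kcal/mol for exact ties.

static const int MAXLOOP = 15;

// base codes: A=0, C=1, G=2, U=3; pair types (top,bottom):
// CG=0, GC=1, GU=2, UG=3, AU=4, UA=5, else -1
static inline int pairType(int a, int b) {
    switch (a * 4 + b) {
    case 1 * 4 + 2: return 0; // C-G
    case 2 * 4 + 1: return 1; // G-C
    case 2 * 4 + 3: return 2; // G-U
    case 3 * 4 + 2: return 3; // U-G
    case 0 * 4 + 3: return 4; // A-U
    case 3 * 4 + 0: return 5; // U-A
    default: return -1;
    }
}

static inline bool isAUGU(int pt) { return pt >= 2; }

struct Model {
    int stack[6][6];  // centi-kcal: stack[outer][inner]
    int loopOpen;
    int loopExtend;
    int termPen;
    bool allowGU;
    int pt(int a, int b) const {
        int p = pairType(a, b);
        if (!allowGU && p >= 2 && p <= 3) return -1;
        return p;
    }
};

static Model makeModel(const NumericMatrix& stack, double loopOpen,
                       double loopExtend, double termPen, bool allowGU) {
    Model m;
    for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j)
            m.stack[i][j] = (int) std::lround(stack(i, j) * 100.0);
    m.loopOpen = (int) std::lround(loopOpen * 100.0);
    m.loopExtend = (int) std::lround(loopExtend * 100.0);
    m.termPen = (int) std::lround(termPen * 100.0);
    m.allowGU = allowGU;
    return m;
}

struct Cell {
    int32_t E;       // energy incl. terminal penalty of the FIRST pair
    int32_t np;      // number of pairs
    int32_t anchor;  // index on a of the first pair
    int32_t pi, pk;  // parent cell (-1 = helix start)
    bool set;
};

// lexicographic preference: lower E, then more pairs, then 5'-most anchor
static inline bool better(int E1, int np1, int a1, int E2, int np2, int a2) {
    if (E1 != E2) return E1 < E2;
    if (np1 != np2) return np1 > np2;
    return a1 < a2;
}

// DP over a (5'->3') and c = reverse(b); pair (i,k) joins a[i] with
// b[m-1-k], so increasing k walks b 3'->5' (antiparallel, non-crossing).
static void dpFill(const std::vector<int>& a, const std::vector<int>& c,
                   const Model& M, std::vector<Cell>& D) {
    int n = (int) a.size(), m = (int) c.size();
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < m; ++k) {
            Cell& cur = D[i * m + k];
            cur.set = false;
            int pt = M.pt(a[i], c[k]);
            if (pt < 0) continue;
            cur.E = isAUGU(pt) ? M.termPen : 0;
            cur.np = 1; cur.anchor = i; cur.pi = -1; cur.pk = -1;
            cur.set = true;
            int pmin = i - 1 - MAXLOOP; if (pmin < 0) pmin = 0;
            int qmin = k - 1 - MAXLOOP; if (qmin < 0) qmin = 0;
            for (int p = pmin; p < i; ++p) {
                for (int q = qmin; q < k; ++q) {
                    const Cell& pre = D[p * m + q];
                    if (!pre.set) continue;
                    int la = i - p - 1, lb = k - q - 1;
                    int step;
                    if (la == 0 && lb == 0) {
                        step = M.stack[M.pt(a[p], c[q])][pt];
                    } else {
                        step = M.loopOpen + M.loopExtend * (la + lb);
                    }
                    int E = pre.E + step;
                    if (better(E, pre.np + 1, pre.anchor,
                               cur.E, cur.np, cur.anchor)) {
                        cur.E = E; cur.np = pre.np + 1;
                        cur.anchor = pre.anchor; cur.pi = p; cur.pk = q;
                    }
                }
            }
        }
    }
}

// returns best total energy (centi-kcal; 0 => empty structure) and,
// if bestI != NULL, the closing cell of the optimum
static int dpBest(const std::vector<int>& a, const std::vector<int>& c,
                  const Model& M, std::vector<Cell>& D,
                  int* bestI, int* bestK) {
    int n = (int) a.size(), m = (int) c.size();
    dpFill(a, c, M, D);
    int bE = 0, bnp = 0, ba = n; // empty structure baseline
    int bi = -1, bk = -1;
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < m; ++k) {
            const Cell& cur = D[i * m + k];
            if (!cur.set) continue;
            int pt = M.pt(a[i], c[k]);
            int tot = cur.E + (isAUGU(pt) ? M.termPen : 0);
            if (tot > 0) continue; // worse than no duplex at all
            if (better(tot, cur.np, cur.anchor, bE, bnp, ba)) {
                bE = tot; bnp = cur.np; ba = cur.anchor; bi = i; bk = k;
            }
        }
    }
    if (bestI) { *bestI = bi; *bestK = bk; }
    return bE;
}

// [[Rcpp::export(name = ".duplexHybridC")]]
List duplexHybridC(IntegerVector aCode, IntegerVector bCode,
                   NumericMatrix stack, double loopOpen, double loopExtend,
                   double termPen, bool allowGU) {
    Model M = makeModel(stack, loopOpen, loopExtend, termPen, allowGU);
    std::vector<int> a(aCode.begin(), aCode.end());
    int m = bCode.size();
    std::vector<int> c(m);
    for (int k = 0; k < m; ++k) c[k] = bCode[m - 1 - k];
    std::vector<Cell> D(a.size() * (size_t) m);
    int bi, bk;
    int E = dpBest(a, c, M, D, &bi, &bk);
    std::vector<int> pi, pj;
    while (bi >= 0) {
        const Cell& cur = D[bi * m + bk];
        pi.push_back(bi + 1);       // 1-based on a
        pj.push_back(m - bk);       // 1-based on b (original orientation)
        int ni = cur.pi, nk = cur.pk;
        bi = ni; bk = nk;
    }
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
    IntegerMatrix pairs(pi.size(), 2);
    for (size_t t = 0; t < pi.size(); ++t) {
        pairs(t, 0) = pi[t];
        pairs(t, 1) = pj[t];
    }
    return List::create(_["energy"] = E / 100.0, _["pairs"] = pairs);
}

// ---- independent exhaustive enumeration (oracle) ----

struct EnumCtx {
    const std::vector<int>* a;
    const std::vector<int>* c;
    const Model* M;
    int n, m;
    int best; // centi-kcal, <= 0
};

static void enumRec(EnumCtx& ctx, int lastI, int lastK, int lastPt,
                    int firstTerm, int curE) {
    const std::vector<int>& a = *ctx.a;
    const std::vector<int>& c = *ctx.c;
    const Model& M = *ctx.M;
    for (int i = lastI + 1; i < ctx.n; ++i) {
        int la = i - lastI - 1;
        if (la > MAXLOOP) break;
        for (int k = lastK + 1; k < ctx.m; ++k) {
            int lb = k - lastK - 1;
            if (lb > MAXLOOP) break;
            int pt = M.pt(a[i], c[k]);
            if (pt < 0) continue;
            int step = (la == 0 && lb == 0)
                ? M.stack[lastPt][pt]
                : M.loopOpen + M.loopExtend * (la + lb);
            int E = curE + step;
            int tot = E + firstTerm + (isAUGU(pt) ? M.termPen : 0);
            if (tot < ctx.best) ctx.best = tot;
            enumRec(ctx, i, k, pt, firstTerm, E);
        }
    }
}

// [[Rcpp::export(name = ".duplexEnumMinC")]]
double duplexEnumMinC(IntegerVector aCode, IntegerVector bCode,
                      NumericMatrix stack, double loopOpen, double loopExtend,
                      double termPen, bool allowGU) {
    Model M = makeModel(stack, loopOpen, loopExtend, termPen, allowGU);
    std::vector<int> a(aCode.begin(), aCode.end());
    int m = bCode.size();
    std::vector<int> c(m);
    for (int k = 0; k < m; ++k) c[k] = bCode[m - 1 - k];
    EnumCtx ctx;
    ctx.a = &a; ctx.c = &c; ctx.M = &M;
    ctx.n = (int) a.size(); ctx.m = m;
    ctx.best = 0;
    for (int i = 0; i < ctx.n; ++i) {
        for (int k = 0; k < m; ++k) {
            int pt = M.pt(a[i], c[k]);
            if (pt < 0) continue;
            int ft = isAUGU(pt) ? M.termPen : 0;
            if (2 * ft < ctx.best) ctx.best = 2 * ft; // single-pair duplex
            enumRec(ctx, i, k, pt, ft, 0);
        }
    }
    return ctx.best / 100.0;
}

// Cross-check DP against enumeration for every sequence pair up to the
// given lengths. Returns c(nChecked, nMismatch, maxAbsDiffCenti).
// [[Rcpp::export(name = ".duplexCheckAllC")]]
IntegerVector duplexCheckAllC(int maxLenA, int maxLenB,
                              NumericMatrix stack, double loopOpen,
                              double loopExtend, double termPen,
                              bool allowGU) {
    Model M = makeModel(stack, loopOpen, loopExtend, termPen, allowGU);
    long long nChecked = 0, nMismatch = 0;
    int maxDiff = 0;
    std::vector<int> a, c;
    std::vector<Cell> D((size_t) maxLenA * maxLenB);
    for (int la = 1; la <= maxLenA; ++la) {
        a.assign(la, 0);
        long long na = 1; for (int t = 0; t < la; ++t) na *= 4;
        for (long long ia = 0; ia < na; ++ia) {
            long long v = ia;
            for (int t = 0; t < la; ++t) { a[t] = v & 3; v >>= 2; }
            for (int lb = 1; lb <= maxLenB; ++lb) {
                c.assign(lb, 0);
                long long nb = 1; for (int t = 0; t < lb; ++t) nb *= 4;
                for (long long ib = 0; ib < nb; ++ib) {
                    long long w = ib;
                    // c enumerated directly in reversed orientation: every
                    // b is visited because reversal is a bijection
                    for (int t = 0; t < lb; ++t) { c[t] = w & 3; w >>= 2; }
                    int e1 = dpBest(a, c, M, D, NULL, NULL);
                    // inline enumeration
                    EnumCtx ctx;
                    ctx.a = &a; ctx.c = &c; ctx.M = &M;
                    ctx.n = la; ctx.m = lb; ctx.best = 0;
                    for (int i = 0; i < la; ++i) {
                        for (int k = 0; k < lb; ++k) {
                            int pt = M.pt(a[i], c[k]);
                            if (pt < 0) continue;
                            int ft = isAUGU(pt) ? M.termPen : 0;
                            if (2 * ft < ctx.best) ctx.best = 2 * ft;
                            enumRec(ctx, i, k, pt, ft, 0);
                        }
                    }
                    ++nChecked;
                    if (e1 != ctx.best) {
                        ++nMismatch;
                        int d = std::abs(e1 - ctx.best);
                        if (d > maxDiff) maxDiff = d;
                    }
                }
            }
            if ((ia & 0xFFF) == 0) Rcpp::checkUserInterrupt();
        }
    }
    return IntegerVector::create((int) std::min<long long>(nChecked, INT32_MAX),
                                 (int) nMismatch, maxDiff);
}
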