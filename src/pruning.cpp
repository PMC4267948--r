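#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// K2P transition probabilities for a branch of length b (expected
// substitutions per site), rates normalized so alpha + 2*beta = 1.
// Base order A, C, G, T; transitions are A<->G and C<->T.
static inline void k2p_fill(double alpha, double beta, double b, double P[4][4]) {
    double e4 = std::exp(-4.0 * beta * b);
    double e2 = std::exp(-2.0 * (alpha + beta) * b);
    double pts = 0.25 + 0.25 * e4 - 0.5 * e2;
    double ptv = 0.25 - 0.25 * e4;
    double pid = 1.0 - pts - 2.0 * ptv;
    static const int partner[4] = {2, 3, 0, 1};
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
            P[i][j] = (i == j) ? pid : (j == partner[i] ? pts : ptv);
}

// [[Rcpp::export(name = ".k2p_pmat_cpp")]]
NumericMatrix k2p_pmat_cpp(double alpha, double beta, double b) {
    double P[4][4];
    k2p_fill(alpha, beta, b, P);
    NumericMatrix out(4, 4);
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) out(i, j) = P[i][j];
    return out;
}

// Pruning (peeling) log-likelihood over compressed site patterns.
//
// edge:     m x 2 matrix of (parent, child) node ids in postorder; tips are
//           1..ntip, internal nodes ntip+1..nnode, root is edge(m-1, 0).
// elen:     branch length per edge row.
// tipp:     (4*ntip) x npat matrix; rows 4*(i-1)+1 .. 4*i hold tip i's
//           error-adjusted conditional vector (A,C,G,T) per pattern.
// w:        pattern weights.
// Per-pattern rescaling with accumulated logs guards against underflow.
// [[Rcpp::export(name = ".pruning_loglik_cpp")]]
double pruning_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                          int nnode, NumericMatrix tipp, NumericVector w,
                          double alpha, double beta) {
    const int m = edge.nrow();
    const int npat = tipp.ncol();
    std::vector<double> L((size_t)nnode * 4 * npat);
    std::vector<double> logscale(npat, 0.0);
    std::vector<int> nchild(nnode + 1, 0);
    std::vector<bool> seen(nnode + 1, false);
    for (int e = 0; e < m; ++e) nchild[edge(e, 0)]++;

    double P[4][4];
    for (int e = 0; e < m; ++e) {
        int par = edge(e, 0), ch = edge(e, 1);
        if (!R_FINITE(elen[e]) || elen[e] < 0.0)
            stop("branch lengths must be finite and non-negative");
        k2p_fill(alpha, beta, elen[e], P);
        double *Lp = &L[((size_t)par - 1) * 4 * npat];
        if (!seen[par]) {
            std::fill(Lp, Lp + 4 * (size_t)npat, 1.0);
            seen[par] = true;
        }
        if (ch <= ntip) {
            for (int s = 0; s < npat; ++s) {
                // column-major: the 4 tip entries of column s are contiguous
                const double *v = &tipp(4 * (ch - 1), s);
                for (int x = 0; x < 4; ++x) {
                    double acc = P[x][0] * v[0] + P[x][1] * v[1] +
                                 P[x][2] * v[2] + P[x][3] * v[3];
                    Lp[(size_t)x * npat + s] *= acc;
                }
            }
        } else {
            const double *Lc = &L[((size_t)ch - 1) * 4 * npat];
            for (int s = 0; s < npat; ++s) {
                double c0 = Lc[0 * (size_t)npat + s], c1 = Lc[1 * (size_t)npat + s];
                double c2 = Lc[2 * (size_t)npat + s], c3 = Lc[3 * (size_t)npat + s];
                for (int x = 0; x < 4; ++x) {
                    double acc = P[x][0] * c0 + P[x][1] * c1 +
                                 P[x][2] * c2 + P[x][3] * c3;
                    Lp[(size_t)x * npat + s] *= acc;
                }
            }
        }
        if (--nchild[par] == 0 && par != edge(m - 1, 0)) {
            // node complete: rescale each pattern by its max entry
            for (int s = 0; s < npat; ++s) {
                double mx = Lp[s];
                for (int x = 1; x < 4; ++x) {
                    double v = Lp[(size_t)x * npat + s];
                    if (v > mx) mx = v;
                }
                if (mx > 0.0 && mx < 1e-40) {
                    for (int x = 0; x < 4; ++x) Lp[(size_t)x * npat + s] /= mx;
                    logscale[s] += std::log(mx);
                }
            }
        }
    }

    int root = edge(m - 1, 0);
    const double *Lr = &L[((size_t)root - 1) * 4 * npat];
    double lnl = 0.0;
    for (int s = 0; s < npat; ++s) {
        double tot = 0.25 * (Lr[s] + Lr[(size_t)npat + s] +
                             Lr[2 * (size_t)npat + s] + Lr[3 * (size_t)npat + s]);
        if (!(tot > 0.0) || !R_FINITE(tot))
            stop("likelihood underflow or invalid value at pattern %d", s + 1);
        lnl += w[s] * (std::log(tot) + logscale[s]);
    }
    return lnl;
}

// Partial-likelihood caches for fast per-branch optimization: for one
// focal edge e = (p, c), return A (the conditional likelihood of all data
// outside the subtree below e, seen at p, with the 1/4 root frequencies
// folded in), D (the conditional below c) and the per-pattern log-scale,
// so that lnL(b) = sum_s w_s [ log( sum_xy A_xs P_xy(b) D_ys ) + scale_s ].
// Layout of A and D: 4 x npat. One postorder pass computes D and the
// edge-transformed vectors T, one preorder pass the above-edge partials.
// [[Rcpp::export(name = ".edge_partials_cpp")]]
List edge_partials_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                       int nnode, NumericMatrix tipp, double alpha,
                       double beta, int eidx) {
    const int m = edge.nrow();
    const int npat = tipp.ncol();
    if (eidx < 1 || eidx > m) stop("edge index out of range");
    const size_t blk = (size_t)4 * npat;
    std::vector<double> D((size_t)nnode * blk);   // below-node conditionals
    std::vector<double> T((size_t)m * blk);       // per-edge transformed D
    std::vector<double> sD((size_t)nnode * npat, 0.0);
    std::vector<bool> seen(nnode + 1, false);
    std::vector<int> nchild(nnode + 1, 0), parent_edge(nnode + 1, -1);
    for (int e = 0; e < m; ++e) {
        nchild[edge(e, 0)]++;
        parent_edge[edge(e, 1)] = e;
    }
    int root = edge(m - 1, 0);

    double P[4][4];
    for (int e = 0; e < m; ++e) {
        int par = edge(e, 0), ch = edge(e, 1);
        if (!R_FINITE(elen[e]) || elen[e] < 0.0)
            stop("branch lengths must be finite and non-negative");
        k2p_fill(alpha, beta, elen[e], P);
        double *Dp = &D[((size_t)par - 1) * blk];
        double *Te = &T[(size_t)e * blk];
        if (!seen[par]) {
            std::fill(Dp, Dp + blk, 1.0);
            seen[par] = true;
        }
        if (ch <= ntip) {
            // tip conditionals live in tipp; copy into D so the upward
            // pass can treat every node uniformly
            double *Dc = &D[((size_t)ch - 1) * blk];
            for (int s = 0; s < npat; ++s)
                for (int x = 0; x < 4; ++x)
                    Dc[(size_t)x * npat + s] = tipp(4 * (ch - 1) + x, s);
        }
        const double *Dc = &D[((size_t)ch - 1) * blk];
        const double *ss = &sD[((size_t)ch - 1) * npat];
        double *sp = &sD[((size_t)par - 1) * npat];
        for (int s = 0; s < npat; ++s) {
            double c0 = Dc[s], c1 = Dc[(size_t)npat + s];
            double c2 = Dc[2 * (size_t)npat + s], c3 = Dc[3 * (size_t)npat + s];
            for (int x = 0; x < 4; ++x) {
                double acc = P[x][0] * c0 + P[x][1] * c1 + P[x][2] * c2 +
                             P[x][3] * c3;
                Te[(size_t)x * npat + s] = acc;
                Dp[(size_t)x * npat + s] *= acc;
            }
            sp[s] += ss[s];
        }
        if (--nchild[par] == 0 && par != root) {
            for (int s = 0; s < npat; ++s) {
                double mx = Dp[s];
                for (int x = 1; x < 4; ++x) {
                    double v = Dp[(size_t)x * npat + s];
                    if (v > mx) mx = v;
                }
                if (mx > 0.0 && mx < 1e-40) {
                    for (int x = 0; x < 4; ++x) Dp[(size_t)x * npat + s] /= mx;
                    sp[s] += std::log(mx);
                }
            }
        }
    }

    // preorder (reverse postorder) pass: A_e for every edge on the path
    // down to the focal edge -- computing it for all edges costs the same
    std::vector<double> U((size_t)nnode * blk);
    std::vector<double> sU((size_t)nnode * npat, 0.0);
    {
        double *Ur = &U[((size_t)root - 1) * blk];
        std::fill(Ur, Ur + blk, 0.25);
    }
    std::vector<double> A(blk);
    std::vector<double> sA(npat);
    for (int e = m - 1; e >= 0; --e) {
        int par = edge(e, 0), ch = edge(e, 1);
        const double *Up = &U[((size_t)par - 1) * blk];
        const double *sup = &sU[((size_t)par - 1) * npat];
        // A_e = U[par] * product of sibling T's
        std::copy(Up, Up + blk, A.begin());
        std::copy(sup, sup + npat, sA.begin());
        for (int e2 = 0; e2 < m; ++e2) {
            if (e2 == e || edge(e2, 0) != par) continue;
            const double *Ts = &T[(size_t)e2 * blk];
            const double *ssib = &sD[((size_t)edge(e2, 1) - 1) * npat];
            for (int s = 0; s < npat; ++s) {
                for (int x = 0; x < 4; ++x)
                    A[(size_t)x * npat + s] *= Ts[(size_t)x * npat + s];
                sA[s] += ssib[s];
            }
        }
        for (int s = 0; s < npat; ++s) {
            double mx = A[s];
            for (int x = 1; x < 4; ++x) {
                double v = A[(size_t)x * npat + s];
                if (v > mx) mx = v;
            }
            if (mx > 0.0 && mx < 1e-40) {
                for (int x = 0; x < 4; ++x) A[(size_t)x * npat + s] /= mx;
                sA[s] += std::log(mx);
            }
        }
        if (e == eidx - 1) {
            NumericMatrix Aout(4, npat), Dout(4, npat);
            NumericVector scale(npat);
            const double *Dc = &D[((size_t)ch - 1) * blk];
            const double *sc = &sD[((size_t)ch - 1) * npat];
            for (int s = 0; s < npat; ++s) {
                for (int x = 0; x < 4; ++x) {
                    Aout(x, s) = A[(size_t)x * npat + s];
                    Dout(x, s) = Dc[(size_t)x * npat + s];
                }
                scale[s] = sA[s] + sc[s];
            }
            return List::create(_["A"] = Aout, _["D"] = Dout,
                                _["scale"] = scale);
        }
        if (ch > ntip) {
            // U[ch] = P(b_e)^T A_e  (P is symmetric for K2P)
            k2p_fill(alpha, beta, elen[e], P);
            double *Uc = &U[((size_t)ch - 1) * blk];
            double *suc = &sU[((size_t)ch - 1) * npat];
            for (int s = 0; s < npat; ++s) {
                double a0 = A[s], a1 = A[(size_t)npat + s];
                double a2 = A[2 * (size_t)npat + s], a3 = A[3 * (size_t)npat + s];
                for (int y = 0; y < 4; ++y)
                    Uc[(size_t)y * npat + s] = P[0][y] * a0 + P[1][y] * a1 +
                                               P[2][y] * a2 + P[3][y] * a3;
                suc[s] = sA[s];
            }
        }
    }
    stop("focal edge not reached");  // unreachable
}

// Log-likelihood as a function of one branch length, using the caches
// from edge_partials_cpp.
// [[Rcpp::export(name = ".edge_loglik_cpp")]]
double edge_loglik_cpp(NumericMatrix A, NumericMatrix D, NumericVector scale,
                       NumericVector w, double alpha, double beta, double b) {
    const int npat = A.ncol();
    double P[4][4];
    k2p_fill(alpha, beta, b, P);
    double lnl = 0.0;
    for (int s = 0; s < npat; ++s) {
        double tot = 0.0;
        for (int x = 0; x < 4; ++x) {
            double px = P[x][0] * D(0, s) + P[x][1] * D(1, s) +
                        P[x][2] * D(2, s) + P[x][3] * D(3, s);
            tot += A(x, s) * px;
        }
        if (!(tot > 0.0) || !R_FINITE(tot))
            stop("likelihood underflow or invalid value at pattern %d", s + 1);
        lnl += w[s] * (std::log(tot) + scale[s]);
    }
    return lnl;
}
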