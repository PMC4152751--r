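// Minimum free energy secondary structure by dynamic programming over a
// nearest-neighbour model: pair stacking energies, hairpin/bulge/internal
// loop initiation penalties (length tables with logarithmic extrapolation
// supplied from R) and an affine multiloop term.  Two-way loops are capped
// at `max_loop` unpaired nucleotides, the standard speed/size restriction.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

// A=0 C=1 G=2 U=3 -> pair type index (AU UA CG GC GU UG), -1 if not pairable
static inline int ptype(int a, int b) {
    if (a == 0 && b == 3) return 0;
    if (a == 3 && b == 0) return 1;
    if (a == 1 && b == 2) return 2;
    if (a == 2 && b == 1) return 3;
    if (a == 2 && b == 3) return 4;
    if (a == 3 && b == 2) return 5;
    return -1;
}

struct FoldTables {
    std::vector<double> V, M; // n x n, row-major
    std::vector<double> W;    // external
    int n;
    double &v(int i, int j) { return V[(size_t)i * n + j]; }
    double &m(int i, int j) { return M[(size_t)i * n + j]; }
};

// [[Rcpp::export]]
List c_fold(IntegerVector seq,
            NumericMatrix stack,
            NumericVector hairpin,
            NumericVector bulge,
            NumericVector internal_pen,
            double asym_coef, double asym_max, int max_loop,
            double ml_init, double ml_branch, double ml_unpaired) {
    const int n = seq.size();
    std::string db(n, '.');
    if (n < 5) return List::create(_["structure"] = db, _["mfe"] = 0.0);

    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = seq[i];

    FoldTables t;
    t.n = n;
    t.V.assign((size_t)n * n, INF);
    t.M.assign((size_t)n * n, INF);
    t.W.assign(n, 0.0);

    // two-way loop energy for closing pair (i,j) and inner pair (k,l)
    auto twoway = [&](int i, int j, int k, int l) -> double {
        int u1 = k - i - 1, u2 = j - l - 1;
        int pi = ptype(s[i], s[j]), pk = ptype(s[k], s[l]);
        if (pi < 0 || pk < 0) return INF;
        if (u1 == 0 && u2 == 0) return stack(pi, pk);
        int sz = u1 + u2;
        if (u1 == 0 || u2 == 0) return bulge[sz - 1];
        double asym = asym_coef * std::abs(u1 - u2);
        if (asym > asym_max) asym = asym_max;
        return internal_pen[sz - 1] + asym;
    };

    for (int len = 5; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            // ---- V(i,j): i pairs j
            if (ptype(s[i], s[j]) >= 0 && j - i - 1 >= 3) {
                double best = hairpin[j - i - 2]; // loop size j-i-1, 1-based table
                // two-way loops (stack, bulge, internal)
                int kmax = std::min(i + 1 + max_loop, j - 5);
                for (int k = i + 1; k <= kmax; ++k) {
                    int u1 = k - i - 1;
                    int lmin = std::max(k + 4, j - 1 - (max_loop - u1));
                    for (int l = j - 1; l >= lmin; --l) {
                        double vin = t.v(k, l);
                        if (vin >= INF / 2) continue;
                        double e = twoway(i, j, k, l) + vin;
                        if (e < best) best = e;
                    }
                }
                // multiloop: closing pair + >= 2 branches inside
                for (int k = i + 2; k <= j - 2; ++k) {
                    double a = t.m(i + 1, k - 1), b = t.m(k, j - 1);
                    if (a >= INF / 2 || b >= INF / 2) continue;
                    double e = ml_init + ml_branch + a + b;
                    if (e < best) best = e;
                }
                t.v(i, j) = best;
            }
            // ---- M(i,j): >= 1 branch inside a multiloop
            double mbest = INF;
            if (t.v(i, j) < INF / 2) mbest = t.v(i, j) + ml_branch;
            if (len > 1) {
                if (t.m(i + 1, j) < INF / 2)
                    mbest = std::min(mbest, t.m(i + 1, j) + ml_unpaired);
                if (t.m(i, j - 1) < INF / 2)
                    mbest = std::min(mbest, t.m(i, j - 1) + ml_unpaired);
                for (int k = i + 1; k <= j; ++k) {
                    double a = t.m(i, k - 1), b = t.m(k, j);
                    if (a >= INF / 2 || b >= INF / 2) continue;
                    mbest = std::min(mbest, a + b);
                }
            }
            t.m(i, j) = mbest;
        }
    }
    // shorter spans of M (len < 5): single unpaired stretches can never hold
    // a branch, stay INF -- already initialised.

    // external loop
    for (int j = 0; j < n; ++j) {
        double best = (j > 0) ? t.W[j - 1] : 0.0;
        for (int k = 0; k <= j; ++k) {
            double v = t.v(k, j);
            if (v >= INF / 2) continue;
            double e = (k > 0 ? t.W[k - 1] : 0.0) + v;
            if (e < best) best = e;
        }
        t.W[j] = best;
    }

    double mfe = t.W[n - 1];
    if (mfe > -EPS)
        return List::create(_["structure"] = db, _["mfe"] = 0.0);

    // ---- traceback (iterative, deterministic case order) ----
    struct Task { int type; int i; int j; }; // 0=W(0..j) 1=V 2=M
    std::vector<Task> todo;
    todo.push_back({0, 0, n - 1});
    while (!todo.empty()) {
        Task tk = todo.back();
        todo.pop_back();
        int i = tk.i, j = tk.j;
        if (tk.type == 0) { // external segment ending at j
            while (j >= 0) {
                if (j >= 1 && t.W[j] >= t.W[j - 1] - EPS) { --j; continue; }
                if (j == 0) break; // single unpaired base
                bool found = false;
                for (int k = 0; k <= j; ++k) {
                    double v = t.v(k, j);
                    if (v >= INF / 2) continue;
                    double e = (k > 0 ? t.W[k - 1] : 0.0) + v;
                    if (std::fabs(e - t.W[j]) < EPS) {
                        todo.push_back({1, k, j});
                        j = k - 1;
                        found = true;
                        break;
                    }
                }
                if (!found) break; // defensive; should not happen
            }
        } else if (tk.type == 1) { // V(i,j)
            db[i] = '(';
            db[j] = ')';
            double target = t.v(i, j);
            bool found = false;
            // two-way loops first (stack is k=i+1, l=j-1, scanned first)
            int kmax = std::min(i + 1 + max_loop, j - 5);
            for (int k = i + 1; k <= kmax && !found; ++k) {
                int u1 = k - i - 1;
                int lmin = std::max(k + 4, j - 1 - (max_loop - u1));
                for (int l = j - 1; l >= lmin; --l) {
                    double vin = t.v(k, l);
                    if (vin >= INF / 2) continue;
                    if (std::fabs(twoway(i, j, k, l) + vin - target) < EPS) {
                        todo.push_back({1, k, l});
                        found = true;
                        break;
                    }
                }
            }
            if (!found) { // multiloop
                for (int k = i + 2; k <= j - 2; ++k) {
                    double a = t.m(i + 1, k - 1), b = t.m(k, j - 1);
                    if (a >= INF / 2 || b >= INF / 2) continue;
                    if (std::fabs(ml_init + ml_branch + a + b - target) < EPS) {
                        todo.push_back({2, i + 1, k - 1});
                        todo.push_back({2, k, j - 1});
                        found = true;
                        break;
                    }
                }
            }
            // else hairpin loop: nothing more to trace
        } else { // M(i,j)
            while (true) {
                double target = t.m(i, j);
                if (t.v(i, j) < INF / 2 &&
                    std::fabs(t.v(i, j) + ml_branch - target) < EPS) {
                    todo.push_back({1, i, j});
                    break;
                }
                bool split = false;
                for (int k = i + 1; k <= j; ++k) {
                    double a = t.m(i, k - 1), b = t.m(k, j);
                    if (a >= INF / 2 || b >= INF / 2) continue;
                    if (std::fabs(a + b - target) < EPS) {
                        todo.push_back({2, i, k - 1});
                        todo.push_back({2, k, j});
                        split = true;
                        break;
                    }
                }
                if (split) break;
                if (i < j && t.m(i + 1, j) < INF / 2 &&
                    std::fabs(t.m(i + 1, j) + ml_unpaired - target) < EPS) {
                    ++i;
                    continue;
                }
                if (i < j && t.m(i, j - 1) < INF / 2 &&
                    std::fabs(t.m(i, j - 1) + ml_unpaired - target) < EPS) {
                    --j;
                    continue;
                }
                break; // defensive
            }
        }
    }

    return List::create(_["structure"] = db, _["mfe"] = mfe);
}
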