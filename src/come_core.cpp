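#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Poisson-binomial tails by the O(n * min(x, n-x)) truncated
// convolution recurrence.  States above the truncation point are absorbed,
// so a single pass yields P(X <= x), the point mass P(X = x), and hence
// P(X >= x) = 1 - P(X <= x) + P(X = x).  When x is in the upper half the
// recurrence runs on the failure count Y = n - X instead, keeping the state
// vector short.
static void pb_tails_core(const double* p, int n, int x,
                          double& p_le, double& p_ge) {
    bool flip = (x > n - x);
    int m = flip ? (n - x) : x;           // truncation point
    std::vector<double> f(m + 1, 0.0);
    f[0] = 1.0;
    for (int i = 0; i < n; ++i) {
        double pi = flip ? (1.0 - p[i]) : p[i];
        int top = (i + 1 < m) ? (i + 1) : m;
        for (int k = top; k >= 1; --k)
            f[k] = f[k] * (1.0 - pi) + f[k - 1] * pi;
        f[0] *= (1.0 - pi);
    }
    double cum = 0.0;
    for (int k = 0; k <= m; ++k) cum += f[k];
    double point = f[m];
    if (cum > 1.0) cum = 1.0;
    if (!flip) {                          // cum = P(X <= x)
        p_le = cum;
        p_ge = 1.0 - cum + point;
    } else {                              // cum = P(Y <= n-x) = P(X >= x)
        p_ge = cum;
        p_le = 1.0 - cum + point;
    }
    if (p_le < 0.0) p_le = 0.0; else if (p_le > 1.0) p_le = 1.0;
    if (p_ge < 0.0) p_ge = 0.0; else if (p_ge > 1.0) p_ge = 1.0;
}

// [[Rcpp::export]]
NumericVector pb_tail_cpp(NumericVector probs, int x, bool lower) {
    int n = probs.size();
    if (x < 0 || x > n) stop("count x out of range [0, n]");
    double p_le, p_ge;
    pb_tails_core(probs.begin(), n, x, p_le, p_ge);
    return NumericVector::create(lower ? p_le : p_ge);
}

// All unordered gene pairs: overlap count, expected overlap under the
// independence background, and exact CO (upper) / ME (lower) tails of the
// Poisson-binomial null on the per-sample joint probabilities.
// [[Rcpp::export]]
DataFrame pair_tests_cpp(NumericMatrix P, IntegerMatrix B) {
    int g = P.nrow(), n = P.ncol();
    if (B.nrow() != g || B.ncol() != n)
        stop("background and binary matrices must share dimensions");
    R_xlen_t npairs = (R_xlen_t)g * (g - 1) / 2;
    IntegerVector ia(npairs), ib(npairs), overlap(npairs);
    NumericVector expected(npairs), p_co(npairs), p_me(npairs);
    std::vector<double> joint(n);
    R_xlen_t idx = 0;
    for (int i = 0; i < g; ++i) {
        for (int j = i + 1; j < g; ++j) {
            int x = 0;
            double mu = 0.0;
            for (int s = 0; s < n; ++s) {
                double ps = P(i, s) * P(j, s);
                joint[s] = ps;
                mu += ps;
                if (B(i, s) == 1 && B(j, s) == 1) ++x;
            }
            double p_le, p_ge;
            pb_tails_core(joint.data(), n, x, p_le, p_ge);
            ia[idx] = i + 1;
            ib[idx] = j + 1;
            overlap[idx] = x;
            expected[idx] = mu;
            p_co[idx] = p_ge;
            p_me[idx] = p_le;
            ++idx;
        }
        Rcpp::checkUserInterrupt();
    }
    return DataFrame::create(_["i"] = ia, _["j"] = ib,
                             _["overlap"] = overlap,
                             _["expected"] = expected,
                             _["p_co"] = p_co, _["p_me"] = p_me);
}
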