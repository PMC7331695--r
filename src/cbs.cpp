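#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal circular binary segmentation statistic for x: over all contiguous
// arcs [i, j) with min_width <= width <= n - min_width, the standardized
// |mean_in - mean_out| (common scale cancels in the permutation test, so the
// residual SD is omitted). Returns the best statistic and arc bounds.
static void max_arc_stat(const std::vector<double>& x, int min_width,
                         double& best, int& bi, int& bj) {
    int n = (int)x.size();
    best = -1.0; bi = -1; bj = -1;
    if (n < 2 * min_width) return;
    std::vector<double> cs(n + 1, 0.0);
    for (int k = 0; k < n; ++k) cs[k + 1] = cs[k] + x[k];
    double tot = cs[n];
    for (int i = 0; i < n; ++i) {
        int jmax = n;
        for (int j = i + min_width; j <= jmax; ++j) {
            int m = j - i;
            if (n - m < min_width && m < n) continue;
            if (m >= n) break;
            double s = cs[j] - cs[i];
            double din = s / m, dout = (tot - s) / (n - m);
            double t = std::fabs(din - dout) *
                std::sqrt((double)m * (double)(n - m) / (double)n);
            if (t > best) { best = t; bi = i; bj = j; }
        }
    }
}

// One CBS change-point scan with a permutation p-value. Returns the arc
// [i, j) (1-based inclusive bounds in R convention: bins i+1 .. j), the
// observed statistic and p. Permutations stop early once `stop_ge`
// exceedances are seen (the p-value is then only known to exceed alpha,
// which is all the caller needs). Uses R's RNG so results are seeded.
// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int nperm, int min_width, int stop_ge) {
    int n = x.size();
    std::vector<double> v(x.begin(), x.end());
    double obs; int bi, bj;
    max_arc_stat(v, min_width, obs, bi, bj);
    if (bi < 0 || obs <= 1e-12) {
        return List::create(_["p"] = 1.0, _["i"] = NA_INTEGER,
                            _["j"] = NA_INTEGER, _["stat"] = obs);
    }
    int ge = 0, done = 0;
    std::vector<double> y(v);
    for (int p = 0; p < nperm; ++p) {
        // Fisher-Yates with R RNG
        for (int k = n - 1; k > 0; --k) {
            int idx = (int)(unif_rand() * (k + 1));
            if (idx > k) idx = k;
            std::swap(y[k], y[idx]);
        }
        double st; int ii, jj;
        max_arc_stat(y, min_width, st, ii, jj);
        ++done;
        if (st >= obs - 1e-12) {
            ++ge;
            if (ge > stop_ge) break;
        }
    }
    double pval = (ge + 1.0) / (done + 1.0);
    return List::create(_["p"] = pval, _["i"] = bi + 1, _["j"] = bj,
                        _["stat"] = obs);
}
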