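#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact (O(n^2)) t-SNE to 2 dimensions. Input is the n x n matrix of squared
// input-space distances. Conditional probabilities are calibrated per point
// by binary search on the Gaussian precision to match the target perplexity;
// the joint P is symmetrized and early-exaggerated for the first 250
// iterations. Gradient descent uses momentum 0.5 (0.8 after iteration 250)
// and per-parameter adaptive gains, the reference implementation's schedule.
// Initial coordinates are drawn from R's RNG, so the embedding is seeded.
// [[Rcpp::export(name = ".tsne_exact")]]
NumericMatrix tsne_exact(NumericMatrix D2, double perplexity, int n_iter,
                         double eta) {
    int n = D2.nrow();
    std::vector<double> P((size_t)n * n, 0.0);
    double logU = std::log(perplexity);

    // per-point precision calibration
    for (int i = 0; i < n; ++i) {
        double betamin = -1e30, betamax = 1e30, beta = 1.0;
        std::vector<double> row(n);
        for (int tries = 0; tries < 64; ++tries) {
            double sum = 0.0;
            for (int j = 0; j < n; ++j) {
                row[j] = (j == i) ? 0.0 : std::exp(-beta * D2(i, j));
                sum += row[j];
            }
            if (sum < 1e-300) sum = 1e-300;
            double H = 0.0;
            for (int j = 0; j < n; ++j) {
                if (j == i || row[j] <= 0) continue;
                double pj = row[j] / sum;
                H -= pj * std::log(pj);
            }
            double diff = H - logU;
            if (std::fabs(diff) < 1e-5) break;
            if (diff > 0) { betamin = beta;
                beta = (betamax > 1e29) ? beta * 2 : (beta + betamax) / 2;
            } else { betamax = beta;
                beta = (betamin < -1e29) ? beta / 2 : (beta + betamin) / 2;
            }
        }
        double sum = 0.0;
        for (int j = 0; j < n; ++j) {
            row[j] = (j == i) ? 0.0 : std::exp(-beta * D2(i, j));
            sum += row[j];
        }
        if (sum < 1e-300) sum = 1e-300;
        for (int j = 0; j < n; ++j) P[(size_t)i * n + j] = row[j] / sum;
    }

    // symmetrize, normalize, early exaggeration
    double psum = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            double v = P[(size_t)i * n + j] + P[(size_t)j * n + i];
            P[(size_t)i * n + j] = v; P[(size_t)j * n + i] = v;
            psum += 2 * v;
        }
    if (psum < 1e-300) psum = 1e-300;
    for (size_t k = 0; k < P.size(); ++k) {
        P[k] = std::max(P[k] / psum, 1e-12);
    }

    std::vector<double> y0(n), y1(n);
    for (int i = 0; i < n; ++i) { y0[i] = norm_rand() * 1e-4;
                                  y1[i] = norm_rand() * 1e-4; }

    std::vector<double> g0(n), g1(n), iY0(n, 0.0), iY1(n, 0.0),
        gn0(n, 1.0), gn1(n, 1.0), Q((size_t)n * n, 0.0);
    int exag_end = std::min(250, n_iter);
    double exag = 12.0;
    const double* Pp = P.data();
    double* Qp = Q.data();

    for (int iter = 0; iter < n_iter; ++iter) {
        double mult = (iter < exag_end) ? exag : 1.0;
        // Student-t affinities (upper triangle)
        double qsum = 0.0;
        for (int i = 0; i < n; ++i) {
            const double yi0 = y0[i], yi1 = y1[i];
            double* Qi = Qp + (size_t)i * n;
            for (int j = i + 1; j < n; ++j) {
                double dx = yi0 - y0[j], dy = yi1 - y1[j];
                double q = 1.0 / (1.0 + dx * dx + dy * dy);
                Qi[j] = q;
                qsum += q;
            }
        }
        qsum *= 2.0;
        if (qsum < 1e-300) qsum = 1e-300;
        double inv_qsum = 1.0 / qsum;
        // symmetric gradient accumulation over pairs
        std::fill(g0.begin(), g0.end(), 0.0);
        std::fill(g1.begin(), g1.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            const double yi0 = y0[i], yi1 = y1[i];
            const double* Pi = Pp + (size_t)i * n;
            const double* Qi = Qp + (size_t)i * n;
            double a0 = 0.0, a1 = 0.0;
            for (int j = i + 1; j < n; ++j) {
                double q = Qi[j];
                double coef = (mult * Pi[j] - q * inv_qsum) * q;
                double cx = coef * (yi0 - y0[j]);
                double cy = coef * (yi1 - y1[j]);
                a0 += cx; a1 += cy;
                g0[j] -= cx; g1[j] -= cy;
            }
            g0[i] += a0; g1[i] += a1;
        }
        double momentum = (iter < 250) ? 0.5 : 0.8;
        double m0 = 0.0, m1 = 0.0;
        for (int i = 0; i < n; ++i) {
            double d0 = 4.0 * g0[i], d1 = 4.0 * g1[i];
            gn0[i] = ((d0 > 0) == (iY0[i] > 0))
                ? std::max(gn0[i] * 0.8, 0.01) : gn0[i] + 0.2;
            gn1[i] = ((d1 > 0) == (iY1[i] > 0))
                ? std::max(gn1[i] * 0.8, 0.01) : gn1[i] + 0.2;
            iY0[i] = momentum * iY0[i] - eta * gn0[i] * d0;
            iY1[i] = momentum * iY1[i] - eta * gn1[i] * d1;
            y0[i] += iY0[i]; y1[i] += iY1[i];
            m0 += y0[i]; m1 += y1[i];
        }
        m0 /= n; m1 /= n;
        for (int i = 0; i < n; ++i) { y0[i] -= m0; y1[i] -= m1; }
    }
    NumericMatrix Y(n, 2);
    for (int i = 0; i < n; ++i) { Y(i, 0) = y0[i]; Y(i, 1) = y1[i]; }
    return Y;
}
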