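#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Recursive binary segmentation support.
//
// The split statistic is the squared scaled partial-sum deviation
//   stat2(i) = (S_i - (i/m) S_m)^2 / (i * (m - i)),
// the square of the two-sample mean-difference statistic up to a factor
// that is constant under permutation (the global standard deviation and
// sqrt(m)), so permutation p-values are unchanged by the simplification.
// Ties in the argmax resolve to the leftmost split.

static void best_split(const double* x, int m, int& best_i, double& best_stat2) {
    best_i = 0;
    best_stat2 = 0.0;
    if (m < 2) return;
    double total = 0.0;
    for (int k = 0; k < m; ++k) total += x[k];
    double s = 0.0;
    for (int i = 1; i < m; ++i) {
        s += x[i - 1];
        double d = s - total * ((double)i / m);
        double st = d * d / ((double)i * (double)(m - i));
        if (st > best_stat2) {
            best_stat2 = st;
            best_i = i;
        }
    }
}

// Permutation test for the best split of x.
//
// Runs up to nperm Fisher-Yates permutations (R RNG; caller seeds from R).
// Early stopping:
//  - reject (not significant) as soon as the exceedance count reaches
//    ceil(alpha * nperm), at which point p >= alpha is certain;
//  - accept (significant) at interim checkpoints chk_n when the exceedance
//    count is at or below chk_kmax (a high-confidence upper bound on the
//    p-value computed in R via qbeta is already below alpha).
//
// Returns: index (last element of the left arm, 1-based within x; 0 = no
// split), stat2 (observed statistic), p_value, significant, nperm_used.
// [[Rcpp::export]]
List cbs_split_test(NumericVector x, int nperm, double alpha,
                    IntegerVector chk_n, IntegerVector chk_kmax) {
    int m = x.size();
    int best_i;
    double obs;
    best_split(REAL(x), m, best_i, obs);
    if (m < 2 || best_i == 0 || obs <= 0.0) {
        return List::create(_["index"] = 0, _["stat2"] = obs,
                            _["p_value"] = 1.0, _["significant"] = false,
                            _["nperm_used"] = 0);
    }

    double total = 0.0;
    for (int k = 0; k < m; ++k) total += x[k];
    std::vector<double> frac(m), invden(m);
    for (int i = 1; i < m; ++i) {
        frac[i] = total * ((double)i / m);
        invden[i] = 1.0 / ((double)i * (double)(m - i));
    }

    std::vector<double> y(x.begin(), x.end());
    int reject_at = (int)std::ceil(alpha * nperm);
    if (reject_at < 1) reject_at = 1;
    int exceed = 0, done = 0, ci = 0;
    bool significant = false, decided = false;
    int nchk = chk_n.size();

    RNGScope scope;
    for (int p = 0; p < nperm; ++p) {
        for (int i = m - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(y[i], y[j]);
        }
        double s = 0.0;
        bool hit = false;
        for (int i = 1; i < m; ++i) {
            s += y[i - 1];
            double d = s - frac[i];
            if (d * d * invden[i] >= obs) { hit = true; break; }
        }
        if (hit) ++exceed;
        ++done;
        if (exceed >= reject_at) {
            decided = true;
            significant = false;
            break;
        }
        while (ci < nchk && done >= chk_n[ci]) {
            if (done == chk_n[ci] && exceed <= chk_kmax[ci]) {
                decided = true;
                significant = true;
            }
            ++ci;
            if (decided) break;
        }
        if (decided) break;
    }
    double pval = (exceed + 1.0) / (done + 1.0);
    if (!decided) significant = pval < alpha;
    return List::create(_["index"] = best_i, _["stat2"] = obs,
                        _["p_value"] = pval, _["significant"] = significant,
                        _["nperm_used"] = done);
}
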