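// Two-state hidden-Markov machinery for burst detection in spike-count
// series: scaled forward-backward / Baum-Welch with Poisson emissions, and a
// variant for avalanche detection where the low state's emission table is
// clamped to p(0) = 1 - p1, p(1) = p1, p(n >= 2) = 0.  Log-space Viterbi.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// emission probability tables for counts 0..maxc, one per state
static void emission_tables(int maxc, double lam0, double lam1, bool clamp,
                            double p1, std::vector<double> &b0,
                            std::vector<double> &b1) {
    b0.resize(maxc + 1);
    b1.resize(maxc + 1);
    for (int n = 0; n <= maxc; ++n) {
        if (clamp)
            b0[n] = (n == 0) ? (1.0 - p1) : ((n == 1) ? p1 : 0.0);
        else
            b0[n] = (lam0 > 0.0) ? R::dpois(n, lam0, 0) : (n == 0 ? 1.0 : 0.0);
        b1[n] = (lam1 > 0.0) ? R::dpois(n, lam1, 0) : (n == 0 ? 1.0 : 0.0);
    }
}

// [[Rcpp::export(name = ".hmm_baum_welch_cpp")]]
List hmm_baum_welch_cpp(IntegerVector counts, double lam0, double lam1,
                        double stay0, double stay1, bool clamp, double p1,
                        int max_iter, double tol) {
    const R_xlen_t T = counts.size();
    int maxc = 0;
    for (R_xlen_t t = 0; t < T; ++t)
        if (counts[t] > maxc) maxc = counts[t];

    double pi0 = 0.5, pi1 = 0.5;
    double a00 = stay0, a01 = 1.0 - stay0, a10 = 1.0 - stay1, a11 = stay1;

    std::vector<double> alpha0(T), alpha1(T), scale(T);
    std::vector<double> b0, b1;
    std::vector<double> loglik_trace;
    bool converged = false;

    for (int iter = 0; iter < max_iter; ++iter) {
        emission_tables(maxc, lam0, lam1, clamp, p1, b0, b1);

        // scaled forward pass
        double a0 = pi0 * b0[counts[0]], a1 = pi1 * b1[counts[0]];
        double c0 = a0 + a1;
        if (c0 <= 0.0) stop("HMM forward pass: zero likelihood at t = 0");
        alpha0[0] = a0 / c0; alpha1[0] = a1 / c0; scale[0] = c0;
        double ll = std::log(c0);
        for (R_xlen_t t = 1; t < T; ++t) {
            double p0 = (alpha0[t - 1] * a00 + alpha1[t - 1] * a10) * b0[counts[t]];
            double p1s = (alpha0[t - 1] * a01 + alpha1[t - 1] * a11) * b1[counts[t]];
            double ct = p0 + p1s;
            if (ct <= 0.0)
                stop("HMM forward pass: zero likelihood at t = %.0f", (double)t);
            alpha0[t] = p0 / ct; alpha1[t] = p1s / ct; scale[t] = ct;
            ll += std::log(ct);
        }
        loglik_trace.push_back(ll);
        if (iter > 0) {
            double prev = loglik_trace[iter - 1];
            if (ll - prev <= tol * (std::fabs(prev) + 1.0)) {
                converged = true;
                break;
            }
        }

        // backward pass, accumulating sufficient statistics on the fly
        double g_sum0 = 0.0, g_sum1 = 0.0;      // sum_t gamma_t(i), t < T-1
        double x00 = 0.0, x01 = 0.0, x10 = 0.0, x11 = 0.0;
        double e_w0 = 0.0, e_w1 = 0.0, e_c0 = 0.0, e_c1 = 0.0;
        double beta0 = 1.0, beta1 = 1.0;
        double g0_last = alpha0[T - 1], g1_last = alpha1[T - 1];
        e_w0 += g0_last; e_c0 += g0_last * counts[T - 1];
        e_w1 += g1_last; e_c1 += g1_last * counts[T - 1];
        double gamma0_first = 0.0, gamma1_first = 0.0;
        for (R_xlen_t t = T - 2; t >= 0; --t) {
            double bb0 = b0[counts[t + 1]] * beta0;
            double bb1 = b1[counts[t + 1]] * beta1;
            double nb0 = (a00 * bb0 + a01 * bb1) / scale[t + 1];
            double nb1 = (a10 * bb0 + a11 * bb1) / scale[t + 1];
            // xi_t(i,j) proportional to alpha_t(i) a_ij b_j(o_{t+1}) beta_{t+1}(j)
            double q00 = alpha0[t] * a00 * bb0 / scale[t + 1];
            double q01 = alpha0[t] * a01 * bb1 / scale[t + 1];
            double q10 = alpha1[t] * a10 * bb0 / scale[t + 1];
            double q11 = alpha1[t] * a11 * bb1 / scale[t + 1];
            x00 += q00; x01 += q01; x10 += q10; x11 += q11;
            double g0 = alpha0[t] * nb0, g1 = alpha1[t] * nb1;
            g_sum0 += g0; g_sum1 += g1;
            e_w0 += g0; e_c0 += g0 * counts[t];
            e_w1 += g1; e_c1 += g1 * counts[t];
            beta0 = nb0; beta1 = nb1;
            if (t == 0) { gamma0_first = g0; gamma1_first = g1; }
        }

        pi0 = gamma0_first; pi1 = gamma1_first;
        double s = pi0 + pi1;
        pi0 /= s; pi1 /= s;
        if (g_sum0 > 0.0) { a00 = x00 / g_sum0; a01 = x01 / g_sum0; }
        if (g_sum1 > 0.0) { a10 = x10 / g_sum1; a11 = x11 / g_sum1; }
        // guard against absorbing degeneracy
        double eps = 1e-12;
        a00 = std::min(std::max(a00, eps), 1.0 - eps); a01 = 1.0 - a00;
        a11 = std::min(std::max(a11, eps), 1.0 - eps); a10 = 1.0 - a11;
        if (!clamp && e_w0 > 0.0) lam0 = e_c0 / e_w0;
        if (e_w1 > 0.0) lam1 = e_c1 / e_w1;
    }

    return List::create(
        _["lambda"] = NumericVector::create(lam0, lam1),
        _["trans"] = NumericMatrix(2, 2, NumericVector::create(a00, a10, a01, a11).begin()),
        _["init"] = NumericVector::create(pi0, pi1),
        _["loglik"] = NumericVector(loglik_trace.begin(), loglik_trace.end()),
        _["converged"] = converged);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(IntegerVector counts, double lam0, double lam1,
                              NumericMatrix trans, NumericVector init,
                              bool clamp, double p1) {
    const R_xlen_t T = counts.size();
    IntegerVector path(T);
    if (T == 0) return path;
    int maxc = 0;
    for (R_xlen_t t = 0; t < T; ++t)
        if (counts[t] > maxc) maxc = counts[t];

    const double NEG = -1e300;
    std::vector<double> lb0(maxc + 1), lb1(maxc + 1);
    for (int n = 0; n <= maxc; ++n) {
        double p0, p1v;
        if (clamp)
            p0 = (n == 0) ? (1.0 - p1) : ((n == 1) ? p1 : 0.0);
        else
            p0 = (lam0 > 0.0) ? R::dpois(n, lam0, 0) : (n == 0 ? 1.0 : 0.0);
        p1v = (lam1 > 0.0) ? R::dpois(n, lam1, 0) : (n == 0 ? 1.0 : 0.0);
        lb0[n] = p0 > 0.0 ? std::log(p0) : NEG;
        lb1[n] = p1v > 0.0 ? std::log(p1v) : NEG;
    }
    double la00 = trans(0, 0) > 0 ? std::log(trans(0, 0)) : NEG;
    double la01 = trans(0, 1) > 0 ? std::log(trans(0, 1)) : NEG;
    double la10 = trans(1, 0) > 0 ? std::log(trans(1, 0)) : NEG;
    double la11 = trans(1, 1) > 0 ? std::log(trans(1, 1)) : NEG;

    std::vector<signed char> back(2 * T);
    double d0 = (init[0] > 0 ? std::log(init[0]) : NEG) + lb0[counts[0]];
    double d1 = (init[1] > 0 ? std::log(init[1]) : NEG) + lb1[counts[0]];
    for (R_xlen_t t = 1; t < T; ++t) {
        double c00 = d0 + la00, c10 = d1 + la10;
        double c01 = d0 + la01, c11 = d1 + la11;
        double n0, n1;
        if (c00 >= c10) { n0 = c00; back[2 * t] = 0; } else { n0 = c10; back[2 * t] = 1; }
        if (c11 >= c01) { n1 = c11; back[2 * t + 1] = 1; } else { n1 = c01; back[2 * t + 1] = 0; }
        d0 = n0 + lb0[counts[t]];
        d1 = n1 + lb1[counts[t]];
    }
    int s = d1 > d0 ? 1 : 0;
    path[T - 1] = s;
    for (R_xlen_t t = T - 1; t >= 1; --t) {
        s = back[2 * t + s];
        path[t - 1] = s;
    }
    return path;
}

// log-likelihood of a fixed state path (for tests / diagnostics)
// [[Rcpp::export(name = ".hmm_path_loglik_cpp")]]
double hmm_path_loglik_cpp(IntegerVector counts, IntegerVector path,
                           double lam0, double lam1, NumericMatrix trans,
                           NumericVector init, bool clamp, double p1) {
    const R_xlen_t T = counts.size();
    const double NEG = -1e300;
    auto lemit = [&](int s, int n) {
        double p;
        if (s == 0) {
            if (clamp)
                p = (n == 0) ? (1.0 - p1) : ((n == 1) ? p1 : 0.0);
            else
                p = (lam0 > 0.0) ? R::dpois(n, lam0, 0) : (n == 0 ? 1.0 : 0.0);
        } else
            p = (lam1 > 0.0) ? R::dpois(n, lam1, 0) : (n == 0 ? 1.0 : 0.0);
        return p > 0.0 ? std::log(p) : NEG;
    };
    double ll = (init[path[0]] > 0 ? std::log(init[path[0]]) : NEG) +
                lemit(path[0], counts[0]);
    for (R_xlen_t t = 1; t < T; ++t) {
        double a = trans(path[t - 1], path[t]);
        ll += (a > 0 ? std::log(a) : NEG) + lemit(path[t], counts[t]);
    }
    return ll;
}
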