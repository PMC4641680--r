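// Leaky integrate-and-fire transfer function (Ricciardi first-passage rate).
//
// Phi(mu, sigma2) = 1 / ( sqrt(pi) tau_V * I + tau_ref ),
//   I = int_a^b exp(s^2) (1 + erf(s)) ds,
//   a = (V_reset - V_rest - mu tau_V) / sqrt(sigma2 tau_V),
//   b = (V_thresh - V_rest - mu tau_V) / sqrt(sigma2 tau_V).
//
// The integrand equals erfcx(-s); for s <= ~26 it is representable in a
// double, beyond that the rate has underflowed to zero and an asymptotic
// log-scale evaluation is used instead.

#include <Rcpp.h>
#include <cmath>
#include "transfer.h"

static const double SQRT_PI = 1.7724538509055160273;

double erfcx_upper(double x) {
    // x >= 0; exp(x^2)*erfc(x) is accurate up to x ~ 26, asymptotic beyond
    if (x < 26.0) return std::exp(x * x) * std::erfc(x);
    double ix2 = 1.0 / (x * x);
    return (1.0 - 0.5 * ix2 * (1.0 - 1.5 * ix2 * (1.0 - 2.5 * ix2))) /
           (x * SQRT_PI);
}

double lif_integrand(double s) {
    if (s <= 0.0) return erfcx_upper(-s);
    // erfcx(-s) = 2 exp(s^2) - erfcx(s); overflows only for s > ~26.6
    return 2.0 * std::exp(s * s) - erfcx_upper(s);
}

// 15-point Gauss-Legendre nodes/weights on [-1, 1] (symmetric half listed)
static const double GL15_X[8] = {
    0.0000000000000000, 0.2011940939974345, 0.3941513470775634,
    0.5709721726085388, 0.7244177313601700, 0.8482065834104272,
    0.9372733924007059, 0.9879925180204854};
static const double GL15_W[8] = {
    0.2025782419255613, 0.1984314853271116, 0.1861610000155622,
    0.1662692058169939, 0.1395706779261543, 0.1071592204671719,
    0.0703660474881081, 0.0307532419961173};
// embedded 7-point Gauss-Legendre for the error estimate
static const double GL7_X[4] = {
    0.0000000000000000, 0.4058451513773972, 0.7415311855993945,
    0.9491079123427585};
static const double GL7_W[4] = {
    0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
    0.1294849661688697};

static void gl_pair(double lo, double hi, double *i15, double *i7) {
    double c = 0.5 * (lo + hi), h = 0.5 * (hi - lo);
    double s15 = GL15_W[0] * lif_integrand(c);
    for (int k = 1; k < 8; ++k)
        s15 += GL15_W[k] * (lif_integrand(c - h * GL15_X[k]) +
                            lif_integrand(c + h * GL15_X[k]));
    double s7 = GL7_W[0] * lif_integrand(c);
    for (int k = 1; k < 4; ++k)
        s7 += GL7_W[k] * (lif_integrand(c - h * GL7_X[k]) +
                          lif_integrand(c + h * GL7_X[k]));
    *i15 = s15 * h;
    *i7 = s7 * h;
}

// adaptive bisection with a GL7/GL15 pair; per-segment relative acceptance
static double adapt_segment(double lo, double hi, double tol, int depth) {
    double i15, i7;
    gl_pair(lo, hi, &i15, &i7);
    if (depth >= 40) return i15;
    double err = std::fabs(i15 - i7);
    if (err <= tol * std::fabs(i15) || err < 1e-300) return i15;
    double mid = 0.5 * (lo + hi);
    return adapt_segment(lo, mid, tol, depth + 1) +
           adapt_segment(mid, hi, tol, depth + 1);
}

double lif_phi_core(double mu, double sigma2,
                    double tau_V, double tau_ref,
                    double V_rest, double V_reset, double V_thresh,
                    double tol) {
    if (sigma2 <= 0.0) return NA_REAL;
    double sd = std::sqrt(sigma2 * tau_V);
    double a = (V_reset - V_rest - mu * tau_V) / sd;
    double b = (V_thresh - V_rest - mu * tau_V) / sd;
    if (tol <= 0.0) tol = 1e-10;

    if (b > 25.0) {
        // I ~ exp(b^2)/b * (1 + 1/(2 b^2)): work with log(tau_V sqrt(pi) I)
        double logI = b * b - std::log(b) + std::log1p(0.5 / (b * b));
        double logT = std::log(SQRT_PI * tau_V) + logI;
        if (logT > 700.0) return 0.0;
        return 1.0 / (std::exp(logT) + tau_ref);
    }
    double I = adapt_segment(a, b, tol, 0);
    double denom = SQRT_PI * tau_V * I + tau_ref;
    if (denom <= 0.0) return NA_REAL;  // b < a cannot happen (thresh > reset)
    return 1.0 / denom;
}

//' @useDynLib netevents, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export(name = ".phi_cpp")]]
Rcpp::NumericVector phi_cpp(Rcpp::NumericVector mu, Rcpp::NumericVector sigma2,
                            double tau_V, double tau_ref, double V_rest,
                            double V_reset, double V_thresh, double tol) {
    R_xlen_t n = std::max(mu.size(), sigma2.size());
    Rcpp::NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = lif_phi_core(mu[i % mu.size()], sigma2[i % sigma2.size()],
                              tau_V, tau_ref, V_rest, V_reset, V_thresh, tol);
    return out;
}
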