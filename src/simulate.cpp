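// Explicit-Euler integrator of the stochastic two-population rate model with
// short-term depression, optional spike-frequency adaptation, and finite-size
// Poisson noise (per-step spike counts with mean n nu dt).
//
// State vector: (nu_E, nu_I, nut_E, nut_I, r_E, c_E); rates in kHz, times ms.

#include <Rcpp.h>
#include <cmath>
#include "transfer.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(NumericVector par, NumericVector init,
                     double duration, double dt, double burn_in,
                     int record_stride, bool noise, double phi_tol) {
    const double n_E = par["n_E"], n_I = par["n_I"], c = par["c"];
    const double w_e = par["w_exc"], w_i = par["w_inh"];
    const double J_EE = par["J_EE"] * w_e, s2_EE = std::pow(par["sigma_J_EE"], 2);
    const double J_IE = par["J_IE"] * w_e, s2_IE = std::pow(par["sigma_J_IE"], 2);
    const double J_EI = par["J_EI"] * w_i, s2_EI = std::pow(par["sigma_J_EI"], 2);
    const double J_II = par["J_II"] * w_i, s2_II = std::pow(par["sigma_J_II"], 2);
    const double J_ext = par["J_ext"], s2_ext = std::pow(par["sigma_J_ext"], 2);
    const double nu_ext = par["nu_ext"];
    const double cE = c * n_E, cI = c * n_I;
    const double vEE = w_e * w_e * (par["J_EE"] * par["J_EE"] + s2_EE);
    const double vIE = w_e * w_e * (par["J_IE"] * par["J_IE"] + s2_IE);
    const double vEI = w_i * w_i * (par["J_EI"] * par["J_EI"] + s2_EI);
    const double vII = w_i * w_i * (par["J_II"] * par["J_II"] + s2_II);
    const double vext = nu_ext * (J_ext * J_ext + s2_ext);
    const double mu_ext = nu_ext * J_ext;
    const double tau_E = par["tau_E"], tau_I = par["tau_I"];
    const double tt_E = par["tau_filter_E"], tt_I = par["tau_filter_I"];
    const double tau_STD = par["tau_STD"], u_STD = par["u_STD"];
    const double g_SFA = par["g_SFA"], tau_SFA = par["tau_SFA"];
    const double tau_V = par["tau_V"], tau_ref = par["tau_refract"];
    const double V_rest = par["V_rest"], V_reset = par["V_reset"],
                 V_thresh = par["V_thresh"];

    const long n_burn = (long)std::llround(burn_in / dt);
    const long n_rec = (long)std::llround(duration / dt);
    const long n_out = (n_rec + record_stride - 1) / record_stride;

    NumericVector count_E(n_rec), count_I(n_rec);
    NumericMatrix states(n_out, 6);
    NumericVector time_out(n_out);

    double nuE = init[0], nuI = init[1], ntE = init[2], ntI = init[3],
           rE = init[4], cA = init[5];

    RNGScope scope;
    long rec_i = 0;
    for (long step = -n_burn; step < n_rec; ++step) {
        if (step >= 0 && (step % record_stride) == 0) {
            time_out[rec_i] = step * dt;
            states(rec_i, 0) = nuE; states(rec_i, 1) = nuI;
            states(rec_i, 2) = ntE; states(rec_i, 3) = ntI;
            states(rec_i, 4) = rE;  states(rec_i, 5) = cA;
            ++rec_i;
        }
        double muE = cE * ntE * J_EE * rE + cI * ntI * J_EI + mu_ext
                     - g_SFA * cA;
        double s2E = cE * ntE * vEE * rE * rE + cI * ntI * vEI + vext;
        double muI = cE * ntE * J_IE * rE + cI * ntI * J_II + mu_ext;
        double s2I = cE * ntE * vIE * rE * rE + cI * ntI * vII + vext;

        double phiE = lif_phi_core(muE, s2E, tau_V, tau_ref, V_rest, V_reset,
                                   V_thresh, phi_tol);
        double phiI = lif_phi_core(muI, s2I, tau_V, tau_ref, V_rest, V_reset,
                                   V_thresh, phi_tol);

        double kE, kI, nu_nE, nu_nI;
        if (noise) {
            kE = R::rpois(n_E * nuE * dt);
            kI = R::rpois(n_I * nuI * dt);
            nu_nE = kE / (n_E * dt);
            nu_nI = kI / (n_I * dt);
        } else {
            nu_nE = nuE; nu_nI = nuI;
            kE = n_E * nuE * dt; kI = n_I * nuI * dt;
        }
        if (step >= 0) { count_E[step] = kE; count_I[step] = kI; }

        double nuE1 = nuE + dt / tau_E * (phiE - nuE);
        double nuI1 = nuI + dt / tau_I * (phiI - nuI);
        double ntE1 = ntE + dt / tt_E * (nu_nE - ntE);
        double ntI1 = ntI + dt / tt_I * (nu_nI - ntI);
        double rE1 = rE + dt * ((1.0 - rE) / tau_STD - u_STD * rE * ntE);
        double cA1 = cA + dt / tau_SFA * (nu_nE - cA);

        // Euler overshoot guards
        nuE = nuE1 > 0.0 ? nuE1 : 0.0;
        nuI = nuI1 > 0.0 ? nuI1 : 0.0;
        ntE = ntE1 > 0.0 ? ntE1 : 0.0;
        ntI = ntI1 > 0.0 ? ntI1 : 0.0;
        rE = rE1 < 0.0 ? 0.0 : (rE1 > 1.0 ? 1.0 : rE1);
        cA = cA1 > 0.0 ? cA1 : 0.0;

        if (!(std::isfinite(nuE) && std::isfinite(nuI) && std::isfinite(ntE) &&
              std::isfinite(ntI) && std::isfinite(rE) && std::isfinite(cA)))
            stop("simulation diverged (non-finite state) at step %.0f (t = %.3f ms)",
                 (double)step, step * dt);
    }

    return List::create(_["time"] = time_out, _["states"] = states,
                        _["count_E"] = count_E, _["count_I"] = count_I);
}
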