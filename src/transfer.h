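#ifndef NETEVENTS_TRANSFER_H
#define NETEVENTS_TRANSFER_H

// erfcx(x) = exp(x^2) erfc(x) for x >= 0, overflow-safe
double erfcx_upper(double x);

// integrand of the first-passage-time integral: exp(s^2)(1 + erf(s)) = erfcx(-s)
double lif_integrand(double s);

// LIF transfer function (rate in kHz).  tol is the relative quadrature
// tolerance; mu in mV/ms, sigma2 in mV^2/ms, times in ms, potentials in mV.
double lif_phi_core(double mu, double sigma2,
                    double tau_V, double tau_ref,
                    double V_rest, double V_reset, double V_thresh,
                    double tol);

#endif
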