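#' Single-neuron transfer-function parameters
#'
#' Membrane constants of the leaky integrate-and-fire neuron whose
#' first-passage-time transfer function maps mean and variance of the input
#' current onto an output firing rate.  Defaults are the reference set used
#' throughout the package.  Membrane resistance is taken as 1, so currents
#' are expressed in mV/ms.
#'
#' @param tau_V membrane time constant (ms)
#' @param tau_refract absolute refractory period (ms)
#' @param V_rest resting potential (mV)
#' @param V_reset post-spike reset potential (mV)
#' @param V_thresh firing threshold (mV)
#' @return an object of class `transfer_params`
#' @export
transfer_params <- function(tau_V = 20, tau_refract = 2,
                            V_rest = -70, V_reset = -70, V_thresh = -55) {
  stopifnot(tau_V > 0, tau_refract >= 0,
            V_reset <= V_thresh, V_rest <= V_thresh)
  structure(list(tau_V = tau_V, tau_refract = tau_refract, V_rest = V_rest,
                 V_reset = V_reset, V_thresh = V_thresh),
            class = "transfer_params")
}

#' Leaky integrate-and-fire transfer function
#'
#' Stationary firing rate of a leaky integrate-and-fire neuron receiving
#' Gaussian white-noise current of mean `mu` and infinitesimal variance
#' `sigma2` (Ricciardi first-passage-time rate),
#' \deqn{\Phi(\mu,\sigma^2) = \left[\sqrt{\pi}\,\tau_V
#'   \int_a^b e^{s^2}(1+\mathrm{erf}(s))\,ds + \tau_{refract}\right]^{-1},}
#' with \eqn{a,b} the reset and threshold expressed in units of the
#' stationary membrane-potential fluctuation \eqn{\sqrt{\sigma^2\tau_V}}.
#' The integrand \eqn{e^{s^2}(1+\mathrm{erf} s) = \mathrm{erfcx}(-s)} is
#' evaluated through a scaled complementary error function so that
#' integration bounds of magnitude up to ~30 neither overflow nor lose the
#' result; beyond that the rate is computed on the log scale (and is
#' numerically zero).
#'
#' @param mu mean input current (mV/ms, unit membrane resistance)
#' @param sigma2 infinitesimal variance of the input current (mV^2/ms);
#'   must be positive
#' @param p a [transfer_params()] object
#' @param tol relative quadrature tolerance (adaptive Gauss rule)
#' @return firing rate in kHz (1/ms); vectorised over `mu` and `sigma2`
#' @export
lif_phi <- function(mu, sigma2, p = transfer_params(), tol = 1e-10) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("lif_phi: sigma2 must be positive and finite")
  .phi_cpp(as.numeric(mu), as.numeric(sigma2), p$tau_V, p$tau_refract,
           p$V_rest, p$V_reset, p$V_thresh, tol)
}

#' Mean and variance of the recurrent synaptic currents
#'
#' Infinitesimal mean and variance of the input currents to the excitatory
#' and inhibitory populations given the synaptically filtered rates, the
#' available excitatory synaptic resources, and the network parameters:
#' \deqn{\mu_E = c n_E \tilde\nu_E w_{exc} J_{EE} r_E
#'             + c n_I \tilde\nu_I w_{inh} J_{EI} + \nu_{ext} J_{ext},}
#' with the variance analogue using squared efficacies \eqn{J^2+\sigma_J^2}
#' and \eqn{r_E^2}, and mirror expressions (via \eqn{J_{IE}, J_{II}}) for the
#' inhibitory population.  Depression multiplies every excitatory efficacy,
#' so the resource fraction enters both populations' excitatory terms.
#'
#' @param nu_tilde_E,nu_tilde_I filtered population rates (kHz)
#' @param r_E fraction of available excitatory synaptic resources in `[0,1]`
#' @param p a [network_params()] object
#' @param c_SFA adaptation variable; its contribution `-g_SFA * c_SFA` is
#'   added to the excitatory mean current
#' @return list with `mu_E`, `sigma2_E`, `mu_I`, `sigma2_I` (mV/ms, mV^2/ms)
#' @export
current_moments <- function(nu_tilde_E, nu_tilde_I, r_E, p, c_SFA = 0) {
  stopifnot(nu_tilde_E >= 0, nu_tilde_I >= 0, r_E >= 0, r_E <= 1)
  kE <- p$c * p$n_E * nu_tilde_E
  kI <- p$c * p$n_I * nu_tilde_I
  we <- p$w_exc
  wi <- p$w_inh
  mu_E <- kE * we * p$J_EE * r_E + kI * wi * p$J_EI + p$nu_ext * p$J_ext -
    p$g_SFA * c_SFA
  s2_E <- kE * we^2 * (p$J_EE^2 + p$sigma_J_EE^2) * r_E^2 +
    kI * wi^2 * (p$J_EI^2 + p$sigma_J_EI^2) +
    p$nu_ext * (p$J_ext^2 + p$sigma_J_ext^2)
  mu_I <- kE * we * p$J_IE * r_E + kI * wi * p$J_II + p$nu_ext * p$J_ext
  s2_I <- kE * we^2 * (p$J_IE^2 + p$sigma_J_IE^2) * r_E^2 +
    kI * wi^2 * (p$J_II^2 + p$sigma_J_II^2) +
    p$nu_ext * (p$J_ext^2 + p$sigma_J_ext^2)
  list(mu_E = mu_E, sigma2_E = s2_E, mu_I = mu_I, sigma2_I = s2_I)
}
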