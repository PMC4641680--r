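#' Network model parameters
#'
#' Biophysical and synaptic constants of the two-population stochastic rate
#' model.  Defaults are the reference parameter set: a sparse random network
#' of 160 excitatory and 40 inhibitory neurons with connection probability
#' 0.25, AMPA/GABA-like synaptic filter times, short-term depression on all
#' excitatory synapses, and an external Poisson drive.  The dimensionless
#' factors `w_exc` and `w_inh` rescale all excitatory (`J_EE`, `J_IE`) and
#' all inhibitory (`J_EI`, `J_II`) efficacies and parameterise the
#' excitation-inhibition plane explored in the stability and event analyses.
#'
#' Spike-frequency adaptation is disabled by default (`g_SFA = 0`); when
#' enabled, the adaptation variable integrates the noisy excitatory rate
#' with time constant `tau_SFA` and subtracts `g_SFA * c_E` from the
#' excitatory mean current.
#'
#' @param n_E,n_I number of excitatory / inhibitory neurons
#' @param c connection probability
#' @param J_EE,J_IE,J_EI,J_II,J_ext mean synaptic efficacies (mV); the first
#'   index is the postsynaptic population.  Inhibitory efficacies are
#'   negative.
#' @param sigma_J_EE,sigma_J_IE,sigma_J_EI,sigma_J_II,sigma_J_ext standard
#'   deviations of the efficacy distributions (mV)
#' @param nu_ext external Poisson rate (kHz)
#' @param tau_E,tau_I rate relaxation time constants (ms)
#' @param tau_filter_E,tau_filter_I synaptic filter time constants (ms)
#' @param tau_STD recovery time of the depleted synaptic resources (ms)
#' @param u_STD fraction of resources consumed per release, in (0,1)
#' @param g_SFA adaptation conductance (mV/ms per unit of the adaptation
#'   variable, which carries kHz units); 0 disables adaptation
#' @param tau_SFA adaptation time constant (ms)
#' @param w_exc,w_inh dimensionless scale factors of excitation / inhibition
#' @param transfer a [transfer_params()] object
#' @return an object of class `network_params`
#' @export
network_params <- function(n_E = 160, n_I = 40, c = 0.25,
                           J_EE = 0.809, sigma_J_EE = 0.202,
                           J_IE = 1.23, sigma_J_IE = 0.307,
                           J_EI = -0.340, sigma_J_EI = 0.0850,
                           J_II = -0.358, sigma_J_II = 0.0894,
                           J_ext = 0.416, sigma_J_ext = 0.104,
                           nu_ext = 1.25,
                           tau_E = 20, tau_I = 20,
                           tau_filter_E = 10, tau_filter_I = 2,
                           tau_STD = 800, u_STD = 0.2,
                           g_SFA = 0, tau_SFA = 15000,
                           w_exc = 1, w_inh = 1,
                           transfer = transfer_params()) {
  stopifnot(n_E >= 1, n_I >= 0, c > 0, c <= 1,
            u_STD > 0, u_STD < 1,
            tau_E > 0, tau_I > 0, tau_filter_E > 0, tau_filter_I > 0,
            tau_STD > 0, tau_SFA > 0, g_SFA >= 0,
            nu_ext >= 0, w_exc >= 0, w_inh >= 0,
            inherits(transfer, "transfer_params"))
  p <- list(n_E = n_E, n_I = n_I, c = c,
            J_EE = J_EE, sigma_J_EE = sigma_J_EE,
            J_IE = J_IE, sigma_J_IE = sigma_J_IE,
            J_EI = J_EI, sigma_J_EI = sigma_J_EI,
            J_II = J_II, sigma_J_II = sigma_J_II,
            J_ext = J_ext, sigma_J_ext = sigma_J_ext,
            nu_ext = nu_ext, tau_E = tau_E, tau_I = tau_I,
            tau_filter_E = tau_filter_E, tau_filter_I = tau_filter_I,
            tau_STD = tau_STD, u_STD = u_STD,
            g_SFA = g_SFA, tau_SFA = tau_SFA,
            w_exc = w_exc, w_inh = w_inh,
            tau_V = transfer$tau_V, tau_refract = transfer$tau_refract,
            V_rest = transfer$V_rest, V_reset = transfer$V_reset,
            V_thresh = transfer$V_thresh)
  structure(p, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("network_params: n_E = %g, n_I = %g, c = %g (c*n_E = %g)\n",
              x$n_E, x$n_I, x$c, x$c * x$n_E))
  cat(sprintf("  w_exc = %g, w_inh = %g, nu_ext = %g kHz\n",
              x$w_exc, x$w_inh, x$nu_ext))
  cat(sprintf("  STD: tau_STD = %g ms, u_STD = %g;  SFA: g_SFA = %g (tau_SFA = %g ms)\n",
              x$tau_STD, x$u_STD, x$g_SFA, x$tau_SFA))
  invisible(x)
}

#' Transfer parameters embedded in a network parameter set
#' @param p a [network_params()] object
#' @return the embedded [transfer_params()] object
#' @export
transfer_of <- function(p) {
  transfer_params(p$tau_V, p$tau_refract, p$V_rest, p$V_reset, p$V_thresh)
}

#' Rescale the network size at constant connectivity per neuron
#'
#' Changes the total number of neurons while holding the number of synaptic
#' connections per neuron (`c * n_E`, `c * n_I`) constant by rescaling the
#' connection probability, so that the deterministic mean-field equations
#' are invariant and only the finite-size noise amplitude changes.  The
#' 4:1 excitatory:inhibitory ratio is preserved.
#'
#' @param p a [network_params()] object
#' @param n_new_total new total neuron count (>= 10, multiple of 5
#'   recommended so the 4:1 split is exact)
#' @return a rescaled `network_params` object
#' @export
scale_network <- function(p, n_new_total) {
  stopifnot(inherits(p, "network_params"), n_new_total >= 10)
  n_E_new <- round(0.8 * n_new_total)
  n_I_new <- round(0.2 * n_new_total)
  c_new <- p$c * p$n_E / n_E_new
  if (c_new > 1)
    stop("scale_network: rescaled connection probability exceeds 1 ",
         "(network too small for the requested connectivity)")
  p$n_E <- n_E_new
  p$n_I <- n_I_new
  p$c <- c_new
  p
}
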