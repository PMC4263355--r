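#' Peak deviation of a single postsynaptic potential from rest
#'
#' Integrates the membrane equation for one synaptic input of given peak
#' conductance delivered at rest, with the conductance following the analytic
#' double-exponential kernel, and returns the PSP peak deviation from `E_L`.
#' Exponential-Euler integration with the conductance evaluated analytically
#' at each step; no spiking (used in the small-signal regime only).
#'
#' @param eps peak conductance of the input (nS)
#' @param neuron a [neuron_params()]
#' @param kernel a [synapse_kernel()] carrying the reversal potential
#' @param dt integration step (ms)
#' @param t_max integration horizon (ms)
#' @return signed peak deviation (mV): positive for an EPSP, negative for an IPSP
#' @export
psp_peak <- function(eps, neuron, kernel, dt = 0.01, t_max = 30) {
  if (eps == 0) return(0)
  tt <- seq(0, t_max, by = dt)
  g <- eps * conductance_kernel(tt, kernel)
  V <- neuron$E_L
  dev <- 0
  for (i in seq_along(tt)) {
    g_tot <- neuron$g_L + g[i]
    V_inf <- (neuron$g_L * neuron$E_L + g[i] * kernel$E_rev) / g_tot
    V <- V_inf + (V - V_inf) * exp(-dt * g_tot / neuron$C_m)
    d <- V - neuron$E_L
    if (abs(d) > abs(dev)) dev <- d
  }
  dev
}

#' Excitation/inhibition balance ratio
#'
#' The ratio \eqn{\alpha} such that an inhibitory input of strength
#' \eqn{\alpha \varepsilon} produces a single-IPSP peak hyperpolarization from
#' rest equal in magnitude to the peak depolarization of a single EPSP of
#' strength \eqn{\varepsilon}. Computed numerically once per parameter set by
#' root finding in the small-signal regime (the conductance-based PSP peak is
#' mildly nonlinear in strength, so `alpha` is defined at a reference
#' excitatory strength).
#'
#' @param neuron a [neuron_params()]
#' @param kernel_ex,kernel_in excitatory and inhibitory [synapse_kernel()]s;
#'   their reversal potentials must bracket `E_L`
#' @param eps_ref reference excitatory strength (nS)
#' @param dt integration step (ms)
#' @return the unitless ratio \eqn{\alpha}
#' @export
balance_ratio <- function(neuron, kernel_ex, kernel_in, eps_ref = 1, dt = 0.01) {
  if (!(kernel_ex$E_rev > neuron$E_L && kernel_in$E_rev < neuron$E_L))
    stop("reversal potentials must bracket E_L; balance undefined")
  target <- psp_peak(eps_ref, neuron, kernel_ex, dt = dt)
  f <- function(a) abs(psp_peak(a * eps_ref, neuron, kernel_in, dt = dt)) - target
  # crude bracket: |E_in - E_L| is small vs |E_ex - E_L|, so alpha > 1 typically
  hi <- 2
  while (f(hi) < 0 && hi < 1024) hi <- hi * 2
  stats::uniroot(f, c(1e-6, hi), tol = 1e-6)$root
}

#' Balanced inhibitory strength for a given excitatory strength
#'
#' Returns \eqn{\alpha_{bal} \cdot \varepsilon_{ex}} where the ratio is
#' computed by [balance_ratio()] (numerically, once per call; cache the ratio
#' via [standard_params()] for repeated use).
#'
#' @inheritParams balance_ratio
#' @param eps_ex excitatory peak conductance (nS)
#' @return balanced inhibitory peak conductance (nS)
#' @export
balanced_inhibitory_strength <- function(eps_ex, neuron, kernel_ex, kernel_in,
                                         dt = 0.01) {
  stopifnot(eps_ex >= 0)
  if (eps_ex == 0) return(0)
  eps_ex * balance_ratio(neuron, kernel_ex, kernel_in, dt = dt)
}
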