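#' Membrane parameters of a conductance-based integrate-and-fire neuron
#'
#' The membrane potential \eqn{V} obeys
#' \deqn{C_m \dot V = g_L (E_L - V) + I_{ex}(t) + I_{in}(t) + I_{ds}(t) + I_0,}
#' with conductance-based synaptic currents \eqn{I_{ex} = g_{ex}(t)(E_{ex}-V)},
#' \eqn{I_{in} = g_{in}(t)(E_{in}-V)}, an optional dendritic-spike current
#' \eqn{I_{ds}} and an optional constant injected current \eqn{I_0}. When
#' \eqn{V} reaches the threshold `V_theta` a somatic spike is emitted, `V` is
#' clamped to `V_reset` for the refractory period `t_ref`.
#'
#' Units follow the usual convention for point-neuron models: pF, nS, mV, ms.
#' Note pF/nS = ms and nS*mV = pA, so the membrane time constant is
#' `C_m / g_L` in ms.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak (equilibrium) potential (mV)
#' @param V_theta somatic spike threshold (mV)
#' @param V_reset reset potential (mV)
#' @param t_ref absolute refractory period (ms); `V` is clamped at `V_reset`
#'   for this long after a spike
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(C_m = 400, g_L = 25, E_L = -65,
                          V_theta = -50, V_reset = -65, t_ref = 3) {
  stopifnot(C_m > 0, g_L > 0, V_reset < V_theta, t_ref >= 0)
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, V_theta = V_theta,
                 V_reset = V_reset, t_ref = t_ref),
            class = "neuron_params")
}

#' Double-exponential synaptic conductance kernel
#'
#' Conductance time course of a single synaptic input,
#' \deqn{g(t) = \bar g \, c \,(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}), \quad t \ge 0,}
#' where the normalization constant \eqn{c} is chosen so that the kernel peak
#' equals 1: an input of strength \eqn{\varepsilon} (nS) produces a peak
#' conductance of exactly \eqn{\varepsilon}. Synaptic "strength" therefore
#' always means peak conductance.
#'
#' @param tau_rise rise time constant (ms)
#' @param tau_decay decay time constant (ms); must exceed `tau_rise`
#' @param E_rev reversal potential (mV)
#' @return an object of class `synapse_kernel` with the derived fields
#'   `norm_const` (peak normalization) and `t_peak` (time of the kernel
#'   maximum, ms)
#' @export
synapse_kernel <- function(tau_rise = 0.5, tau_decay = 2.0, E_rev = 0) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  t_peak <- (tau_decay * tau_rise / (tau_decay - tau_rise)) *
    log(tau_decay / tau_rise)
  norm_const <- 1 / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, E_rev = E_rev,
                 norm_const = norm_const, t_peak = t_peak),
            class = "synapse_kernel")
}

#' Evaluate the normalized synaptic conductance kernel
#'
#' @param t_since_arrival time since the input arrived (ms); may be a vector
#' @param kernel a [synapse_kernel()]
#' @return unitless factor in \[0, 1\]; 0 for negative times, peak 1 at
#'   `kernel$t_peak`
#' @export
conductance_kernel <- function(t_since_arrival, kernel) {
  out <- numeric(length(t_since_arrival))
  pos <- t_since_arrival >= 0
  t <- t_since_arrival[pos]
  out[pos] <- kernel$norm_const *
    (exp(-t / kernel$tau_decay) - exp(-t / kernel$tau_rise))
  out
}

#' Parameters of the nonlinear (dendritic-spike) compartment
#'
#' In non-additive mode every excitatory input additionally lands on a
#' nonlinear dendrite. If the summed peak-conductance of excitatory inputs
#' arriving within a trailing window of length `window` reaches the dendritic
#' threshold `threshold`, a stereotyped current pulse
#' \deqn{I_{ds}(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + A_3 e^{-t/\tau_3}}
#' is injected into the soma starting `latency` ms after the crossing. The
#' pulse is all-or-none: its shape is independent of how far the input
#' exceeded the threshold. The conductance counted towards the threshold (and
#' towards the somatic conductance drive of the triggering volley) is capped
#' at `cap`, and after initiation the dendrite is refractory for `t_ref_d`,
#' which together produce the experimentally observed saturation of the
#' somatic depolarization.
#'
#' @param window dendritic integration window \eqn{\Delta} (ms)
#' @param threshold dendritic threshold \eqn{\Theta_b} (summed peak
#'   conductance, nS)
#' @param cap maximal conductance change counted within one window (nS)
#' @param latency delay between threshold crossing and somatic current onset (ms)
#' @param amps prefactors \eqn{A_1, A_2, A_3} (nA), all positive
#' @param taus decay time constants \eqn{\tau_1, \tau_2, \tau_3} (ms)
#' @param t_ref_d dendritic refractory period (ms); must cover the window
#' @return an object of class `dendrite_params`
#' @export
dendrite_params <- function(window = 2, threshold = 8.65, cap = 12.975,
                            latency = 2.7,
                            amps = c(6.0, 4.0, 1.0),
                            taus = c(0.5, 1.5, 4.0),
                            t_ref_d = 5) {
  stopifnot(window > 0, threshold > 0, cap >= threshold, latency >= 0,
            t_ref_d >= window, length(amps) == 3, length(taus) == 3,
            all(amps > 0), all(taus > 0))
  structure(list(window = window, threshold = threshold, cap = cap,
                 latency = latency, amps = as.numeric(amps),
                 taus = as.numeric(taus), t_ref_d = t_ref_d),
            class = "dendrite_params")
}

#' Dendritic-spike current waveform
#'
#' @param t_since_onset time since somatic current onset (ms); vectorized
#' @param dendrite a [dendrite_params()]
#' @return current in nA; 0 for negative times
#' @export
dendritic_current <- function(t_since_onset, dendrite) {
  out <- numeric(length(t_since_onset))
  pos <- t_since_onset >= 0
  t <- t_since_onset[pos]
  out[pos] <- dendrite$amps[1] * exp(-t / dendrite$taus[1]) +
    dendrite$amps[2] * exp(-t / dendrite$taus[2]) +
    dendrite$amps[3] * exp(-t / dendrite$taus[3])
  out
}

#' Standard model parameters
#'
#' One coherent default parameter set for a hippocampal-like pyramidal
#' population: membrane constants, AMPA/GABA_A kernels (same time constants
#' for both signs), the dendritic-spike compartment, balanced Poisson
#' background, and the propagation detector. The excitatory/inhibitory
#' balance ratio `alpha` is computed numerically so that single EPSP and IPSP
#' peaks from rest are equal (see [balance_ratio()]).
#'
#' @param dt integration step used when deriving `alpha` (ms)
#' @return a named list with components `neuron`, `kernel_ex`, `kernel_in`,
#'   `dendrite`, `alpha`, `background`, `detector`
#' @export
standard_params <- function(dt = 0.01) {
  neuron <- neuron_params()
  kernel_ex <- synapse_kernel(0.5, 2.0, E_rev = 0)
  kernel_in <- synapse_kernel(0.5, 2.0, E_rev = -75)
  alpha <- balance_ratio(neuron, kernel_ex, kernel_in, dt = dt)
  list(neuron = neuron,
       kernel_ex = kernel_ex,
       kernel_in = kernel_in,
       dendrite = dendrite_params(),
       alpha = alpha,
       background = background_spec(rate_ex = 0.6, rate_in = 0.6,
                                    eps_ex = 1.0, eps_in = alpha * 1.0),
       detector = detector_config())
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> C_m=%g pF g_L=%g nS (tau_m=%g ms) E_L=%g mV",
              x$C_m, x$g_L, x$C_m / x$g_L, x$E_L),
      sprintf("V_theta=%g mV V_reset=%g mV t_ref=%g ms\n",
              x$V_theta, x$V_reset, x$t_ref))
  invisible(x)
}

#' @export
print.dendrite_params <- function(x, ...) {
  cat(sprintf(
    "<dendrite_params> Delta=%g ms Theta_b=%g nS cap=%g nS latency=%g ms t_ref_d=%g ms\n",
    x$window, x$threshold, x$cap, x$latency, x$t_ref_d))
  cat(sprintf("  I_ds(0)=%g nA amps=(%s) nA taus=(%s) ms\n",
              sum(x$amps), paste(x$amps, collapse = ", "),
              paste(x$taus, collapse = ", ")))
  invisible(x)
}
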