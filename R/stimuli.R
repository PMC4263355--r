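#' Poisson background specification
#'
#' Each neuron receives independent excitatory and inhibitory homogeneous
#' Poisson input trains emulating the influence of remote networks. With the
#' inhibitory strength set to the balanced partner of the excitatory one, the
#' total input is balanced and neurons sit in a fluctuation-driven
#' asynchronous-irregular ground state.
#'
#' @param rate_ex,rate_in rates per neuron (kHz)
#' @param eps_ex,eps_in strengths (peak conductances, nS)
#' @return an object of class `background_spec`
#' @export
background_spec <- function(rate_ex = 0.6, rate_in = 0.6,
                            eps_ex = 1.0, eps_in = 6.63) {
  stopifnot(rate_ex >= 0, rate_in >= 0, eps_ex >= 0, eps_in >= 0)
  structure(list(rate_ex = rate_ex, rate_in = rate_in,
                 eps_ex = eps_ex, eps_in = eps_in),
            class = "background_spec")
}

#' Oscillatory virtual-population specification
#'
#' A virtual population of `n_osc` neurons spikes once per oscillation cycle
#' of frequency `nu_stim`; spike times are Gaussian around the cycle centers
#' `t_k = k / nu_stim` (plus a phase offset) with standard deviation
#' `sigma_osc`, tails not truncated at cycle boundaries. Each source spike is
#' delivered to each network neuron independently: excitatory with
#' probability `p_deliver_ex` at strength `eps_ex`, inhibitory with
#' probability `p_deliver_in` at strength `unbalance_g * eps_in`. With
#' `unbalance_g = 1` and `eps_in` the balanced partner of `eps_ex` the
#' oscillation is balanced; `unbalance_g < 1` yields net depolarization,
#' `> 1` net hyperpolarization.
#'
#' @param n_osc virtual population size
#' @param nu_stim oscillation frequency (Hz)
#' @param sigma_osc within-cycle spike-time jitter (ms)
#' @param p_deliver_ex,p_deliver_in per-spike per-target delivery probabilities
#' @param eps_ex,eps_in strengths (nS)
#' @param unbalance_g inhibition scaling factor relative to balance
#' @param phase offset of the first cycle center (ms)
#' @return an object of class `oscillation_spec`
#' @export
oscillation_spec <- function(n_osc = 120, nu_stim = 180, sigma_osc = 1,
                             p_deliver_ex = 0.5, p_deliver_in = 0.5,
                             eps_ex = 0.1, eps_in = 0.663,
                             unbalance_g = 1, phase = 0) {
  stopifnot(n_osc >= 0, nu_stim > 0, sigma_osc >= 0,
            p_deliver_ex >= 0, p_deliver_ex <= 1,
            p_deliver_in >= 0, p_deliver_in <= 1,
            eps_ex >= 0, eps_in >= 0, unbalance_g > 0)
  structure(list(n_osc = n_osc, nu_stim = nu_stim, sigma_osc = sigma_osc,
                 p_deliver_ex = p_deliver_ex, p_deliver_in = p_deliver_in,
                 eps_ex = eps_ex, eps_in = eps_in,
                 unbalance_g = unbalance_g, phase = phase),
            class = "oscillation_spec")
}

#' Generate per-neuron Poisson background event streams
#'
#' Explicit event-list form, used for small simulations and tests. Large
#' scans instead let the simulation engine draw identical-in-distribution
#' Poisson input internally at step resolution (see [sim_config()]).
#'
#' @param spec a [background_spec()]
#' @param n_neurons number of target neurons
#' @param duration stream length (ms)
#' @param seed seed (stream `"background"`)
#' @return data.frame `neuron, time_ms, sign, strength_nS` sorted by time
#' @export
generate_background <- function(spec, n_neurons, duration, seed = 1) {
  stopifnot(duration > 0)
  with_stream_seed(seed, "background", {
    one_sign <- function(rate, strength, sgn) {
      if (rate <= 0 || strength < 0) {
        if (rate < 0) stop("negative rate")
        return(NULL)
      }
      counts <- stats::rpois(n_neurons, rate * duration)  # rate kHz * ms
      data.frame(neuron = rep(seq_len(n_neurons), counts),
                 time_ms = stats::runif(sum(counts), 0, duration),
                 sign = sgn, strength_nS = strength)
    }
    ev <- rbind(one_sign(spec$rate_ex, spec$eps_ex, 1L),
                one_sign(spec$rate_in, spec$eps_in, -1L))
    if (is.null(ev))
      ev <- data.frame(neuron = integer(0), time_ms = numeric(0),
                       sign = integer(0), strength_nS = numeric(0))
    ev[order(ev$time_ms), , drop = FALSE]
  })
}

#' Source spike times of the oscillatory virtual population
#'
#' @param spec an [oscillation_spec()]
#' @param duration stream length (ms)
#' @param seed seed (stream `"oscillation"`)
#' @return sorted numeric vector of source spike times in `[0, duration]`
#' @export
oscillation_source_spikes <- function(spec, duration, seed = 1) {
  period <- 1000 / spec$nu_stim
  stopifnot(duration >= period)
  if (spec$n_osc == 0) return(numeric(0))
  with_stream_seed(seed, "oscillation", {
    centers <- seq(spec$phase, duration, by = period)
    t <- stats::rnorm(length(centers) * spec$n_osc,
                      mean = rep(centers, each = spec$n_osc),
                      sd = spec$sigma_osc)
    sort(t[t >= 0 & t <= duration])
  })
}

#' Generate per-neuron oscillatory event streams
#'
#' Draws the shared source spikes with [oscillation_source_spikes()] and then
#' delivers each source spike to each neuron independently per sign.
#'
#' @inheritParams generate_background
#' @param spec an [oscillation_spec()]
#' @return data.frame `neuron, time_ms, sign, strength_nS` sorted by time
#' @export
generate_oscillation <- function(spec, n_neurons, duration, seed = 1) {
  src <- oscillation_source_spikes(spec, duration, seed)
  if (length(src) == 0 || n_neurons == 0)
    return(data.frame(neuron = integer(0), time_ms = numeric(0),
                      sign = integer(0), strength_nS = numeric(0)))
  with_stream_seed(seed, "osc_delivery", {
    deliver <- function(p, strength, sgn) {
      if (p <= 0 || strength <= 0) return(NULL)
      hits <- which(matrix(stats::runif(length(src) * n_neurons) < p,
                           nrow = length(src)), arr.ind = TRUE)
      data.frame(neuron = as.integer(hits[, 2]), time_ms = src[hits[, 1]],
                 sign = sgn, strength_nS = strength)
    }
    ev <- rbind(deliver(spec$p_deliver_ex, spec$eps_ex, 1L),
                deliver(spec$p_deliver_in, spec$unbalance_g * spec$eps_in, -1L))
    if (is.null(ev))
      ev <- data.frame(neuron = integer(0), time_ms = numeric(0),
                       sign = integer(0), strength_nS = numeric(0))
    ev[order(ev$time_ms), , drop = FALSE]
  })
}

#' Time-averaged drive delivered by the oscillatory input
#'
#' Mean delivered input per neuron and second for each sign, as strength
#' times expected deliveries per second (nS/s). Used to build the matched
#' constant current for the additive-equivalence experiment.
#'
#' @param spec an [oscillation_spec()]
#' @return named numeric vector `c(ex = ..., in_ = ...)` in nS/s
#' @export
effective_mean_drive <- function(spec) {
  rate <- spec$n_osc * spec$nu_stim  # source spikes per second
  c(ex = rate * spec$p_deliver_ex * spec$eps_ex,
    in_ = rate * spec$p_deliver_in * spec$unbalance_g * spec$eps_in)
}

#' Constant current matching the mean oscillatory drive
#'
#' Converts the mean delivered conductance drive of [effective_mean_drive()]
#' into the constant somatic current that produces the same mean input
#' current at the resting potential: each delivered input of strength
#' `eps` contributes a conductance integral `eps * norm_const * (tau_decay -
#' tau_rise)` (ms*nS), so the mean conductance per sign is drive/1000 times
#' that integral per nS, and the current follows from the driving force at
#' `E_L`.
#'
#' @param spec an [oscillation_spec()]
#' @param neuron a [neuron_params()]
#' @param kernel_ex,kernel_in the synaptic kernels
#' @return equivalent constant current (nA)
#' @export
matched_constant_current <- function(spec, neuron, kernel_ex, kernel_in) {
  drive <- effective_mean_drive(spec)  # nS/s
  kint <- function(k) k$norm_const * (k$tau_decay - k$tau_rise)  # ms per nS
  g_ex <- drive[["ex"]] / 1000 * kint(kernel_ex)  # mean conductance, nS
  g_in <- drive[["in_"]] / 1000 * kint(kernel_in)
  # pA = nS * mV; return nA
  (g_ex * (kernel_ex$E_rev - neuron$E_L) +
      g_in * (kernel_in$E_rev - neuron$E_L)) / 1000
}
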