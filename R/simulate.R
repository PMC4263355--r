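#' Simulation configuration
#'
#' @param dt integration step (ms); fixed-step exponential-Euler, threshold
#'   crossings resolved to the step, delays rounded to the nearest step
#' @param duration total simulated time (ms)
#' @param mode `"additive"` (linear conductance summation only) or
#'   `"non_additive"` (every excitatory input additionally drives the
#'   nonlinear dendrite; inhibition acts on the soma only)
#' @param seed master seed for the engine-internal noise streams
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.1, duration = 1000,
                       mode = c("non_additive", "additive"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, duration >= dt)
  structure(list(dt = dt, duration = duration, mode = mode, seed = seed),
            class = "sim_config")
}

#' Run a network simulation
#'
#' Time-stepped simulation of a network realization under external input.
#' Every somatic spike of neuron i at time t schedules a synaptic event at
#' `t + delay_ij` on each outgoing edge; external events are delivered
#' directly. In non-additive mode excitatory deliveries pass through the
#' dendritic-window bookkeeping. Deterministic given the seeds and inputs.
#'
#' Background Poisson input and the thinning of oscillatory source spikes are
#' drawn inside the engine (streams `"bg"` and `"osc_deliver"` derived from
#' `config$seed`), so explicit event streams are only needed for bespoke
#' stimuli.
#'
#' @param network a [build_network()] result, or `NULL` for `n_neurons`
#'   unconnected neurons
#' @param config a [sim_config()]
#' @param params model parameters as returned by [standard_params()]
#' @param background a [background_spec()] or `NULL`
#' @param oscillation an [oscillation_spec()] or `NULL`
#' @param external optional explicit event data.frame
#'   (`neuron, time_ms, sign, strength_nS`)
#' @param forced optional data.frame (`neuron, time_ms`) of forced somatic
#'   spikes (pulse initiation)
#' @param injected per-neuron constant current (nA), scalar or vector
#' @param n_neurons neuron count when `network` is `NULL`
#' @param record_ids neuron ids whose membrane potential and conductances are
#'   recorded each step
#' @param V0 initial potentials; default drawn uniformly between `V_reset`
#'   and `V_theta` (stream `"init"`)
#' @return an object of class `spike_record`: list with `spikes` (data.frame
#'   `neuron, time_ms` ordered by time), `layers`, `config`, `duration`, and,
#'   if requested, `trace` (list of `time`, `V`, `g_ex`, `g_in` matrices)
#' @export
simulate_network <- function(network = NULL, config = sim_config(),
                             params = standard_params(),
                             background = NULL, oscillation = NULL,
                             external = NULL, forced = NULL,
                             injected = 0, n_neurons = NULL,
                             record_ids = integer(0), V0 = NULL) {
  if (is.null(network)) {
    stopifnot(!is.null(n_neurons))
    N <- n_neurons
    edges <- data.frame(source = integer(0), target = integer(0),
                        sign = integer(0), strength_nS = numeric(0),
                        delay_ms = numeric(0))
    layers <- NULL
  } else {
    N <- network$N
    edges <- network$edges
    layers <- network$layers
  }
  if (length(injected) == 1) injected <- rep(injected, N)
  stopifnot(length(injected) == N)
  if (is.null(V0)) {
    V0 <- with_stream_seed(config$seed, "init",
                           stats::runif(N, params$neuron$V_reset,
                                        params$neuron$V_theta))
  }
  stopifnot(length(V0) == N)

  if (is.null(external))
    external <- data.frame(neuron = integer(0), time_ms = numeric(0),
                           sign = integer(0), strength_nS = numeric(0))
  if (is.null(forced))
    forced <- data.frame(neuron = integer(0), time_ms = numeric(0))

  bg <- background %||% background_spec(0, 0, 0, 0)
  osc_times <- numeric(0)
  osc <- oscillation
  if (!is.null(osc) && osc$n_osc > 0) {
    osc_times <- oscillation_source_spikes(osc, config$duration, config$seed)
    osc_times <- osc_times[osc_times < config$duration]
  } else {
    osc <- oscillation_spec(n_osc = 0)
  }

  res <- .sim_run_cpp(
    n_neurons = N,
    neuron = unclass(params$neuron),
    kernel_ex = unclass(params$kernel_ex),
    kernel_in = unclass(params$kernel_in),
    nonadditive = config$mode == "non_additive",
    dendrite = unclass(params$dendrite),
    e_src = as.integer(edges$source), e_tgt = as.integer(edges$target),
    e_sign = as.integer(edges$sign), e_strength = as.numeric(edges$strength_nS),
    e_delay = as.numeric(edges$delay_ms),
    x_neuron = as.integer(external$neuron),
    x_time = as.numeric(external$time_ms),
    x_sign = as.integer(external$sign),
    x_strength = as.numeric(external$strength_nS),
    bg_rate_ex = bg$rate_ex, bg_rate_in = bg$rate_in,
    bg_eps_ex = bg$eps_ex, bg_eps_in = bg$eps_in,
    bg_seed = derive_seed(config$seed, "bg"),
    osc_times = osc_times,
    osc_p_ex = osc$p_deliver_ex, osc_p_in = osc$p_deliver_in,
    osc_eps_ex = osc$eps_ex, osc_eps_in = osc$unbalance_g * osc$eps_in,
    osc_seed = derive_seed(config$seed, "osc_deliver"),
    f_neuron = as.integer(forced$neuron), f_time = as.numeric(forced$time_ms),
    I_inj = as.numeric(injected),
    dt = config$dt, duration = config$duration,
    V0 = as.numeric(V0),
    record_ids = as.integer(record_ids))

  ord <- order(res$time, res$id)
  rec <- list(spikes = data.frame(neuron = res$id[ord], time_ms = res$time[ord]),
              layers = layers, config = config, duration = config$duration,
              n_neurons = N)
  if (length(record_ids) > 0) {
    rec$trace <- list(time = seq(0, config$duration, by = config$dt),
                      ids = record_ids,
                      V = res$V, g_ex = res$g_ex, g_in = res$g_in)
  }
  structure(rec, class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes from %d neurons over %g ms (%s mode)\n",
              nrow(x$spikes), x$n_neurons, x$duration, x$config$mode))
  invisible(x)
}

#' Write / read a spike record as CSV
#'
#' @param record a `spike_record`
#' @param path CSV file path (columns `neuron, time_ms`)
#' @return `read_spikes` returns a data.frame `neuron, time_ms`.
#' @export
write_spikes <- function(record, path) {
  utils::write.csv(record$spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) utils::read.csv(path)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike latency distribution after a synchronous compound input
#'
#' Each trial places one neuron in the fluctuating ground state (balanced
#' Poisson background) and delivers a single compound synchronous excitatory
#' input of the given strength at `t0`; trials run as unconnected neurons of
#' one network, so a call is a single engine run. Returns the latencies of
#' first spikes within the response window, plus the trigger probability.
#'
#' @param strength compound input strength (summed peak conductance, nS)
#' @param mode coupling mode, see [sim_config()]
#' @param n_trials number of trials (neurons)
#' @param params model parameters
#' @param background a [background_spec()]
#' @param window response window after `t0` (ms)
#' @param warmup settling time before the input (ms)
#' @param seed master seed
#' @param dt integration step (ms)
#' @return list with `latency` (ms, one per triggered trial), `p_trigger`,
#'   `n_trials`
#' @export
measure_spike_latency <- function(strength, mode = "non_additive",
                                  n_trials = 200,
                                  params = standard_params(),
                                  background = params$background,
                                  window = 10, warmup = 200, seed = 1,
                                  dt = 0.1) {
  stopifnot(n_trials >= 1)
  t0 <- warmup
  ext <- if (strength > 0)
    data.frame(neuron = seq_len(n_trials), time_ms = t0, sign = 1L,
               strength_nS = strength)
  else NULL
  cfg <- sim_config(dt = dt, duration = warmup + window + 5, mode = mode,
                    seed = seed)
  rec <- simulate_network(NULL, cfg, params, background = background,
                          external = ext, n_neurons = n_trials)
  sp <- rec$spikes[rec$spikes$time_ms > t0 &
                     rec$spikes$time_ms <= t0 + window, ]
  first <- tapply(sp$time_ms, factor(sp$neuron, levels = seq_len(n_trials)),
                  min)
  lat <- as.numeric(first[!is.na(first)]) - t0
  list(latency = lat, p_trigger = length(lat) / n_trials,
       n_trials = n_trials)
}
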