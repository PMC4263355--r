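#' Set an oscillation in phase with a pulse initiated at t0
#'
#' The initiating pulse is forced in layer 1 at `t0`; its synchronous input
#' arrives at layer 2 one mean conduction delay later. "In phase" places an
#' oscillation cycle center at that arrival time.
#'
#' @param osc an [oscillation_spec()]
#' @param t0 initiation time (ms)
#' @param d_mean mean conduction delay (ms)
#' @return the oscillation spec with its `phase` set
#' @export
inphase_oscillation <- function(osc, t0, d_mean) {
  period <- 1000 / osc$nu_stim
  osc$phase <- (t0 + d_mean) %% period
  osc
}

#' Run one propagation trial (stimulated run + matched control)
#'
#' Builds the network, simulates a run in which a fraction of layer-1
#' neurons is forced to spike synchronously at the end of the warmup
#' (in-phase with the oscillation, if any), simulates an identical
#' non-initiated control run, and applies the propagation detector.
#'
#' @param spec a [network_spec()]
#' @param delay_model a [delay_models] object
#' @param params model parameters
#' @param mode coupling mode
#' @param oscillation optional [oscillation_spec()] (phase is set via
#'   [inphase_oscillation()] using the delay model's mean)
#' @param seed master seed (network, noise and initiation all derive from it)
#' @param init_frac fraction of layer-1 neurons forced to spike
#' @param warmup settling time before initiation (ms)
#' @param observe time simulated after initiation (ms)
#' @param detector a [detector_config()]; its `control_interval` is capped at
#'   the control run length
#' @param injected per-neuron constant current (nA)
#' @param net optional pre-built network (skips `build_network`)
#' @param ffn_delay_models passed to [build_network()]
#' @param phase_delay delay used to phase the oscillation to the layer-2
#'   arrival; defaults to the mean excitatory conduction delay
#' @return list with `trace` (or list of traces, one per FFN, if the network
#'   has several), `record`, `control`, `net`, `t0`
#' @export
propagation_trial <- function(spec, delay_model = delay_homogeneous(2),
                              params = standard_params(),
                              mode = "non_additive", oscillation = NULL,
                              seed = 1, init_frac = 0.8,
                              warmup = 300, observe = 120,
                              detector = detector_config(),
                              injected = 0, net = NULL,
                              ffn_delay_models = NULL, phase_delay = NULL) {
  if (is.null(net))
    net <- build_network(spec, delay_model, seed = seed,
                         ffn_delay_models = ffn_delay_models)
  t0 <- warmup
  d_mean <- phase_delay %||% mean(net$edges$delay_ms[net$edges$sign == 1])
  if (!is.finite(d_mean)) d_mean <- 0
  osc <- oscillation
  if (!is.null(osc) && osc$n_osc > 0)
    osc <- inphase_oscillation(osc, t0, d_mean)
  duration <- warmup + observe
  l1 <- layer_neurons(net, 1, ffn = 1)
  n_force <- max(1, round(init_frac * length(l1)))
  forced <- with_stream_seed(seed, "init_pulse",
    data.frame(neuron = sample(l1, n_force), time_ms = t0))
  cfg <- sim_config(dt = 0.1, duration = duration, mode = mode, seed = seed)
  rec <- simulate_network(net, cfg, params, background = params$background,
                          oscillation = osc, forced = forced,
                          injected = injected)
  cfg_c <- sim_config(dt = 0.1, duration = duration, mode = mode,
                      seed = derive_seed(seed, "control"))
  ctl <- simulate_network(net, cfg_c, params, background = params$background,
                          oscillation = osc, injected = injected)
  det <- detector
  det$control_interval <- min(det$control_interval, duration - 50)
  traces <- lapply(seq_len(net$spec$n_ffn), function(f)
    detect_propagation(rec, t0, det, control = ctl, ffn = f))
  list(trace = if (net$spec$n_ffn == 1) traces[[1]] else traces,
       record = rec, control = ctl, net = net, t0 = t0)
}

#' Mean firing rate of the FFN population in a record
#' @param record a `spike_record`
#' @param net the network realization (for the FFN member list)
#' @return rate in Hz per neuron
#' @export
ffn_rate <- function(record, net) {
  ids <- unique(net$layers$neuron)
  sum(record$spikes$neuron %in% ids) / length(ids) / (record$duration / 1000)
}

#' Natural propagation frequency of an FFN
#'
#' The intrinsic layer-hop rate: the inverse of mean conduction delay plus
#' spike latency, with the latency measured from single-neuron trials at
#' suprathreshold input strength.
#'
#' @param d_mean mean conduction delay (ms)
#' @param params model parameters
#' @param mode coupling mode
#' @param strength input strength for the latency measurement (nS); default
#'   twice the dendritic threshold
#' @param n_trials latency trials
#' @param seed seed
#' @return frequency (Hz)
#' @export
natural_frequency <- function(d_mean = 2, params = standard_params(),
                              mode = "non_additive",
                              strength = 2 * params$dendrite$threshold,
                              n_trials = 200, seed = 1) {
  m <- measure_spike_latency(strength, mode = mode, n_trials = n_trials,
                             params = params, seed = seed)
  1000 / (d_mean + stats::median(m$latency))
}

#' Critical feed-forward coupling from simulation (bisection)
#'
#' Bisects on `eps_ff` for the smallest coupling at which the initiated
#' pulse is detected down to the final layer in at least `success_frac` of
#' trials. Also reports `eps_patho`, the smallest probed coupling whose
#' non-initiated control run is pathological (spontaneous network-wide
#' synchrony, flagged by the control FFN rate exceeding `patho_rate`; mass
#' synchrony drives most neurons once per cycle, far above the cycle-locked
#' but sparse activity of the supported regime), `NA` if none was seen.
#'
#' @param spec a [network_spec()]; its `eps_ff` is overridden by the search
#' @param delay_model delay model
#' @param oscillation optional oscillation spec
#' @param params,mode,detector,init_frac,warmup,observe as in
#'   [propagation_trial()]
#' @param bracket `c(lo, hi)` coupling bracket (nS); `lo` must fail and `hi`
#'   succeed
#' @param n_trials trials per probed coupling
#' @param success_frac required fraction of full-depth trials
#' @param tol bisection tolerance (nS)
#' @param patho_rate control-rate threshold for the pathological flag (Hz)
#' @param seed master seed
#' @return list with `eps_crit`, `eps_patho`, `probes` (data.frame of probed
#'   couplings and success fractions)
#' @export
critical_coupling_sim <- function(spec, delay_model = delay_homogeneous(2),
                                  oscillation = NULL,
                                  params = standard_params(),
                                  mode = "non_additive",
                                  bracket = c(0.1, 1.5), n_trials = 5,
                                  success_frac = 0.5, tol = 0.05,
                                  detector = detector_config(),
                                  init_frac = 0.8, warmup = 300,
                                  observe = 120, patho_rate = 60, seed = 1) {
  probes <- data.frame(eps_ff = numeric(0), frac = numeric(0),
                       patho = logical(0))
  eval_eps <- function(eps) {
    sp <- spec
    sp$eps_ff <- eps
    res <- vapply(seq_len(n_trials), function(i) {
      tr <- propagation_trial(sp, delay_model, params, mode, oscillation,
                              seed = derive_seed(seed, paste0("cc", eps, "_", i)),
                              init_frac = init_frac, warmup = warmup,
                              observe = observe, detector = detector)
      c(full = max_successful_layer(tr$trace) == sp$L,
        patho = ffn_rate(tr$control, tr$net) > patho_rate)
    }, logical(2))
    out <- list(frac = mean(res["full", ]), patho = any(res["patho", ]))
    probes <<- rbind(probes, data.frame(eps_ff = eps, frac = out$frac,
                                        patho = out$patho))
    out
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- eval_eps(lo); r_hi <- eval_eps(hi)
  if (r_lo$patho && r_hi$patho)
    stop("pathological activity throughout the bracket")
  if (r_lo$frac >= success_frac)
    stop("bracket does not straddle the critical coupling (lower end succeeds)")
  if (r_hi$frac < success_frac) {
    # propagation is possible only on an interval (eps_crit, eps_patho): at
    # strong couplings spontaneous synchrony floods the control and detection
    # fails. Probe the interior for a working coupling and bisect below it.
    interior <- seq(lo, hi, length.out = 8)[2:7]
    works <- NA_real_
    for (e in interior) {
      if (eval_eps(e)$frac >= success_frac) { works <- e; break }
    }
    if (is.na(works))
      stop("no coupling in the bracket supports detectable propagation")
    lo <- max(probes$eps_ff[probes$eps_ff < works & probes$frac < success_frac])
    hi <- works
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_eps(mid)$frac >= success_frac) hi <- mid else lo <- mid
  }
  patho <- probes$eps_ff[probes$patho]
  list(eps_crit = (lo + hi) / 2,
       eps_patho = if (length(patho)) min(patho) else NA_real_,
       probes = probes[order(probes$eps_ff), ])
}

#' Nearest small-integer rational ratio
#'
#' Identifies the locking ratio n:m (n, m <= `max_den`) closest to
#' `ratio = nu_prop / nu_stim`; the pair is `locked` if the relative error is
#' below `tol`.
#'
#' @param ratio observed frequency ratio
#' @param max_den largest admissible integer in the ratio
#' @param tol relative tolerance for the locked flag
#' @return list with `n`, `m`, `err` (relative), `locked`
#' @export
locking_ratio <- function(ratio, max_den = 4, tol = 0.02) {
  best <- NULL
  for (n in 1:max_den) for (m in 1:max_den) {
    err <- abs(ratio - n / m) / (n / m)
    if (is.null(best) || err < best$err)
      best <- list(n = n, m = m, err = err)
  }
  g <- .gcd(best$n, best$m)
  list(n = best$n / g, m = best$m / g, err = best$err,
       locked = best$err < tol)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Resonance scan over stimulation frequencies
#'
#' For each stimulation frequency runs `n_trials` propagation trials and
#' aggregates the maximal successful layer, the measured propagation
#' frequency, and the locking ratio of propagation to stimulation frequency.
#'
#' @param spec a [network_spec()] (with the coupling of interest in
#'   `eps_ff`)
#' @param delay_model delay model
#' @param oscillation oscillation template; its `nu_stim` is overridden
#' @param nu_grid stimulation frequencies (Hz)
#' @param n_trials trials per frequency
#' @param params,mode,detector,init_frac,warmup,observe as in
#'   [propagation_trial()]
#' @param seed master seed
#' @return data.frame with one row per frequency: `nu_stim`, `max_layer`
#'   (median over trials), `nu_prop` (median over trials with >= 3
#'   successful layers; NA otherwise), `lock_n`, `lock_m`, `locked`
#' @export
resonance_scan <- function(spec, delay_model = delay_homogeneous(2),
                           oscillation = oscillation_spec(),
                           nu_grid = seq(60, 240, by = 20), n_trials = 3,
                           params = standard_params(),
                           mode = "non_additive",
                           detector = detector_config(), init_frac = 0.8,
                           warmup = 300, observe = 150, seed = 1) {
  stopifnot(length(nu_grid) >= 1)
  rows <- lapply(nu_grid, function(nu) {
    osc <- oscillation
    osc$nu_stim <- nu
    res <- lapply(seq_len(n_trials), function(i)
      propagation_trial(spec, delay_model, params, mode, osc,
                        seed = derive_seed(seed, paste0("rs", nu, "_", i)),
                        init_frac = init_frac, warmup = warmup,
                        observe = observe, detector = detector))
    ml <- vapply(res, function(r) max_successful_layer(r$trace), numeric(1))
    nup <- vapply(res, function(r)
      tryCatch(propagation_frequency(r$trace), error = function(e) NA_real_),
      numeric(1))
    nu_prop <- if (all(is.na(nup))) NA_real_ else stats::median(nup, na.rm = TRUE)
    lock <- if (is.na(nu_prop)) list(n = NA, m = NA, locked = FALSE)
            else locking_ratio(nu_prop / nu)
    data.frame(nu_stim = nu, max_layer = stats::median(ml),
               nu_prop = nu_prop, lock_n = lock$n, lock_m = lock$m,
               locked = lock$locked)
  })
  do.call(rbind, rows)
}

#' Frequency-gated routing between two FFNs
#'
#' Builds a recurrent network containing two FFNs that share their first
#' layer but have distinct mean feed-forward conduction delays (hence
#' distinct resonance frequencies), initiates a pulse in the shared layer
#' in-phase with a balanced oscillation of frequency `nu_stim`, and reports
#' the propagation depth in each FFN.
#'
#' @param nu_stim stimulation frequency (Hz)
#' @param d_means mean feed-forward delays of the two FFNs (ms)
#' @param d_rest mean delay of the remaining recurrent connections (ms)
#' @param width delay jitter width (ms, uniform)
#' @param spec a [network_spec()] with `n_ffn = 2`, `share_first = TRUE`.
#'   The default keeps the recurrent coupling weak (0.02 nS) because
#'   recurrent excitation feeds the oscillation-assisted dendritic cascade
#'   and drives the network into pathological mass synchrony if prominent.
#' @param oscillation oscillation template (`nu_stim` overridden; `n_osc =
#'   0` for the no-oscillation control)
#' @param params,mode,detector,init_frac,warmup,observe,seed as in
#'   [propagation_trial()]
#' @return list with `max_layer` (length-2 vector), `nu_prop` (length-2),
#'   `traces`
#' @export
gating_experiment <- function(nu_stim, d_means = c(2, 4), d_rest = 2,
                              width = 0.5,
                              spec = network_spec(N = 2000, p_ex = 0.1,
                                                  p_in = 0.1, eps = 0.02,
                                                  eps_in = 0.133,
                                                  L = 8, w = 120,
                                                  eps_ff = 0.5,
                                                  isolated = FALSE,
                                                  n_ffn = 2,
                                                  share_first = TRUE),
                              oscillation = oscillation_spec(),
                              params = standard_params(),
                              mode = "non_additive",
                              detector = detector_config(), init_frac = 0.8,
                              warmup = 300, observe = 120, seed = 1) {
  stopifnot(spec$n_ffn == 2, spec$share_first)
  osc <- oscillation
  if (osc$n_osc > 0) osc$nu_stim <- nu_stim
  ffn_dm <- list(delay_uniform(d_means[1], width),
                 delay_uniform(d_means[2], width))
  net <- build_network(spec, delay_uniform(d_rest, width), seed = seed,
                       ffn_delay_models = ffn_dm)
  osc_use <- if (osc$n_osc > 0) osc else NULL
  # phase the initiation to the FFN whose resonance the stimulation
  # frequency addresses (nearest layer-hop rate 1000/(d + latency))
  lat <- stats::median(measure_spike_latency(
    2 * params$dendrite$threshold, mode, n_trials = 100, params = params,
    seed = derive_seed(seed, "gate_lat"))$latency)
  nu_res <- 1000 / (d_means + lat)
  target <- which.min(abs(nu_res - nu_stim))
  res <- propagation_trial(spec, net = net, params = params, mode = mode,
                           oscillation = osc_use, seed = seed,
                           init_frac = init_frac, warmup = warmup,
                           observe = observe, detector = detector,
                           phase_delay = d_means[target])
  traces <- res$trace
  ml <- vapply(traces, max_successful_layer, numeric(1))
  nup <- vapply(traces, function(tr)
    tryCatch(propagation_frequency(tr), error = function(e) NA_real_),
    numeric(1))
  list(max_layer = ml, nu_prop = nup, traces = traces, net = net)
}

#' Oscillation-induced reduction of the critical feed-forward coupling
#'
#' The headline quantity of the package: in an isolated FFN with nonlinear
#' dendrites, (1) the critical coupling without oscillation is found by
#' bisection; (2) the natural propagation frequency is measured from a
#' just-supercritical unstimulated run (the onset regime); (3) for each
#' oscillation amplitude in `n_osc_grid`, the critical coupling under
#' balanced oscillatory drive at that frequency is bisected; amplitudes
#' whose bisection fails (e.g. pathological control activity throughout)
#' are skipped. The reported reduction factor is the no-oscillation critical
#' coupling divided by the minimum over amplitudes, mirroring the
#' coupling-amplitude phase diagram this experiment reproduces.
#'
#' @param seed master seed
#' @param spec FFN spec (the scaled-down standard: 10 layers x 150 neurons)
#' @param d_mean homogeneous conduction delay (ms)
#' @param n_osc_grid oscillation amplitudes to scan
#' @param n_trials_ref,n_trials_osc trials per bisection probe for the
#'   reference and per-amplitude searches
#' @param params model parameters
#' @return list with `reduction` (the factor), `eps_crit_ref`,
#'   `eps_crit_osc` (per amplitude, NA where the search failed), `nu_onset`
#' @export
oscillation_coupling_reduction <- function(seed = 1,
                                           spec = network_spec(L = 10,
                                                               w = 150,
                                                               eps_ff = 1),
                                           d_mean = 2,
                                           n_osc_grid = c(100, 120, 140, 160),
                                           n_trials_ref = 5,
                                           n_trials_osc = 3,
                                           params = standard_params()) {
  dm <- delay_homogeneous(d_mean)
  ref <- critical_coupling_sim(spec, dm, NULL, params, "non_additive",
                               bracket = c(0.4, 1.4),
                               n_trials = n_trials_ref, tol = 0.05,
                               seed = derive_seed(seed, "t1_ref"))
  # propagation frequency at the onset of propagation (just supercritical)
  sp_on <- spec
  sp_on$eps_ff <- ref$eps_crit + 0.05
  nus <- vapply(1:3, function(i) {
    tr <- propagation_trial(sp_on, dm, params, "non_additive", NULL,
                            seed = derive_seed(seed, paste0("t1_nu", i)))
    tryCatch(propagation_frequency(tr$trace), error = function(e) NA_real_)
  }, numeric(1))
  nu_onset <- stats::median(nus, na.rm = TRUE)
  crit_osc <- vapply(n_osc_grid, function(no) {
    osc <- oscillation_spec(n_osc = no, nu_stim = nu_onset)
    tryCatch(critical_coupling_sim(spec, dm, osc, params, "non_additive",
                                   bracket = c(0.15, ref$eps_crit),
                                   n_trials = n_trials_osc, tol = 0.05,
                                   seed = derive_seed(seed, paste0("t1_", no))
                                   )$eps_crit,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(crit_osc)))
    stop("no oscillation amplitude supported propagation")
  list(reduction = ref$eps_crit / min(crit_osc, na.rm = TRUE),
       eps_crit_ref = ref$eps_crit,
       eps_crit_osc = stats::setNames(crit_osc, n_osc_grid),
       nu_onset = nu_onset)
}
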