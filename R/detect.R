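#' Propagation detector configuration
#'
#' Parameters of the signal-to-noise pulse detector: for each layer k >= 2 a
#' window of length `window` is slid (by a shift `delta` up to `max_shift`
#' behind the previous pulse center) to maximize the layer's spike count
#' `chi_k`; the chance-level count `lambda_k` is the smallest count whose
#' probability of occurrence in a sliding window during a control interval is
#' at most `chance_const`; the layer is successful if
#' `chi_k / lambda_k >= snr_min` and all previous layers were successful.
#'
#' @param window window length Delta-T (ms)
#' @param max_shift maximal lag delta between successive pulses (ms)
#' @param chance_const chance-level constant c (probability)
#' @param snr_min minimal signal-to-noise ratio R
#' @param control_interval length of the control interval (ms)
#' @param shift_step grid resolution of the shift search (ms)
#' @return an object of class `detector_config`
#' @export
detector_config <- function(window = 3, max_shift = 10, chance_const = 0.05,
                            snr_min = 2, control_interval = 1000,
                            shift_step = 0.1) {
  stopifnot(window > 0, max_shift >= 0, chance_const > 0, chance_const < 1,
            snr_min > 0, control_interval > 0, shift_step > 0)
  structure(list(window = window, max_shift = max_shift,
                 chance_const = chance_const, snr_min = snr_min,
                 control_interval = control_interval,
                 shift_step = shift_step),
            class = "detector_config")
}

#' Chance-level count of a layer from a control record
#'
#' Slides a window of length `window` over the control spike times at
#' `shift_step` resolution and returns the minimal count `lambda` with
#' empirical `P(count >= lambda) <= chance_const` (at least 1).
#'
#' @param times spike times of the layer's neurons during the control
#'   interval (ms)
#' @param t_range `c(start, end)` of the control interval (ms)
#' @param detector a [detector_config()]
#' @return integer chance level `lambda >= 1`
#' @export
noise_level <- function(times, t_range, detector) {
  starts <- seq(t_range[1], t_range[2] - detector$window,
                by = detector$shift_step)
  if (length(starts) < 1) stop("control interval shorter than the window")
  times <- sort(times[times >= t_range[1] & times <= t_range[2]])
  counts <- findInterval(starts + detector$window, times) -
    findInterval(starts - 1e-9, times)
  lambda <- 1
  n <- length(starts)
  while (sum(counts >= lambda) / n > detector$chance_const)
    lambda <- lambda + 1
  lambda
}

#' Detect layer-to-layer propagation of a synchronous pulse
#'
#' Implements the windowed signal-to-noise detector. Starting from the
#' initiation time `t0` (pulse center of layer 1), for each layer k >= 2 the
#' spike count `chi_k` of the layer's neurons is maximized over windows of
#' length `window` centered at `t_{k-1} + delta`, `delta` on a grid in
#' `[0, max_shift]` (ties broken by the smallest shift); the new pulse center
#' `t_k` is the mean spike time within the maximizing window. The layer
#' counts as successful if `chi_k / lambda_k >= snr_min` with `lambda_k` from
#' [noise_level()] on the control record, and every previous layer was
#' successful; the first failure terminates the trace.
#'
#' @param record a [simulate_network()] spike record of the stimulated run
#' @param t0 initiation time (ms); becomes `t_1`
#' @param detector a [detector_config()]
#' @param control a spike record of an identical but non-initiated run; its
#'   last `control_interval` ms are used (or a data.frame `neuron, time_ms`)
#' @param control_range optional `c(start, end)` restricting the control
#'   interval (ms)
#' @param ffn FFN index to trace
#' @param layers optional layer-assignment data.frame overriding
#'   `record$layers`
#' @return an object of class `pulse_trace`: data.frame with one row per
#'   layer (`layer, chi, lambda, t_center, success`) plus attributes
#'   `max_layer` (maximal successful layer, >= 1) and `t0`
#' @export
detect_propagation <- function(record, t0, detector = detector_config(),
                               control = NULL, control_range = NULL,
                               ffn = 1, layers = NULL) {
  layers <- layers %||% record$layers
  stopifnot(!is.null(layers))
  lay <- layers[layers$ffn == ffn, ]
  L <- max(lay$layer)
  ctrl_sp <- if (inherits(control, "spike_record")) control$spikes else control
  if (is.null(ctrl_sp) || nrow(ctrl_sp) == 0) {
    # empty control record is an error per the detector contract unless the
    # caller passes an explicit silent-control range
    if (is.null(control)) stop("control record required")
    ctrl_sp <- data.frame(neuron = integer(0), time_ms = numeric(0))
  }
  if (is.null(control_range)) {
    ctrl_end <- if (inherits(control, "spike_record")) control$duration
                else max(c(ctrl_sp$time_ms, detector$control_interval))
    control_range <- c(max(0, ctrl_end - detector$control_interval), ctrl_end)
  }

  shifts <- seq(0, detector$max_shift, by = detector$shift_step)
  sp <- record$spikes
  out <- data.frame(layer = seq_len(L), chi = NA_integer_,
                    lambda = NA_integer_, t_center = NA_real_,
                    success = FALSE)
  out$success[1] <- TRUE
  out$t_center[1] <- t0
  t_prev <- t0
  alive <- TRUE
  for (k in 2:L) {
    ids <- lay$neuron[lay$layer == k]
    lt <- sort(sp$time_ms[sp$neuron %in% ids])
    ct <- ctrl_sp$time_ms[ctrl_sp$neuron %in% ids]
    lambda <- noise_level(ct, control_range, detector)
    centers <- t_prev + shifts
    lo <- centers - detector$window / 2
    hi <- centers + detector$window / 2
    counts <- findInterval(hi, lt) - findInterval(lo - 1e-9, lt)
    best <- which.max(counts)  # ties: smallest shift
    chi <- counts[best]
    t_k <- if (chi > 0)
      mean(lt[lt >= lo[best] - 1e-9 & lt <= hi[best]])
    else centers[best]
    ok <- alive && (chi / lambda >= detector$snr_min)
    out$chi[k] <- chi
    out$lambda[k] <- lambda
    out$t_center[k] <- t_k
    out$success[k] <- ok
    if (!ok) alive <- FALSE
    t_prev <- t_k
  }
  structure(out, class = c("pulse_trace", "data.frame"),
            max_layer = max(out$layer[out$success]), t0 = t0)
}

#' Maximal successful layer of a pulse trace
#' @param trace a [detect_propagation()] result
#' @return integer layer index (1 when nothing propagated)
#' @export
max_successful_layer <- function(trace) attr(trace, "max_layer")

#' Propagation frequency from a pulse trace
#'
#' The inverse of the average time interval between consecutive synchronous
#' pulses over the successful layers, in Hz.
#'
#' @param trace a [detect_propagation()] result (or any data.frame with
#'   `t_center` and `success`)
#' @return frequency (Hz)
#' @export
propagation_frequency <- function(trace) {
  tc <- trace$t_center[trace$success]
  if (length(tc) < 3) stop("need at least 3 successful layers")
  1000 / mean(diff(tc))
}
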