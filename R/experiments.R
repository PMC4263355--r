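#' Experiment configuration
#'
#' Config-driven reproduction of the main experiment designs at configurable
#' scale. `experiment` is one of `propagation_demo`, `map_bifurcation`,
#' `balanced_amplitude_scan`, `unbalance_scan`, `resonance_scan`, `gating`,
#' `lognormal_delay_scan`, `hippocampal_delay_scan`. Any entry of `opts`
#' overrides that experiment's defaults (see [run_experiment()] for the
#' per-experiment options).
#'
#' @param experiment experiment name
#' @param seed master seed
#' @param out_dir output directory (created if missing); `NULL` for no file
#'   output
#' @param mode coupling mode
#' @param opts named list of experiment-specific overrides
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(experiment, seed = 1, out_dir = NULL,
                              mode = "non_additive", opts = list()) {
  experiments <- c("propagation_demo", "map_bifurcation",
                   "balanced_amplitude_scan", "unbalance_scan",
                   "resonance_scan", "gating", "lognormal_delay_scan",
                   "hippocampal_delay_scan")
  if (!experiment %in% experiments)
    stop("unknown experiment: ", experiment, "; choose one of ",
         paste(experiments, collapse = ", "))
  structure(list(experiment = experiment, seed = seed, out_dir = out_dir,
                 mode = mode, opts = opts),
            class = "experiment_config")
}

#' Read an experiment configuration from a JSON file
#'
#' Flat key/value JSON mirroring [experiment_config()] arguments; unknown
#' keys land in `opts`.
#'
#' @param path JSON file
#' @return an `experiment_config`
#' @export
read_experiment_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  main <- intersect(names(j), c("experiment", "seed", "out_dir", "mode"))
  args <- j[main]
  args$opts <- j[setdiff(names(j), main)]
  do.call(experiment_config, args)
}

.opt <- function(cfg, name, default) cfg$opts[[name]] %||% default

#' Run a named experiment end-to-end
#'
#' Builds the network and stimuli, simulates, analyzes, and (if `out_dir`
#' is set) writes tidy CSV tables, spike CSVs and a JSON summary including
#' the full configuration echo. Deterministic given the config seed.
#'
#' @param cfg an [experiment_config()]
#' @return list with `summary` (experiment-specific), `tables` (named list
#'   of data.frames), and `config`
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  params <- standard_params()
  seed <- cfg$seed
  mode <- cfg$mode
  out <- switch(cfg$experiment,
    propagation_demo = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      n_osc <- .opt(cfg, "n_osc", 120)
      nu <- .opt(cfg, "nu_stim", 180)
      no_osc <- propagation_trial(spec, params = params, mode = mode,
                                  seed = seed)
      with_osc <- propagation_trial(spec, params = params, mode = mode,
                                    oscillation = oscillation_spec(
                                      n_osc = n_osc, nu_stim = nu),
                                    seed = seed)
      list(summary = list(max_layer_no_osc = max_successful_layer(no_osc$trace),
                          max_layer_osc = max_successful_layer(with_osc$trace)),
           tables = list(trace_no_osc = as.data.frame(no_osc$trace),
                         trace_osc = as.data.frame(with_osc$trace)),
           records = list(no_osc = no_osc$record, osc = with_osc$record))
    },
    map_bifurcation = {
      w <- .opt(cfg, "w", 150); p <- .opt(cfg, "p", 0.1)
      eps_grid <- .opt(cfg, "eps_grid", c(0.3, 0.6, 0.9))
      curve <- estimate_response_curve(seq(0, 25, by = 1), mode = mode,
                                       n_trials = .opt(cfg, "n_trials", 400),
                                       params = params, seed = seed)
      maps <- lapply(eps_grid, function(e) build_map(curve, w, p, e))
      counts <- vapply(maps, function(m) nrow(m$fixed_points), numeric(1))
      list(summary = list(eps_grid = eps_grid, n_fixed_points = counts),
           tables = list(curve = as.data.frame(curve),
                         fixed_points = do.call(rbind, lapply(seq_along(maps),
                           function(i) cbind(eps_ff = eps_grid[i],
                                             maps[[i]]$fixed_points)))))
    },
    balanced_amplitude_scan = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      nu <- .opt(cfg, "nu_stim", 180)
      n_osc_grid <- .opt(cfg, "n_osc_grid", c(0, 40, 80, 120, 160))
      rows <- lapply(n_osc_grid, function(no) {
        osc <- if (no > 0) oscillation_spec(n_osc = no, nu_stim = nu) else NULL
        tr <- propagation_trial(spec, params = params, mode = mode,
                                oscillation = osc, seed = seed)
        data.frame(n_osc = no, max_layer = max_successful_layer(tr$trace),
                   ctl_rate_Hz = ffn_rate(tr$control, tr$net))
      })
      tab <- do.call(rbind, rows)
      list(summary = as.list(tab), tables = list(amplitude_scan = tab))
    },
    unbalance_scan = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      g_grid <- .opt(cfg, "g_grid", c(0.5, 0.75, 1, 1.5, 2))
      n_osc <- .opt(cfg, "n_osc", 120)
      nu <- .opt(cfg, "nu_stim", 180)
      rows <- lapply(g_grid, function(g) {
        osc <- oscillation_spec(n_osc = n_osc, nu_stim = nu, unbalance_g = g)
        tr <- propagation_trial(spec, params = params, mode = mode,
                                oscillation = osc, seed = seed)
        data.frame(unbalance_g = g,
                   max_layer = max_successful_layer(tr$trace))
      })
      tab <- do.call(rbind, rows)
      list(summary = as.list(tab), tables = list(unbalance_scan = tab))
    },
    resonance_scan = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      tab <- resonance_scan(spec,
                            oscillation = oscillation_spec(
                              n_osc = .opt(cfg, "n_osc", 120)),
                            nu_grid = .opt(cfg, "nu_grid",
                                           seq(100, 220, by = 20)),
                            n_trials = .opt(cfg, "n_trials", 2),
                            params = params, mode = mode, seed = seed)
      list(summary = as.list(tab), tables = list(resonance = tab))
    },
    gating = {
      nu <- .opt(cfg, "nu_stim", 180)
      res <- gating_experiment(nu, d_means = .opt(cfg, "d_means", c(2, 4)),
                               params = params, mode = mode, seed = seed)
      list(summary = list(nu_stim = nu, max_layer = res$max_layer,
                          nu_prop = res$nu_prop),
           tables = list(gating = data.frame(ffn = c(1, 2),
                                             max_layer = res$max_layer,
                                             nu_prop = res$nu_prop)))
    },
    lognormal_delay_scan = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      sigmas <- .opt(cfg, "sigma_grid", c(0.1, 0.3, 0.5))
      n_osc <- .opt(cfg, "n_osc", 120)
      nu <- .opt(cfg, "nu_stim", 180)
      rows <- lapply(sigmas, function(s) {
        dm <- delay_lognormal(mode = 2, sigma = s)
        tr <- propagation_trial(spec, dm, params = params, mode = mode,
                                oscillation = oscillation_spec(n_osc = n_osc,
                                                               nu_stim = nu),
                                seed = seed)
        data.frame(sigma = s, sd_ms = lognormal_delay_sd(2, s),
                   max_layer = max_successful_layer(tr$trace))
      })
      tab <- do.call(rbind, rows)
      list(summary = as.list(tab), tables = list(lognormal_scan = tab))
    },
    hippocampal_delay_scan = {
      spec <- network_spec(L = .opt(cfg, "L", 10), w = .opt(cfg, "w", 150),
                           eps_ff = .opt(cfg, "eps_ff", 0.45))
      sides <- .opt(cfg, "side_grid", c(200, 400))
      n_osc <- .opt(cfg, "n_osc", 120)
      nu_grid <- .opt(cfg, "nu_grid", seq(120, 200, by = 40))
      rows <- list()
      for (S in sides) for (nu in nu_grid) {
        dm <- delay_hippocampal(side_length = S)
        tr <- propagation_trial(spec, dm, params = params, mode = mode,
                                oscillation = oscillation_spec(n_osc = n_osc,
                                                               nu_stim = nu),
                                seed = seed)
        rows[[length(rows) + 1]] <-
          data.frame(side_um = S, nu_stim = nu,
                     max_layer = max_successful_layer(tr$trace))
      }
      tab <- do.call(rbind, rows)
      list(summary = as.list(tab), tables = list(hippocampal_scan = tab))
    })

  out$config <- cfg
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out$tables))
      utils::write.csv(out$tables[[nm]],
                       file.path(cfg$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(out$records))
      for (nm in names(out$records))
        write_spikes(out$records[[nm]],
                     file.path(cfg$out_dir, paste0("spikes_", nm, ".csv")))
    jsonlite::write_json(list(experiment = cfg$experiment, seed = cfg$seed,
                              mode = cfg$mode, opts = cfg$opts,
                              summary = out$summary),
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Canned miniature fixtures for tests and demos
#'
#' Hand-constructed spike records with known detector outcomes on a tiny
#' layered geometry (`L` layers of `w` neurons, neuron ids assigned in layer
#' order): a perfect chain (every layer fires `w` spikes at 5 ms hops), a
#' chain broken at a given layer, and a silent control.
#'
#' @param seed seed (jitters the spike times within +/- 0.2 ms)
#' @param L,w layers and layer size
#' @param t0 initiation time (ms)
#' @return list with `layers` (assignment data.frame), `perfect_chain`,
#'   `broken_at_4` (spike data.frames), `silent_control` (empty spike
#'   data.frame), `t0`
#' @export
make_fixtures <- function(seed = 1, L = 6, w = 20, t0 = 50) {
  layers <- data.frame(neuron = seq_len(L * w), ffn = 1,
                       layer = rep(seq_len(L), each = w))
  chain <- with_stream_seed(seed, "fixtures", {
    do.call(rbind, lapply(seq_len(L), function(k)
      data.frame(neuron = layers$neuron[layers$layer == k],
                 time_ms = t0 + (k - 1) * 5 +
                   stats::runif(w, -0.2, 0.2))))
  })
  chain <- chain[order(chain$time_ms), ]
  broken <- chain[chain$time_ms < t0 + 3 * 5 - 2, ]
  silent <- data.frame(neuron = integer(0), time_ms = numeric(0))
  list(layers = layers, perfect_chain = chain, broken_at_4 = broken,
       silent_control = silent, t0 = t0)
}
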