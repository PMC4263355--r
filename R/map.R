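#' Estimate the single-neuron response-probability curve
#'
#' The probability p(g) that a neuron in the fluctuating ground state spikes
#' within `window` ms after a synchronous compound input of strength g.
#' Estimated per grid point from `n_trials` independent trials (one engine
#' run of `n_trials` unconnected neurons per strength).
#'
#' @param strength_grid input strengths (nS)
#' @param mode coupling mode (`"additive"` or `"non_additive"`)
#' @param n_trials trials per strength (>= 100)
#' @param params model parameters from [standard_params()]
#' @param background a [background_spec()]
#' @param oscillation optional [oscillation_spec()]; if given, the compound
#'   input is delivered at an oscillation cycle center, mimicking an in-phase
#'   pulse arrival
#' @param window response window (ms)
#' @param seed master seed
#' @return an object of class `response_curve`: data.frame with `strength`,
#'   `p`, `n`, `ci_lo`, `ci_hi` (95% binomial CI)
#' @export
estimate_response_curve <- function(strength_grid, mode = "non_additive",
                                    n_trials = 400,
                                    params = standard_params(),
                                    background = params$background,
                                    oscillation = NULL,
                                    window = 10, seed = 1) {
  stopifnot(n_trials >= 100)
  warmup <- 200
  t0 <- warmup
  osc <- oscillation
  if (!is.null(osc)) {
    period <- 1000 / osc$nu_stim
    osc$phase <- t0 %% period  # cycle center at the input time
  }
  p_hat <- vapply(seq_along(strength_grid), function(i) {
    g <- strength_grid[i]
    ext <- if (g > 0)
      data.frame(neuron = seq_len(n_trials), time_ms = t0, sign = 1L,
                 strength_nS = g)
    else NULL
    cfg <- sim_config(dt = 0.1, duration = warmup + window + 2, mode = mode,
                      seed = derive_seed(seed, paste0("rc", i)))
    rec <- simulate_network(NULL, cfg, params, background = background,
                            oscillation = osc, external = ext,
                            n_neurons = n_trials)
    sp <- rec$spikes
    length(unique(sp$neuron[sp$time_ms > t0 & sp$time_ms <= t0 + window])) /
      n_trials
  }, numeric(1))
  ci <- 1.96 * sqrt(pmax(p_hat * (1 - p_hat), 1e-12) / n_trials)
  structure(data.frame(strength = strength_grid, p = p_hat, n = n_trials,
                       ci_lo = pmax(0, p_hat - ci),
                       ci_hi = pmin(1, p_hat + ci)),
            class = c("response_curve", "data.frame"),
            mode = mode, window = window)
}

# continuous-in-xi binomial pmf via gamma functions: the standard continuous
# interpolation of choose(xi, k) p^k (1-p)^(xi-k) for real xi >= k
.binom_pmf_cont <- function(k, xi, p) {
  if (xi <= 0) return(as.numeric(k == 0))
  ok <- k <= xi
  out <- numeric(length(k))
  kk <- k[ok]
  out[ok] <- exp(lgamma(xi + 1) - lgamma(kk + 1) - lgamma(xi - kk + 1) +
                   kk * log(p) + (xi - kk) * log1p(-p))
  out
}

#' Build the layerwise iterated map of synchronous group size
#'
#' Given the single-neuron response curve p(g), the expected number of
#' synchronously spiking neurons in a layer, when xi neurons spiked in the
#' previous layer, is
#' \deqn{G(\xi) = w \sum_k B(k; \xi, p)\, \hat p(k\, \varepsilon_{ff}),}
#' the binomial mixture over the number k of received inputs. `G` is
#' evaluated on a fine grid using the gamma-function (continuous-in-xi)
#' interpolation of the binomial weights; p-hat between curve grid points is
#' linearly interpolated. Fixed points are located by sign changes of
#' `G(xi) - xi` with root polishing, and classified by the slope `G'` at the
#' root (stable iff |G'| < 1).
#'
#' @param curve a [estimate_response_curve()] result (or any data.frame with
#'   `strength` and `p`); must cover strengths up to `w * eps_ff`
#' @param w layer size
#' @param p connection probability between consecutive layers
#' @param eps_ff feed-forward strength (nS)
#' @param grid_n evaluation grid resolution
#' @return an object of class `iterated_map`: list with `xi` (grid), `G`
#'   (map values), `fixed_points` (data.frame `xi, stable`), `fun` (function
#'   xi -> G(xi)), and the inputs
#' @export
build_map <- function(curve, w, p, eps_ff, grid_n = 512) {
  # the binomial input-count mass sits near w*p senders; beyond the curve's
  # last grid point p-hat is extended as constant (rule = 2), which is safe
  # only once the curve has covered the mean compound input
  if (max(curve$strength) < w * p * eps_ff)
    stop("response curve too short: cover strengths up to w*p*eps_ff")
  p_of_g <- stats::approxfun(curve$strength, curve$p, rule = 2)
  G1 <- function(xi) {
    vapply(xi, function(x) {
      # continuum limit at 0 senders: every neuron responds at the ground
      # probability p(0)
      if (x <= 0) return(w * p_of_g(0))
      ks <- 0:ceiling(x)
      sum(.binom_pmf_cont(ks, x, p) * p_of_g(ks * eps_ff)) * w
    }, numeric(1))
  }
  xi <- seq(0, w, length.out = grid_n)
  Gv <- G1(xi)
  # fixed points: sign changes of G - xi (0 is always checked explicitly)
  d <- Gv - xi
  fp <- numeric(0)
  for (i in seq_len(length(xi) - 1)) {
    if (d[i] == 0 && xi[i] == 0) next
    if (sign(d[i]) != sign(d[i + 1])) {
      r <- tryCatch(stats::uniroot(function(x) G1(x) - x,
                                   c(xi[i], xi[i + 1]), tol = 1e-6)$root,
                    error = function(e) NA_real_)
      if (!is.na(r)) fp <- c(fp, r)
    }
  }
  if (abs(d[1]) < 1e-9) fp <- c(0, fp)
  fp <- sort(unique(round(fp, 6)))
  h <- max(w * 1e-4, 1e-4)
  slope <- vapply(fp, function(x) {
    (G1(min(x + h, w)) - G1(max(x - h, 0))) /
      (min(x + h, w) - max(x - h, 0))
  }, numeric(1))
  structure(list(xi = xi, G = Gv,
                 fixed_points = data.frame(xi = fp, slope = slope,
                                           stable = abs(slope) < 1),
                 fun = G1, w = w, p = p, eps_ff = eps_ff),
            class = "iterated_map")
}

#' @export
print.iterated_map <- function(x, ...) {
  cat(sprintf("<iterated_map> w=%d p=%g eps_ff=%g nS; %d fixed point(s)\n",
              x$w, x$p, x$eps_ff, nrow(x$fixed_points)))
  print(x$fixed_points)
  invisible(x)
}

#' Iterate the group-size map
#'
#' @param map an [build_map()] result
#' @param xi0 initial group size
#' @param n number of iterations
#' @return numeric vector of length `n + 1` starting at `xi0`
#' @export
iterate_map <- function(map, xi0, n = 50) {
  out <- numeric(n + 1)
  out[1] <- xi0
  for (i in seq_len(n)) out[i + 1] <- min(map$w, map$fun(out[i]))
  out
}

#' Monte-Carlo realization of the layerwise response
#'
#' Direct stochastic oracle of the binomial-mixture expectation: each of the
#' `w` neurons receives k ~ Binomial(xi, p) synchronous inputs of strength
#' `eps_ff` and spikes with probability p(k eps_ff) read off the response
#' curve. Returns the mean next-layer group size over `n_rep` repetitions,
#' with its standard error.
#'
#' @param curve a response curve
#' @param xi integer group size in the sending layer
#' @param w,p,eps_ff as in [build_map()]
#' @param n_rep repetitions
#' @param seed seed
#' @return list with `mean` and `se`
#' @export
mc_layer_response <- function(curve, xi, w, p, eps_ff, n_rep = 2000,
                              seed = 1) {
  p_of_g <- stats::approxfun(curve$strength, curve$p, rule = 2)
  with_stream_seed(seed, "mc_layer", {
    sizes <- vapply(seq_len(n_rep), function(r) {
      k <- stats::rbinom(w, round(xi), p)
      sum(stats::runif(w) < p_of_g(k * eps_ff))
    }, numeric(1))
    list(mean = mean(sizes), se = stats::sd(sizes) / sqrt(n_rep))
  })
}

#' Critical coupling of the map family via bisection (tangent bifurcation)
#'
#' For weak feed-forward coupling the map has a single stable fixed point at
#' (or near) zero; at the critical coupling two additional fixed points, one
#' unstable and one stable, appear via a tangent bifurcation. This function
#' bisects on `eps_ff` for the change in fixed-point count.
#'
#' @param curve_fn function(eps_ff) returning a response curve (may ignore
#'   its argument if the curve does not depend on the coupling)
#' @param w,p as in [build_map()]
#' @param bracket `c(lo, hi)` coupling bracket (nS); must straddle the
#'   transition
#' @param tol bisection tolerance on eps_ff (nS)
#' @return list with `eps_crit`, `n_lo`, `n_hi` (fixed-point counts at the
#'   final bracket ends)
#' @export
tangent_bifurcation <- function(curve_fn, w, p, bracket, tol = 1e-3) {
  count_fp <- function(eps) nrow(build_map(curve_fn(eps), w, p, eps)$fixed_points)
  lo <- bracket[1]; hi <- bracket[2]
  n_lo <- count_fp(lo); n_hi <- count_fp(hi)
  if (!(n_lo < 3 && n_hi >= 3))
    stop("bracket does not straddle the bifurcation (counts ", n_lo, ", ",
         n_hi, ")")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count_fp(mid) >= 3) hi <- mid else lo <- mid
  }
  list(eps_crit = (lo + hi) / 2, n_lo = n_lo, n_hi = n_hi)
}
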