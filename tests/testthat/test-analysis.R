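test_that("detector fixtures: perfect chain, broken chain, silent layers", {
  fx <- make_fixtures(seed = 1)
  det <- detector_config(control_interval = 100)
  tr <- detect_propagation(list(spikes = fx$perfect_chain), fx$t0, det,
                           control = fx$silent_control, layers = fx$layers,
                           control_range = c(0, 100))
  expect_equal(max_successful_layer(tr), 6)
  expect_true(all(tr$lambda[-1] == 1))  # silent control floors at 1
  expect_equal(mean(diff(tr$t_center)), 5, tolerance = 0.05)
  expect_equal(propagation_frequency(tr), 200, tolerance = 2)

  tr2 <- detect_propagation(list(spikes = fx$broken_at_4), fx$t0, det,
                            control = fx$silent_control, layers = fx$layers,
                            control_range = c(0, 100))
  expect_equal(max_successful_layer(tr2), 3)

  # nothing after t0 at all -> max layer 1
  tr3 <- detect_propagation(list(spikes = fx$silent_control), fx$t0, det,
                            control = fx$silent_control, layers = fx$layers,
                            control_range = c(0, 100))
  expect_equal(max_successful_layer(tr3), 1)
})

test_that("alternating 4/6 ms pulse spacing still gives 200 Hz", {
  layers <- data.frame(neuron = 1:50, ffn = 1, layer = rep(1:5, each = 10))
  times <- c(0, 4, 10, 14, 20)  # cumulative 4/6 alternation
  sp <- data.frame(neuron = 1:50, time_ms = rep(100 + times, each = 10))
  tr <- detect_propagation(list(spikes = sp), 100,
                           detector_config(control_interval = 90),
                           control = data.frame(neuron = integer(0),
                                                time_ms = numeric(0)),
                           layers = layers, control_range = c(0, 90))
  expect_equal(propagation_frequency(tr), 200, tolerance = 1e-6)
  expect_error(propagation_frequency(tr[1:2, ]), "3 successful")
})

test_that("noise level matches the brute-force Poisson window-count quantile", {
  det <- detector_config(window = 3, chance_const = 0.05,
                         control_interval = 2000, shift_step = 0.5)
  rate <- 2  # spikes per ms across the layer
  set.seed(99)
  n_exp <- rpois(1, rate * 2000)
  times <- sort(runif(n_exp, 0, 2000))
  lam <- noise_level(times, c(0, 2000), det)
  # brute force: P(Poisson(rate * window) >= lambda) <= c
  p_tail <- function(l) 1 - stats::ppois(l - 1, rate * det$window)
  lam_exact <- 1
  while (p_tail(lam_exact) > det$chance_const) lam_exact <- lam_exact + 1
  expect_lt(abs(lam - lam_exact), 2)  # within +-1 count
})

test_that("detector monotonicity: extra spikes in the window never lower chi; larger c never raises lambda", {
  fx <- make_fixtures(seed = 2)
  det <- detector_config(control_interval = 100)
  base <- detect_propagation(list(spikes = fx$perfect_chain), fx$t0, det,
                             control = fx$silent_control, layers = fx$layers,
                             control_range = c(0, 100))
  extra <- rbind(fx$perfect_chain,
                 data.frame(neuron = fx$layers$neuron[fx$layers$layer == 3][1:5],
                            time_ms = base$t_center[3]))
  more <- detect_propagation(list(spikes = extra), fx$t0, det,
                             control = fx$silent_control, layers = fx$layers,
                             control_range = c(0, 100))
  expect_true(all(more$chi[-1] >= base$chi[-1]))
  # lambda is non-increasing in the chance constant
  set.seed(1)
  times <- sort(runif(500, 0, 1000))
  l_strict <- noise_level(times, c(0, 1000),
                          detector_config(chance_const = 0.01))
  l_loose <- noise_level(times, c(0, 1000),
                         detector_config(chance_const = 0.2))
  expect_gte(l_strict, l_loose)
})

test_that("response curve: additive monotone, non-additive jumps at the dendritic threshold", {
  th <- std$dendrite$threshold
  rc_na <- estimate_response_curve(c(0, th - 1.5, th + 1.5, 2 * th),
                                   "non_additive", n_trials = 300,
                                   params = std, seed = 11)
  jump <- rc_na$p[3] - rc_na$p[2]
  ci_w <- mean(rc_na$ci_hi[2:3] - rc_na$ci_lo[2:3]) / 2
  expect_gt(jump, 5 * ci_w)
  # baseline at strength 0 is the (tiny) ground rate times the window
  expect_lt(rc_na$p[1], 0.02)
  rc_add <- estimate_response_curve(seq(0, 120, by = 20), "additive",
                                    n_trials = 300, params = std, seed = 12)
  expect_true(all(diff(rc_add$p) > -2 * 1.96 * sqrt(0.25 / 300)))
  expect_gt(rc_add$p[7], 0.9)
})

test_that("map: zero response gives the zero map; toy step map matches brute-force roots", {
  flat <- data.frame(strength = seq(0, 100, 5), p = 0)
  m0 <- build_map(flat, w = 50, p = 0.2, eps_ff = 1)
  expect_true(all(m0$G == 0))
  expect_equal(m0$fixed_points$xi, 0)
  expect_true(m0$fixed_points$stable)

  m <- build_map(toy_step_curve(3), w = 50, p = 0.2, eps_ff = 3)
  # brute-force: exhaustive scan of G(xi) - xi on a fine grid
  xi_grid <- seq(0.1, 50, by = 1e-3)  # skip the known root at 0
  d <- m$fun(xi_grid) - xi_grid
  sign_flips <- which(diff(sign(d)) != 0)
  brute <- xi_grid[sign_flips]
  fp <- m$fixed_points$xi
  expect_equal(length(fp), length(brute) + 1)  # + the root at 0
  expect_true(all(abs(sort(fp[-1]) - sort(brute)) < 5e-3))
  # stability labels: 0 stable, middle unstable, top stable
  expect_equal(m$fixed_points$stable, c(TRUE, FALSE, TRUE))
  # iterating from w converges to the upper stable point; from below the
  # unstable point it collapses to 0
  expect_equal(tail(iterate_map(m, 50, 60), 1), max(fp), tolerance = 1e-3)
  expect_lt(tail(iterate_map(m, 0.9 * fp[2], 60), 1), 1e-3)
})

test_that("map equals the Monte-Carlo layer oracle within 3 SE (sigmoid and step)", {
  for (curve in list(toy_sigmoid_curve(), toy_step_curve(2, g_max = 60))) {
    m <- build_map(curve, w = 150, p = 0.1, eps_ff = 2)
    for (xi in c(5, 15, 40, 100)) {
      mc <- mc_layer_response(curve, xi, 150, 0.1, 2, n_rep = 3000,
                              seed = xi)
      expect_lt(abs(mc$mean - m$fun(xi)), 3 * mc$se + 1e-9)
    }
  }
})

test_that("tangent bifurcation: bisection matches a dense-grid scan to 1e-3 nS", {
  w <- 50; p <- 0.2
  fam <- function(e) toy_step_curve(e, g_max = 60)
  tb <- tangent_bifurcation(fam, w, p, c(0.5, 3), tol = 1e-4)
  expect_equal(tb$n_lo, 1)
  expect_gte(tb$n_hi, 3)
  # dense scan oracle
  eps_grid <- seq(0.5, 3, by = 1e-3)
  counts <- vapply(eps_grid, function(e)
    nrow(build_map(fam(e), w, p, e)$fixed_points), numeric(1))
  first3 <- eps_grid[min(which(counts >= 3))]
  expect_lt(abs(tb$eps_crit - first3), 2e-3)
  # fixed-point count is odd (1 or 3) across the family
  expect_true(all(counts %in% c(1, 3)))
})

test_that("locking ratio picks small-integer rationals within tolerance", {
  l <- locking_ratio(0.505)
  expect_equal(c(l$n, l$m), c(1, 2))
  expect_true(l$locked)
  l2 <- locking_ratio(0.662)
  expect_equal(c(l2$n, l2$m), c(2, 3))
  expect_false(locking_ratio(0.58)$locked)
})
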