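test_that("background generator: Poisson counts, empty at rate 0, error on negative rate", {
  expect_equal(nrow(generate_background(background_spec(0, 0, 1, 1), 5, 100,
                                        seed = 1)), 0)
  bg <- background_spec(rate_ex = 1, rate_in = 0, eps_ex = 1, eps_in = 0)
  ev <- generate_background(bg, 3, 1e4, seed = 2)
  for (i in 1:3) {
    n_i <- sum(ev$neuron == i)
    expect_lt(abs(n_i - 1e4), 4 * sqrt(1e4))
  }
  bad <- background_spec(1, 1, 1, 1)
  bad$rate_ex <- -1
  expect_error(generate_background(bad, 2, 10), "negative rate")
})

test_that("background streams of different neurons are uncorrelated", {
  bg <- background_spec(rate_ex = 1, rate_in = 0, eps_ex = 1, eps_in = 0)
  ev <- generate_background(bg, 2, 1e5, seed = 3)
  b <- seq(0, 1e5, by = 1)
  c1 <- tabulate(findInterval(ev$time_ms[ev$neuron == 1], b), length(b))
  c2 <- tabulate(findInterval(ev$time_ms[ev$neuron == 2], b), length(b))
  expect_lt(abs(stats::cor(c1, c2)), 0.02)
})

test_that("oscillation generator: empty at n_osc 0, binomial deliveries, jitter sd", {
  expect_equal(nrow(generate_oscillation(oscillation_spec(n_osc = 0), 5, 100,
                                         seed = 1)), 0)
  spec <- oscillation_spec(n_osc = 10, nu_stim = 200, sigma_osc = 1,
                           p_deliver_ex = 0.3, p_deliver_in = 0.2,
                           eps_ex = 1, eps_in = 1, unbalance_g = 1.5)
  dur <- 5000  # 10^3 cycles
  ev <- generate_oscillation(spec, 4, dur, seed = 4)
  n_cycles <- dur / (1000 / spec$nu_stim)
  for (i in 1:4) {
    n_ex <- sum(ev$neuron == i & ev$sign == 1)
    mu <- n_cycles * spec$n_osc * spec$p_deliver_ex
    expect_lt(abs(n_ex - mu), 4 * sqrt(mu))
  }
  # inhibitory strength carries the unbalance factor
  expect_equal(unique(ev$strength_nS[ev$sign == -1]), 1.5)
  # pooled within-cycle spike-time sd of the source spikes
  src <- oscillation_source_spikes(spec, dur, seed = 4)
  period <- 1000 / spec$nu_stim
  resid <- (src + period / 2) %% period - period / 2  # distance to center
  expect_lt(abs(stats::sd(resid) - spec$sigma_osc) / spec$sigma_osc, 0.03)
})

test_that("effective mean drive: balance, proportionality in nu, zero at n_osc 0", {
  spec <- oscillation_spec(n_osc = 50, nu_stim = 100, p_deliver_ex = 0.5,
                           p_deliver_in = 0.5, eps_ex = 1, eps_in = 6.63)
  d1 <- effective_mean_drive(spec)
  # balanced: inhibitory drive is the alpha-scaled partner
  expect_equal(d1[["in_"]] / d1[["ex"]], 6.63)
  spec2 <- spec; spec2$nu_stim <- 200
  expect_equal(effective_mean_drive(spec2), 2 * d1)
  spec0 <- spec; spec0$n_osc <- 0
  expect_equal(unname(effective_mean_drive(spec0)), c(0, 0))
})

test_that("balanced oscillation barely shifts a passive neuron's mean potential; unbalance shifts it in the stated direction", {
  pp <- std
  pp$neuron <- neuron_params(V_theta = 30)  # passive: never spikes
  mean_V <- function(osc) {
    cfg <- sim_config(dt = 0.1, duration = 2000, mode = "additive", seed = 6)
    rec <- simulate_network(NULL, cfg, pp, oscillation = osc, n_neurons = 1,
                            record_ids = 1, V0 = std$neuron$E_L)
    mean(rec$trace$V[5001:20001, 1])
  }
  v_bal <- mean_V(oscillation_spec(n_osc = 120, nu_stim = 180))
  expect_lt(abs(v_bal - std$neuron$E_L), 1)
  v_dep <- mean_V(oscillation_spec(n_osc = 120, nu_stim = 180,
                                   unbalance_g = 0.5))
  v_hyp <- mean_V(oscillation_spec(n_osc = 120, nu_stim = 180,
                                   unbalance_g = 2))
  expect_gt(v_dep, v_bal)
  expect_lt(v_hyp, v_bal)
})

test_that("stimulus generators are deterministic given the seed", {
  bg <- background_spec()
  expect_identical(generate_background(bg, 3, 500, seed = 9),
                   generate_background(bg, 3, 500, seed = 9))
  osc <- oscillation_spec(n_osc = 5)
  expect_identical(generate_oscillation(osc, 3, 500, seed = 9),
                   generate_oscillation(osc, 3, 500, seed = 9))
  expect_false(identical(generate_background(bg, 3, 500, seed = 9),
                         generate_background(bg, 3, 500, seed = 10)))
})
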