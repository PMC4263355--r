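# Shared fixtures: computed once per test run.

std <- standard_params()

# step-response family with a fixed absolute threshold (the dendritic one):
# p(g) = 1 iff g >= theta. Under coupling eps_ff the map becomes
# G(xi) = w * P[Binom(xi, p) >= theta / eps_ff], which undergoes a tangent
# bifurcation as eps_ff grows.
toy_step_curve <- function(eps_ff, theta = 8.65, g_max = NULL) {
  g <- seq(0, max(g_max %||% 0, 40, 15 * eps_ff), by = 0.25)
  data.frame(strength = g, p = as.numeric(g >= theta))
}

# smooth sigmoid response (additive-like)
toy_sigmoid_curve <- function(g50 = 60, slope = 8, g_max = 150) {
  g <- seq(0, g_max, by = 1)
  data.frame(strength = g, p = stats::plogis((g - g50) / slope))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard scaled-down FFN spec used across propagation tests
ffn_spec <- function(eps_ff, w = 150, L = 10)
  network_spec(L = L, w = w, eps_ff = eps_ff)

# balanced oscillation at the package's standard quanta
osc_at <- function(nu, n_osc = 120) oscillation_spec(n_osc = n_osc, nu_stim = nu)
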