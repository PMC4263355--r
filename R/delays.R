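#' Conduction-delay models
#'
#' Four per-edge conduction-delay models:
#' \describe{
#'   \item{homogeneous}{every delay equals `d0`.}
#'   \item{uniform}{delays drawn uniformly from an interval of length `width`
#'     centered at `d_mean` (truncated at 0 by the positivity invariant;
#'     parameters must keep the support positive).}
#'   \item{lognormal}{log-normal density with *fixed mode*: given the mode
#'     \eqn{d_{mode}} and width parameter \eqn{\sigma}, the location parameter
#'     is \eqn{\mu = \ln d_{mode} + \sigma^2}, so the density maximum stays at
#'     `mode` as `sigma` grows. The standard deviation of this distribution is
#'     [lognormal_delay_sd()].}
#'   \item{hippocampal}{delay = axonal + dendritic. Neurons sit uniformly on a
#'     square patch of side `side_length` (um); the axonal delay is the
#'     Euclidean pair distance divided by `velocity` (um/ms); the dendritic
#'     delay is uniform on `dendritic_range` (ms).}
#' }
#'
#' @param d0,d_mean,width,mode,sigma,side_length,velocity,dendritic_range
#'   model parameters, see Details
#' @return an object of class `delay_model`
#' @name delay_models
NULL

#' @rdname delay_models
#' @export
delay_homogeneous <- function(d0 = 2) {
  stopifnot(d0 > 0)
  structure(list(variant = "homogeneous", d0 = d0), class = "delay_model")
}

#' @rdname delay_models
#' @export
delay_uniform <- function(d_mean = 2, width = 1) {
  stopifnot(d_mean > 0, width >= 0, d_mean - width / 2 > 0)
  structure(list(variant = "uniform", d_mean = d_mean, width = width),
            class = "delay_model")
}

#' @rdname delay_models
#' @export
delay_lognormal <- function(mode = 2, sigma = 0.4) {
  stopifnot(mode > 0, sigma > 0)
  structure(list(variant = "lognormal", mode = mode, sigma = sigma,
                 mu = log(mode) + sigma^2),
            class = "delay_model")
}

#' @rdname delay_models
#' @export
delay_hippocampal <- function(side_length = 400, velocity = 300,
                              dendritic_range = c(0.5, 1.5)) {
  stopifnot(side_length >= 0, velocity > 0, length(dendritic_range) == 2,
            dendritic_range[1] >= 0, dendritic_range[2] > dendritic_range[1])
  structure(list(variant = "hippocampal", side_length = side_length,
                 velocity = velocity, dendritic_range = dendritic_range),
            class = "delay_model")
}

#' Closed-form standard deviation of the mode-parameterized log-normal delay
#'
#' For mode \eqn{m} and width parameter \eqn{\sigma} (so \eqn{\mu = \ln m +
#' \sigma^2}) the standard deviation is
#' \deqn{s = m\, e^{3\sigma^2/2} \sqrt{e^{\sigma^2} - 1}.}
#'
#' @param mode mode of the density (ms)
#' @param sigma log-scale width parameter (unitless)
#' @return standard deviation (ms)
#' @export
lognormal_delay_sd <- function(mode, sigma) {
  mode * exp(1.5 * sigma^2) * sqrt(exp(sigma^2) - 1)
}

#' Sample i.i.d. conduction delays
#'
#' For the hippocampal model this draws, per delay, an independent pair of
#' uniform points on the patch (geometric sampling); inside
#' [build_network()] delays are instead derived from each neuron pair's fixed
#' coordinates.
#'
#' @param delay_model a [delay_models] object
#' @param n number of draws
#' @param seed optional seed (stream `"delays"`)
#' @return numeric vector of `n` positive delays (ms)
#' @export
sample_delays <- function(delay_model, n, seed = NULL) {
  stopifnot(n >= 1)
  with_stream_seed(seed, "delays", {
    d <- switch(delay_model$variant,
      homogeneous = rep(delay_model$d0, n),
      uniform = stats::runif(n, delay_model$d_mean - delay_model$width / 2,
                             delay_model$d_mean + delay_model$width / 2),
      lognormal = stats::rlnorm(n, meanlog = delay_model$mu,
                                sdlog = delay_model$sigma),
      hippocampal = {
        S <- delay_model$side_length
        dx <- abs(stats::runif(n, 0, S) - stats::runif(n, 0, S))
        dy <- abs(stats::runif(n, 0, S) - stats::runif(n, 0, S))
        sqrt(dx^2 + dy^2) / delay_model$velocity +
          stats::runif(n, delay_model$dendritic_range[1],
                       delay_model$dendritic_range[2])
      },
      stop("unknown delay model variant"))
    if (any(d <= 0)) stop("delay model produced non-positive delays")
    d
  })
}

# pdf of the distance between two uniform points in the unit square
# ("square line picking")
.unit_square_dist_pdf <- function(r) {
  out <- numeric(length(r))
  i1 <- r >= 0 & r <= 1
  out[i1] <- 2 * r[i1] * (r[i1]^2 - 4 * r[i1] + pi)
  i2 <- r > 1 & r <= sqrt(2)
  x <- r[i2]
  out[i2] <- 2 * x * (4 * sqrt(x^2 - 1) - (x^2 + 2 - pi) -
                        4 * atan(sqrt(x^2 - 1)))
  out
}

#' Analytic density of the hippocampal (distance-based) delay
#'
#' The delay decomposes into an axonal part, the Euclidean distance between
#' two uniformly placed points on a square patch divided by the conduction
#' velocity, and a dendritic part, uniform on `dendritic_range`. The axonal
#' density follows from the classical distance distribution between two
#' random points in a square; the total density is its convolution with the
#' uniform dendritic density, evaluated through the axonal CDF.
#'
#' @param side_length patch side (um); `0` degenerates to the pure dendritic
#'   uniform density
#' @param velocity axonal conduction velocity (um/ms)
#' @param dendritic_range dendritic delay interval `c(min, max)` (ms)
#' @return a function `f(d)` returning the density at delay `d` (ms), with
#'   attribute `support = c(min, max)`
#' @export
hippocampal_delay_density <- function(side_length, velocity,
                                      dendritic_range = c(0.5, 1.5)) {
  stopifnot(side_length >= 0, velocity > 0,
            dendritic_range[2] > dendritic_range[1], dendritic_range[1] >= 0)
  a <- dendritic_range[1]; b <- dendritic_range[2]
  if (side_length == 0) {
    f <- function(d) stats::dunif(d, a, b)
    attr(f, "support") <- c(a, b)
    return(f)
  }
  d_ax_max <- sqrt(2) * side_length / velocity
  # axonal-delay CDF on a fine grid (pdf is the scaled unit-square pdf)
  grid <- seq(0, d_ax_max, length.out = 4097)
  pdf_ax <- (velocity / side_length) *
    .unit_square_dist_pdf(grid * velocity / side_length)
  cdf_vals <- c(0, cumsum((pdf_ax[-1] + pdf_ax[-length(pdf_ax)]) / 2 *
                            diff(grid)))
  cdf_vals <- cdf_vals / cdf_vals[length(cdf_vals)]
  F_ax <- stats::approxfun(grid, cdf_vals, yleft = 0, yright = 1)
  f <- function(d) {
    sapply(d, function(di) (F_ax(di - a) - F_ax(di - b)) / (b - a))
  }
  attr(f, "support") <- c(a, b + d_ax_max)
  f
}
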