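#' Specification of a recurrent network with embedded feed-forward subnetworks
#'
#' The network is a directed Erdos-Renyi graph on `N` neurons: each ordered
#' pair (i != j) carries an excitatory edge with probability `p_ex` and,
#' independently, an inhibitory edge with probability `p_in` (a pair may carry
#' both). `n_ffn` feed-forward networks (FFNs) of `L` layers times `w` neurons
#' are embedded by assigning neurons randomly to disjoint groups; existing
#' excitatory edges between consecutive layers of the same FFN are upgraded
#' from the recurrent strength `eps` to `eps_ff` (edges are never added, so
#' the FFN is a "naturally occurring" substructure). In `isolated` mode only
#' those consecutive-layer excitatory edges are kept.
#'
#' @param N total neuron count
#' @param p_ex,p_in excitatory / inhibitory connection probabilities
#' @param eps recurrent excitatory peak conductance (nS)
#' @param eps_in inhibitory peak conductance (nS); typically the balanced
#'   partner of `eps`
#' @param L layers per FFN
#' @param w neurons per layer
#' @param eps_ff feed-forward peak conductance (nS), `>= eps`
#' @param isolated if `TRUE`, keep only consecutive-layer excitatory edges
#' @param n_ffn number of embedded FFNs
#' @param share_first if `TRUE` (and `n_ffn > 1`) all FFNs share their first
#'   layer (frequency-gating setup)
#' @return an object of class `network_spec`
#' @export
network_spec <- function(N = NULL, p_ex = 0.1, p_in = 0.1,
                         eps = 0, eps_in = 0,
                         L = 10, w = 150, eps_ff = 1,
                         isolated = TRUE, n_ffn = 1, share_first = FALSE) {
  groups <- if (share_first && n_ffn > 1) w * (1 + n_ffn * (L - 1)) else L * w * n_ffn
  if (is.null(N)) N <- groups
  stopifnot(groups <= N, p_ex >= 0, p_ex <= 1, p_in >= 0, p_in <= 1,
            eps_ff >= eps, L >= 2, w >= 1, n_ffn >= 1)
  structure(list(N = N, p_ex = p_ex, p_in = p_in, eps = eps, eps_in = eps_in,
                 L = L, w = w, eps_ff = eps_ff, isolated = isolated,
                 n_ffn = n_ffn, share_first = share_first),
            class = "network_spec")
}

# directed ER edges source->target with prob p, no self loops;
# returns two integer vectors
.er_edges <- function(N, p) {
  if (p <= 0 || N < 2) return(list(src = integer(0), tgt = integer(0)))
  src <- integer(0); tgt <- integer(0)
  for (i in seq_len(N)) {
    hit <- which(stats::runif(N) < p)
    hit <- hit[hit != i]
    src <- c(src, rep.int(i, length(hit)))
    tgt <- c(tgt, hit)
  }
  list(src = src, tgt = tgt)
}

# edges between two specific groups with prob p
.pair_edges <- function(from, to, p) {
  m <- matrix(stats::runif(length(from) * length(to)) < p,
              nrow = length(from))
  idx <- which(m, arr.ind = TRUE)
  list(src = from[idx[, 1]], tgt = to[idx[, 2]])
}

#' Build one network realization
#'
#' Draws the Erdos-Renyi topology, assigns FFN layers, upgrades feed-forward
#' strengths and attaches per-edge conduction delays. Deterministic given
#' `seed` (independent streams for topology, layer assignment, coordinates
#' and delays).
#'
#' @param spec a [network_spec()]
#' @param delay_model a [delay_models] object applied to all edges
#' @param seed master seed
#' @param ffn_delay_models optional list of length `n_ffn`: per-FFN delay
#'   models overriding `delay_model` on that FFN's consecutive-layer
#'   (feed-forward) edges
#' @return an object of class `network_realization`: list with `edges`
#'   (data.frame `source, target, sign, strength_nS, delay_ms`), `layers`
#'   (data.frame `neuron, ffn, layer`), `spec`, `N`
#' @export
build_network <- function(spec, delay_model = delay_homogeneous(2), seed = 1,
                          ffn_delay_models = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(ffn_delay_models)) stopifnot(length(ffn_delay_models) == spec$n_ffn)

  # --- layer assignment -------------------------------------------------
  layers <- with_stream_seed(seed, "layers", {
    if (spec$share_first && spec$n_ffn > 1) {
      n_groups <- 1 + spec$n_ffn * (spec$L - 1)
      picked <- sample.int(spec$N, n_groups * spec$w)
      first <- picked[seq_len(spec$w)]
      rest <- matrix(picked[-seq_len(spec$w)], nrow = spec$w)
      do.call(rbind, lapply(seq_len(spec$n_ffn), function(f) {
        cols <- (f - 1) * (spec$L - 1) + seq_len(spec$L - 1)
        data.frame(neuron = c(first, as.integer(rest[, cols])),
                   ffn = f,
                   layer = rep(seq_len(spec$L), each = spec$w))
      }))
    } else {
      picked <- sample.int(spec$N, spec$n_ffn * spec$L * spec$w)
      data.frame(neuron = picked,
                 ffn = rep(seq_len(spec$n_ffn), each = spec$L * spec$w),
                 layer = rep(rep(seq_len(spec$L), each = spec$w),
                             times = spec$n_ffn))
    }
  })

  # --- topology ---------------------------------------------------------
  topo <- with_stream_seed(seed, "topology", {
    if (spec$isolated) {
      src <- integer(0); tgt <- integer(0)
      for (f in seq_len(spec$n_ffn)) {
        for (l in seq_len(spec$L - 1)) {
          from <- layers$neuron[layers$ffn == f & layers$layer == l]
          to <- layers$neuron[layers$ffn == f & layers$layer == l + 1]
          e <- .pair_edges(from, to, spec$p_ex)
          src <- c(src, e$src); tgt <- c(tgt, e$tgt)
        }
      }
      list(ex = list(src = src, tgt = tgt),
           in_ = list(src = integer(0), tgt = integer(0)))
    } else {
      list(ex = .er_edges(spec$N, spec$p_ex),
           in_ = .er_edges(spec$N, spec$p_in))
    }
  })

  # --- feed-forward upgrade --------------------------------------------
  # with a shared first layer a neuron can belong to several FFNs; use a
  # per-FFN layer map for the upgrade instead of a single assignment vector
  strength <- rep(spec$eps, length(topo$ex$src))
  ffn_edge <- rep(NA_integer_, length(topo$ex$src))
  for (f in seq_len(spec$n_ffn)) {
    sub <- layers[layers$ffn == f, ]
    lay <- rep(NA_integer_, spec$N)
    lay[sub$neuron] <- sub$layer
    sl <- lay[topo$ex$src]; tl <- lay[topo$ex$tgt]
    ff <- !is.na(sl) & !is.na(tl) & tl == sl + 1
    strength[ff] <- spec$eps_ff
    ffn_edge[ff] <- f
  }

  # --- delays -----------------------------------------------------------
  n_ex <- length(topo$ex$src); n_in <- length(topo$in_$src)
  hip <- delay_model$variant == "hippocampal" ||
    (!is.null(ffn_delay_models) &&
       any(vapply(ffn_delay_models, function(m) m$variant == "hippocampal",
                  logical(1))))
  coords <- if (hip) with_stream_seed(seed, "coords", {
    cbind(stats::runif(spec$N), stats::runif(spec$N))
  }) else NULL

  edge_delays <- function(model, src, tgt, sub_seed) {
    n <- length(src)
    if (n == 0) return(numeric(0))
    if (model$variant == "hippocampal") {
      S <- model$side_length
      dx <- S * abs(coords[src, 1] - coords[tgt, 1])
      dy <- S * abs(coords[src, 2] - coords[tgt, 2])
      sqrt(dx^2 + dy^2) / model$velocity +
        stats::runif(n, model$dendritic_range[1], model$dendritic_range[2])
    } else {
      sample_delays(model, n)
    }
  }

  delays_ex <- with_stream_seed(seed, "delays_ex",
                                edge_delays(delay_model, topo$ex$src, topo$ex$tgt))
  if (!is.null(ffn_delay_models)) {
    delays_ex <- with_stream_seed(seed, "delays_ffn", {
      for (f in seq_len(spec$n_ffn)) {
        idx <- which(ffn_edge == f)
        if (length(idx))
          delays_ex[idx] <- edge_delays(ffn_delay_models[[f]],
                                        topo$ex$src[idx], topo$ex$tgt[idx])
      }
      delays_ex
    })
  }
  delays_in <- with_stream_seed(seed, "delays_in",
                                edge_delays(delay_model, topo$in_$src, topo$in_$tgt))

  edges <- rbind(
    data.frame(source = topo$ex$src, target = topo$ex$tgt,
               sign = rep(1L, n_ex),
               strength_nS = strength, delay_ms = delays_ex),
    data.frame(source = topo$in_$src, target = topo$in_$tgt,
               sign = rep(-1L, n_in),
               strength_nS = rep(spec$eps_in, n_in), delay_ms = delays_in))

  structure(list(edges = edges, layers = layers, spec = spec, N = spec$N,
                 seed = seed, delay_model = delay_model),
            class = "network_realization")
}

#' Neuron ids of one FFN layer
#'
#' @param net a [build_network()] result
#' @param layer layer index (1-based)
#' @param ffn FFN index
#' @return integer vector of neuron ids
#' @export
layer_neurons <- function(net, layer, ffn = 1) {
  net$layers$neuron[net$layers$ffn == ffn & net$layers$layer == layer]
}

#' @export
print.network_realization <- function(x, ...) {
  cat(sprintf("<network_realization> N=%d, %d excitatory + %d inhibitory edges\n",
              x$N, sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  cat(sprintf("  %d FFN(s) of %d layers x %d neurons (%s)\n",
              x$spec$n_ffn, x$spec$L, x$spec$w,
              if (x$spec$isolated) "isolated" else "recurrent"))
  invisible(x)
}

#' Export / import a network realization as plain-text CSV
#'
#' Writes `<stem>_edges.csv` with columns
#' `source,target,sign,strength_nS,delay_ms` and `<stem>_layers.csv` with
#' columns `neuron,ffn,layer`.
#'
#' @param net a `network_realization`
#' @param stem file stem (path without extension)
#' @return `write_network`: the stem, invisibly. `read_network`: a list with
#'   `edges` and `layers` data.frames.
#' @export
write_network <- function(net, stem) {
  utils::write.csv(net$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  utils::write.csv(net$layers, paste0(stem, "_layers.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  list(edges = utils::read.csv(paste0(stem, "_edges.csv")),
       layers = utils::read.csv(paste0(stem, "_layers.csv")))
}
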