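#' Build a spiking network with seeded topology and weights
#'
#' Constructs the neuron population (excitatory regular-spiking neurons first,
#' inhibitory fast-spiking neurons after) and the synaptic state for one of
#' three topologies:
#'
#' * `"fully_connected"`: every ordered pair of distinct neurons is connected
#'   (self-connections are forbidden).
#' * `"sparse_fixed_outdegree"`: each neuron draws `connections_per_neuron`
#'   output targets uniformly *with replacement*; duplicate draws collapse, so
#'   the realised out-degree can be smaller.
#' * `"chain3"`: three excitatory neurons, all six ordered pairs connected
#'   (input, hidden and output neuron of the minimal-circuit experiments).
#'
#' Initial weights are drawn per connection. With `weight_init = "uniform"`,
#' magnitudes are Uniform(0, `weight_init_max`); with `"mean_offset"` (the
#' connectivity-sweep initialisation), the magnitude is
#' `weight_mean + Uniform(-weight_variance, weight_variance)`, clipped at 0 to
#' preserve the sign. Excitatory output weights are positive, inhibitory output
#' weights negative.
#'
#' @param n_neurons Total number of neurons.
#' @param frac_inhibitory Fraction of inhibitory neurons (default 0.2).
#' @param topology One of `"fully_connected"`, `"sparse_fixed_outdegree"`,
#'   `"chain3"`.
#' @param connections_per_neuron Output draws per neuron (sparse topology).
#' @param weight_init `"uniform"` or `"mean_offset"`.
#' @param weight_init_max Upper bound of the uniform magnitude (default 5).
#' @param weight_mean,weight_variance Mean magnitude and half-range of the
#'   `"mean_offset"` initialisation.
#' @param w_max Weight cap used by plasticity (stored on the network).
#' @param seed Seed for topology and weights (`NULL` leaves the RNG alone).
#' @return An object of class `lsa_network`: a list with a `neurons` tibble
#'   (`id`, `type`, Izhikevich coefficients, state `v`, `u`), the `weights` and
#'   `exists` matrices (`[pre, post]`), counts `n` and `n_exc`, `w_max`, and an
#'   empty zone layout.
#' @export
#' @examples
#' net <- lsa_network(n_neurons = 100, seed = 1)
#' net$n_exc
lsa_network <- function(n_neurons = 100, frac_inhibitory = 0.2,
                        topology = c("fully_connected",
                                     "sparse_fixed_outdegree", "chain3"),
                        connections_per_neuron = 20,
                        weight_init = c("uniform", "mean_offset"),
                        weight_init_max = 5, weight_mean = 5,
                        weight_variance = 1, w_max = 10, seed = NULL) {
  topology <- match.arg(topology)
  weight_init <- match.arg(weight_init)
  if (!is.null(seed)) set.seed(seed)
  if (topology == "chain3") {
    n_neurons <- 3L
    frac_inhibitory <- 0
  }
  n <- as.integer(n_neurons)
  n_inh <- as.integer(round(n * frac_inhibitory))
  n_exc <- n - n_inh

  rs <- izhikevich_params("regular_spiking")
  fs <- izhikevich_params("fast_spiking")
  type <- rep(c("excitatory", "inhibitory"), c(n_exc, n_inh))
  neurons <- tibble(
    id = seq_len(n),
    type = type,
    a = ifelse(type == "excitatory", rs$a, fs$a),
    b = ifelse(type == "excitatory", rs$b, fs$b),
    c = ifelse(type == "excitatory", rs$c, fs$c),
    d = ifelse(type == "excitatory", rs$d, fs$d)
  )
  neurons$v <- rep(-65, n)
  neurons$u <- neurons$b * neurons$v

  draw_mag <- function(k) {
    switch(weight_init,
      uniform = runif(k, 0, weight_init_max),
      mean_offset = pmax(
        weight_mean + runif(k, -weight_variance, weight_variance), 0)
    )
  }
  sign_of <- ifelse(type == "excitatory", 1, -1)
  exists <- matrix(FALSE, n, n)
  weights <- matrix(0, n, n)
  if (topology %in% c("fully_connected", "chain3")) {
    exists[] <- TRUE
    diag(exists) <- FALSE
    for (j in seq_len(n)) {
      mag <- draw_mag(n - 1L)
      weights[j, -j] <- sign_of[j] * mag
    }
  } else {
    m <- as.integer(connections_per_neuron)
    for (j in seq_len(n)) {
      targets <- sample(seq_len(n)[-j], m, replace = TRUE)
      mag <- draw_mag(m)
      # later duplicate draws overwrite earlier ones
      weights[j, targets] <- sign_of[j] * mag
      exists[j, targets] <- TRUE
    }
  }

  structure(
    list(neurons = neurons, weights = weights, exists = exists,
         n = n, n_exc = n_exc, w_max = w_max, topology = topology,
         zones = NULL, forbid_direct_io = FALSE, seed = seed),
    class = "lsa_network"
  )
}

#' @export
print.lsa_network <- function(x, ...) {
  cat(sprintf("<lsa_network> %d neurons (%d excitatory, %d inhibitory), %s\n",
              x$n, x$n_exc, x$n - x$n_exc, x$topology))
  cat(sprintf("  connections: %d, w_max: %g\n", sum(x$exists), x$w_max))
  if (!is.null(x$zones)) {
    cat("  zones:", paste(sprintf("%s(%d)", names(x$zones),
                                  lengths(x$zones)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign disjoint input/output zones among the excitatory neurons
#'
#' Zones are pairwise-disjoint sets of excitatory neurons, chosen uniformly at
#' random (or fixed via `fixed_indices` for reproducible fixtures). With
#' `forbid_direct_io`, every connection from a neuron in an `input*` zone to a
#' neuron in an `output*` zone is set to weight 0 and masked non-existent, so
#' it can never be re-potentiated: learning must then recruit indirect
#' pathways.
#'
#' @param network An [lsa_network()].
#' @param sizes Named integer vector of zone sizes, e.g.
#'   `c(input = 10, output_a = 10, output_b = 10)`.
#' @param seed Seed for the random zone draw.
#' @param forbid_direct_io Zero and freeze all input-zone to output-zone
#'   weights.
#' @param fixed_indices Optional named list of explicit neuron indices,
#'   overriding the random draw.
#' @return The network with a `zones` element (named list of integer vectors).
#' @export
#' @examples
#' net <- lsa_network(seed = 1)
#' net <- assign_zones(net, c(input = 10, output_a = 10, output_b = 10), seed = 2)
assign_zones <- function(network, sizes = c(input = 10, output_a = 10,
                                            output_b = 10),
                         seed = NULL, forbid_direct_io = FALSE,
                         fixed_indices = NULL) {
  stopifnot(inherits(network, "lsa_network"))
  if (!is.null(fixed_indices)) {
    zones <- lapply(fixed_indices, as.integer)
  } else {
    if (sum(sizes) > network$n_exc) {
      abort(sprintf(
        "zone sizes (total %d) exceed the excitatory population (%d)",
        sum(sizes), network$n_exc))
    }
    if (!is.null(seed)) set.seed(seed)
    pool <- sample(seq_len(network$n_exc))
    zones <- list()
    at <- 1L
    for (k in seq_along(sizes)) {
      zones[[names(sizes)[k]]] <- sort(pool[at:(at + sizes[k] - 1L)])
      at <- at + as.integer(sizes[k])
    }
  }
  ids <- unlist(zones)
  if (anyDuplicated(ids) || any(ids > network$n_exc)) {
    abort("zones must be disjoint subsets of the excitatory neurons")
  }
  network$zones <- zones
  if (forbid_direct_io) {
    ins <- unlist(zones[startsWith(names(zones), "input")])
    outs <- unlist(zones[startsWith(names(zones), "output")])
    if (length(ins) && length(outs)) {
      network$weights[ins, outs] <- 0
      network$exists[ins, outs] <- FALSE
    }
    network$forbid_direct_io <- TRUE
  }
  network
}
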