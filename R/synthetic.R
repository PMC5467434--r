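#' Specification for a synthetic geometric circuit
#'
#' Describes a layered slab of neurons with distance-dependent connectivity:
#' somata are placed uniformly within per-layer depth slabs over a square
#' lateral extent, each neuron is excitatory or inhibitory, and every ordered
#' pair is connected independently with a probability given by a kernel of
#' soma distance and the (pre, post) synapse classes.
#'
#' @param n_per_layer integer vector, neurons per layer.
#' @param layer_depths numeric vector of layer boundary depths in
#'   micrometres, length `length(n_per_layer) + 1`, increasing.
#' @param lateral lateral extent in micrometres (square footprint).
#' @param kernel function `(distance_um, pre_class, post_class) -> probability`.
#' @param excitatory_fraction probability a neuron is excitatory.
#' @param seed integer RNG seed.
#' @return a `circuit_spec` list.
#' @export
circuit_spec <- function(n_per_layer = c(60, 120, 120, 100),
                         layer_depths = c(0, 300, 700, 1200, 1600),
                         lateral = 400,
                         kernel = exponential_kernel(),
                         excitatory_fraction = 0.86,
                         seed = 1L) {
  stopifnot(length(layer_depths) == length(n_per_layer) + 1,
            all(diff(layer_depths) > 0))
  structure(list(n_per_layer = as.integer(n_per_layer),
                 layer_depths = layer_depths, lateral = lateral,
                 kernel = kernel,
                 excitatory_fraction = excitatory_fraction,
                 seed = as.integer(seed)),
            class = "circuit_spec")
}

#' Distance-decaying connection kernel
#'
#' Connection probability `p0 * exp(-d / scale)`, with a multiplicative
#' factor for inhibitory presynaptic neurons. Typical cortical connectivity
#' falls off over one to a few hundred micrometres.
#'
#' @param p0 probability at zero distance.
#' @param scale decay length in micrometres.
#' @param inh_factor factor applied when the presynaptic neuron is inhibitory.
#' @return a kernel function for [circuit_spec()].
#' @export
exponential_kernel <- function(p0 = 0.25, scale = 180, inh_factor = 1.2) {
  function(d, pre_class, post_class) {
    pmin(1, p0 * exp(-d / scale) * ifelse(pre_class == "INH", inh_factor, 1))
  }
}

#' Generate a synthetic geometric circuit
#'
#' @param spec a [circuit_spec()].
#' @return a `directed_graph` with positions (um) and labels
#'   (`layer`, `mtype`, `synapse_class`).
#' @export
make_circuit <- function(spec) {
  n <- sum(spec$n_per_layer)
  withr::with_seed(spec$seed, {
    layer <- rep(seq_along(spec$n_per_layer), spec$n_per_layer)
    z <- stats::runif(n, spec$layer_depths[layer], spec$layer_depths[layer + 1])
    pos <- cbind(x = stats::runif(n, 0, spec$lateral),
                 y = stats::runif(n, 0, spec$lateral),
                 z = z)
    synapse_class <- ifelse(stats::runif(n) < spec$excitatory_fraction, "EXC", "INH")
    mtype <- paste0("L", layer, "_", synapse_class)
    # independent Bernoulli per ordered pair with kernel probability
    pre <- rep(0:(n - 1L), each = n)
    post <- rep(0:(n - 1L), times = n)
    off <- pre != post
    pre <- pre[off]; post <- post[off]
    d <- sqrt(rowSums((pos[pre + 1L, ] - pos[post + 1L, ])^2))
    p <- spec$kernel(d, synapse_class[pre + 1L], synapse_class[post + 1L])
    hit <- stats::runif(length(p)) < p
    directed_graph(cbind(pre[hit], post[hit]), n_vertices = n,
                   positions = pos,
                   labels = tibble::tibble(layer = paste0("L", layer),
                                           mtype = mtype,
                                           synapse_class = synapse_class))
  })
}

#' Reference complexes with known topology
#'
#' * `"simplex-n"` (e.g. `"simplex-3"`): the acyclic tournament on n+1
#'   vertices ordered by index — a single directed n-simplex; Betti profile
#'   (1, 0, ..., 0).
#' * `"cycle-3"`: the directed 3-cycle; its flag complex has three vertices
#'   and three edges but no 2-simplex; Betti profile (1, 1).
#' * `"octahedron-sphere"`: six vertices with antipodal pairs (0,5), (1,4),
#'   (2,3) non-adjacent and every other pair connected from lower to higher
#'   index. Its flag complex consists of eight directed triangles tiling a
#'   2-sphere (no 3-simplices), so the Betti profile is (1, 0, 1).
#' * `"disjoint-union(a, b)"`: disjoint union of two named complexes, e.g.
#'   `"disjoint-union(cycle-3, simplex-2)"`.
#'
#' @param name one of the recognised names above.
#' @return a `directed_graph`.
#' @export
known_complex <- function(name) {
  name <- gsub(" ", "", name)
  if (grepl("^simplex-[0-9]+$", name)) {
    n <- as.integer(sub("^simplex-", "", name))
    verts <- 0:n
    e <- t(utils::combn(verts, 2))   # lower index -> higher index
    return(directed_graph(e, n_vertices = n + 1L))
  }
  if (name == "cycle-3") {
    return(directed_graph(rbind(c(0, 1), c(1, 2), c(2, 0)), n_vertices = 3L))
  }
  if (name == "octahedron-sphere") {
    antipodal <- list(c(0, 5), c(1, 4), c(2, 3))
    pairs <- t(utils::combn(0:5, 2))
    keep <- !apply(pairs, 1, function(p) any(vapply(antipodal, function(a)
      all(sort(a) == p), logical(1))))
    return(directed_graph(pairs[keep, , drop = FALSE], n_vertices = 6L))
  }
  m <- regmatches(name, regexec("^disjoint-union\\((.+),(.+)\\)$", name))[[1]]
  if (length(m) == 3) {
    return(disjoint_union(known_complex(m[2]), known_complex(m[3])))
  }
  rlang::abort(sprintf("unknown complex name '%s'.", name))
}

#' Specification for a correlated spike-train generator
#'
#' Each neuron fires background homogeneous Poisson spikes at `baseline_rate`.
#' On top, each *ensemble* (a vertex tuple, typically a directed simplex of a
#' target graph) carries an independent Poisson stream of coactivation
#' events; each event injects one spike per member, delayed cumulatively
#' along the ensemble order (source earliest, sink latest) with exponential
#' inter-member gaps of mean `jitter` ms, so transmission runs along the
#' simplex orientation. Optionally each member participates in an event with
#' a probability ramping linearly from `participation[1]` at the source to
#' `participation[2]` at the sink, mimicking the accumulation of shared drive
#' toward the sink.
#'
#' @param n_neurons neuron count.
#' @param duration trial duration T in ms.
#' @param n_trials number of independent trials.
#' @param baseline_rate background rate in Hz.
#' @param ensembles list of 0-based vertex vectors (ordered source to sink).
#' @param coactivation_rate event rate in Hz per ensemble (recycled).
#' @param jitter mean inter-member transmission delay in ms.
#' @param participation length-2 probabilities at source and sink
#'   (default `c(1, 1)`: every member spikes on every event).
#' @param seed integer RNG seed.
#' @return a `spike_gen_spec` list.
#' @export
spike_gen_spec <- function(n_neurons, duration = 2000, n_trials = 1,
                           baseline_rate = 2, ensembles = list(),
                           coactivation_rate = 1, jitter = 2,
                           participation = c(1, 1), seed = 1L) {
  stopifnot(baseline_rate >= 0, all(coactivation_rate >= 0), jitter >= 0,
            all(participation >= 0 & participation <= 1))
  structure(list(n_neurons = as.integer(n_neurons), duration = duration,
                 n_trials = as.integer(n_trials),
                 baseline_rate = baseline_rate, ensembles = ensembles,
                 coactivation_rate = rep_len(coactivation_rate,
                                             max(1L, length(ensembles))),
                 jitter = jitter, participation = participation,
                 seed = as.integer(seed)),
            class = "spike_gen_spec")
}

#' Generate correlated spike trains
#'
#' @param spec a [spike_gen_spec()].
#' @param structure optional `directed_graph`; when supplied, its maximal
#'   simplices may be used as ensembles by the caller (kept for interface
#'   symmetry; the generator itself only uses `spec`).
#' @return a [spike_train_set()].
#' @export
make_spikes <- function(spec, structure = NULL) {
  T <- spec$duration
  withr::with_seed(spec$seed, {
    out <- vector("list", spec$n_trials)
    for (trial in seq_len(spec$n_trials)) {
      neuron <- integer(0); time <- numeric(0)
      # background
      lam <- spec$baseline_rate * T / 1000
      if (lam > 0) {
        counts <- stats::rpois(spec$n_neurons, lam)
        neuron <- rep(0:(spec$n_neurons - 1L), counts)
        time <- stats::runif(sum(counts), 0, T)
      }
      # ensemble coactivation events
      for (ei in seq_along(spec$ensembles)) {
        ens <- spec$ensembles[[ei]]
        rate <- spec$coactivation_rate[ei]
        if (rate <= 0 || length(ens) == 0) next
        n_ev <- stats::rpois(1, rate * T / 1000)
        if (n_ev == 0) next
        t_ev <- stats::runif(n_ev, 0, T)
        k <- length(ens)
        p_member <- if (k == 1) spec$participation[2] else
          seq(spec$participation[1], spec$participation[2], length.out = k)
        for (t0 in t_ev) {
          gaps <- if (spec$jitter > 0) stats::rexp(k, rate = 1 / spec$jitter)
                  else rep(0, k)
          delays <- cumsum(gaps) - gaps[1]   # source at t0
          fire <- stats::runif(k) < p_member
          tt <- t0 + delays[fire]
          ok <- tt < T
          neuron <- c(neuron, ens[fire][ok])
          time <- c(time, tt[ok])
        }
      }
      df <- tibble::tibble(neuron = neuron, trial = trial, time = time)
      # enforce strictly increasing trains: drop exact duplicates within train
      df <- dplyr::arrange(df, .data$neuron, .data$time)
      df <- df[!(duplicated(paste(df$neuron, df$time))), ]
      out[[trial]] <- df
    }
    spike_train_set(dplyr::bind_rows(out), n_neurons = spec$n_neurons,
                    duration = T, n_trials = spec$n_trials)
  })
}

#' In-silico patch-sampling census
#'
#' Emulates a multi-patch experiment: a sampling volume (default
#' 200 x 200 x 20 um) is placed uniformly at random inside the circuit's
#' bounding box, the vertices of a chosen class inside it are collected, a
#' random fraction is kept (modelling limited pipettes and patching failure)
#' and capped at `max_cells`, and the directed simplices of the induced
#' subgraph are counted.
#'
#' @param g a `directed_graph` with positions.
#' @param box numeric length-3 volume dimensions in micrometres.
#' @param max_cells cap on cells per experiment (default 12).
#' @param keep_fraction probability of keeping each candidate cell.
#' @param n_experiments number of placements.
#' @param seed integer RNG seed.
#' @param label_filter optional predicate on the labels tibble selecting
#'   patchable cells (e.g. thick-tufted pyramidal analogue); default all.
#' @return a tibble with columns `experiment`, `n_cells`, `dimension`,
#'   `count` (dimensions with zero count omitted beyond the top dimension).
#' @export
sample_patch <- function(g, box = c(200, 200, 20), max_cells = 12,
                         keep_fraction = 0.5, n_experiments = 100, seed = 1L,
                         label_filter = NULL) {
  if (is.null(g$positions)) rlang::abort("patch sampling requires positions.")
  pos <- g$positions
  eligible <- if (is.null(label_filter)) rep(TRUE, g$n_vertices)
              else label_filter(g$labels)
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  corner_max <- pmax(lo, hi - box)
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (ex in seq_len(n_experiments)) {
      corner <- stats::runif(3, lo, corner_max)
      inside <- eligible &
        pos[, 1] >= corner[1] & pos[, 1] <= corner[1] + box[1] &
        pos[, 2] >= corner[2] & pos[, 2] <= corner[2] + box[2] &
        pos[, 3] >= corner[3] & pos[, 3] <= corner[3] + box[3]
      cand <- which(inside) - 1L
      keep <- cand[stats::runif(length(cand)) < keep_fraction]
      if (length(keep) > max_cells) keep <- sample(keep, max_cells)
      if (length(keep) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          experiment = ex, n_cells = 0L, dimension = integer(0), count = integer(0))
        next
      }
      st <- flag_complex(induced_subgraph(g, keep))
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        simplex_counts(st), experiment = ex, n_cells = length(keep),
        .before = 1)
    }
  })
  dplyr::bind_rows(rows)
}
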