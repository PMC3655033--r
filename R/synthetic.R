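# Synthetic benchmark generators: planted point-cloud graphs (stand-ins
# for chromosome conformation graphs), frequency-annotated variants, and
# the independent-set gadget used to probe worst-case behaviour.

#' Planted-geometry conformation graph
#'
#' Samples `n_nodes` points uniformly in the unit cube, connects a random
#' subset of pairs at the requested density, and assigns each edge the
#' true Euclidean distance perturbed by noise. Rewards imitate
#' `1 - q`-style confidences: edges whose measured length deviates more
#' from the truth get lower confidence, via
#' `r = 1 / (1 + reward_scale * |d - true| / true)`.
#' With zero noise the complete graph is exactly realizable in `dim`
#' dimensions and metrically consistent for every `k`.
#'
#' @param n_nodes number of fragments (>= 2).
#' @param dim dimension of the planted point cloud (default 3).
#' @param edge_density fraction of all node pairs connected, in (0, 1].
#' @param noise_sd noise magnitude (standard deviation); 0 means exact
#'   distances.
#' @param noise_model `"lognormal"` (multiplicative, keeps lengths
#'   positive; default) or `"gaussian"` (additive, clamped at 1e-6).
#' @param reward_scale slope of the confidence decay with relative
#'   distance error (default 5).
#' @param seed integer seed; the generated graph is identical across runs
#'   for a fixed seed.
#' @return list with `graph` (a `conformation_graph`), `coords` (true
#'   coordinates, named rows) and `true_distances` (per-edge, canonical
#'   order).
#' @export
planted_graph <- function(n_nodes, dim = 3, edge_density = 1, noise_sd = 0,
                          noise_model = c("lognormal", "gaussian"),
                          reward_scale = 5, seed = 0) {
  noise_model <- match.arg(noise_model)
  if (n_nodes < 2) stop_param("`n_nodes` must be >= 2")
  if (edge_density <= 0 || edge_density > 1) {
    stop_param("`edge_density` must lie in (0, 1]")
  }
  if (noise_sd < 0) stop_param("`noise_sd` must be nonnegative")
  width <- max(2, nchar(as.character(n_nodes)))
  ids <- sprintf(paste0("f%0", width, "d"), seq_len(n_nodes))
  with_seed(seed, {
    P <- matrix(stats::runif(n_nodes * dim), n_nodes, dim,
                dimnames = list(ids, paste0("x", seq_len(dim))))
    pairs <- utils::combn(ids, 2)
    npairs <- ncol(pairs)
    m <- max(1L, round(edge_density * npairs))
    keep <- if (m >= npairs) seq_len(npairs) else sort(sample.int(npairs, m))
    a <- pairs[1, keep]; b <- pairs[2, keep]
    true_d <- unname(sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2)))
    d <- switch(noise_model,
      lognormal = true_d * exp(stats::rnorm(length(true_d), 0, noise_sd)),
      gaussian = pmax(true_d + stats::rnorm(length(true_d), 0, noise_sd), 1e-6)
    )
    rel_err <- abs(d - true_d) / pmax(true_d, 1e-12)
    r <- 1 / (1 + reward_scale * rel_err)
    edges <- data.frame(a = a, b = b, d = d, r = r, stringsAsFactors = FALSE)
    g <- conformation_graph(edges, nodes = ids)
    # conformation_graph re-sorts rows; align the truth with it
    key_in <- edge_key(a, b)
    key_out <- edge_key(g$edges$a, g$edges$b)
    list(graph = g, coords = P, true_distances = true_d[match(key_out, key_in)])
  })
}

#' Independent-set gadget graph
#'
#' Augments a simple graph `G` with an apex node joined to every vertex.
#' Original edges get length 3 (reward 3 or 1 depending on the variant);
#' apex edges get length and reward 1. In the resulting graph every
#' violated structure is a triangle through the apex, and the optimal
#' triangle-consistent reward equals `3|E(G)| + s` (variant `"three"`)
#' where `s` is the size of a maximum independent set of `G` — the
#' construction behind the problem's NP-hardness.
#'
#' @param nodes character vector of `G`'s vertices (isolated vertices
#'   allowed).
#' @param edges two-column data frame (or matrix) of `G`'s edges; may have
#'   zero rows.
#' @param reward_variant `"three"` (original edges reward 3, default) or
#'   `"unit"` (all rewards 1).
#' @param apex identifier for the apex node (default `"_apex"`); must not
#'   collide with `nodes`.
#' @return a `conformation_graph` with `|V| + 1` nodes and
#'   `|E| + |V|` edges.
#' @export
independent_set_gadget <- function(nodes, edges = NULL,
                                   reward_variant = c("three", "unit"),
                                   apex = "_apex") {
  reward_variant <- match.arg(reward_variant)
  nodes <- as.character(nodes)
  if (apex %in% nodes) stop_param("`apex` collides with a node of G")
  if (is.null(edges) || NROW(edges) == 0) {
    base <- data.frame(a = character(0), b = character(0),
                       d = numeric(0), r = numeric(0))
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    base <- data.frame(a = as.character(edges[[1]]),
                       b = as.character(edges[[2]]),
                       d = 3,
                       r = if (reward_variant == "three") 3 else 1,
                       stringsAsFactors = FALSE)
  }
  apex_edges <- data.frame(a = apex, b = nodes, d = 1, r = 1,
                           stringsAsFactors = FALSE)
  conformation_graph(rbind(base, apex_edges), nodes = c(nodes, apex))
}

#' Planted graph with synthetic interaction frequencies
#'
#' Wraps [planted_graph()] and adds a frequency column following the
#' inverse power-law relationship between spatial distance and contact
#' frequency, `f = c * d^(-gamma)`, optionally with multiplicative
#' log-normal noise. Without noise the frequencies round-trip exactly
#' through [frequency_to_distance()].
#'
#' @inheritParams planted_graph
#' @param c_coef power-law coefficient (> 0).
#' @param gamma power-law exponent (> 0).
#' @param freq_noise_sd log-normal noise on frequencies (default 0).
#' @return as [planted_graph()], with `f` populated on the graph's edges.
#' @export
frequency_graph <- function(n_nodes, dim = 3, edge_density = 1, noise_sd = 0,
                            reward_scale = 5, c_coef = 1, gamma = 1,
                            freq_noise_sd = 0, seed = 0) {
  if (gamma <= 0) stop_param("`gamma` must be positive")
  if (c_coef <= 0) stop_param("`c_coef` must be positive")
  pl <- planted_graph(n_nodes, dim = dim, edge_density = edge_density,
                      noise_sd = noise_sd, reward_scale = reward_scale,
                      seed = seed)
  edges <- pl$graph$edges
  f <- c_coef * edges$d^(-gamma)
  if (freq_noise_sd > 0) {
    f <- f * with_seed(seed + 1, exp(stats::rnorm(length(f), 0, freq_noise_sd)))
  }
  edges$f <- f
  pl$graph <- conformation_graph(edges, nodes = pl$graph$nodes)
  pl
}
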