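# Stress-minimizing 3D embedding of filtered conformation graphs, plus the
# evaluation statistics used to compare filterings: sum-squared embedding
# error, rigid-body superposition RMSD, and MST-based ensemble variability.

#' Embed a conformation graph in Euclidean space
#'
#' Places every node so as to locally minimize the stress
#' \eqn{\sum_{e}(o(e) - d(e))^2}, where `o(e)` is the realized Euclidean
#' distance between the endpoints of edge `e` and `d(e)` its assigned
#' length. Optimization is quasi-Newton (L-BFGS-B) with an analytic
#' gradient, from a seeded isotropic Gaussian initialization scaled to the
#' mean edge length; results are deterministic given the seed.
#'
#' @param graph a `conformation_graph` (connected graphs recommended;
#'   disconnected components are positioned independently by the same
#'   objective).
#' @param dim embedding dimension (default 3).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum optimizer iterations (default 2000).
#' @param tol relative convergence tolerance on the objective
#'   (default 1e-12).
#' @return object of class `embedding`: list with `coords` (numeric
#'   matrix, one named row per node), `error` (final stress), `seed`, and
#'   `converged` (logical; `FALSE` with a warning if the iteration cap was
#'   hit, in which case the best iterate is returned).
#' @export
embed_graph <- function(graph, dim = 3, seed = 0, max_iter = 2000, tol = 1e-12) {
  check_graph(graph)
  n <- length(graph$nodes)
  if (n_edges(graph) == 0) stop_param("cannot embed a graph without edges")
  i <- match(graph$edges$a, graph$nodes)
  j <- match(graph$edges$b, graph$nodes)
  d <- graph$edges$d
  scale <- mean(d)
  if (scale <= 0) scale <- 1
  x0 <- with_seed(seed, stats::rnorm(n * dim, sd = scale))

  fn <- function(x) {
    X <- matrix(x, n, dim)
    diff <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    o <- sqrt(rowSums(diff^2))
    sum((o - d)^2)
  }
  gr <- function(x) {
    X <- matrix(x, n, dim)
    diff <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    o <- sqrt(rowSums(diff^2))
    g <- 2 * (o - d) / pmax(o, 1e-12)
    C <- diff * g
    G <- matrix(0, n, dim)
    for (c in seq_len(dim)) {
      G[, c] <- tabulate_sum(i, C[, c], n) - tabulate_sum(j, C[, c], n)
    }
    as.vector(G)
  }

  factr <- max(tol / .Machine$double.eps, 1)
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = factr))
  # line-search aborts in flat (rigid-motion) directions still count as
  # converged when the gradient has essentially vanished
  converged <- res$convergence == 0 ||
    sqrt(sum(gr(res$par)^2)) < 1e-6 * max(1, res$value)
  if (!converged) {
    warning("embedding optimizer did not converge within ", max_iter,
            " iterations (code ", res$convergence, "); returning best iterate",
            call. = FALSE)
  }
  coords <- matrix(res$par, n, dim,
                   dimnames = list(graph$nodes, paste0("x", seq_len(dim))))
  structure(list(coords = coords, error = res$value, seed = seed,
                 converged = converged),
            class = "embedding")
}

# sum of `values` grouped by integer index `idx` into a length-n vector
tabulate_sum <- function(idx, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d nodes in %d-D, stress %.6g (seed %d%s)\n",
              nrow(x$coords), ncol(x$coords), x$error, x$seed,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Realized edge distances of an embedding
#'
#' @param structure an `embedding` (or a coordinate matrix with named rows).
#' @param graph the `conformation_graph` whose edges to measure.
#' @return numeric vector `o(e)`, one entry per edge in canonical order.
#' @export
realized_distances <- function(structure, graph) {
  check_graph(graph)
  X <- if (inherits(structure, "embedding")) structure$coords else structure
  missing_nodes <- setdiff(graph$nodes, rownames(X))
  if (length(missing_nodes) > 0) {
    stop_param("structure lacks coordinates for: ",
               paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  diff <- X[graph$edges$a, , drop = FALSE] - X[graph$edges$b, , drop = FALSE]
  unname(sqrt(rowSums(diff^2)))
}

#' Sum-squared embedding error
#'
#' \eqn{\sum_{e}(o(e) - d(e))^2} over the graph's edges; zero exactly when
#' every assigned distance is realized. Invariant under rigid motions of
#' the coordinates.
#'
#' @inheritParams realized_distances
#' @return nonnegative number.
#' @export
embedding_error <- function(structure, graph) {
  o <- realized_distances(structure, graph)
  sum((o - graph$edges$d)^2)
}

#' Embed a graph several times from different initializations
#'
#' @inheritParams embed_graph
#' @param n_restarts number of embeddings (>= 1).
#' @param seed base seed; restart `i` uses `seed + i - 1`.
#' @return object of class `embedding_ensemble`: list with `structures`
#'   (list of `embedding`s), `errors`, `seeds`.
#' @export
embed_ensemble <- function(graph, n_restarts = 10, dim = 3, seed = 0,
                           max_iter = 2000, tol = 1e-12) {
  if (n_restarts < 1) stop_param("`n_restarts` must be >= 1")
  seeds <- seed + seq_len(n_restarts) - 1
  structures <- lapply(seeds, function(s) {
    embed_graph(graph, dim = dim, seed = s, max_iter = max_iter, tol = tol)
  })
  structure(list(
    structures = structures,
    errors = vapply(structures, function(s) s$error, numeric(1)),
    seeds = seeds
  ), class = "embedding_ensemble")
}

#' @export
print.embedding_ensemble <- function(x, ...) {
  cat(sprintf("embedding ensemble: %d structures, mean stress %.6g\n",
              length(x$structures), mean(x$errors)))
  invisible(x)
}

#' Inject triangle-inequality violations into a graph
#'
#' Repeatedly picks a random triangle `{u, v, w}` (roles assigned in
#' lexicographic node order) and shrinks the shorter
#' of the two edges at `u`: if `d(u,v) < d(u,w)` it sets
#' `d(u,v) = alpha * |d(v,w) - d(u,w)|`, otherwise
#' `d(u,w) = alpha * |d(v,w) - d(u,v)|`, for `0 < alpha < 1`, which makes
#' the triangle violate the triangle inequality. Sampling continues until
#' the violated-triangle fraction reaches `target_fraction` or an attempt
#' cap is hit. Rewards are untouched; a degenerate assignment of 0 is
#' clamped to 1e-6.
#'
#' @param graph a `conformation_graph` containing at least one triangle.
#' @param alpha shrink factor in (0, 1).
#' @param target_fraction desired fraction of violated triangles in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param max_attempts attempt cap (default 100 per triangle); if hit, the
#'   partially perturbed graph is returned with a warning.
#' @return the perturbed `conformation_graph`, with attributes
#'   `achieved_fraction` and `n_modified`.
#' @export
reintroduce_violations <- function(graph, alpha = 0.9, target_fraction = 0.3,
                                   seed = 0, max_attempts = NULL) {
  check_graph(graph)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_param("`alpha` must lie strictly between 0 and 1")
  }
  if (!is.numeric(target_fraction) || target_fraction < 0 || target_fraction > 1) {
    stop_param("`target_fraction` must lie in [0, 1]")
  }
  tt <- triangle_edge_table(graph)
  ntri <- nrow(tt$edges)
  if (ntri == 0) stop_param("graph has no triangles to perturb")
  max_attempts <- max_attempts %||% (100L * ntri)

  edges <- graph$edges
  keys <- edge_key(edges$a, edges$b)
  eix <- function(p, q) {
    sw <- sort(c(p, q), method = "radix")
    match(edge_key(sw[1], sw[2]), keys)
  }
  spec <- consistency_spec(k = 2)
  violated_fraction <- function(d) {
    tol <- spec$tolerance * pmax(1, abs(d))
    e1 <- tt$edges[, 1]; e2 <- tt$edges[, 2]; e3 <- tt$edges[, 3]
    viol <- (d[e2] + d[e3] < d[e1] - tol[e1]) |
            (d[e1] + d[e3] < d[e2] - tol[e2]) |
            (d[e1] + d[e2] < d[e3] - tol[e3])
    mean(viol)
  }

  d <- edges$d
  n_modified <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (violated_fraction(d) < target_fraction && attempts < max_attempts) {
      attempts <- attempts + 1L
      row <- sample.int(ntri, 1)
      trip <- tt$nodes[row, ] # roles (u, v, w) in lexicographic node order
      u <- trip[1]; v <- trip[2]; w <- trip[3]
      uv <- eix(u, v); uw <- eix(u, w); vw <- eix(v, w)
      if (d[uv] < d[uw]) {
        d[uv] <- max(alpha * abs(d[vw] - d[uw]), 1e-6)
      } else {
        d[uw] <- max(alpha * abs(d[vw] - d[uv]), 1e-6)
      }
      n_modified <- n_modified + 1L
    }
  })
  achieved <- violated_fraction(d)
  if (achieved < target_fraction) {
    warning("attempt cap reached: achieved violated fraction ",
            signif(achieved, 3), " < target ", target_fraction, call. = FALSE)
  }
  edges$d <- d
  if (!is.null(edges$l)) {
    # keep stored ranges valid around the perturbed lengths
    edges$l <- pmin(edges$l, edges$d)
    edges$u <- pmax(edges$u, edges$d)
  }
  out <- conformation_graph(edges, nodes = graph$nodes)
  attr(out, "achieved_fraction") <- achieved
  attr(out, "n_modified") <- n_modified
  out
}

#' Least-squares rigid-body superposition of two structures
#'
#' Aligns structure B onto structure A by the optimal translation and
#' proper rotation (Kabsch algorithm, no reflection) and reports the
#' root-mean-square coordinate deviation after alignment. Symmetric in its
#' arguments up to numerical tolerance.
#'
#' @param a,b `embedding` objects or coordinate matrices with matching
#'   named rows (same node set).
#' @param allow_reflection also consider improper rotations (default
#'   `FALSE`). Distance-only stress objectives cannot distinguish a
#'   structure from its mirror image, so comparisons between independent
#'   stress embeddings are usually made modulo reflection.
#' @return list with `rmsd` and `aligned` (B's coordinates after
#'   alignment, rows ordered as in A).
#' @export
superpose <- function(a, b, allow_reflection = FALSE) {
  A <- if (inherits(a, "embedding")) a$coords else a
  B <- if (inherits(b, "embedding")) b$coords else b
  if (is.null(rownames(A)) || is.null(rownames(B)) ||
      !setequal(rownames(A), rownames(B))) {
    stop_param("structures must share the same node set")
  }
  B <- B[rownames(A), , drop = FALSE]
  n <- nrow(A); dim <- ncol(A)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (n < dim || qr(Ac)$rank < dim - 1) {
    warning("fewer than ", dim, " non-collinear points; alignment is degenerate",
            call. = FALSE)
  }
  H <- crossprod(Bc, Ac) # dim x dim; maximize tr(R^T H) over rotations R
  s <- svd(H)
  sgn <- if (allow_reflection) 1 else sign(det(s$u %*% t(s$v)))
  if (sgn == 0) sgn <- 1
  R <- s$u %*% diag(c(rep(1, dim - 1), sgn), nrow = dim) %*% t(s$v)
  aligned <- Bc %*% R
  aligned <- sweep(aligned, 2, ca, FUN = "+")
  rownames(aligned) <- rownames(A)
  rmsd <- sqrt(mean(rowSums((aligned - A)^2)))
  list(rmsd = rmsd, aligned = aligned)
}

#' MST-based variability of an embedding ensemble
#'
#' Builds the complete graph whose vertices are the embedded structures
#' and whose edge weights are pairwise superposed RMSDs, and returns the
#' total branch length of its minimum spanning tree: a parsimonious
#' summary of how spread out the ensemble is. Zero for an ensemble of
#' identical (up to rigid motion) structures.
#'
#' Because the stress objective depends on coordinates only through
#' pairwise distances, independent embeddings of one graph are determined
#' at best up to an orthogonal transformation (including reflection);
#' pairwise RMSDs are therefore computed modulo reflection by default.
#'
#' @param ensemble an `embedding_ensemble`, or a list of `embedding`s /
#'   coordinate matrices (at least 2).
#' @param allow_reflection quotient out improper rotations in the pairwise
#'   superpositions (default `TRUE`; see [superpose()]).
#' @return nonnegative number.
#' @export
ensemble_variability <- function(ensemble, allow_reflection = TRUE) {
  structures <- if (inherits(ensemble, "embedding_ensemble")) {
    ensemble$structures
  } else {
    ensemble
  }
  m <- length(structures)
  if (m < 2) stop_param("need at least 2 structures")
  rmsd <- matrix(0, m, m)
  for (p in seq_len(m - 1)) {
    for (q in (p + 1):m) {
      v <- superpose(structures[[p]], structures[[q]],
                     allow_reflection = allow_reflection)$rmsd
      rmsd[p, q] <- v; rmsd[q, p] <- v
    }
  }
  ig <- igraph::graph_from_adjacency_matrix(rmsd, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  # zero RMSDs drop out of the weighted adjacency; restore them explicitly
  missing <- which(rmsd == 0 & upper.tri(rmsd), arr.ind = TRUE)
  if (nrow(missing) > 0) {
    ig <- igraph::add_edges(ig, t(missing), weight = 0)
  }
  mst <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  sum(igraph::E(mst)$weight)
}

#' Compare two filterings by embedding error and ensemble variability
#'
#' Applies both filterings, embeds each retained subgraph `n_restarts`
#' times with matched seeds, and reports the mean sum-squared embedding
#' error and the MST ensemble variability per filtering.
#'
#' @param graph a `conformation_graph`.
#' @param filter_a,filter_b either a function `graph -> filter_result`, an
#'   algorithm name among `"setcov"`, `"setcov3"`, `"maxcut"`,
#'   `"spunion"`, `"mstadd"`, or (for `filter_b` only) `"crank-matched"`,
#'   which keeps as many highest-confidence edges as `filter_a` retained.
#' @param spec a [consistency_spec()] passed to named algorithms.
#' @param n_restarts embeddings per filtering (default 5).
#' @param seed base embedding seed, shared by both filterings.
#' @param dim embedding dimension.
#' @return list of class `filter_comparison` with one entry per filtering:
#'   algorithm label, retained edge count, `mean_error`, `variability`.
#' @export
compare_filterings <- function(graph, filter_a, filter_b = "crank-matched",
                               spec = consistency_spec(k = 2),
                               n_restarts = 5, seed = 0, dim = 3) {
  check_graph(graph)
  res_a <- apply_filter(graph, filter_a, spec)
  res_b <- if (identical(filter_b, "crank-matched")) {
    crank(graph, length(res_a$retained))
  } else {
    apply_filter(graph, filter_b, spec)
  }
  evaluate_one <- function(res) {
    sub <- subgraph_edges(graph, res$retained, drop_isolated = TRUE)
    ens <- embed_ensemble(sub, n_restarts = n_restarts, dim = dim, seed = seed)
    list(
      algorithm = res$algorithm,
      n_edges = length(res$retained),
      mean_error = mean(ens$errors),
      variability = if (n_restarts >= 2) ensemble_variability(ens) else NA_real_
    )
  }
  structure(list(a = evaluate_one(res_a), b = evaluate_one(res_b),
                 n_restarts = n_restarts, seed = seed),
            class = "filter_comparison")
}

#' @export
print.filter_comparison <- function(x, ...) {
  for (side in c("a", "b")) {
    s <- x[[side]]
    cat(sprintf("%-20s %5d edges  mean error %.6g  variability %.6g\n",
                s$algorithm, s$n_edges, s$mean_error, s$variability))
  }
  invisible(x)
}

# Resolve a filtering given as a function or algorithm name.
apply_filter <- function(graph, filter, spec) {
  if (is.function(filter)) return(filter(graph))
  if (is.character(filter) && length(filter) == 1) {
    return(switch(filter,
      setcov = setcover_greedy(graph, spec),
      setcov3 = setcover_fapprox(graph, spec),
      maxcut = maxcut_hierarchical(graph, spec),
      spunion = sp_union(graph, spec),
      mstadd = mst_add(graph, spec),
      stop_param("unknown filtering: ", filter)
    ))
  }
  stop_param("filterings must be functions or algorithm names")
}
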