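#' Consistency specification for metric filtering
#'
#' Bundles the parameters of the Consistent-k-Paths condition: the maximum
#' number of hops `k` in an alternative path, a floating-point comparison
#' tolerance, and an optional slack factor `rho` widening each edge's
#' admissible distance range.
#'
#' @param k integer >= 2, or `"all"` / `Inf` for the all-paths condition
#'   (`k = |V| - 1`, a true metric subgraph). `k = 2` enforces the triangle
#'   inequality only.
#' @param tolerance nonnegative relative tolerance for violation tests; an
#'   edge is violated only when the witness path undershoots its threshold
#'   by more than `tolerance * max(1, threshold)`. Equality is consistent.
#' @param rho optional slack factor in `[0, 1]`; when present each edge's
#'   range becomes `l = (1 - rho) d`, `u = (1 + rho) d`. At `rho = 1` the
#'   lower bound is 0 and nothing can be violated; at `rho = 0` the ranged
#'   condition reduces to the strict one.
#'
#' @return object of class `consistency_spec`.
#' @export
consistency_spec <- function(k = 2, tolerance = 1e-9, rho = NULL) {
  if (identical(k, "all")) k <- Inf
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || (is.finite(k) && (k < 2 || k != floor(k)))) {
    stop_param("`k` must be an integer >= 2, Inf, or \"all\"")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1 || is.na(tolerance) || tolerance < 0) {
    stop_param("`tolerance` must be a nonnegative number")
  }
  if (!is.null(rho)) {
    if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho < 0 || rho > 1) {
      stop_param("`rho` must lie in [0, 1]")
    }
  }
  structure(list(k = as.numeric(k), tolerance = tolerance, rho = rho),
            class = "consistency_spec")
}

#' @export
print.consistency_spec <- function(x, ...) {
  cat(sprintf("consistency spec: k = %s, tolerance = %g, rho = %s\n",
              if (is.finite(x$k)) format(x$k) else "|V|-1 (all paths)",
              x$tolerance,
              if (is.null(x$rho)) "none (strict)" else format(x$rho)))
  invisible(x)
}

check_spec <- function(spec) {
  if (!inherits(spec, "consistency_spec")) stop_param("expected a `consistency_spec`")
  invisible(spec)
}

# Effective hop budget for a given graph.
resolve_k <- function(graph, spec) {
  if (is.finite(spec$k)) spec$k else max(length(graph$nodes) - 1, 2)
}

#' Effective per-edge distance bounds
#'
#' Returns, for every edge, the `[l, u]` range used by the ranged
#' consistency condition. Explicit ranges stored on the graph take
#' precedence; otherwise `rho` (when present) gives `l = (1 - rho) d`,
#' `u = (1 + rho) d`; with neither, `l = u = d` and the ranged condition
#' reduces to the strict one.
#'
#' @param graph a `conformation_graph`.
#' @param spec a [consistency_spec()].
#' @return data frame with numeric columns `l` and `u`, one row per edge,
#'   in the graph's canonical edge order.
#' @export
effective_bounds <- function(graph, spec = consistency_spec()) {
  check_graph(graph); check_spec(spec)
  d <- graph$edges$d
  if (!is.null(spec$rho)) {
    l <- (1 - spec$rho) * d
    u <- (1 + spec$rho) * d
  } else {
    l <- d
    u <- d
  }
  if (!is.null(graph$edges$l)) {
    have <- !is.na(graph$edges$l)
    l[have] <- graph$edges$l[have]
    u[have] <- graph$edges$u[have]
  }
  data.frame(l = l, u = u)
}

#' Enumerate triangles of a conformation graph
#'
#' @param graph a `conformation_graph`.
#' @return character matrix with 3 columns; each row is one triangle, node
#'   identifiers sorted within the row, rows sorted lexicographically. Zero
#'   rows when the graph is triangle-free.
#' @export
enumerate_triangles <- function(graph) {
  check_graph(graph)
  ig <- as_igraph(graph)
  tri <- igraph::triangles(ig)
  if (length(tri) == 0) {
    return(matrix(character(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  m <- matrix(igraph::V(ig)$name[as.integer(tri)], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort, method = "radix"))
  m <- m[c_order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

# Triangles with their member edge indices: list(nodes = n x 3 character,
# edges = n x 3 integer). Internal workhorse for all k = 2 machinery.
triangle_edge_table <- function(graph) {
  tri <- enumerate_triangles(graph)
  if (nrow(tri) == 0) {
    return(list(nodes = tri, edges = matrix(integer(0), ncol = 3)))
  }
  keys <- edge_key(graph$edges$a, graph$edges$b)
  eidx <- cbind(
    match(edge_key(tri[, 1], tri[, 2]), keys),
    match(edge_key(tri[, 1], tri[, 3]), keys),
    match(edge_key(tri[, 2], tri[, 3]), keys)
  )
  list(nodes = tri, edges = eidx)
}

#' Shortest bounded-hop path length between two fragments
#'
#' Minimum total length over paths of at most `k` edges joining `source`
#' and `target`, computed by `k` rounds of Bellman-Ford-style relaxation
#' (exact for nonnegative lengths). When `source` and `target` are directly
#' joined by an edge, that edge itself is excluded from the candidate
#' paths, matching its role in the consistency test.
#'
#' @param graph a `conformation_graph`.
#' @param source,target fragment identifiers.
#' @param k maximum number of hops (>= 1), or `Inf` for unbounded.
#' @param length_key which per-edge value to sum: `"d"` (default), `"u"`,
#'   or `"l"` (the latter two from [effective_bounds()] with no `rho`,
#'   i.e. explicit stored ranges).
#' @return nonnegative number, or `Inf` when no such path exists.
#' @export
bounded_hop_shortest_length <- function(graph, source, target, k = 2,
                                        length_key = c("d", "u", "l")) {
  check_graph(graph)
  length_key <- match.arg(length_key)
  source <- as.character(source); target <- as.character(target)
  if (!(source %in% graph$nodes)) stop_param("unknown node: ", source)
  if (!(target %in% graph$nodes)) stop_param("unknown node: ", target)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop_param("`k` must be >= 1")
  }
  w <- switch(length_key,
    d = graph$edges$d,
    u = effective_bounds(graph, consistency_spec())$u,
    l = effective_bounds(graph, consistency_spec())$l
  )
  keys <- edge_key(graph$edges$a, graph$edges$b)
  sw <- if (c_gt(source, target)) c(target, source) else c(source, target)
  direct <- match(edge_key(sw[1], sw[2]), keys)
  keep <- seq_along(keys)
  if (!is.na(direct)) keep <- keep[keep != direct]
  res <- hop_limited_dp(graph, keep, w, source, k)
  res$dist[match(target, graph$nodes)]
}

# Hop-indexed DP over the edge subset `idx` with weights `w` (aligned to
# graph$edges rows). Row h+1 of the table holds the minimum length over
# walks of <= h edges from `source`; for nonnegative weights these equal
# the path minima. Exact parent tables allow witness reconstruction.
hop_limited_dp <- function(graph, idx, w, source, k) {
  nodes <- graph$nodes
  n <- length(nodes)
  ai <- match(graph$edges$a[idx], nodes)
  bi <- match(graph$edges$b[idx], nodes)
  wi <- w[idx]
  tails <- c(ai, bi)
  heads <- c(bi, ai)
  we <- c(wi, wi)
  eid <- c(idx, idx)

  kk <- if (is.finite(k)) as.integer(min(k, n - 1)) else n - 1L
  kk <- max(kk, 1L)
  D <- matrix(Inf, nrow = kk + 1L, ncol = n)
  D[1L, match(source, nodes)] <- 0
  pn <- matrix(NA_integer_, nrow = kk, ncol = n) # parent node at hop h
  pe <- matrix(NA_integer_, nrow = kk, ncol = n) # parent edge at hop h
  for (h in seq_len(kk)) {
    prev <- D[h, ]
    cand <- prev[tails] + we
    o <- order(heads, cand)
    first <- o[!duplicated(heads[o])]
    newd <- prev
    hh <- heads[first]
    take <- cand[first] < prev[hh]
    newd[hh[take]] <- cand[first][take]
    pn[h, hh[take]] <- tails[first][take]
    pe[h, hh[take]] <- eid[first][take]
    D[h + 1L, ] <- newd
    if (!any(take)) {
      if (h < kk) {
        D[(h + 1L):(kk + 1L), ] <- rep(newd, each = kk + 1L - h)
      }
      break
    }
  }
  list(dist = D[kk + 1L, ], D = D, pn = pn, pe = pe, kk = kk)
}

# Reconstruct a shortest <= k-hop witness path (vector of edge indices)
# ending at node index `target_i`, walking the exact hop-indexed tables.
walk_parents <- function(dp, target_i) {
  h <- dp$kk
  cur <- target_i
  edges <- integer(0)
  while (h >= 1L) {
    if (dp$D[h + 1L, cur] == dp$D[h, cur]) {
      h <- h - 1L
      next
    }
    edges <- c(dp$pe[h, cur], edges)
    cur <- dp$pn[h, cur]
    h <- h - 1L
  }
  edges
}

#' Find metric violations
#'
#' An edge `e` is *violated* when some path of at most `k` edges joining
#' its endpoints (not using `e` itself) is strictly shorter than `e`:
#' in the strict condition the path's summed lengths fall below `d(e)`;
#' in the ranged condition the summed upper bounds fall below `l(e)`.
#' Equality never violates.
#'
#' @param graph a `conformation_graph`.
#' @param spec a [consistency_spec()].
#' @return object of class `violation_set`: list with `entries` (data frame
#'   of violated edge index, endpoints, witness path as a list-column of
#'   edge indices, and witness length), `violated_edges` (sorted integer
#'   indices), and for `k = 2` also `triangles` (the violated triangles,
#'   node-triple matrix).
#' @export
find_violations <- function(graph, spec = consistency_spec()) {
  check_graph(graph); check_spec(spec)
  bounds <- effective_bounds(graph, spec)
  k <- resolve_k(graph, spec)
  tol <- spec$tolerance * pmax(1, abs(bounds$l))

  if (k == 2) {
    return(violations_k2(graph, spec, bounds, tol))
  }

  ne <- n_edges(graph)
  entries <- list()
  violated <- integer(0)
  if (k >= length(graph$nodes) - 1) {
    # all-paths case: one Dijkstra sweep; the direct edge (weight u >= l)
    # can never be the witness, so no per-edge exclusion is needed.
    ig <- as_igraph(graph, weight = bounds$u)
    dmat <- igraph::distances(ig, algorithm = "dijkstra")
    ai <- match(graph$edges$a, graph$nodes)
    bi <- match(graph$edges$b, graph$nodes)
    sp <- dmat[cbind(ai, bi)]
    violated <- which(sp < bounds$l - tol)
    for (e in violated) {
      p <- igraph::shortest_paths(ig, from = graph$edges$a[e],
                                  to = graph$edges$b[e], output = "epath")
      ep <- as.integer(p$epath[[1]])
      entries[[length(entries) + 1]] <- list(
        edge = e, witness = ep, witness_length = sp[e]
      )
    }
  } else {
    for (e in seq_len(ne)) {
      keep <- setdiff(seq_len(ne), e)
      dp <- hop_limited_dp(graph, keep, bounds$u, graph$edges$a[e], k)
      ti <- match(graph$edges$b[e], graph$nodes)
      if (dp$dist[ti] < bounds$l[e] - tol[e]) {
        violated <- c(violated, e)
        entries[[length(entries) + 1]] <- list(
          edge = e, witness = walk_parents(dp, ti),
          witness_length = dp$dist[ti]
        )
      }
    }
  }
  new_violation_set(graph, spec, entries, violated, triangles = NULL)
}

violations_k2 <- function(graph, spec, bounds, tol) {
  tt <- triangle_edge_table(graph)
  entries <- list()
  violated <- integer(0)
  tri_violated <- logical(nrow(tt$edges))
  if (nrow(tt$edges) > 0) {
    for (j in seq_len(nrow(tt$edges))) {
      es <- tt$edges[j, ]
      for (pos in 1:3) {
        e <- es[pos]; others <- es[-pos]
        wlen <- sum(bounds$u[others])
        if (wlen < bounds$l[e] - tol[e]) {
          entries[[length(entries) + 1]] <- list(
            edge = e, witness = as.integer(others), witness_length = wlen
          )
          violated <- c(violated, e)
          tri_violated[j] <- TRUE
        }
      }
    }
  }
  new_violation_set(graph, spec, entries, unique(violated),
                    triangles = tt$nodes[tri_violated, , drop = FALSE])
}

new_violation_set <- function(graph, spec, entries, violated, triangles) {
  if (length(entries) > 0) {
    ed <- vapply(entries, function(x) x$edge, integer(1))
    df <- data.frame(
      edge = ed,
      a = graph$edges$a[ed],
      b = graph$edges$b[ed],
      witness_length = vapply(entries, function(x) x$witness_length, numeric(1)),
      stringsAsFactors = FALSE
    )
    df$witness <- lapply(entries, function(x) x$witness)
  } else {
    df <- data.frame(edge = integer(0), a = character(0), b = character(0),
                     witness_length = numeric(0), stringsAsFactors = FALSE)
    df$witness <- list()
  }
  structure(list(
    entries = df,
    violated_edges = sort(unique(violated)),
    triangles = triangles,
    k = spec$k, rho = spec$rho, tolerance = spec$tolerance
  ), class = "violation_set")
}

#' @export
print.violation_set <- function(x, ...) {
  cat(sprintf("violation set: %d violated edge(s), %d witness entr%s\n",
              length(x$violated_edges), nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies"))
  if (!is.null(x$triangles)) {
    cat(sprintf("  violated triangles (k = 2): %d\n", nrow(x$triangles)))
  }
  invisible(x)
}

#' Number of violated edges
#' @param x a `violation_set`.
#' @return integer.
#' @export
n_violations <- function(x) {
  if (!inherits(x, "violation_set")) stop_param("expected a `violation_set`")
  length(x$violated_edges)
}

#' Test whether an edge subset is metrically consistent
#'
#' A subset `S` is consistent when no edge of `S` is violated by a path of
#' at most `k` edges lying entirely *inside* `S`. The empty subset is
#' consistent; consistency is hereditary (any subset of a consistent set
#' is consistent).
#'
#' @param graph a `conformation_graph`.
#' @param subset edge subset (see [subgraph_edges()]); `NULL` means all edges.
#' @param spec a [consistency_spec()].
#' @return logical scalar.
#' @export
is_consistent <- function(graph, subset = NULL, spec = consistency_spec()) {
  check_graph(graph); check_spec(spec)
  idx <- resolve_edges(graph, subset)
  if (length(idx) == 0) return(TRUE)
  # the subgraph keeps the full node set, so k = "all" resolves identically
  sub <- subgraph_edges(graph, idx)
  n_violations(find_violations(sub, spec)) == 0
}
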