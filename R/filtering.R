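# Metric filtering algorithms.
#
# ConsT (k = 2, triangle consistency): set-cover greedy, set-cover LP
# rounding (f-approximation with f = 3), hierarchical max-cut, exact
# small-instance solver, LP upper bound. ConsP (all paths): SP-Union and
# MST-Add. C-Rank is the confidence-only baseline. All algorithms support
# the ranged condition via `rho` or explicit per-edge ranges in the spec.

new_filter_result <- function(graph, retained, algorithm, params,
                              upper_bound = NULL) {
  retained <- sort(unique(as.integer(retained)))
  removed <- setdiff(seq_len(n_edges(graph)), retained)
  structure(list(
    graph = graph,
    retained = retained,
    removed = removed,
    total_reward = total_reward(graph, retained),
    algorithm = algorithm,
    params = params,
    upper_bound = upper_bound
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("%s filtering: kept %d / %d edges, total reward %.6g\n",
              x$algorithm, length(x$retained), n_edges(x$graph),
              x$total_reward))
  if (!is.null(x$upper_bound)) {
    cat(sprintf("  LP upper bound: %.6g\n", x$upper_bound))
  }
  invisible(x)
}

#' Retained / removed edges of a filtering
#' @param result a `filter_result`.
#' @return data frame of edge records.
#' @export
retained_edges <- function(result) result$graph$edges[result$retained, , drop = FALSE]

#' @rdname retained_edges
#' @export
removed_edges <- function(result) result$graph$edges[result$removed, , drop = FALSE]

check_k2 <- function(spec) {
  if (!identical(spec$k, 2)) {
    stop_param("this algorithm solves the triangle-consistency problem; use k = 2")
  }
}

# Edge-index triples of the *violated* triangles under the spec's bounds,
# plus the incidence structure reused by the set-cover and LP routines.
violated_triangle_edges <- function(graph, spec) {
  bounds <- effective_bounds(graph, spec)
  tol <- spec$tolerance * pmax(1, abs(bounds$l))
  tt <- triangle_edge_table(graph)
  if (nrow(tt$edges) == 0) {
    return(list(nodes = tt$nodes, edges = tt$edges[0, , drop = FALSE]))
  }
  e1 <- tt$edges[, 1]; e2 <- tt$edges[, 2]; e3 <- tt$edges[, 3]
  viol <- (bounds$u[e2] + bounds$u[e3] < bounds$l[e1] - tol[e1]) |
          (bounds$u[e1] + bounds$u[e3] < bounds$l[e2] - tol[e2]) |
          (bounds$u[e1] + bounds$u[e2] < bounds$l[e3] - tol[e3])
  list(nodes = tt$nodes[viol, , drop = FALSE],
       edges = tt$edges[viol, , drop = FALSE])
}

#' Greedy set-cover metric filtering (ConsT)
#'
#' Casts triangle repair as minimum-weight set cover: each edge "covers"
#' the violated triangles it belongs to at cost equal to its reward, and
#' a cover corresponds to a removal set that resolves every violated
#' triangle. The greedy rule repeatedly removes the edge with the smallest
#' cost per newly covered triangle (ties: lower cost, then lexicographic
#' edge order).
#'
#' @param graph a `conformation_graph`.
#' @param spec a [consistency_spec()] with `k = 2`.
#' @param rule greedy score: `"cost_per_coverage"` (default) or plain
#'   `"cost"` (cheapest covering edge first).
#' @return a `filter_result`; the retained set has no violated triangles.
#' @export
setcover_greedy <- function(graph, spec = consistency_spec(k = 2),
                            rule = c("cost_per_coverage", "cost")) {
  check_graph(graph); check_spec(spec); check_k2(spec)
  rule <- match.arg(rule)
  vt <- violated_triangle_edges(graph, spec)
  ne <- n_edges(graph)
  removed <- integer(0)
  if (nrow(vt$edges) > 0) {
    uncovered <- rep(TRUE, nrow(vt$edges))
    r <- graph$edges$r
    repeat {
      rows <- which(uncovered)
      if (length(rows) == 0) break
      cand <- sort(unique(as.integer(vt$edges[rows, ])))
      cov <- vapply(cand, function(e) {
        sum(vt$edges[rows, 1] == e | vt$edges[rows, 2] == e | vt$edges[rows, 3] == e)
      }, numeric(1))
      score <- if (rule == "cost_per_coverage") r[cand] / cov else r[cand]
      pick <- cand[order(score, r[cand], cand)][1]
      removed <- c(removed, pick)
      hit <- vt$edges[rows, 1] == pick | vt$edges[rows, 2] == pick |
             vt$edges[rows, 3] == pick
      uncovered[rows[hit]] <- FALSE
    }
  }
  new_filter_result(graph, setdiff(seq_len(ne), removed), "setcover-greedy",
                    list(k = 2, rho = spec$rho, rule = rule))
}

#' LP-rounding set-cover filtering (3-approximation, ConsT)
#'
#' Solves the fractional covering relaxation of the removal problem and
#' removes every edge with fractional value at least 1/3. Since each
#' violated triangle contains at most three removable edges, some member
#' always reaches 1/3, so the rounding covers every violated triangle and
#' its cost is at most 3 times the minimum removal cost.
#'
#' @inheritParams setcover_greedy
#' @return a `filter_result`; `params$lp_cost` records the fractional
#'   covering optimum (a lower bound on the removal cost).
#' @export
setcover_fapprox <- function(graph, spec = consistency_spec(k = 2)) {
  check_graph(graph); check_spec(spec); check_k2(spec)
  vt <- violated_triangle_edges(graph, spec)
  ne <- n_edges(graph)
  if (nrow(vt$edges) == 0) {
    return(new_filter_result(graph, seq_len(ne), "setcover-lp3",
                             list(k = 2, rho = spec$rho, lp_cost = 0)))
  }
  cand <- sort(unique(as.integer(vt$edges)))
  m <- nrow(vt$edges)
  incidence <- matrix(0, nrow = m, ncol = length(cand))
  for (col in 1:3) {
    incidence[cbind(seq_len(m), match(vt$edges[, col], cand))] <- 1
  }
  sol <- lp_min_cover(graph$edges$r[cand], incidence)
  removed <- cand[sol$y >= 1 / 3 - LP_TOL]
  new_filter_result(graph, setdiff(seq_len(ne), removed), "setcover-lp3",
                    list(k = 2, rho = spec$rho, lp_cost = sol$objective))
}

#' Local-search maximum cut
#'
#' Single-vertex-move local search on the reward-weighted cut, from a
#' seeded uniform random bipartition. At a local optimum every vertex has
#' at least half of its incident reward crossing the cut, so the cut
#' carries at least half of the graph's total reward.
#'
#' @param graph a nonempty `conformation_graph`.
#' @param seed integer seed for the initial partition (default 0).
#' @return list of class `max_cut`: `v1`, `v2` (node partition),
#'   `cut_edges` (integer edge indices), `cut_reward`, `seed`.
#' @export
maxcut_local <- function(graph, seed = 0) {
  check_graph(graph)
  n <- length(graph$nodes)
  if (n == 0) stop_param("graph has no nodes")
  side <- with_seed(seed, sample(c(TRUE, FALSE), n, replace = TRUE))
  ai <- match(graph$edges$a, graph$nodes)
  bi <- match(graph$edges$b, graph$nodes)
  r <- graph$edges$r
  if (n_edges(graph) > 0) {
    M <- matrix(0, n, n)
    M[cbind(ai, bi)] <- r
    M[cbind(bi, ai)] <- r
    s <- ifelse(side, 1, -1)
    Ms <- as.vector(M %*% s)
    tol_gain <- 1e-12 * max(sum(r), 1)
    repeat {
      gain <- s * Ms # same-side reward minus cut reward, per vertex
      v <- which.max(gain)
      if (gain[v] <= tol_gain) break
      Ms <- Ms - 2 * s[v] * M[, v]
      s[v] <- -s[v]
    }
    side <- s > 0
  }
  cut <- which(side[ai] != side[bi])
  structure(list(
    v1 = graph$nodes[side],
    v2 = graph$nodes[!side],
    cut_edges = cut,
    cut_reward = sum(r[cut]),
    seed = seed
  ), class = "max_cut")
}

#' Hierarchical maximum-cut metric filtering (ConsT)
#'
#' Finds a reward-weighted local max cut, keeps every cut edge (a
#' bipartite set contains no triangle), deletes any same-side edge that
#' closes a violated triangle with two cut edges, and recurses into the
#' two sides. Deletions are permanent across recursion levels; recursion
#' stops at components of at most two nodes or with no violated triangles
#' left. The first cut alone guarantees at least half the total reward.
#'
#' @inheritParams setcover_greedy
#' @param seed integer seed; each recursive cut uses a derived seed so the
#'   whole run is reproducible.
#' @return a `filter_result`.
#' @export
maxcut_hierarchical <- function(graph, spec = consistency_spec(k = 2), seed = 0) {
  check_graph(graph); check_spec(spec); check_k2(spec)
  ne <- n_edges(graph)
  tt <- triangle_edge_table(graph)
  bounds <- effective_bounds(graph, spec)
  tol <- spec$tolerance * pmax(1, abs(bounds$l))
  tri_violated <- logical(nrow(tt$edges))
  if (nrow(tt$edges) > 0) {
    e1 <- tt$edges[, 1]; e2 <- tt$edges[, 2]; e3 <- tt$edges[, 3]
    tri_violated <-
      (bounds$u[e2] + bounds$u[e3] < bounds$l[e1] - tol[e1]) |
      (bounds$u[e1] + bounds$u[e3] < bounds$l[e2] - tol[e2]) |
      (bounds$u[e1] + bounds$u[e2] < bounds$l[e3] - tol[e3])
  }
  tri_key <- if (nrow(tt$nodes) > 0) {
    paste(tt$nodes[, 1], tt$nodes[, 2], tt$nodes[, 3], sep = "\x1f")
  } else character(0)
  tri_row <- stats::setNames(seq_along(tri_key), tri_key)
  keys <- edge_key(graph$edges$a, graph$edges$b)
  edge_row <- stats::setNames(seq_len(ne), keys)

  st <- new.env(parent = emptyenv())
  st$alive <- rep(TRUE, ne)
  st$kept <- rep(FALSE, ne)
  st$counter <- 0L

  edges_within <- function(nodeset) {
    which(st$alive & !st$kept &
          graph$edges$a %in% nodeset & graph$edges$b %in% nodeset)
  }
  has_violated_triangle <- function(eidx) {
    if (!any(tri_violated)) return(FALSE)
    inset <- rep(FALSE, ne); inset[eidx] <- TRUE
    any(tri_violated &
        inset[tt$edges[, 1]] & inset[tt$edges[, 2]] & inset[tt$edges[, 3]])
  }

  recurse <- function(nodeset) {
    eidx <- edges_within(nodeset)
    if (length(eidx) == 0) return(invisible(NULL))
    if (length(nodeset) <= 2 || !has_violated_triangle(eidx)) {
      st$kept[eidx] <- TRUE
      return(invisible(NULL))
    }
    sub <- conformation_graph(graph$edges[eidx, , drop = FALSE],
                              nodes = nodeset)
    cut <- maxcut_local(sub, seed = seed + st$counter)
    st$counter <- st$counter + 1L
    cut_global <- eidx[match(
      edge_key(sub$edges$a[cut$cut_edges], sub$edges$b[cut$cut_edges]),
      keys[eidx]
    )]
    st$kept[cut_global] <- TRUE

    # delete same-side edges closing a violated triangle with two cut edges
    ca <- graph$edges$a[cut_global]; cb <- graph$edges$b[cut_global]
    verts <- sort(unique(c(ca, cb)), method = "radix")
    for (x in verts) {
      opp <- sort(c(cb[ca == x], ca[cb == x]), method = "radix")
      if (length(opp) < 2) next
      prs <- utils::combn(opp, 2)
      for (j in seq_len(ncol(prs))) {
        v <- prs[1, j]; w <- prs[2, j]
        ek <- edge_key(v, w)
        erow <- edge_row[ek]
        if (is.na(erow) || !st$alive[erow] || st$kept[erow]) next
        trip <- sort(c(x, v, w), method = "radix")
        trow <- tri_row[paste(trip[1], trip[2], trip[3], sep = "\x1f")]
        if (!is.na(trow) && tri_violated[trow]) {
          st$alive[erow] <- FALSE
        }
      }
    }
    recurse(cut$v1)
    recurse(cut$v2)
    invisible(NULL)
  }

  recurse(graph$nodes)
  new_filter_result(graph, which(st$kept), "maxcut-hierarchical",
                    list(k = 2, rho = spec$rho, seed = seed))
}

#' LP relaxation upper bound (ConsT)
#'
#' Solves the linear relaxation of the edge-selection integer program:
#' maximize the fractional total reward subject to
#' \eqn{x_{e_1} + x_{e_2} + x_{e_3} \le 2} for every violated triangle and
#' \eqn{0 \le x_e \le 1}. The objective bounds the reward of every
#' triangle-consistent subset from above. With no violated triangles the
#' bound equals the total graph reward and all `x` are 1.
#'
#' @inheritParams setcover_greedy
#' @return object of class `lp_solution`: list with per-edge fractional
#'   values `x` (aligned to the graph's edges) and `objective`.
#' @export
lp_upper_bound <- function(graph, spec = consistency_spec(k = 2)) {
  check_graph(graph); check_spec(spec); check_k2(spec)
  vt <- violated_triangle_edges(graph, spec)
  ne <- n_edges(graph)
  x <- rep(1, ne)
  obj <- sum(graph$edges$r)
  if (nrow(vt$edges) > 0) {
    cand <- sort(unique(as.integer(vt$edges)))
    m <- nrow(vt$edges)
    incidence <- matrix(0, nrow = m, ncol = length(cand))
    for (col in 1:3) {
      incidence[cbind(seq_len(m), match(vt$edges[, col], cand))] <- 1
    }
    sol <- lp_max_pack(graph$edges$r[cand], incidence)
    x[cand] <- sol$x
    obj <- sol$objective + sum(graph$edges$r[-cand])
  }
  structure(list(x = x, objective = obj,
                 n_constraints = nrow(vt$edges)),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("LP relaxation: objective %.6g over %d edges (%d triangle constraints)\n",
              x$objective, length(x$x), x$n_constraints))
  invisible(x)
}

# Exact minimum-reward removal set resolving all violated triangles.
# method "branch_and_bound": depth-first search branching on the three
# edges of an uncovered triangle, pruned by the best cost found (seeded
# with the greedy solution). method "enumerate": exhaustive scan of all
# subsets of the candidate edges. Both are exact.
min_removal_exact <- function(graph, spec = consistency_spec(k = 2),
                              size_limit = 25,
                              method = c("branch_and_bound", "enumerate")) {
  method <- match.arg(method)
  vt <- violated_triangle_edges(graph, spec)
  if (nrow(vt$edges) == 0) return(list(removed = integer(0), cost = 0))
  cand <- sort(unique(as.integer(vt$edges)))
  if (length(cand) > size_limit) {
    stop_param("exact search limited to ", size_limit,
               " candidate edges (got ", length(cand),
               "); raise `size_limit` to proceed")
  }
  r <- graph$edges$r
  tris <- lapply(seq_len(nrow(vt$edges)), function(i) as.integer(vt$edges[i, ]))

  if (method == "enumerate") {
    nc <- length(cand)
    best_cost <- Inf; best_set <- integer(0)
    tri_masks <- vapply(tris, function(t) {
      sum(2^(match(t, cand) - 1))
    }, numeric(1))
    for (mask in 0:(2^nc - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
      cost <- sum(r[cand[sel]])
      if (cost >= best_cost) next
      selmask <- sum(2^(sel - 1))
      if (all(bitwAnd(tri_masks, selmask) > 0)) {
        best_cost <- cost; best_set <- cand[sel]
      }
    }
    return(list(removed = sort(best_set), cost = best_cost))
  }

  seedfit <- setcover_greedy(graph, spec)
  st <- new.env(parent = emptyenv())
  st$best_cost <- sum(r[seedfit$removed])
  st$best_set <- seedfit$removed
  dive <- function(uncov, removed, cost) {
    if (cost >= st$best_cost - 1e-12) return(invisible(NULL))
    if (length(uncov) == 0) {
      st$best_cost <- cost
      st$best_set <- removed
      return(invisible(NULL))
    }
    tri <- tris[[uncov[1]]]
    for (e in tri[order(r[tri])]) {
      if (e %in% removed) next
      still <- uncov[vapply(uncov, function(i) !(e %in% tris[[i]]), logical(1))]
      dive(still, c(removed, e), cost + r[e])
    }
    invisible(NULL)
  }
  dive(seq_along(tris), integer(0), 0)
  list(removed = sort(st$best_set), cost = st$best_cost)
}

#' Exact maximum-reward triangle-consistent subset (small instances)
#'
#' Solves the ConsT selection problem exactly via its complement: the
#' minimum-reward edge-removal set hitting every violated triangle, found
#' by exhaustive branch-and-bound search. Intended as an optimality oracle
#' for small instances; the search is restricted to at most `size_limit`
#' candidate edges (edges occurring in violated triangles).
#'
#' @inheritParams setcover_greedy
#' @param size_limit maximum number of candidate edges for the exact
#'   search (default 25); exceeded instances raise an error.
#' @param method `"branch_and_bound"` (default) or `"enumerate"` (plain
#'   subset scan); both certify optimality.
#' @return a `filter_result` with `params$optimal = TRUE`.
#' @export
ilp_exact <- function(graph, spec = consistency_spec(k = 2), size_limit = 25,
                      method = c("branch_and_bound", "enumerate")) {
  check_graph(graph); check_spec(spec); check_k2(spec)
  sol <- min_removal_exact(graph, spec, size_limit = size_limit,
                           method = match.arg(method))
  new_filter_result(graph, setdiff(seq_len(n_edges(graph)), sol$removed),
                    "ilp-exact",
                    list(k = 2, rho = spec$rho, optimal = TRUE,
                         removal_cost = sol$cost))
}

#' Shortest-path-union metric filtering (ConsP)
#'
#' Keeps exactly the edges that lie on some shortest path between their
#' endpoints: an edge is removed when the shortest-path length between its
#' endpoints is strictly below the edge's own length (ranged mode: path
#' lengths use the upper bounds `u`, the threshold is the lower bound
#' `l`). The retained set satisfies the all-paths condition.
#'
#' @param graph a `conformation_graph`.
#' @param spec a [consistency_spec()]; its `k` is ignored (the output is
#'   all-paths consistent, hence consistent for every `k`).
#' @return a `filter_result`.
#' @export
sp_union <- function(graph, spec = consistency_spec(k = "all")) {
  check_graph(graph); check_spec(spec)
  bounds <- effective_bounds(graph, spec)
  tol <- spec$tolerance * pmax(1, abs(bounds$l))
  ne <- n_edges(graph)
  retained <- seq_len(ne)
  if (ne > 0) {
    ig <- as_igraph(graph, weight = bounds$u)
    D <- igraph::distances(ig, algorithm = "dijkstra")
    ai <- match(graph$edges$a, graph$nodes)
    bi <- match(graph$edges$b, graph$nodes)
    sp <- D[cbind(ai, bi)]
    retained <- which(sp >= bounds$l - tol)
  }
  new_filter_result(graph, retained, "sp-union",
                    list(k = "all", rho = spec$rho))
}

#' Maximum-spanning-tree metric filtering (ConsP)
#'
#' Starts from a maximum-reward spanning forest (Kruskal with
#' lexicographic tie-breaks), then scans the remaining edges in descending
#' reward order and adds each edge whenever the grown set stays all-paths
#' consistent, recomputing shortest paths after every tentative addition.
#'
#' @inheritParams sp_union
#' @param recheck `"incremental"` (default) maintains the all-pairs
#'   shortest-path matrix under O(n^2) updates per accepted edge;
#'   `"naive"` rebuilds shortest paths from scratch after every tentative
#'   addition. Both give identical results; the naive path is the
#'   reference implementation.
#' @return a `filter_result` with reward at least that of the spanning
#'   forest.
#' @export
mst_add <- function(graph, spec = consistency_spec(k = "all"),
                    recheck = c("incremental", "naive")) {
  check_graph(graph); check_spec(spec)
  recheck <- match.arg(recheck)
  bounds <- effective_bounds(graph, spec)
  tol <- spec$tolerance * pmax(1, abs(bounds$l))
  ne <- n_edges(graph)
  e <- graph$edges
  ord <- order(-e$r, e$a, e$b, method = "radix")

  # Kruskal maximum-reward spanning forest
  parent <- seq_along(graph$nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ai <- match(e$a, graph$nodes)
  bi <- match(e$b, graph$nodes)
  in_tree <- rep(FALSE, ne)
  for (i in ord) {
    ra <- find(ai[i]); rb <- find(bi[i])
    if (ra != rb) {
      parent[ra] <- rb
      in_tree[i] <- TRUE
    }
  }

  retained <- in_tree
  if (recheck == "naive") {
    consp_ok <- function(mask) {
      idx <- which(mask)
      ig <- as_igraph(graph, idx = idx, weight = bounds$u[idx])
      D <- igraph::distances(ig, algorithm = "dijkstra")
      sp <- D[cbind(ai[idx], bi[idx])]
      all(sp >= bounds$l[idx] - tol[idx])
    }
    for (i in ord) {
      if (retained[i]) next
      trial <- retained
      trial[i] <- TRUE
      if (consp_ok(trial)) retained <- trial
    }
  } else {
    # all-pairs u-distance matrix over the current retained set, updated
    # through each accepted edge in O(n^2)
    idx0 <- which(retained)
    ig <- as_igraph(graph, idx = idx0, weight = bounds$u[idx0])
    D <- igraph::distances(ig, algorithm = "dijkstra")
    for (i in ord) {
      if (retained[i]) next
      x <- ai[i]; y <- bi[i]; w <- bounds$u[i]
      Dn <- pmin(D,
                 outer(D[, x], D[y, ], `+`) + w,
                 outer(D[, y], D[x, ], `+`) + w)
      trial <- retained
      trial[i] <- TRUE
      ti <- which(trial)
      if (all(Dn[cbind(ai[ti], bi[ti])] >= bounds$l[ti] - tol[ti])) {
        retained <- trial
        D <- Dn
      }
    }
  }
  new_filter_result(graph, which(retained), "mst-add",
                    list(k = "all", rho = spec$rho))
}

#' Confidence-rank baseline filtering (C-Rank)
#'
#' Keeps the `m` highest-reward edges (ties broken lexicographically),
#' ignoring metric structure entirely. The standard baseline against which
#' metric filterings are compared.
#'
#' @param graph a `conformation_graph`.
#' @param m number of edges to keep, `0 <= m <= |E|`.
#' @return a `filter_result` with no consistency guarantee.
#' @export
crank <- function(graph, m) {
  check_graph(graph)
  ne <- n_edges(graph)
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0 || m > ne ||
      m != floor(m)) {
    stop_param("`m` must be an integer in [0, ", ne, "]")
  }
  e <- graph$edges
  ord <- order(-e$r, e$a, e$b, method = "radix")
  new_filter_result(graph, ord[seq_len(m)], "crank", list(m = as.integer(m)))
}

#' Summary profile of a filtering
#'
#' @param result a `filter_result`.
#' @return list with `n_edges`, `total_reward`, `normalized_reward`
#'   (reward per retained edge) and `crank_intersection` (size of the
#'   overlap with the equal-size C-Rank set).
#' @export
confidence_profile <- function(result) {
  if (!inherits(result, "filter_result")) stop_param("expected a `filter_result`")
  m <- length(result$retained)
  ck <- crank(result$graph, m)
  list(
    n_edges = m,
    total_reward = result$total_reward,
    normalized_reward = if (m > 0) result$total_reward / m else 0,
    crank_intersection = length(intersect(result$retained, ck$retained))
  )
}
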