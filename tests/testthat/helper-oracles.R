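# Independent brute-force oracles. These deliberately avoid the package's
# own consistency/triangle machinery: violations are recomputed from node
# triples and igraph path enumeration, optima by subset enumeration.

toy_triangle <- function(d = c(3, 1, 1), r = c(3, 1, 1)) {
  conformation_graph(data.frame(
    a = c("u", "u", "v"), b = c("v", "w", "w"), d = d, r = r
  ))
}

# Per-edge [l, u] bounds under a slack factor (NULL = strict).
oracle_bounds <- function(graph, rho = NULL) {
  d <- graph$edges$d
  if (is.null(rho)) data.frame(l = d, u = d)
  else data.frame(l = (1 - rho) * d, u = (1 + rho) * d)
}

# Violated edge indices by explicit path enumeration (igraph
# all_simple_paths), independent of the package's DP / Dijkstra route.
oracle_violated_edges <- function(graph, k = 2, rho = NULL, tol = 1e-9) {
  ne <- n_edges(graph)
  if (ne == 0) return(integer(0))
  b <- oracle_bounds(graph, rho)
  if (is.infinite(k)) k <- length(graph$nodes) - 1
  ig <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                      directed = FALSE,
                                      vertices = graph$nodes)
  keys <- paste(graph$edges$a, graph$edges$b)
  out <- integer(0)
  for (e in seq_len(ne)) {
    ig2 <- igraph::delete_edges(ig, e)
    paths <- igraph::all_simple_paths(ig2, from = graph$edges$a[e],
                                      to = graph$edges$b[e], cutoff = k)
    best <- Inf
    for (p in paths) {
      nm <- names(p)
      len <- 0
      for (j in seq_len(length(nm) - 1)) {
        pa <- sort(c(nm[j], nm[j + 1]), method = "radix")
        len <- len + b$u[match(paste(pa[1], pa[2]), keys)]
      }
      best <- min(best, len)
    }
    if (best < b$l[e] - tol * max(1, abs(b$l[e]))) out <- c(out, e)
  }
  out
}

# Violated triangles by direct triple enumeration: rows of edge indices.
oracle_violated_triangles <- function(graph, rho = NULL, tol = 1e-9) {
  b <- oracle_bounds(graph, rho)
  keys <- paste(graph$edges$a, graph$edges$b)
  eix <- function(p, q) {
    s <- sort(c(p, q), method = "radix")
    match(paste(s[1], s[2]), keys)
  }
  nodes <- graph$nodes
  out <- NULL
  if (length(nodes) >= 3) {
    for (trip in utils::combn(nodes, 3, simplify = FALSE)) {
      e12 <- eix(trip[1], trip[2]); e13 <- eix(trip[1], trip[3])
      e23 <- eix(trip[2], trip[3])
      if (anyNA(c(e12, e13, e23))) next
      es <- c(e12, e13, e23)
      viol <- FALSE
      for (pos in 1:3) {
        e <- es[pos]; oth <- es[-pos]
        if (sum(b$u[oth]) < b$l[e] - tol * max(1, abs(b$l[e]))) viol <- TRUE
      }
      if (viol) out <- rbind(out, es)
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 3) else unname(out)
}

# Minimum-reward removal set resolving all violated triangles, by full
# subset enumeration over the edges occurring in violated triangles.
oracle_min_removal <- function(graph, rho = NULL) {
  vt <- oracle_violated_triangles(graph, rho)
  if (nrow(vt) == 0) return(list(cost = 0, removed = integer(0)))
  cand <- sort(unique(as.integer(vt)))
  stopifnot(length(cand) <= 18)
  best_cost <- Inf; best <- integer(0)
  for (mask in 0:(2^length(cand) - 1)) {
    sel <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
    cost <- sum(graph$edges$r[sel])
    if (cost >= best_cost) next
    covered <- apply(vt, 1, function(tr) any(tr %in% sel))
    if (all(covered)) { best_cost <- cost; best <- sel }
  }
  list(cost = best_cost, removed = best)
}

# Maximum-reward triangle-consistent subset by subset enumeration
# (complement of oracle_min_removal; kept separate as a cross-check).
oracle_best_const_reward <- function(graph, rho = NULL) {
  total_reward(graph) - oracle_min_removal(graph, rho)$cost
}

# Brute-force maximum independent set size of a simple graph.
oracle_mis_size <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 0) return(0)
  best <- 0
  am <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (NROW(edges) > 0) {
    for (i in seq_len(NROW(edges))) {
      am[edges[i, 1], edges[i, 2]] <- TRUE
      am[edges[i, 2], edges[i, 1]] <- TRUE
    }
  }
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    if (!any(am[sel, sel])) best <- length(sel)
  }
  best
}

# Horn's quaternion method for optimal proper-rotation superposition:
# an independent check on the SVD-based Kabsch implementation.
oracle_quaternion_rmsd <- function(A, B) {
  B <- B[rownames(A), , drop = FALSE]
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  aligned <- Bc %*% t(R)
  sqrt(mean(rowSums((aligned - Ac)^2)))
}

# Small Erdos-Renyi style random instance with random lengths/rewards;
# lengths drawn wide enough that violated triangles are common.
random_instance <- function(seed, n = 7, p = 0.7) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- which(stats::runif(ncol(pairs)) < p)
  if (length(keep) < 1) keep <- 1
  data.frame(
    a = pairs[1, keep], b = pairs[2, keep],
    d = stats::runif(length(keep), 0.1, 2),
    r = stats::runif(length(keep), 0.05, 1),
    stringsAsFactors = FALSE
  ) |> conformation_graph()
}
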