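#' Construct a chromosome conformation graph
#'
#' A conformation graph is an undirected weighted graph whose nodes are
#' restriction fragments and whose edges are measured 3C/4C interactions.
#' Every edge carries a nonnegative spatial length `d` (arbitrary units,
#' typically micrometres) and a positive reward `r` (a statistical
#' confidence, conventionally `1 - q` for an FDR-adjusted q-value).
#' Edges may optionally carry a raw interaction frequency `f` and an
#' explicit admissible distance range `[l, u]`.
#'
#' @param edges data frame with character (or coercible) columns `a`, `b`
#'   naming the two fragments, numeric `d` (length, >= 0) and `r`
#'   (reward, > 0), and optional numeric `f` (frequency, >= 0), `l`, `u`
#'   (distance range with `0 <= l <= d <= u`).
#' @param nodes optional character vector of fragment identifiers; defaults
#'   to the identifiers appearing in `edges`. Extra isolated nodes are kept.
#'
#' @return An object of class `conformation_graph`: a list with `nodes`
#'   (sorted character vector) and `edges` (data frame with canonicalized
#'   endpoints, `a < b` in C collation, rows sorted lexicographically).
#'
#' @details Self-loops and duplicate (parallel) edges are rejected. Edge
#'   endpoint order is canonicalized so `{a, b}` and `{b, a}` denote the
#'   same interaction.
#'
#' @examples
#' g <- conformation_graph(data.frame(
#'   a = c("u", "u", "v"), b = c("v", "w", "w"),
#'   d = c(3, 1, 1), r = c(3, 1, 1)
#' ))
#' n_edges(g)
#' @export
conformation_graph <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges)) stop_param("`edges` must be a data frame")
  required <- c("a", "b", "d", "r")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop_param("`edges` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  d <- as.numeric(edges$d)
  r <- as.numeric(edges$r)
  if (anyNA(a) || anyNA(b)) stop_param("edge endpoints must not be NA")
  if (any(a == b)) stop_param("self-loops are not allowed")
  if (anyNA(d) || any(d < 0)) stop_param("edge lengths d must be nonnegative")
  if (anyNA(r) || any(r <= 0)) stop_param("edge rewards r must be positive")

  swap <- c_gt(a, b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  out <- data.frame(a = a, b = b, d = d, r = r, stringsAsFactors = FALSE)
  if (!is.null(edges$f)) {
    f <- as.numeric(edges$f)
    if (any(!is.na(f) & f < 0)) stop_param("frequencies f must be nonnegative")
    out$f <- f
  }
  has_l <- !is.null(edges$l); has_u <- !is.null(edges$u)
  if (xor(has_l, has_u)) stop_param("provide both `l` and `u` or neither")
  if (has_l) {
    l <- as.numeric(edges$l); u <- as.numeric(edges$u)
    both <- !is.na(l) & !is.na(u)
    if (any(is.na(l) != is.na(u))) stop_param("`l` and `u` must be NA on the same edges")
    if (any(both & (l < 0 | l > u))) stop_param("ranges must satisfy 0 <= l <= u")
    if (any(both & (d < l | d > u))) stop_param("ranges must bracket the length: l <= d <= u")
    out$l <- l; out$u <- u
  }

  key <- edge_key(out$a, out$b)
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), , drop = FALSE]
    stop_param("duplicate undirected edge(s): ",
               paste(edge_label(dup$a, dup$b), collapse = ", "))
  }
  ord <- c_order(out$a, out$b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  all_nodes <- unique(c(out$a, out$b))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    if (!all(all_nodes %in% nodes)) stop_param("`nodes` must cover all edge endpoints")
    all_nodes <- unique(nodes)
  }
  all_nodes <- sort(all_nodes, method = "radix")

  structure(list(nodes = all_nodes, edges = out), class = "conformation_graph")
}

#' @export
print.conformation_graph <- function(x, ...) {
  cat(sprintf("conformation graph: %d fragments, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  d in [%.4g, %.4g], total reward %.4g",
              if (nrow(x$edges)) min(x$edges$d) else NA,
              if (nrow(x$edges)) max(x$edges$d) else NA,
              sum(x$edges$r)))
  extras <- intersect(c("f", "l", "u"), names(x$edges))
  if (length(extras)) cat(" (with ", paste(extras, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of nodes / edges of a conformation graph
#' @param graph a `conformation_graph`.
#' @return integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

is_conformation_graph <- function(x) inherits(x, "conformation_graph")

check_graph <- function(graph) {
  if (!is_conformation_graph(graph)) stop_param("expected a `conformation_graph`")
  invisible(graph)
}

# Resolve an edge subset given as integer indices, logical mask, edge-key
# characters, or a two-column data frame, to sorted integer indices.
resolve_edges <- function(graph, subset) {
  ne <- n_edges(graph)
  if (is.null(subset)) return(seq_len(ne))
  if (is.logical(subset)) {
    if (length(subset) != ne) stop_param("logical subset has wrong length")
    return(which(subset))
  }
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
    if (length(idx) && (anyNA(idx) || any(idx < 1) || any(idx > ne))) {
      stop_param("edge index out of range")
    }
    return(sort(unique(idx)))
  }
  if (is.data.frame(subset)) {
    a <- as.character(subset$a %||% subset[[1]])
    b <- as.character(subset$b %||% subset[[2]])
    swap <- c_gt(a, b)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    keys <- edge_key(a, b)
    idx <- match(keys, edge_key(graph$edges$a, graph$edges$b))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop_param("unknown edge in subset: ", edge_label(a[bad], b[bad]))
    }
    return(sort(unique(idx)))
  }
  stop_param("unsupported edge subset representation")
}

# igraph view of (a subset of) the graph, with a chosen per-edge weight.
as_igraph <- function(graph, idx = NULL, weight = NULL) {
  idx <- resolve_edges(graph, idx)
  e <- graph$edges[idx, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    e[, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(weight)) igraph::E(ig)$weight <- weight
  ig
}

#' Restrict a conformation graph to an edge subset
#'
#' @param graph a `conformation_graph`.
#' @param subset edge subset: integer indices into `graph$edges`, a logical
#'   mask, or a data frame with columns `a`, `b`.
#' @param drop_isolated drop nodes left without incident edges (default
#'   `FALSE`).
#' @return a `conformation_graph`.
#' @export
subgraph_edges <- function(graph, subset, drop_isolated = FALSE) {
  check_graph(graph)
  idx <- resolve_edges(graph, subset)
  e <- graph$edges[idx, , drop = FALSE]
  nodes <- if (drop_isolated) NULL else graph$nodes
  conformation_graph(e, nodes = nodes)
}

#' Total reward of an edge subset
#'
#' The objective maximized by metric filtering: \eqn{R(S) = \sum_{e \in S} r(e)}.
#'
#' @param graph a `conformation_graph`.
#' @param subset edge subset (see [subgraph_edges()]); `NULL` means all edges.
#' @return numeric scalar; `0` for the empty subset.
#' @export
total_reward <- function(graph, subset = NULL) {
  check_graph(graph)
  idx <- resolve_edges(graph, subset)
  sum(graph$edges$r[idx])
}
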