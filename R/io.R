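# TSV/BED/JSON input-output and the frequency-to-distance mapping.

#' Map interaction frequencies to spatial distances
#'
#' Default mapping is the inverse power law `d = (f / c)^(-1/gamma)`,
#' strictly decreasing in `f` and the inverse of the forward map
#' `f = c * d^(-gamma)` used by [frequency_graph()]. Alternatively a
#' piecewise-linear calibration table may be supplied (for data whose
#' published calibration curve is tabulated rather than parametric).
#'
#' @param f positive frequencies.
#' @param c_coef power-law coefficient (> 0, default 1).
#' @param gamma power-law exponent (> 0, default 1).
#' @param calibration optional data frame with numeric columns `frequency`
#'   and `distance`; when given, distances are linearly interpolated
#'   (constant beyond the table's range) and `c_coef`/`gamma` are ignored.
#' @return numeric distances.
#' @export
frequency_to_distance <- function(f, c_coef = 1, gamma = 1, calibration = NULL) {
  if (any(is.na(f)) || any(f <= 0)) stop_param("frequencies must be positive")
  if (!is.null(calibration)) {
    if (!all(c("frequency", "distance") %in% names(calibration))) {
      stop_param("`calibration` needs columns `frequency` and `distance`")
    }
    o <- order(calibration$frequency)
    return(stats::approx(calibration$frequency[o], calibration$distance[o],
                         xout = f, rule = 2)$y)
  }
  if (c_coef <= 0) stop_param("`c_coef` must be positive")
  if (gamma <= 0) stop_param("`gamma` must be positive")
  (f / c_coef)^(-1 / gamma)
}

#' @rdname frequency_to_distance
#' @param d positive distances (forward map).
#' @export
distance_to_frequency <- function(d, c_coef = 1, gamma = 1) {
  if (any(is.na(d)) || any(d <= 0)) stop_param("distances must be positive")
  if (c_coef <= 0) stop_param("`c_coef` must be positive")
  if (gamma <= 0) stop_param("`gamma` must be positive")
  c_coef * d^(-gamma)
}

#' Read an interaction edge list from TSV
#'
#' Expects a tab-separated file with a header row. Recognized columns
#' (by name, not position): `fragment_a`, `fragment_b` (required),
#' `distance` and/or `frequency` (at least one), `confidence` (required,
#' in (0, 1] by convention but any positive reward is accepted), and
#' optional `lower`, `upper` range bounds. Missing distances are derived
#' from frequencies via [frequency_to_distance()] when `mapping` is
#' supplied.
#'
#' @param path file path.
#' @param mapping optional list with elements `c_coef`, `gamma` and/or
#'   `calibration`, passed to [frequency_to_distance()].
#' @return a `conformation_graph` (frequencies kept in column `f` when
#'   present).
#' @export
read_edges <- function(path, mapping = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("fragment_a", "fragment_b", "confidence")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_param(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_d <- "distance" %in% names(raw)
  has_f <- "frequency" %in% names(raw)
  if (!has_d && !has_f) {
    stop_param(path, ": need a `distance` and/or `frequency` column")
  }
  check_numeric <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(allow_na & is.na(raw[[col]])))
    if (length(bad) > 0) {
      stop_param(path, ": malformed `", col, "` at line ", bad[1] + 1)
    }
    v
  }
  d <- if (has_d) check_numeric("distance", allow_na = has_f) else rep(NA_real_, nrow(raw))
  f <- if (has_f) check_numeric("frequency", allow_na = has_d) else NULL
  conf <- check_numeric("confidence")
  neg <- which(!is.na(d) & d < 0)
  if (length(neg) > 0) stop_param(path, ": negative distance at line ", neg[1] + 1)
  if (!is.null(f)) {
    neg <- which(!is.na(f) & f < 0)
    if (length(neg) > 0) stop_param(path, ": negative frequency at line ", neg[1] + 1)
  }
  bad <- which(conf <= 0)
  if (length(bad) > 0) stop_param(path, ": non-positive confidence at line ", bad[1] + 1)

  need_d <- which(is.na(d))
  if (length(need_d) > 0) {
    if (is.null(f)) stop_param(path, ": missing distance at line ", need_d[1] + 1)
    if (is.null(mapping)) {
      stop_param(path, ": ", length(need_d),
                 " row(s) lack a distance; supply `mapping` to derive it from frequency")
    }
    d[need_d] <- frequency_to_distance(
      f[need_d],
      c_coef = mapping$c_coef %||% 1,
      gamma = mapping$gamma %||% 1,
      calibration = mapping$calibration
    )
  }

  edges <- data.frame(a = as.character(raw$fragment_a),
                      b = as.character(raw$fragment_b),
                      d = d, r = conf, stringsAsFactors = FALSE)
  if (!is.null(f)) edges$f <- f
  if (all(c("lower", "upper") %in% names(raw))) {
    edges$l <- check_numeric("lower", allow_na = TRUE)
    edges$u <- check_numeric("upper", allow_na = TRUE)
  }
  dup_key <- edge_key(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  dup <- which(duplicated(dup_key))
  if (length(dup) > 0) {
    stop_param(path, ": duplicate undirected edge at line ", dup[1] + 1)
  }
  conformation_graph(edges)
}

#' Write an interaction edge list to TSV
#'
#' Inverse of [read_edges()]: `write_edges()` then `read_edges()` is the
#' identity on canonicalized graphs.
#'
#' @param graph a `conformation_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  check_graph(graph)
  e <- graph$edges
  out <- data.frame(fragment_a = e$a, fragment_b = e$b,
                    distance = e$d, confidence = e$r,
                    stringsAsFactors = FALSE)
  if (!is.null(e$f)) out$frequency <- e$f
  if (!is.null(e$l)) { out$lower <- e$l; out$upper <- e$u }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragment coordinates from a BED file
#'
#' Standard 0-based half-open BED; only the first four columns are used
#' (chrom, start, end, optional name). Fragments without a name column
#' are labelled `chrom:start-end`.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_fragments_bed <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3) stop_param(path, ": BED needs at least 3 columns")
  out <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end) || any(out$start < 0) ||
      any(out$end <= out$start)) {
    stop_param(path, ": malformed BED intervals")
  }
  out$name <- if (ncol(raw) >= 4) as.character(raw[[4]]) else
    sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Write coordinates of an embedding to TSV
#'
#' @param structure an `embedding` or coordinate matrix with named rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(structure, path) {
  X <- if (inherits(structure, "embedding")) structure$coords else structure
  out <- data.frame(node = rownames(X), X, stringsAsFactors = FALSE,
                    row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' JSON run report for a filtering
#'
#' Serializes the algorithm, its parameters, edge counts, rewards and
#' violation counts before/after filtering (under the spec the algorithm
#' ran with), plus an optional LP upper bound.
#'
#' @param result a `filter_result`.
#' @param spec the [consistency_spec()] used for the violation counts;
#'   defaults to the spec implied by the result's parameters.
#' @param bound optional `lp_solution` (or numeric) upper bound to record.
#' @param path optional file to write the JSON document to.
#' @return the report as a named list, invisibly when `path` is given.
#' @export
run_report <- function(result, spec = NULL, bound = NULL, path = NULL) {
  if (!inherits(result, "filter_result")) stop_param("expected a `filter_result`")
  graph <- result$graph
  if (is.null(spec)) {
    k <- result$params$k %||% 2
    spec <- consistency_spec(k = if (identical(k, "all")) Inf else k,
                             rho = result$params$rho)
  }
  prof <- confidence_profile(result)
  report <- list(
    algorithm = result$algorithm,
    parameters = result$params,
    n_edges_input = n_edges(graph),
    n_edges_retained = length(result$retained),
    n_edges_removed = length(result$removed),
    total_reward = result$total_reward,
    normalized_reward = prof$normalized_reward,
    crank_intersection = prof$crank_intersection,
    violations_before = n_violations(find_violations(graph, spec)),
    violations_after = as.integer(
      n_violations(find_violations(subgraph_edges(graph, result$retained), spec))
    ),
    lp_bound = if (inherits(bound, "lp_solution")) bound$objective else bound
  )
  validate_report(report)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}

validate_report <- function(report) {
  required <- c("algorithm", "parameters", "n_edges_input",
                "n_edges_retained", "n_edges_removed", "total_reward",
                "normalized_reward", "violations_before", "violations_after")
  missing_fields <- setdiff(required, names(report))
  if (length(missing_fields) > 0) {
    stop_param("report is missing field(s): ",
               paste(missing_fields, collapse = ", "))
  }
  stopifnot(report$n_edges_retained + report$n_edges_removed ==
            report$n_edges_input)
  invisible(report)
}
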