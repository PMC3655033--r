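# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Locale-independent (C collation) string ordering; all deterministic
# tie-breaking on fragment identifiers goes through these.
c_order <- function(...) order(..., method = "radix")

# TRUE where a sorts strictly after b in C collation.
c_gt <- function(a, b) {
  n <- length(a)
  vapply(seq_len(n), function(i) {
    if (a[i] == b[i]) return(FALSE)
    identical(sort(c(a[i], b[i]), method = "radix")[1L], b[i])
  }, logical(1))
}

edge_key <- function(a, b) paste(a, b, sep = "\x1f")

edge_label <- function(a, b) paste(a, b, sep = "--")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_param <- function(...) stop(..., call. = FALSE)
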