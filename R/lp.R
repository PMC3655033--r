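# LP back-ends for the filtering module.
#
# Small instances are solved exactly with the dense tableau simplex from
# boot. Larger instances (hundreds of variables = edges in violated
# triangles) switch to quadprog's dual active-set method on a
# ridge-regularized objective: the regularization (1e-6 relative) keeps the
# quadratic strictly convex while perturbing the optimum by far less than
# any tolerance used downstream, and the returned point is always feasible
# for the original LP.

LP_TOL <- 1e-6 # constraint-satisfaction tolerance

SIMPLEX_MAX_VARS <- 150
SIMPLEX_MAX_CONS <- 300

simplex_iters <- function(nvar, ncon) max(2000L, 50L * (nvar + ncon))

# min sum(cost * y) s.t. incidence %*% y >= 1, 0 <= y <= 1.
# incidence: m x n 0/1 matrix (rows = violated triangles, cols = edges).
lp_min_cover <- function(cost, incidence) {
  n <- length(cost)
  m <- nrow(incidence)
  if (n <= SIMPLEX_MAX_VARS && m <= SIMPLEX_MAX_CONS) {
    res <- boot::simplex(
      a = cost,
      A1 = diag(n), b1 = rep(1, n),
      A2 = incidence, b2 = rep(1, m),
      maxi = FALSE,
      n.iter = simplex_iters(n, n + m)
    )
    if (res$solved != 1) {
      stop("covering LP solver failed (status ", res$solved,
           "); ", n, " variables, ", m, " constraints", call. = FALSE)
    }
    return(list(y = unname(res$soln), objective = unname(res$value)))
  }
  eps <- 1e-6 * max(cost)
  qp <- tryCatch(
    quadprog::solve.QP(
      Dmat = diag(eps, n), dvec = -cost,
      Amat = cbind(diag(n), -diag(n), t(incidence)),
      bvec = c(rep(0, n), rep(-1, n), rep(1, m))
    ),
    error = function(e) stop("covering LP solver failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  y <- pmin(pmax(qp$solution, 0), 1)
  list(y = y, objective = sum(cost * y))
}

# max sum(reward * x) s.t. incidence %*% x <= 2, 0 <= x <= 1.
lp_max_pack <- function(reward, incidence) {
  n <- length(reward)
  m <- nrow(incidence)
  if (n <= SIMPLEX_MAX_VARS && m <= SIMPLEX_MAX_CONS) {
    res <- boot::simplex(
      a = reward,
      A1 = rbind(incidence, diag(n)),
      b1 = c(rep(2, m), rep(1, n)),
      maxi = TRUE,
      n.iter = simplex_iters(n, n + m)
    )
    if (res$solved != 1) {
      stop("packing LP solver failed (status ", res$solved,
           "); ", n, " variables, ", m, " constraints", call. = FALSE)
    }
    return(list(x = unname(res$soln), objective = unname(res$value)))
  }
  eps <- 1e-6 * max(reward)
  qp <- tryCatch(
    quadprog::solve.QP(
      Dmat = diag(eps, n), dvec = reward,
      Amat = cbind(diag(n), -diag(n), -t(incidence)),
      bvec = c(rep(0, n), rep(-1, n), rep(-2, m))
    ),
    error = function(e) stop("packing LP solver failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  x <- pmin(pmax(qp$solution, 0), 1)
  list(x = x, objective = sum(reward * x))
}
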