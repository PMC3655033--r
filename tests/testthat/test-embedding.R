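test_that("exactly realizable graphs embed with near-zero stress", {
  pl <- planted_graph(4, dim = 3, noise_sd = 0, seed = 1)
  emb <- embed_graph(pl$graph, seed = 7)
  expect_lt(emb$error, 1e-6)

  single <- conformation_graph(data.frame(a = "x", b = "y", d = 1, r = 1))
  e1 <- embed_graph(single, seed = 0)
  expect_equal(realized_distances(e1, single), 1, tolerance = 1e-5)

  # 10-point cloud, complete graph, several seeds: every restart recovers
  # the configuration (up to rigid motion and reflection)
  pl10 <- planted_graph(10, noise_sd = 0, seed = 3)
  ens <- embed_ensemble(pl10$graph, n_restarts = 5, seed = 20)
  expect_true(all(ens$errors < 1e-4))
  for (p in 1:4) {
    rmsd <- superpose(ens$structures[[p]], ens$structures[[p + 1]],
                      allow_reflection = TRUE)$rmsd
    expect_lt(rmsd, 1e-3)
  }
})

test_that("embedding is deterministic given the seed", {
  g <- planted_graph(8, noise_sd = 0.2, seed = 5)$graph
  e1 <- embed_graph(g, seed = 42)
  e2 <- embed_graph(g, seed = 42)
  expect_identical(e1$coords, e2$coords)
  e3 <- embed_graph(g, seed = 43)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("embedding error is the sum of squared distance residuals", {
  single <- conformation_graph(data.frame(a = "x", b = "y", d = 1, r = 1))
  X <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  expect_equal(embedding_error(X, single), 1) # (2 - 1)^2
  expect_equal(embedding_error(X / 2, single), 0)

  two <- conformation_graph(data.frame(a = c("x", "y"), b = c("y", "z"),
                                       d = c(1, 1), r = 1))
  Y <- matrix(c(0, 0, 0, 2, 0, 0, 2, 3, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  expect_equal(embedding_error(Y, two), 1^2 + 2^2) # off by 1 and by 2

  expect_error(embedding_error(X, two), "lacks coordinates")
})

test_that("embedding error is invariant under rigid motions", {
  pl <- planted_graph(6, noise_sd = 0.3, seed = 2)
  emb <- embed_graph(pl$graph, seed = 1)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  moved <- emb$coords %*% R
  moved <- sweep(moved, 2, c(5, -2, 1), FUN = "+")
  rownames(moved) <- rownames(emb$coords)
  expect_equal(embedding_error(moved, pl$graph),
               embedding_error(emb, pl$graph), tolerance = 1e-9)
})

test_that("violation injection applies the alpha-shrink formula", {
  # start consistent; roles in lexicographic order: u=a, v=b, w=c;
  # d(u,v)=0.5 < d(u,w)=1, so d(a,b) := 0.9 * |d(b,c) - d(a,c)| = 0.18,
  # after which 0.18 + 1 < 1.2 violates (b,c)
  tri <- conformation_graph(data.frame(
    a = c("a", "a", "b"), b = c("b", "c", "c"),
    d = c(0.5, 1, 1.2), r = 1))
  expect_equal(n_violations(find_violations(tri, consistency_spec(k = 2))), 0)
  pert <- reintroduce_violations(tri, alpha = 0.9, target_fraction = 1, seed = 1)
  expect_equal(pert$edges$d[1], 0.9 * abs(1.2 - 1))
  expect_equal(pert$edges$d[2:3], c(1, 1.2)) # other edges untouched
  expect_equal(n_violations(find_violations(pert, consistency_spec(k = 2))), 1)
  expect_equal(pert$edges$r, tri$edges$r) # rewards untouched
  expect_equal(attr(pert, "achieved_fraction"), 1)

  # degenerate |d(v,w) - d(u,w)| = 0 clamps to epsilon, cannot reach the
  # target, and warns when the attempt cap is hit
  degen <- conformation_graph(data.frame(
    a = c("a", "a", "b"), b = c("b", "c", "c"),
    d = c(0.5, 1, 1), r = 1))
  expect_warning(
    pd <- reintroduce_violations(degen, alpha = 0.9, target_fraction = 1,
                                 seed = 1, max_attempts = 5),
    "attempt cap")
  expect_equal(pd$edges$d[1], 1e-6)

  expect_identical(
    reintroduce_violations(tri, alpha = 0.5, target_fraction = 0, seed = 1)$edges$d,
    tri$edges$d)
  expect_error(reintroduce_violations(tri, alpha = 1.2), "alpha")
  star <- conformation_graph(data.frame(a = "h", b = c("s1", "s2"), d = 1, r = 1))
  expect_error(reintroduce_violations(star), "no triangles")
})

test_that("superposition removes rigid motions and matches the quaternion oracle", {
  pl <- planted_graph(6, noise_sd = 0, seed = 8)
  A <- pl$coords
  expect_equal(superpose(A, A)$rmsd, 0)

  theta <- 1.1
  R <- matrix(c(cos(theta), 0, sin(theta),
                0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  B <- sweep(A %*% R, 2, c(1, 2, 3), FUN = "+")
  rownames(B) <- rownames(A)
  expect_lt(superpose(A, B)$rmsd, 1e-9)

  for (seed in 1:5) {
    set.seed(seed)
    A4 <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
    B4 <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
    sp <- superpose(A4, B4)
    expect_equal(sp$rmsd, oracle_quaternion_rmsd(A4, B4), tolerance = 1e-9)
    # symmetry
    expect_equal(sp$rmsd, superpose(B4, A4)$rmsd, tolerance = 1e-9)
  }
  expect_error(superpose(A, A[-1, , drop = FALSE]), "same node set")
})

test_that("ensemble variability is the MST weight of the RMSD graph", {
  pl <- planted_graph(5, noise_sd = 0, seed = 4)
  A <- pl$coords
  copies <- list(A, A, A)
  expect_equal(ensemble_variability(copies), 0)
  expect_error(ensemble_variability(list(A)), "at least 2")

  # independent oracle: enumerate all spanning trees of the RMSD graph
  set.seed(11)
  structs <- lapply(1:4, function(i) {
    X <- A + matrix(rnorm(length(A), sd = 0.3), nrow(A))
    rownames(X) <- rownames(A); X
  })
  m <- 4
  rmsd <- matrix(0, m, m)
  for (p in 1:(m - 1)) for (q in (p + 1):m) {
    rmsd[p, q] <- rmsd[q, p] <-
      superpose(structs[[p]], structs[[q]], allow_reflection = TRUE)$rmsd
  }
  # brute force over all 16 labelled spanning trees of K4 (Prufer sequences)
  best <- Inf
  for (p1 in 1:4) for (p2 in 1:4) {
    pruefer <- c(p1, p2)
    deg <- rep(1, 4); for (x in pruefer) deg[x] <- deg[x] + 1
    w <- 0; avail <- 1:4
    pq <- pruefer
    for (x in pq) {
      leaf <- min(avail[deg[avail] == 1])
      w <- w + rmsd[leaf, x]
      deg[leaf] <- deg[leaf] - 1; deg[x] <- deg[x] - 1
      avail <- setdiff(avail, leaf)
    }
    w <- w + rmsd[avail[1], avail[2]]
    best <- min(best, w)
  }
  expect_equal(ensemble_variability(structs), best, tolerance = 1e-12)

  # invariance under a global rigid motion of every structure
  R <- diag(3)[, c(2, 1, 3)] * c(1, -1, 1) # a proper rotation
  moved <- lapply(structs, function(X) {
    Y <- sweep(X %*% R, 2, c(3, 3, 3), FUN = "+"); rownames(Y) <- rownames(X); Y
  })
  expect_equal(ensemble_variability(moved), ensemble_variability(structs),
               tolerance = 1e-9)
})

test_that("filter comparisons are reproducible and size-matched", {
  pl <- planted_graph(10, edge_density = 0.8, noise_sd = 0.25, seed = 6)
  cmp_same <- compare_filterings(pl$graph, "setcov", "setcov",
                                 n_restarts = 2, seed = 3)
  expect_equal(cmp_same$a$mean_error, cmp_same$b$mean_error)
  expect_equal(cmp_same$a$variability, cmp_same$b$variability)

  cmp <- compare_filterings(pl$graph, "setcov", "crank-matched",
                            n_restarts = 2, seed = 3)
  expect_equal(cmp$a$n_edges, cmp$b$n_edges)
})

test_that("injected violations raise the mean embedding error", {
  errs <- sapply(1:4, function(seed) {
    pl <- planted_graph(8, noise_sd = 0, seed = seed)
    clean <- mean(embed_ensemble(pl$graph, n_restarts = 2, seed = seed)$errors)
    pert <- reintroduce_violations(pl$graph, alpha = 0.9,
                                   target_fraction = 0.4, seed = seed)
    dirty <- mean(embed_ensemble(pert, n_restarts = 2, seed = seed)$errors)
    c(clean, dirty)
  })
  expect_gt(mean(errs[2, ]), mean(errs[1, ]))
})
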