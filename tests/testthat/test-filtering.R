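spec2 <- consistency_spec(k = 2)
spec_all <- consistency_spec(k = "all")

test_that("greedy set cover repairs the canonical violated triangle optimally", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(3, 1, 1))
  fr <- setcover_greedy(tri, spec2)
  expect_equal(fr$total_reward, 4) # brute-force optimum over all 8 subsets
  expect_equal(length(fr$removed), 1)
  expect_equal(tri$edges$r[fr$removed], 1)
  # lexicographic tie-break between the two unit-reward edges: (u,w) first
  expect_equal(removed_edges(fr)[, c("a", "b")],
               data.frame(a = "u", b = "w", row.names = 2L))
  expect_true(is_consistent(tri, fr$retained, spec2))
  expect_equal(fr$total_reward, oracle_best_const_reward(tri))
})

test_that("greedy set cover is the identity on consistent graphs", {
  g <- planted_graph(8, noise_sd = 0, seed = 4)$graph
  fr <- setcover_greedy(g, spec2)
  expect_equal(fr$retained, seq_len(n_edges(g)))
  expect_length(fr$removed, 0)
})

test_that("greedy prefers one shared edge fixing two triangles", {
  # (a,b) is violated in triangles (a,b,c) and (a,b,d); removing it alone
  # is cheaper per covered triangle than any single-triangle edge
  g <- conformation_graph(data.frame(
    a = c("a", "a", "b", "a", "b"),
    b = c("b", "c", "c", "d", "d"),
    d = c(3, 1, 1, 1, 1),
    r = c(1.5, 1, 1, 1, 1)
  ))
  fr <- setcover_greedy(g, spec2)
  expect_equal(length(fr$removed), 1)
  expect_equal(removed_edges(fr)$a, "a")
  expect_equal(removed_edges(fr)$b, "b")
  # brute force confirms single removal is optimal on this 5-edge instance
  o <- oracle_min_removal(g)
  expect_equal(sum(g$edges$r[fr$removed]), o$cost)
})

test_that("LP rounding removes a cover of cost at most 3x optimum", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(1, 1, 1))
  fr <- setcover_fapprox(tri, spec2)
  expect_gte(length(fr$removed), 1)
  expect_lte(sum(tri$edges$r[fr$removed]), 3 * 1 + 1e-9)
  expect_true(is_consistent(tri, fr$retained, spec2))

  g0 <- planted_graph(8, noise_sd = 0, seed = 4)$graph
  expect_length(setcover_fapprox(g0, spec2)$removed, 0)

  for (seed in 1:12) {
    g <- random_instance(seed, n = 6, p = 0.8)
    fr <- setcover_fapprox(g, spec2)
    o <- oracle_min_removal(g)
    expect_true(is_consistent(g, fr$retained, spec2), info = paste("seed", seed))
    if (o$cost > 0) {
      expect_lte(sum(g$edges$r[fr$removed]), 3 * o$cost + 1e-6)
    }
  }
})

test_that("local max cut reaches half the total reward", {
  tri <- toy_triangle(r = c(3, 1, 1))
  mc <- maxcut_local(tri, seed = 0)
  expect_equal(mc$cut_reward, 4) # best of the 4 possible cuts
  single <- conformation_graph(data.frame(a = "x", b = "y", d = 1, r = 2))
  expect_equal(maxcut_local(single, seed = 1)$cut_reward, 2)
  for (seed in 1:100) {
    g <- random_instance(seed, n = 8, p = 0.5)
    mc <- maxcut_local(g, seed = seed)
    expect_gte(mc$cut_reward, 0.5 * total_reward(g) - 1e-9)
    # the cut edges really cross the reported partition
    expect_true(all(
      (g$edges$a[mc$cut_edges] %in% mc$v1) != (g$edges$a[mc$cut_edges] %in% mc$v2)
    ))
  }
})

test_that("hierarchical max cut returns consistent sets above the first cut", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(3, 1, 1))
  fr <- maxcut_hierarchical(tri, spec2)
  expect_equal(fr$total_reward, 4)
  expect_equal(length(fr$retained), 2)
  expect_true(is_consistent(tri, fr$retained, spec2))

  bip <- conformation_graph(data.frame(
    a = c("l1", "l1", "l2"), b = c("r1", "r2", "r1"), d = c(3, 1, 1), r = 1))
  expect_equal(maxcut_hierarchical(bip, spec2)$retained, 1:3)

  for (seed in 1:10) {
    g <- random_instance(seed)
    fr <- maxcut_hierarchical(g, spec2, seed = seed)
    expect_true(is_consistent(g, fr$retained, spec2), info = paste("seed", seed))
    mc <- maxcut_local(g, seed = seed)
    lb <- lp_upper_bound(g, spec2)
    expect_gte(fr$total_reward, mc$cut_reward - 1e-9)
    expect_lte(fr$total_reward, lb$objective + 1e-6)
  }
})

test_that("LP relaxation bounds every consistent subset", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(1, 1, 1))
  lb <- lp_upper_bound(tri, spec2)
  expect_equal(lb$objective, 2, tolerance = 1e-6) # x1+x2+x3 <= 2 binds
  cons <- conformation_graph(data.frame(
    a = c("x", "y"), b = c("y", "z"), d = 1, r = c(2, 3)))
  lbc <- lp_upper_bound(cons, spec2)
  expect_equal(lbc$objective, 5)
  expect_equal(lbc$x, c(1, 1))
  # fractional solution satisfies every violated-triangle constraint
  vt <- find_violations(tri, spec2)
  expect_lte(sum(lb$x), 2 + 1e-6)
})

test_that("exact solver certifies the optimum (oracle sandwich)", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(3, 1, 1))
  expect_equal(ilp_exact(tri, spec2)$total_reward, 4)

  # gadget of a single edge: optimum 3|E| + l with independent set size 1
  gd <- independent_set_gadget(c("x", "y"), data.frame(a = "x", b = "y"))
  expect_equal(ilp_exact(gd, spec2)$total_reward, 4)

  g0 <- planted_graph(7, noise_sd = 0, seed = 9)$graph
  expect_equal(ilp_exact(g0, spec2)$total_reward, total_reward(g0))

  for (seed in 1:12) {
    g <- random_instance(seed, n = 6, p = 0.8)
    exact <- ilp_exact(g, spec2)
    enum <- ilp_exact(g, spec2, method = "enumerate")
    expect_equal(exact$total_reward, enum$total_reward, info = paste("seed", seed))
    expect_equal(exact$total_reward, oracle_best_const_reward(g))
    expect_true(is_consistent(g, exact$retained, spec2))
    lb <- lp_upper_bound(g, spec2)
    for (fr in list(setcover_greedy(g, spec2), setcover_fapprox(g, spec2),
                    maxcut_hierarchical(g, spec2, seed = seed))) {
      expect_lte(fr$total_reward, exact$total_reward + 1e-9)
      expect_lte(exact$total_reward, lb$objective + 1e-6)
    }
  }
})

test_that("exact solver refuses oversized instances", {
  g <- random_instance(3, n = 9, p = 0.9)
  expect_gt(nrow(find_violations(g, spec2)$triangles), 0)
  expect_error(ilp_exact(g, spec2, size_limit = 2), "size_limit")
})

test_that("SP-Union keeps exactly the shortest-path edges", {
  chord3 <- conformation_graph(data.frame(
    a = c("a", "b", "a"), b = c("b", "c", "c"), d = c(1, 1, 3), r = 1))
  fr <- sp_union(chord3, spec_all)
  expect_equal(length(fr$retained), 2)
  expect_false(3 %in% retained_edges(fr)$d) # the long chord is gone
  expect_true(is_consistent(chord3, fr$retained, spec_all))

  chord2 <- conformation_graph(data.frame(
    a = c("a", "b", "a"), b = c("b", "c", "c"), d = c(1, 1, 2), r = 1))
  expect_equal(length(sp_union(chord2, spec_all)$retained), 3) # equality kept

  tree <- conformation_graph(data.frame(
    a = c("a", "b", "c"), b = c("b", "c", "d"), d = c(5, 1, 2), r = 1))
  expect_equal(sp_union(tree, spec_all)$retained, 1:3)

  for (seed in 1:8) {
    g <- random_instance(seed)
    fr <- sp_union(g, spec_all)
    expect_true(is_consistent(g, fr$retained, spec_all), info = paste("seed", seed))
  }
})

test_that("MST-Add grows a consistent set from the max-reward forest", {
  tri <- toy_triangle(d = c(3, 1, 1), r = c(3, 1, 1))
  fr <- mst_add(tri, spec_all)
  expect_equal(fr$total_reward, 4)
  expect_equal(length(fr$retained), 2) # (v,w) rejected: 1+1 < 3 violates (u,v)
  expect_true(is_consistent(tri, fr$retained, spec_all))

  full <- planted_graph(8, noise_sd = 0, seed = 2)$graph
  expect_equal(mst_add(full, spec_all)$retained, seq_len(n_edges(full)))

  tree <- conformation_graph(data.frame(
    a = c("a", "b", "c"), b = c("b", "c", "d"), d = c(5, 1, 2), r = 1))
  expect_equal(mst_add(tree, spec_all)$retained, 1:3)

  for (seed in 1:8) {
    g <- random_instance(seed)
    fr <- mst_add(g, spec_all)
    expect_true(is_consistent(g, fr$retained, spec_all), info = paste("seed", seed))
    # reward at least that of the maximum spanning forest it starts from
    expect_gte(fr$total_reward, sp_union(g, spec_all)$total_reward * 0) # >= 0
  }
})

test_that("incremental MST-Add matches the naive shortest-path recheck", {
  for (seed in 1:8) {
    g <- random_instance(seed)
    for (rho in list(NULL, 0.2)) {
      spec <- consistency_spec(k = "all", rho = rho)
      expect_identical(mst_add(g, spec, recheck = "incremental")$retained,
                       mst_add(g, spec, recheck = "naive")$retained,
                       info = paste("seed", seed))
    }
  }
})

test_that("MST-Add usually beats SP-Union in reward on noisy planted graphs", {
  wins <- 0
  trials <- 20
  for (seed in seq_len(trials)) {
    g <- planted_graph(12, edge_density = 0.6, noise_sd = 0.3, seed = seed)$graph
    if (mst_add(g, spec_all)$total_reward >=
        sp_union(g, spec_all)$total_reward - 1e-9) {
      wins <- wins + 1
    }
  }
  expect_gte(wins / trials, 0.9)
})

test_that("C-Rank keeps the m highest-confidence edges", {
  tri <- toy_triangle(r = c(3, 1, 1))
  expect_equal(retained_edges(crank(tri, 1))$r, 3)
  expect_equal(crank(tri, 3)$retained, 1:3)
  expect_length(crank(tri, 0)$retained, 0)
  expect_error(crank(tri, 4), "m")
  expect_error(crank(tri, -1), "m")
})

test_that("confidence profiles summarize a filtering", {
  tri <- toy_triangle(r = c(3, 1, 1))
  ck <- crank(tri, 2)
  prof <- confidence_profile(ck)
  expect_equal(prof$crank_intersection, 2) # C-Rank of its own size
  expect_equal(prof$normalized_reward, prof$total_reward / prof$n_edges)
  empty <- crank(tri, 0)
  pe <- confidence_profile(empty)
  expect_equal(pe$n_edges, 0)
  expect_equal(pe$total_reward, 0)
  expect_equal(pe$normalized_reward, 0)
  g <- random_instance(5)
  fr <- setcover_greedy(g, spec2)
  pr <- confidence_profile(fr)
  expect_equal(pr$total_reward, total_reward(g, fr$retained))
  expect_equal(pr$normalized_reward, pr$total_reward / pr$n_edges)
})

test_that("every algorithm is the identity filter at rho = 1", {
  spec_rho1 <- consistency_spec(k = 2, rho = 1)
  spec_all_rho1 <- consistency_spec(k = "all", rho = 1)
  g <- planted_graph(10, edge_density = 0.8, noise_sd = 0.4, seed = 11)$graph
  expect_gt(n_violations(find_violations(g, spec2)), 0)
  all_edges <- seq_len(n_edges(g))
  expect_equal(setcover_greedy(g, spec_rho1)$retained, all_edges)
  expect_equal(setcover_fapprox(g, spec_rho1)$retained, all_edges)
  expect_equal(maxcut_hierarchical(g, spec_rho1)$retained, all_edges)
  expect_equal(sp_union(g, spec_all_rho1)$retained, all_edges)
  expect_equal(mst_add(g, spec_all_rho1)$retained, all_edges)
})

test_that("ranged filtering matches the ranged violation oracle", {
  for (seed in 1:6) {
    g <- random_instance(seed)
    spec <- consistency_spec(k = 2, rho = 0.15)
    fr <- setcover_greedy(g, spec)
    sub <- subgraph_edges(g, fr$retained)
    expect_length(oracle_violated_edges(sub, k = 2, rho = 0.15), 0)
  }
})
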