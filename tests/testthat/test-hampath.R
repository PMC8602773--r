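test_that("clustering at extremes behaves: singletons at k = N, blobs at k = 2", {
  set.seed(8)
  # two blobs with opposite expression-profile shapes (the rank-based
  # distance cares about profile shape, not overall level)
  shape1 <- seq(1, 6)
  shape2 <- seq(6, 1)
  blob1 <- matrix(rep(shape1, each = 5L), 5L) + rnorm(30L, sd = 0.1)
  blob2 <- matrix(rep(shape2, each = 5L), 5L) + rnorm(30L, sd = 0.1)
  e <- rbind(blob1, blob2)
  rownames(e) <- paste0("c", 1:10)
  a <- cluster_for_k(e, k = 10)
  expect_equal(length(unique(a$labels)), 10L)
  expect_equal(unname(a$centroids), unname(e[order(a$labels), ]))
  b <- cluster_for_k(e, k = 2, allow_small = TRUE)
  expect_equal(length(unique(b$labels[1:5])), 1L)
  expect_equal(length(unique(b$labels[6:10])), 1L)
  expect_false(b$labels[1] == b$labels[6])
  expect_error(cluster_for_k(e, k = 11), "exceeds")
  expect_error(cluster_for_k(e, k = 2), "k must be >= 3")
})

test_that("duplicate rows always co-cluster", {
  set.seed(9)
  base <- matrix(runif(4 * 8), 4L)
  e <- rbind(base, base[2, , drop = FALSE])  # row 5 duplicates row 2
  for (k in 3:4) {
    a <- cluster_for_k(e, k, allow_small = TRUE)
    expect_equal(a$labels[[2]], a$labels[[5]])
  }
})

test_that("centroids are arithmetic means of member rows", {
  set.seed(10)
  e <- matrix(runif(60), 12L, 5L)
  a <- cluster_for_k(e, 4L)
  for (g in seq_len(4L)) {
    expect_equal(unname(a$centroids[g, ]),
                 unname(colMeans(e[a$labels == g, , drop = FALSE])))
  }
})

test_that("insertion path solves trivial and collinear instances exactly", {
  asym <- matrix(c(0, 5, 1, 0), 2L, byrow = TRUE)
  p <- insertion_path(asym, seed = 1)
  expect_equal(p$order, c(2L, 1L))
  expect_equal(p$cost, 1)
  x <- c(0, 1, 2, 3)
  costs <- outer(x, x, function(a, b) (a - b)^2)
  p4 <- insertion_path(costs, seed = 1)
  expect_true(identical(p4$order, 1:4) || identical(p4$order, 4:1))
  expect_equal(p4$cost, 3)
  expect_error(insertion_path(matrix(c(0, Inf, 1, 0), 2L)), "non-finite")
})

test_that("brute force enumerates exactly and breaks ties lexicographically", {
  bf <- brute_force_path(matrix(c(0, 5, 1, 0), 2L, byrow = TRUE))
  expect_equal(bf$order, c(2L, 1L))
  expect_equal(bf$cost, 1)
  ties <- matrix(2, 3L, 3L); diag(ties) <- 0
  bf3 <- brute_force_path(ties)
  expect_equal(bf3$order, 1:3)
  expect_equal(bf3$cost, 4)
  expect_error(brute_force_path(matrix(0, 10L, 10L)), "n > 9")
})

test_that("path cost is recomputable and permutation-equivariant", {
  set.seed(12)
  costs <- matrix(runif(49), 7L); diag(costs) <- 0
  p <- insertion_path(costs, seed = 3)
  expect_equal(p$cost, path_cost(p$order, costs), tolerance = 1e-9)
  perm <- sample(7L)
  relabeled <- costs[perm, perm]
  expect_equal(path_cost(match(p$order, perm), relabeled), p$cost,
               tolerance = 1e-12)
})

test_that("heuristic never beats the oracle; asymmetric spot checks", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:7, 1L)
    costs <- matrix(rexp(n * n), n); diag(costs) <- 0
    bf <- brute_force_path(costs)
    ip <- insertion_path(costs, seed = i)
    expect_gte(ip$cost, bf$cost - 1e-9)
  }
})

test_that("monotone band costs are recovered in monotone order", {
  x <- seq(0, 1, length.out = 8L)
  costs <- outer(x, x, function(a, b) (a - b)^2)
  p <- insertion_path(costs, seed = 2)
  expect_true(identical(p$order, 1:8) || identical(p$order, 8:1))
})

test_that("insertion path is deterministic for a fixed seed", {
  set.seed(14)
  costs <- matrix(runif(100), 10L); diag(costs) <- 0
  p1 <- insertion_path(costs, seed = 99)
  p2 <- insertion_path(costs, seed = 99)
  expect_identical(p1, p2)
})

test_that("cluster paths project to scaled per-cell scores", {
  assign <- list(k = 3L, labels = c(a = 1L, b = 2L, c = 3L, d = 1L))
  path <- structure(list(order = c(3L, 1L, 2L), cost = 0),
                    class = "hamiltonian_path")
  s <- path_to_cell_scores(path, assign)
  expect_equal(unname(s), c(0.5, 1, 0, 0.5))
  rev_path <- structure(list(order = c(2L, 1L, 3L), cost = 0),
                        class = "hamiltonian_path")
  expect_equal(unname(path_to_cell_scores(rev_path, assign)),
               1 - unname(s))
  bad <- structure(list(order = c(1L, 2L), cost = 0),
                   class = "hamiltonian_path")
  expect_error(path_to_cell_scores(bad, assign), "exactly")
})

test_that("singleton clusters give a permutation of the uniform grid", {
  set.seed(15)
  e <- matrix(runif(36), 6L, 6L)
  a <- cluster_for_k(e, 6L)
  costs <- kl_cost_matrix(a$centroids)
  p <- insertion_path(costs, seed = 1)
  s <- path_to_cell_scores(p, a)
  expect_equal(sort(unname(s)), seq(0, 1, by = 0.2))
})
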