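test_that("reference construction counts its orientation search honestly", {
  set.seed(21)
  v <- runif(40)
  ref <- build_reference_path(rep(list(v), 5L))
  expect_equal(attr(ref, "n_assignments"), 32L)
  expect_equal(attr(ref, "n_pairwise"), 10L)
  expect_equal(attr(ref, "best_score"), 10)    # 10 perfect correlations
  expect_equal(as.numeric(ref), (v - min(v)) / (max(v) - min(v)))
})

test_that("reference construction re-flips reflected inputs", {
  set.seed(22)
  v <- runif(30)
  inputs <- list(v, v, 1 - v, v, v)
  ref <- build_reference_path(inputs)
  expect_equal(as.numeric(ref), (v - min(v)) / (max(v) - min(v)))
  expect_equal(attr(ref, "best_score"), 10)
})

test_that("merging noisy monotone vectors denoises the consensus", {
  set.seed(23)
  clean <- seq(0, 1, length.out = 60L)
  noisy <- lapply(1:5, function(i) {
    s <- clean + rnorm(60L, sd = 0.05)
    (s - min(s)) / (max(s) - min(s))
  })
  ref <- build_reference_path(noisy)
  rho_ref <- cor(as.numeric(ref), clean, method = "spearman")
  rho_each <- vapply(noisy, function(v) cor(v, clean, method = "spearman"),
                     numeric(1L))
  expect_gte(rho_ref, max(rho_each) - 1e-12)
})

test_that("merge step is idempotent on self and orientation-corrects", {
  set.seed(24)
  ref <- runif(25)
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(merge_paths(ref, list(ref)), ref)
  merged <- merge_paths(ref, list(1 - ref))
  expect_equal(merged, ref)
  expect_error(merge_paths(ref, list(runif(10))), "mismatch")
})

test_that("consensus pseudotime is scaled, reversal-robust and recovers stages", {
  fix <- simulate_linear(seed = 7)
  fit <- consensus_pseudotime(fix$expr, seed = 7)
  pt <- fit$scores
  expect_equal(min(pt), 0)
  expect_equal(max(pt), 1)
  expect_length(pt, 150L)
  kc <- kendall_correlation(pt, fix$true_stage)
  expect_gte(kc, 0.8)
  # reflecting any subset of input score vectors cannot change the result
  # beyond a global reflection: check via the orientation machinery
  set.seed(25)
  base <- lapply(1:5, function(i) {
    v <- sort(runif(40)) + rnorm(40, sd = 0.02)
    (v - min(v)) / (max(v) - min(v))
  })
  flipped <- base
  for (j in c(2L, 4L)) flipped[[j]] <- 1 - flipped[[j]]
  r1 <- as.numeric(build_reference_path(base))
  r2 <- as.numeric(build_reference_path(flipped))
  agree <- min(max(abs(r1 - r2)), max(abs(r1 - (1 - r2))))
  expect_lt(agree, 1e-10)
})

test_that("root cell anchors the global direction", {
  fix <- simulate_linear(n_cells = 60, seed = 3)
  early <- rownames(fix$expr)[which.min(fix$true_pt)]
  fit <- consensus_pseudotime(fix$expr, seed = 3, root_cell = early)
  expect_lt(fit$scores[early], 0.5)
  expect_match(fit$direction_anchor, "root cell")
})

test_that("transition matrix records the worked 3-cell example and adds up", {
  # single path 2-3-1: unit mass at (2,3) and (3,1) only
  p <- structure(list(order = c(2L, 3L, 1L), cost = 0),
                 class = "hamiltonian_path")
  t1 <- transition_matrix(list(p), n_cells = 3L)
  expected <- matrix(0, 3L, 3L)
  expected[2L, 3L] <- 1; expected[3L, 1L] <- 1
  expect_equal(t1, expected)
  expect_equal(transition_matrix(list(p, p), n_cells = 3L), 2 * expected)
})

test_that("transition mass totals sum(path length - 1) for any mix", {
  set.seed(26)
  cells <- structure(list(order = sample(6L), cost = 0),
                     class = "hamiltonian_path")
  assign <- list(k = 3L, labels = c(1L, 1L, 2L, 2L, 3L, 3L))
  clus <- structure(list(order = c(2L, 1L, 3L), cost = 0),
                    class = "hamiltonian_path")
  t2 <- transition_matrix(list(cells, clus), list(NULL, assign))
  expect_equal(sum(t2), (6 - 1) + (3 - 1))
  # p identical cell paths: N-1 entries of mass p each
  t3 <- transition_matrix(rep(list(cells), 4L), n_cells = 6L)
  expect_equal(sum(t3 > 0), 5L)
  expect_equal(unique(t3[t3 > 0]), 4)
})

test_that("embedding of a linear consensus recovers the chain order on PC1", {
  # cluster-level chains at several granularities over 12 cells in a fixed
  # order: the multi-resolution band matrix a linear consensus produces
  n <- 12L
  paths <- list(); assigns <- list()
  for (k in c(3L, 4L, 6L, 12L)) {
    assigns[[length(assigns) + 1L]] <- list(k = k, labels = rep(1:k, each = n / k))
    paths[[length(paths) + 1L]] <- structure(list(order = 1:k, cost = 0),
                                             class = "hamiltonian_path")
  }
  tm <- transition_matrix(paths, assigns, n_cells = n)
  emb <- embed_transitions(tm)
  expect_gt(abs(cor(emb[, 1L], 1:n, method = "spearman")), 0.9)
  expect_error(embed_transitions(matrix(0, 4L, 4L)), "no transitions")
  # minimal case: 3 cells, one path, no degeneracy
  p3 <- structure(list(order = c(1L, 2L, 3L), cost = 0),
                  class = "hamiltonian_path")
  e3 <- embed_transitions(transition_matrix(list(p3), n_cells = 3L))
  expect_equal(dim(e3), c(3L, 2L))
})

test_that("embedding separates the arms of a branched path set", {
  fix <- simulate_branch(branch_at = 0.5, seed = 7)
  fit <- consensus_pseudotime(fix$expr, seed = 7)
  tm <- transition_matrix(fit$paths, fit$assignments,
                          n_cells = nrow(fix$expr))
  emb <- embed_transitions(tm)
  post <- fix$true_pt > 0.5
  sil <- silhouette_width(emb[post, ], fix$branch_id[post])
  expect_gt(sil, 0.25)
})
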