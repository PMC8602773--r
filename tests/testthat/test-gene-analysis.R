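test_that("distance correlation matches the direct-summation oracle to 1e-10", {
  set.seed(31)
  cases <- list(
    list(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)),
    list(x = rnorm(20), y = rnorm(20)),
    list(x = runif(50), y = runif(50)^2),
    list(x = rnorm(35), y = sin(rnorm(35)))
  )
  for (cs in cases) {
    expect_equal(distance_correlation(cs$x, cs$y), dcor_direct(cs$x, cs$y),
                 tolerance = 1e-10)
  }
})

test_that("distance correlation detects deterministic linear maps and symmetry", {
  x <- rnorm(15)
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, -x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, 3 * x + 2), 1, tolerance = 1e-12)
  set.seed(32)
  y <- rnorm(15)
  expect_equal(distance_correlation(x, y), distance_correlation(y, x))
  expect_warning(z <- distance_correlation(rep(1, 15), y), "constant")
  expect_equal(z, 0)
})

test_that("MIC reaches 1 on noiseless monotone data and stays symmetric", {
  x <- seq(0, 1, length.out = 100L)
  expect_equal(mic_score(x, x), 1, tolerance = 1e-6)
  expect_equal(mic_score(x, exp(3 * x)), 1, tolerance = 1e-6)
  expect_equal(mic_score(x, -x^3), 1, tolerance = 1e-6)
  set.seed(33)
  y <- rnorm(100)
  expect_equal(mic_score(x, y), mic_score(y, x))
  expect_equal(mic_score(rep(2, 50), y[1:50]), 0)
})

test_that("MIC stays low for independent data", {
  set.seed(3)
  mics <- vapply(1:20, function(i) {
    mic_score(runif(200), runif(200))
  }, numeric(1L))
  expect_lt(mean(mics), 0.3)
})

test_that("gene ranking keeps pseudotime-tracking genes and drops shuffled ones", {
  set.seed(34)
  pt <- sort(runif(200))
  expr <- cbind(track = pt,
                perm = sample(pt),
                flat = rep(1, 200))
  scores <- rank_genes(expr, pt)
  expect_equal(scores$gene_id[1L], "track")
  expect_true(scores$kept[scores$gene_id == "track"])
  expect_equal(scores$dcor[scores$gene_id == "track"], 1, tolerance = 1e-9)
  expect_equal(scores$mic[scores$gene_id == "track"], 1, tolerance = 1e-6)
  expect_false(scores$kept[scores$gene_id == "perm"])
  all_kept <- rank_genes(expr[, 1:2], pt, threshold = 0)
  expect_true(all(all_kept$kept))
})

test_that("HMM decoding matches exhaustive MAP enumeration", {
  # clean two-block sequence
  x <- c(0, 0, 0, 0, 10, 10, 10, 10)
  suppressWarnings(tr <- fit_gene_hmm(x))
  expect_equal(tr$states, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  map <- hmm_map_enumerate(x, tr$means, tr$sds, tr$transition, tr$initial)
  expect_equal(tr$states, map - 1L)
  # known generating HMM, length 12
  set.seed(11)
  states_true <- numeric(12L); s <- 1L
  for (t in 1:12) {
    states_true[t] <- s
    s <- if (runif(1) < 0.9) s else 3L - s
  }
  x2 <- rnorm(12L, mean = c(0, 5)[states_true], sd = 1)
  tr2 <- fit_gene_hmm(x2)
  map2 <- hmm_map_enumerate(x2, tr2$means, tr2$sds, tr2$transition, tr2$initial)
  expect_equal(tr2$states, map2 - 1L)
})

test_that("HMM decoding equals enumeration across random short sequences", {
  set.seed(35)
  for (i in 1:8) {
    len <- sample(5:12, 1L)
    x <- rnorm(len, mean = sample(c(0, 4), len, replace = TRUE), sd = 0.8)
    suppressWarnings(tr <- fit_gene_hmm(x))
    if (tr$degenerate) next
    map <- hmm_map_enumerate(x, tr$means, tr$sds, tr$transition, tr$initial)
    expect_equal(tr$states, map - 1L)
  }
})

test_that("HMM internals respect their contracts", {
  set.seed(36)
  x <- rnorm(40, mean = rep(c(0, 5), each = 20L))
  tr <- fit_gene_hmm(x, update_emissions = TRUE)
  expect_true(all(diff(tr$loglik) > -1e-8))      # EM monotonicity
  expect_equal(rowSums(tr$transition), rep(1, 2L))
  expect_true(tr$means[2L] >= tr$means[1L])      # relabeling convention
  const <- fit_gene_hmm(rep(3, 10L))
  expect_true(const$degenerate)
  expect_equal(const$states, rep(0L, 10L))
  tr3 <- fit_gene_hmm(sort(x), n_states = 3L)
  expect_equal(sort(unique(tr3$states)), c(0L, 1L, 2L))
})

test_that("module ordering clusters identical tracks and splits complements", {
  mk <- function(s) structure(list(states = s), class = "gene_state_track")
  a <- mk(c(0L, 0L, 1L, 1L))
  b <- mk(c(0L, 0L, 1L, 1L))
  comp <- mk(c(1L, 1L, 0L, 0L))
  res <- order_gene_modules(list(g1 = a, g2 = b, g3 = comp), cut_height = 0.5)
  expect_equal(res$modules[["g1"]], res$modules[["g2"]])
  expect_false(res$modules[["g1"]] == res$modules[["g3"]])
  pos <- match(c("g1", "g2"), res$order)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("block-duplicated tracks recover their blocks as modules", {
  set.seed(37)
  patterns <- list(c(rep(0L, 10), rep(1L, 10)),
                   c(rep(1L, 10), rep(0L, 10)),
                   rep(c(0L, 1L), 10))
  tracks <- list()
  for (b in 1:3) for (i in 1:10) {
    tracks[[paste0("b", b, "_", i)]] <-
      structure(list(states = patterns[[b]]), class = "gene_state_track")
  }
  res <- order_gene_modules(tracks, cut_height = 0.25)
  expect_equal(length(unique(res$modules)), 3L)
  expect_equal(length(unique(res$modules[paste0("b1_", 1:10)])), 1L)
})
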