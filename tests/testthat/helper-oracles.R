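# Independent brute-force oracles, kept deliberately separate from the
# package implementations they verify.

# distance correlation by direct triple summation (Szekely's S1/S2/S3 form),
# no double centering
dcor_direct <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  s_stats <- function(a, b) {
    s1 <- mean(a * b)
    s2 <- mean(a) * mean(b)
    s3 <- mean(rowMeans(a) * rowMeans(b))
    s1 + s2 - 2 * s3
  }
  dcov2 <- s_stats(a, b)
  dvx <- s_stats(a, a)
  dvy <- s_stats(b, b)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvx * dvy))
}

# exact MAP state path of a Gaussian HMM by enumerating all k^L paths
hmm_map_enumerate <- function(x, means, sds, trans, init) {
  k <- length(means)
  len <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), len)))
  best_lp <- -Inf
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    lp <- log(init[s[1L]]) + dnorm(x[1L], means[s[1L]], sds[s[1L]], log = TRUE)
    for (t in 2:len) {
      lp <- lp + log(trans[s[t - 1L], s[t]]) +
        dnorm(x[t], means[s[t]], sds[s[t]], log = TRUE)
    }
    if (lp > best_lp) { best_lp <- lp; best <- s }
  }
  unname(best)
}

# random point on the probability simplex
runif_simplex <- function(m) {
  e <- -log(runif(m))
  e / sum(e)
}
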