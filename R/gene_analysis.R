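#' Distance correlation (dCor)
#'
#' Szekely's sample distance correlation between two numeric vectors, via
#' double-centered pairwise absolute-difference matrices: with `A`, `B` the
#' centered matrices, `dCov2 = mean(A * B)` and
#' `dCor = sqrt(dCov2 / sqrt(dVar(x) * dVar(y)))`. Detects arbitrary (not
#' just monotone) dependence; value in \[0, 1\].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return dCor in \[0, 1\]; 0 (with a warning) for a constant input.
#' @export
distance_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; distance correlation defined as 0")
    return(0)
  }
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  A <- a - rowMeans(a) - rep(colMeans(a), each = n) + mean(a)
  B <- b - rowMeans(b) - rep(colMeans(b), each = n) + mean(b)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  den <- sqrt(dvarx * dvary)
  if (den <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvarx * dvary))
}

#' Maximal information coefficient (MIC)
#'
#' Grid-search MIC: for every grid shape (nx, ny) with `nx * ny <= n^alpha`
#' and at most `c` bins per axis, both variables are cut into
#' equal-frequency bins, the empirical mutual information of the grid is
#' computed, normalized by `log2(min(nx, ny))`, and the maximum over grid
#' shapes is returned. This equal-frequency-grid search is a simplification
#' of the original dynamic-programming partition optimization; it attains 1
#' on noiseless monotone relationships and stays near 0 for independent
#' data.
#'
#' @param x,y Numeric vectors of equal length >= 10.
#' @param alpha Grid budget exponent: total bins bounded by `n^alpha`
#'   (default 0.6).
#' @param c Maximum bins per axis (default 15).
#' @return MIC in \[0, 1\]; 0 for a constant input.
#' @export
mic_score <- function(x, y, alpha = 0.6, c = 15) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 10L) stop("need at least 10 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  budget <- max(4, floor(n^alpha))
  best <- 0
  for (nx in 2:min(c, floor(budget / 2))) {
    for (ny in 2:min(c, floor(budget / nx))) {
      bx <- equal_freq_bins(x, nx)
      by <- equal_freq_bins(y, ny)
      mi <- mutual_information_bits(bx, by)
      best <- max(best, mi / log2(min(nx, ny)))
    }
  }
  min(1, best)
}

# rank-based equal-frequency binning; ties broken by first occurrence so the
# binning is deterministic
equal_freq_bins <- function(v, nb) {
  r <- rank(v, ties.method = "first")
  ceiling(r * nb / length(v))
}

mutual_information_bits <- function(bx, by) {
  joint <- table(bx, by) / length(bx)
  px <- rowSums(joint)
  py <- colSums(joint)
  e <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / e[nz]))
}

#' Rank genes by association with pseudotime
#'
#' Scores every gene with [distance_correlation()] and [mic_score()]
#' against the pseudotime and keeps genes whose selection statistic reaches
#' `threshold` (default 0.5): `max(dCor, MIC)` by default, or both when
#' `require_both`.
#'
#' @param expr Numeric matrix, cells as rows.
#' @param pt Pseudotime vector (length = number of cells).
#' @param threshold Selection threshold in \[0, 1\].
#' @param require_both Keep a gene only if both statistics reach the
#'   threshold.
#' @return Data frame (one row per gene, sorted by `max(dcor, mic)`
#'   descending) with columns `gene_id`, `dcor`, `mic`, `kept`.
#' @export
rank_genes <- function(expr, pt, threshold = 0.5, require_both = FALSE) {
  if (nrow(expr) != length(pt)) stop("pseudotime length mismatch")
  gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(expr)))
  dcor <- apply(expr, 2L, function(g)
    suppressWarnings(distance_correlation(g, pt)))
  mic <- apply(expr, 2L, function(g) mic_score(g, pt))
  sel <- if (require_both) pmin(dcor, mic) else pmax(dcor, mic)
  out <- data.frame(gene_id = gene_ids, dcor = dcor, mic = mic,
                    kept = sel >= threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(pmax(out$dcor, out$mic), decreasing = TRUE), , drop = FALSE]
}

#' Fit a Gaussian hidden Markov model to one gene along pseudotime
#'
#' Two (or three) hidden states with univariate Gaussian emissions model an
#' off/lowly-expressed vs on/highly-expressed gene. Emissions are
#' initialized from the sorted observations split into `n_states` equal
#' blocks (block mean/sd, sd floored at 1e-3); transition probabilities
#' (and optionally emissions) are re-estimated by Baum-Welch until the
#' log-likelihood gain falls below `tol`; the maximum a posteriori state
#' path is decoded by Viterbi. States are relabeled so that the state mean
#' increases with the state index.
#'
#' @param values_ordered Numeric vector of one gene's expression, ordered
#'   by pseudotime (length >= 4).
#' @param n_states 2 (default) or 3.
#' @param max_iter,tol Baum-Welch stopping controls.
#' @param update_emissions Re-estimate Gaussian means/sds as well as
#'   transitions (default `FALSE`: transitions only).
#' @return List of class `gene_state_track`: `states` (0-based, per cell),
#'   `means`, `sds`, `transition` (rows sum to 1), `initial`, `loglik`
#'   (per-iteration trace), `degenerate` flag.
#' @export
fit_gene_hmm <- function(values_ordered, n_states = 2, max_iter = 100,
                         tol = 1e-4, update_emissions = FALSE) {
  x <- as.numeric(values_ordered)
  len <- length(x)
  if (len < 4L) stop("need at least 4 observations")
  if (!n_states %in% c(2L, 3L)) stop("n_states must be 2 or 3")
  if (stats::sd(x) == 0) {
    return(structure(list(states = rep(0L, len),
                          means = x[1L], sds = 1e-3,
                          transition = matrix(1, 1L, 1L),
                          initial = 1, loglik = NA_real_,
                          degenerate = TRUE),
                     class = "gene_state_track"))
  }
  srt <- sort(x)
  blocks <- split(srt, ceiling(seq_along(srt) * n_states / len))
  mu <- vapply(blocks, mean, numeric(1L))
  sd_ <- vapply(blocks, stats::sd, numeric(1L))
  if (any(is.na(sd_) | sd_ < 1e-3)) {
    warning("zero-variance emission block; sd floored at 1e-3")
    sd_[is.na(sd_) | sd_ < 1e-3] <- 1e-3
  }
  k <- n_states
  trans <- matrix(0.1 / (k - 1), k, k)
  diag(trans) <- 0.9
  init <- rep(1 / k, k)
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    em <- emission_matrix(x, mu, sd_)
    fb <- forward_backward(em, trans, init)
    ll_trace <- c(ll_trace, fb$loglik)
    if (iter > 1L) {
      gain <- fb$loglik - ll_trace[iter - 1L]
      if (gain < -1e-8) stop("Baum-Welch log-likelihood decreased")
      if (gain < tol) break
    }
    # M-step
    xi_sum <- fb$xi_sum
    trans <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    init <- fb$gamma[1L, ]
    if (update_emissions) {
      w <- fb$gamma
      mu <- colSums(w * x) / colSums(w)
      sd_ <- sqrt(colSums(w * (outer(x, mu, "-")^2)) / colSums(w))
      sd_[sd_ < 1e-3] <- 1e-3
    }
  }
  states <- viterbi(x, mu, sd_, trans, init)
  relab <- order(mu)
  states <- match(states, relab) - 1L
  structure(list(states = states,
                 means = unname(mu[relab]), sds = unname(sd_[relab]),
                 transition = trans[relab, relab, drop = FALSE],
                 initial = init[relab],
                 loglik = ll_trace,
                 degenerate = FALSE),
            class = "gene_state_track")
}

emission_matrix <- function(x, mu, sd_) {
  e <- vapply(seq_along(mu), function(s) stats::dnorm(x, mu[s], sd_[s]),
              numeric(length(x)))
  pmax(e, .Machine$double.xmin)
}

# scaled forward-backward; returns loglik, per-time state posteriors and
# summed transition posteriors
forward_backward <- function(em, trans, init) {
  len <- nrow(em)
  k <- ncol(em)
  alpha <- matrix(0, len, k)
  scale <- numeric(len)
  a <- init * em[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2:len) {
    a <- (alpha[t - 1L, ] %*% trans) * em[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, len, k)
  beta[len, ] <- 1
  for (t in (len - 1L):1L) {
    beta[t, ] <- (trans %*% (em[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, k, k)
  for (t in seq_len(len - 1L)) {
    xi <- (alpha[t, ] %o% (em[t + 1L, ] * beta[t + 1L, ])) * trans / scale[t + 1L]
    xi_sum <- xi_sum + xi
  }
  list(loglik = sum(log(scale)), gamma = gamma, xi_sum = xi_sum)
}

viterbi <- function(x, mu, sd_, trans, init) {
  em <- log(emission_matrix(x, mu, sd_))
  lt <- log(pmax(trans, .Machine$double.xmin))
  len <- length(x)
  k <- length(mu)
  delta <- matrix(-Inf, len, k)
  psi <- matrix(0L, len, k)
  delta[1L, ] <- log(pmax(init, .Machine$double.xmin)) + em[1L, ]
  for (t in 2:len) {
    for (s in seq_len(k)) {
      cand <- delta[t - 1L, ] + lt[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + em[t, s]
    }
  }
  states <- integer(len)
  states[len] <- which.max(delta[len, ])
  for (t in (len - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  states
}

#' Order gene state tracks into modules
#'
#' Hierarchical clustering (average linkage) of binary on/off state tracks
#' under Hamming distance; returns the dendrogram leaf order (the heatmap
#' row order) and flat module labels cut at `cut_height` (a Hamming
#' fraction in \[0, 1\]). Three-state tracks are collapsed to binary by
#' merging the top two states unless `keep_3_states`.
#'
#' @param tracks Named list of `gene_state_track` objects (equal lengths).
#' @param cut_height Hamming-distance cut for module labels (default 0.5).
#' @param keep_3_states Keep the 3-state coding (Hamming on 3 symbols).
#' @return List: `order` (gene ids, leaf order), `modules` (named integer
#'   vector), `states` (genes x cells integer matrix in leaf order).
#' @export
order_gene_modules <- function(tracks, cut_height = 0.5, keep_3_states = FALSE) {
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  lens <- vapply(tracks, function(t) length(t$states), integer(1L))
  if (length(unique(lens)) != 1L) stop("tracks differ in length")
  ids <- names(tracks)
  if (is.null(ids)) ids <- paste0("g", seq_along(tracks))
  m <- do.call(rbind, lapply(tracks, function(t) t$states))
  if (!keep_3_states) m <- pmin(m, 1L)
  rownames(m) <- ids
  len <- ncol(m)
  d <- stats::as.dist(vapply(seq_len(nrow(m)), function(i)
    rowMeans(m != rep(m[i, ], each = nrow(m))), numeric(nrow(m))))
  hc <- stats::hclust(d, method = "average")
  modules <- stats::cutree(hc, h = cut_height)
  list(order = ids[hc$order],
       modules = modules,
       states = m[hc$order, , drop = FALSE])
}
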