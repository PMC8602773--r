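#' Spearman correlation distance between cells
#'
#' Computes the pairwise Spearman correlation rho between cell expression
#' profiles (rows) and maps it to a dissimilarity. The default convention is
#' `D = (1 - rho) / 2`, which is 0 for identical cells and 1 for perfectly
#' anti-ranked cells; `as_printed` gives the similarity `(rho + 1) / 2`
#' instead. Ties are handled by average ranks.
#'
#' @param expr Numeric matrix, cells as rows (>= 2 cells and >= 2 genes).
#' @param convention `"dissimilarity"` (default, `(1 - rho)/2`) or
#'   `"as_printed"` (`(rho + 1)/2`).
#' @return N x N symmetric matrix in \[0, 1\] with zero diagonal (under the
#'   default convention). Cells with zero rank variance get correlation 0
#'   against every other cell, with a warning.
#' @export
spearman_distance <- function(expr,
                              convention = c("dissimilarity", "as_printed")) {
  convention <- match.arg(convention)
  if (nrow(expr) < 2L || ncol(expr) < 2L) {
    stop("need at least 2 cells and 2 genes")
  }
  r <- t(apply(expr, 1L, rank))               # average ranks per cell
  sds <- apply(r, 1L, stats::sd)
  flat <- sds == 0
  rho <- suppressWarnings(stats::cor(t(r)))   # Pearson on ranks = Spearman
  if (any(flat)) {
    warning(sum(flat), " cell(s) have constant ranks; their correlations set to 0")
    rho[flat, ] <- 0
    rho[, flat] <- 0
  }
  diag(rho) <- 1
  d <- if (convention == "dissimilarity") (1 - rho) / 2 else (rho + 1) / 2
  if (convention == "dissimilarity") diag(d) <- 0
  dimnames(d) <- list(rownames(expr), rownames(expr))
  d
}

#' Double-center a distance matrix
#'
#' Classical multidimensional-scaling centering: `B = -1/2 * J D2 J` where
#' `D2` is the element-wise square of the input and `J = I - (1/N) 11'`.
#' Every row and column mean of the result is 0.
#'
#' @param d Square symmetric matrix of distances.
#' @return The doubly-centered Gram-like matrix `B`.
#' @export
double_center <- function(d) {
  if (nrow(d) != ncol(d)) stop("double centering needs a square matrix")
  d2 <- d^2
  rm <- rowMeans(d2)
  gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rep(1, ncol(d2))) - outer(rep(1, nrow(d2)), colMeans(d2)) + gm)
}

#' Directed Kullback-Leibler cost between two expression vectors
#'
#' Both vectors are smoothed by a pseudocount and normalized to the
#' probability simplex; the cost is `sum(p * log(p / q))` in nats. The
#' asymmetry (`kl_cost(p, q) != kl_cost(q, p)` in general) encodes the
#' directionality of differentiation.
#'
#' @param p_raw,q_raw Nonnegative numeric vectors of equal length.
#' @param pseudocount Added to every entry before normalization
#'   (default 1e-6); avoids `log(0)`.
#' @return Nonnegative scalar; 0 iff `p_raw == q_raw`.
#' @export
kl_cost <- function(p_raw, q_raw, pseudocount = 1e-6) {
  if (length(p_raw) != length(q_raw)) stop("vectors differ in length")
  if (any(p_raw < 0) || any(q_raw < 0)) stop("expression values must be >= 0")
  p <- p_raw + pseudocount
  q <- q_raw + pseudocount
  sp <- sum(p); sq <- sum(q)
  if (sp == 0 || sq == 0) stop("all-zero vector with zero pseudocount")
  p <- p / sp
  q <- q / sq
  max(0, sum(p * log(p / q)))
}

#' Asymmetric KL cost matrix over a set of expression vectors
#'
#' Entry `(i, j)` is [kl_cost()] from vector i to vector j. Computed via a
#' single matrix product for speed.
#'
#' @param vectors Numeric matrix whose rows are expression vectors (cells or
#'   cluster centroids), or a list of equal-length vectors.
#' @param pseudocount Passed to the KL smoothing.
#' @return n x n nonnegative matrix with zero diagonal.
#' @export
kl_cost_matrix <- function(vectors, pseudocount = 1e-6) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 vectors")
  if (any(vectors < 0)) stop("expression values must be >= 0")
  p <- vectors + pseudocount
  p <- p / rowSums(p)
  lp <- log(p)
  self <- rowSums(p * lp)
  k <- self - p %*% t(lp)     # k[i, j] = sum_m p_im (log p_im - log p_jm)
  k[k < 0] <- 0
  diag(k) <- 0
  dimnames(k) <- list(rownames(vectors), rownames(vectors))
  k
}
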