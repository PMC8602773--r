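#' Build the reference pseudotime from the base paths
#'
#' Given per-cell score vectors from the base clusterings (k = 3..7 by
#' default, i.e. 5 vectors), enumerates every orientation assignment (each
#' vector kept or reflected, 2^5 = 32 assignments), scores each assignment
#' by the sum of its C(5,2) = 10 pairwise Spearman correlations, keeps the
#' best assignment, averages the oriented vectors and min-max rescales the
#' mean to \[0, 1\].
#'
#' @param per_cell_scores List of equal-length numeric score vectors in
#'   \[0, 1\] (at least 2).
#' @return Numeric pseudotime vector in \[0, 1\] with attributes
#'   `n_assignments` (orientation assignments evaluated),
#'   `n_pairwise` (pairwise correlations per assignment), `orientation`
#'   (logical, `TRUE` where the vector was reflected) and `best_score`.
#' @export
build_reference_path <- function(per_cell_scores) {
  m <- length(per_cell_scores)
  if (m < 2L) stop("need at least 2 base score vectors")
  n <- unique(lengths(per_cell_scores))
  if (length(n) != 1L) stop("score vectors differ in length")
  vecs <- do.call(cbind, per_cell_scores)
  flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  pairs <- utils::combn(m, 2L)
  best_score <- -Inf
  best_flip <- flips[1L, ]
  n_eval <- 0L
  n_pairwise <- ncol(pairs)
  for (a in seq_len(nrow(flips))) {
    oriented <- vecs
    for (j in which(flips[a, ])) oriented[, j] <- 1 - oriented[, j]
    score <- 0
    for (p in seq_len(ncol(pairs))) {
      rho <- suppressWarnings(
        stats::cor(oriented[, pairs[1L, p]], oriented[, pairs[2L, p]],
                   method = "spearman"))
      if (is.na(rho)) rho <- 0   # constant vector: orientation-neutral
      score <- score + rho
    }
    n_eval <- n_eval + 1L
    if (score > best_score) {
      best_score <- score
      best_flip <- flips[a, ]
    }
  }
  oriented <- vecs
  for (j in which(best_flip)) oriented[, j] <- 1 - oriented[, j]
  ref <- rescale01(rowMeans(oriented))
  structure(ref,
            n_assignments = n_eval,
            n_pairwise = n_pairwise,
            orientation = unname(best_flip),
            best_score = best_score)
}

#' Merge later path scores into the reference pseudotime
#'
#' Each incoming score vector is oriented (kept or reflected, whichever has
#' the larger Spearman correlation with the current reference) and folded
#' into a running mean; the reference enters with weight `ref_weight` so
#' that every contributing path counts once. The final mean is min-max
#' rescaled to \[0, 1\].
#'
#' @param reference Reference pseudotime from [build_reference_path()].
#' @param later_scores List of per-cell score vectors (k = 7..N stream).
#' @param ref_weight Number of base paths behind the reference (default 5).
#' @return Numeric pseudotime vector in \[0, 1\].
#' @export
merge_paths <- function(reference, later_scores, ref_weight = 5) {
  n <- length(reference)
  total <- reference * ref_weight
  w <- ref_weight
  current <- reference
  for (v in later_scores) {
    if (length(v) != n) stop("score vector length mismatch")
    rho <- suppressWarnings(stats::cor(current, v, method = "spearman"))
    if (!is.na(rho) && rho < 0) v <- 1 - v
    total <- total + v
    w <- w + 1
    current <- total / w
  }
  rescale01(current)
}

rescale01 <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Consensus Hamiltonian-path pseudotime
#'
#' The full consensus procedure: cells are clustered hierarchically once;
#' for every k in the grid the dendrogram is cut at k, cluster centroids
#' are formed, the directed KL cost matrix over centroids is built, an
#' asymmetric Hamiltonian path is solved by [insertion_path()], and the
#' path is projected to per-cell scores. Scores from `k_ref` build the
#' orientation-aligned reference ([build_reference_path()]); scores from
#' `k_merge` are folded in by [merge_paths()]. Sorting the returned scores
#' gives the consensus ordering.
#'
#' @param expr Numeric matrix, cells as rows (log-scale expression over the
#'   selected genes).
#' @param k_ref Integer vector of base granularities (default `3:7`,
#'   truncated at N).
#' @param k_merge Integer vector of merge granularities (default
#'   `max(k_ref):N`); a stride may be used for very large N.
#' @param restarts Restarts per insertion-heuristic solve.
#' @param seed Integer seed controlling all randomized steps.
#' @param linkage Hierarchical-clustering linkage.
#' @param pseudocount KL smoothing pseudocount.
#' @param root_cell Optional cell id (or index) known to be early; the final
#'   pseudotime is reflected if needed so this cell scores < 0.5.
#' @return List of class `consensus_pseudotime` with elements `scores`
#'   (named per-cell pseudotime in \[0, 1\]), `reference`, `paths` (list of
#'   per-k `hamiltonian_path`), `assignments` (per-k cluster labels),
#'   `k_grid`, and `direction_anchor` (how global direction was fixed).
#' @export
consensus_pseudotime <- function(expr, k_ref = 3:7, k_merge = NULL,
                                 restarts = 10, seed = 1,
                                 linkage = "average", pseudocount = 1e-6,
                                 root_cell = NULL) {
  n <- nrow(expr)
  if (n < 4L) stop("need at least 4 cells")
  k_ref <- k_ref[k_ref <= n & k_ref >= 2L]
  if (length(k_ref) < 2L) stop("k_ref grid too small for ", n, " cells")
  if (is.null(k_merge)) k_merge <- seq(max(k_ref), n)
  k_merge <- k_merge[k_merge <= n & k_merge >= 2L]

  hc <- cluster_tree(expr, linkage)
  k_all <- sort(unique(c(k_ref, k_merge)))
  paths <- vector("list", length(k_all))
  assigns <- vector("list", length(k_all))
  scores <- vector("list", length(k_all))
  names(paths) <- names(assigns) <- names(scores) <- as.character(k_all)
  for (i in seq_along(k_all)) {
    k <- k_all[i]
    assign <- cluster_for_k(expr, k, linkage = linkage,
                            allow_small = TRUE, hc = hc)
    costs <- kl_cost_matrix(assign$centroids, pseudocount = pseudocount)
    path <- insertion_path(costs, restarts = restarts,
                           seed = seed + k)   # distinct, reproducible per k
    paths[[i]] <- path
    assigns[[i]] <- assign
    scores[[i]] <- path_to_cell_scores(path, assign)
  }

  reference <- build_reference_path(scores[as.character(k_ref)])
  pt <- merge_paths(reference, scores[as.character(k_merge)],
                    ref_weight = length(k_ref))
  anchor <- "arbitrary (no root cell supplied)"
  if (!is.null(root_cell)) {
    idx <- if (is.character(root_cell)) match(root_cell, rownames(expr)) else root_cell
    if (is.na(idx) || idx < 1L || idx > n) stop("unknown root cell")
    if (pt[idx] > 0.5) pt <- 1 - pt
    anchor <- paste0("root cell '", root_cell, "' anchored early")
  }
  names(pt) <- rownames(expr)
  structure(list(scores = pt,
                 reference = reference,
                 paths = paths,
                 assignments = assigns,
                 k_grid = k_all,
                 direction_anchor = anchor),
            class = "consensus_pseudotime")
}

#' @method print consensus_pseudotime
#' @export
print.consensus_pseudotime <- function(x, ...) {
  cat("Consensus Hamiltonian-path pseudotime\n")
  cat("  cells:", length(x$scores), "\n")
  cat("  k grid:", min(x$k_grid), "..", max(x$k_grid),
      "(", length(x$k_grid), "solves )\n")
  cat("  direction:", x$direction_anchor, "\n")
  invisible(x)
}

#' Accumulate Hamiltonian-path solutions into a cell transition matrix
#'
#' Every consecutive node pair (u, v) of every path adds transition mass at
#' (u, v). For cluster-level paths, the unit mass of an adjacent cluster
#' pair is split uniformly over all member-cell pairs, so cluster sizes do
#' not inflate the total; cell-level paths add unit mass per edge. Total
#' mass therefore equals `sum(path lengths - 1)`.
#'
#' @param paths List of `hamiltonian_path` objects.
#' @param assignments Optional list (parallel to `paths`) of cluster
#'   assignments from [cluster_for_k()]; `NULL` entries mean the path is
#'   already at cell level.
#' @param n_cells Number of cells (required when all paths are cell-level).
#' @return N x N nonnegative matrix with zero diagonal.
#' @export
transition_matrix <- function(paths, assignments = NULL, n_cells = NULL) {
  if (length(paths) < 1L) stop("need at least one path")
  if (is.null(assignments)) assignments <- vector("list", length(paths))
  if (is.null(n_cells)) {
    sizes <- vapply(seq_along(paths), function(i) {
      if (is.null(assignments[[i]])) length(paths[[i]]$order)
      else length(assignments[[i]]$labels)
    }, integer(1L))
    n_cells <- max(sizes)
  }
  t_mat <- matrix(0, n_cells, n_cells)
  for (i in seq_along(paths)) {
    ord <- paths[[i]]$order
    assign <- assignments[[i]]
    if (is.null(assign)) {
      if (any(ord > n_cells)) stop("node index outside matrix")
      from <- ord[-length(ord)]
      to <- ord[-1L]
      for (e in seq_along(from)) {
        t_mat[from[e], to[e]] <- t_mat[from[e], to[e]] + 1
      }
    } else {
      members <- split(seq_len(n_cells), assign$labels)
      for (e in seq_len(length(ord) - 1L)) {
        mu <- members[[ord[e]]]
        mv <- members[[ord[e + 1L]]]
        t_mat[mu, mv] <- t_mat[mu, mv] + 1 / (length(mu) * length(mv))
      }
    }
  }
  diag(t_mat) <- 0
  t_mat
}

#' PCA embedding of a transition matrix
#'
#' Rows of the (optionally symmetrized and row-normalized) transition
#' matrix are embedded by principal components. A linear consensus gives a
#' band-structured matrix whose first component recovers the chain order; a
#' branched path set separates the arms. Component signs are fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param t_mat Transition matrix from [transition_matrix()].
#' @param n_components Number of components to return (default 2).
#' @param symmetrize Use `t_mat + t(t_mat)` (default `TRUE`); `FALSE` keeps
#'   the directed matrix.
#' @param row_normalize Scale rows to sum 1 before PCA so each row is a
#'   transition probability distribution (default `TRUE`; zero rows kept).
#'   Without normalization the row profiles of a chain-like consensus have a
#'   nearly flat PCA spectrum and the leading component is uninformative.
#' @return N x n_components matrix of component scores.
#' @export
embed_transitions <- function(t_mat, n_components = 2,
                              symmetrize = TRUE, row_normalize = TRUE) {
  if (all(t_mat == 0)) stop("no transitions recorded")
  n <- nrow(t_mat)
  if (n < n_components + 1L) stop("too few cells for ", n_components, " components")
  m <- if (symmetrize) t_mat + t(t_mat) else t_mat
  if (row_normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  x <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) x[, j] <- -x[, j]
  }
  colnames(x) <- paste0("PC", seq_len(nc))
  x
}
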