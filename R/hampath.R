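#' Cluster cells at a given granularity k
#'
#' Hierarchical clustering of cells on the double-centered Spearman-distance
#' representation: the Spearman dissimilarity matrix is squared and doubly
#' centered (classical MDS operator) and cells are clustered on the
#' Euclidean distances between rows of that representation. Centroids are
#' arithmetic means of the member rows of the original log-expression.
#'
#' @param expr Numeric matrix, cells as rows (log scale).
#' @param k Number of clusters; 3 <= k <= N unless `allow_small`.
#' @param linkage Agglomeration method: `"average"` (default), `"complete"`
#'   or `"ward"` (mapped to `ward.D2`).
#' @param allow_small Permit k < 3 (used by tests and toy examples).
#' @param hc Optional precomputed `hclust` object from [cluster_tree()];
#'   avoids recomputing the dendrogram when cutting at many k.
#' @return List with `k`, `labels` (per-cell integer in 1..k), and
#'   `centroids` (k x M matrix).
#' @export
cluster_for_k <- function(expr, k, linkage = c("average", "complete", "ward"),
                          allow_small = FALSE, hc = NULL) {
  linkage <- match.arg(linkage)
  n <- nrow(expr)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  if (k < 3L && !allow_small) stop("k must be >= 3 (set allow_small for tests)")
  if (is.null(hc)) hc <- cluster_tree(expr, linkage)
  labels <- stats::cutree(hc, k = k)
  centroids <- rowsum(expr, labels) / as.vector(table(labels))
  list(k = k, labels = labels, centroids = centroids)
}

#' Build the cell dendrogram used by [cluster_for_k()]
#'
#' @inheritParams cluster_for_k
#' @return An `hclust` object over cells.
#' @export
cluster_tree <- function(expr, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  b <- double_center(spearman_distance(expr))
  stats::hclust(stats::dist(b), method = method)
}

#' Heuristic minimum-cost open Hamiltonian path (asymmetric)
#'
#' Modified arbitrary insertion for directed cost matrices. Each restart
#' seeds the path with a directed pair (a, b) drawn from the `top_q` largest
#' off-diagonal costs (endpoint-spread seeding), then inserts the remaining
#' nodes in random order at the position with the smallest directed
#' insertion cost: `d(u, v) + d(v, w) - d(u, w)` for an interior slot, or
#' `d(v, head)` / `d(tail, v)` at the two ends. The best-cost path over all
#' restarts is returned; ties are broken lexicographically on the order.
#'
#' @param costs n x n nonnegative matrix with zero diagonal; entries need
#'   not be symmetric.
#' @param restarts Number of randomized restarts (default 10).
#' @param seed Integer seed making the result deterministic; `NULL` uses the
#'   current RNG state.
#' @param top_q Seed pairs are sampled from the `top_q` largest directed
#'   entries (default 10).
#' @return List of class `hamiltonian_path` with `order` (1-based node
#'   indices) and `cost`.
#' @export
insertion_path <- function(costs, restarts = 10, seed = NULL, top_q = 10) {
  n <- nrow(costs)
  if (n < 2L) stop("need at least 2 nodes")
  if (any(!is.finite(costs))) stop("non-finite costs")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (n == 2L) {
    ord <- if (costs[1L, 2L] <= costs[2L, 1L]) c(1L, 2L) else c(2L, 1L)
    return(new_path(ord, costs))
  }
  off <- which(row(costs) != col(costs))
  top <- off[order(costs[off], decreasing = TRUE)][seq_len(min(top_q, length(off)))]
  best <- NULL
  for (r in seq_len(restarts)) {
    pick <- top[sample.int(length(top), 1L)]
    a <- row(costs)[pick]; b <- col(costs)[pick]
    path <- c(a, b)
    rest <- setdiff(seq_len(n), path)
    if (length(rest) > 1L) rest <- sample(rest)
    for (v in rest) {
      m <- length(path)
      # candidate slots: 0 = prepend, 1..m-1 = interior after position i, m = append
      d_head <- costs[v, path[1L]]
      d_tail <- costs[path[m], v]
      if (m > 1L) {
        u <- path[-m]; w <- path[-1L]
        d_int <- costs[u, v] + costs[v, w] - costs[cbind(u, w)]
      } else {
        d_int <- numeric(0)
      }
      deltas <- c(d_head, d_int, d_tail)
      slot <- which.min(deltas) - 1L
      path <- append(path, v, after = slot)
    }
    cand <- new_path(path, costs)
    if (is.null(best) || cand$cost < best$cost - 1e-12 ||
        (abs(cand$cost - best$cost) <= 1e-12 && lex_less(cand$order, best$order))) {
      best <- cand
    }
  }
  best
}

#' Exact minimum-cost open Hamiltonian path by enumeration
#'
#' Brute-force oracle: evaluates all n! directed orderings. Guarded to
#' n <= 9. Ties are broken lexicographically.
#'
#' @param costs n x n cost matrix (asymmetric allowed), zero diagonal.
#' @return A `hamiltonian_path` list (`order`, `cost`).
#' @export
brute_force_path <- function(costs) {
  n <- nrow(costs)
  if (n < 2L) stop("need at least 2 nodes")
  if (n > 9L) stop("brute force refused for n > 9 (n = ", n, ")")
  perms <- all_permutations(n)          # lexicographic order
  cost <- rep(0, nrow(perms))
  for (i in seq_len(n - 1L)) {
    cost <- cost + costs[cbind(perms[, i], perms[, i + 1L])]
  }
  new_path(perms[which.min(cost), ], costs)  # first minimum = lexicographic
}

# all permutations of 1..n in lexicographic row order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), i)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

new_path <- function(order, costs) {
  order <- as.integer(order)
  cost <- path_cost(order, costs)
  structure(list(order = order, cost = cost), class = "hamiltonian_path")
}

#' Total directed cost of a path
#'
#' @param order Integer permutation of node indices.
#' @param costs Directed cost matrix.
#' @return Sum of directed edge weights along consecutive pairs.
#' @export
path_cost <- function(order, costs) {
  if (length(order) < 2L) return(0)
  sum(costs[cbind(order[-length(order)], order[-1L])])
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Project a cluster-level path onto per-cell pseudotime scores
#'
#' Each cell inherits the rank position of its cluster along the path,
#' min-max scaled to \[0, 1\]; cells sharing a cluster share a score.
#'
#' @param path A `hamiltonian_path` over the k clusters of `assign`.
#' @param assign A clustering from [cluster_for_k()].
#' @return Numeric vector of per-cell scores in \[0, 1\].
#' @export
path_to_cell_scores <- function(path, assign) {
  k <- assign$k
  if (!setequal(path$order, seq_len(k))) {
    stop("path must visit exactly the ", k, " clusters of the assignment")
  }
  pos <- match(seq_len(k), path$order)   # rank of each cluster along the path
  s <- (pos - 1) / max(1L, k - 1L)
  out <- s[assign$labels]
  names(out) <- names(assign$labels)
  out
}
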