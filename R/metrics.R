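#' Change index (CI) of an ordering against ordered stage labels
#'
#' Counts the adjacent positions whose stage labels differ (`s`) along the
#' ordering and maps the count to \[0, 1\]: a block-contiguous ordering
#' (s = ns - 1) scores 1 and a maximally alternating ordering (s = N - 1)
#' scores 0, via `CI = 1 - (s - ns + 1) / (N - ns)`. The historically
#' printed variant `1 - (s - ns - 1)/(N - ns)` (which exceeds 1 at the
#' perfect ordering) is available with `as_printed`. The count of adjacent
#' changes is invariant under reversal, so no direction selection is
#' needed.
#'
#' @param order Integer permutation of 1..N giving the inferred ordering.
#' @param labels Integer (or factor) stage label per cell, stages coded in
#'   developmental order.
#' @param as_printed Use the uncorrected formula.
#' @return CI in \[0, 1\] (clamped).
#' @export
change_index <- function(order, labels, as_printed = FALSE) {
  labels <- as_stage_int(labels)
  n <- length(labels)
  ns <- length(unique(labels))
  if (n <= ns) stop("need more cells than stages")
  lab <- labels[order]
  s <- sum(diff(lab) != 0)
  ci <- if (as_printed) 1 - (s - ns - 1) / (n - ns) else 1 - (s - ns + 1) / (n - ns)
  if (as_printed) ci else min(1, max(0, ci))
}

#' Bubble sort index (BI) of an ordering
#'
#' `s` is the number of cross-stage inversions (pairs placed against the
#' stage order; within-stage order is free) and `S` the total number of
#' cross-stage pairs (the inversion count of the fully reversed ordering).
#' `BI = 1 - s/S`, and the better of the ordering and its reverse is
#' reported unless `signed`.
#'
#' @inheritParams change_index
#' @param signed Return `1 - s/S` for the ordering as given (no direction
#'   selection).
#' @return BI in \[0, 1\].
#' @export
bubble_sort_index <- function(order, labels, signed = FALSE) {
  inv <- stage_inversions(order, labels)
  bi <- 1 - inv$s / inv$S
  if (signed) bi else max(bi, 1 - bi)
}

#' Pseudo-temporal ordering score (POS)
#'
#' Concordance of cross-stage pairs: (concordant - discordant) / total
#' cross-stage pairs, which equals `2 * BI - 1` under this package's
#' definitions. Direction-selected unless `signed`.
#'
#' @inheritParams bubble_sort_index
#' @return POS in \[-1, 1\] (signed) or \[0, 1\] (direction-selected).
#' @export
pos_score <- function(order, labels, signed = FALSE) {
  2 * bubble_sort_index(order, labels, signed = signed) - 1
}

stage_inversions <- function(order, labels) {
  labels <- as_stage_int(labels)
  if (length(order) < 2L) stop("need at least 2 cells")
  stages <- sort(unique(labels))
  if (length(stages) < 2L) stop("need at least 2 stages present")
  lab <- labels[order]
  counts <- table(factor(labels, levels = stages))
  total <- (length(lab)^2 - sum(counts^2)) / 2
  # s: pairs (i before j) with stage(i) > stage(j); O(N * ns) sweep
  seen <- setNames(rep(0, length(stages)), stages)
  s <- 0
  for (l in lab) {
    higher <- seen[as.character(stages[stages > l])]
    s <- s + sum(higher)
    seen[as.character(l)] <- seen[as.character(l)] + 1
  }
  list(s = s, S = total)
}

as_stage_int <- function(labels) {
  if (is.factor(labels)) as.integer(labels) else as.integer(labels)
}

#' Kendall correlation between pseudotime and stage labels
#'
#' Tie-corrected Kendall tau-b; the absolute value is reported by default
#' because the global direction of a consensus ordering is arbitrary. Note
#' that with an untied pseudotime and tied stage labels tau-b cannot reach
#' 1: its ceiling is `sqrt((n0 - n2) / n0)` where `n0` is the number of
#' cell pairs and `n2` the number of same-stage pairs.
#'
#' @param pt Numeric pseudotime vector.
#' @param labels Stage labels in developmental order (integer or factor).
#' @param signed Return the signed tau-b.
#' @return Correlation in \[0, 1\] (or \[-1, 1\] if signed).
#' @export
kendall_correlation <- function(pt, labels, signed = FALSE) {
  labels <- as_stage_int(labels)
  if (length(pt) != length(labels)) stop("length mismatch")
  if (stats::sd(pt) == 0) stop("constant pseudotime")
  if (length(unique(labels)) < 2L) stop("constant labels")
  tau <- stats::cor(pt, labels, method = "kendall")  # tau-b (tie-corrected)
  if (signed) tau else abs(tau)
}

#' Evaluate a pseudotime against ordered stage labels
#'
#' Computes all four ordering metrics: change index (CI), bubble sort index
#' (BI), Kendall correlation (KC) and POS.
#'
#' @param pt Numeric pseudotime vector (sorting it gives the ordering).
#' @param labels Stage labels in developmental order.
#' @return Data frame with columns `metric` and `value`.
#' @export
evaluate_ordering <- function(pt, labels) {
  ord <- order(pt)
  data.frame(
    metric = c("CI", "BI", "KC", "POS"),
    value = c(change_index(ord, labels),
              bubble_sort_index(ord, labels),
              kendall_correlation(pt, labels),
              pos_score(ord, labels)),
    stringsAsFactors = FALSE
  )
}

#' Mean silhouette width of a labelled embedding
#'
#' Small self-contained silhouette computation (Euclidean distances) used
#' to quantify how well an embedding separates groups, e.g. the two arms of
#' a branching trajectory in the transition-matrix PCA.
#'
#' @param x Numeric matrix of coordinates (rows = points).
#' @param labels Group label per row (>= 2 groups, each of size >= 1).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_width <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    a <- if (length(same)) mean(d[i, same]) else 0
    b <- min(vapply(levels(labels)[levels(labels) != labels[i]], function(l) {
      mean(d[i, labels == l])
    }, numeric(1L)))
    sil[i] <- if (length(same)) (b - a) / max(a, b) else 0
  }
  mean(sil)
}
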