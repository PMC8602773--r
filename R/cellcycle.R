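#' Per-cell cell-cycle phase scores
#'
#' Mean log-expression per cell over each of six phase gene lists
#' (G1, S, G1/S, G2, M, G2/M), e.g. Cyclebase-derived annotations.
#' Duplicate genes inside a list count once; genes absent from the matrix
#' are ignored, but a phase whose list has no overlap at all is an error.
#'
#' @param expr Numeric matrix, cells as rows (log scale).
#' @param phase_sets Named list of six character vectors of gene ids; the
#'   names are the phase labels.
#' @return N x 6 numeric matrix of phase scores (rows = cells).
#' @export
phase_scores <- function(expr, phase_sets) {
  if (length(phase_sets) != 6L) stop("expected 6 phase gene sets, got ",
                                     length(phase_sets))
  if (is.null(names(phase_sets))) {
    names(phase_sets) <- c("G1", "S", "G1S", "G2", "M", "G2M")
  }
  out <- vapply(names(phase_sets), function(ph) {
    genes <- intersect(unique(phase_sets[[ph]]), colnames(expr))
    if (length(genes) == 0L) {
      stop("phase '", ph, "' has no genes in the expression matrix")
    }
    rowMeans(expr[, genes, drop = FALSE])
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Detect quiescent (G0-like) cells from phase scores
#'
#' k-means (k = 5 by default, for G0/G1/S/G2/M) partitions cells on the six
#' phase scores; the cluster with the lowest grand mean across scores is
#' the G0 candidate. For every score and every other cluster a one-sided
#' test (candidate lower) is run; the candidate is declared G0 only if all
#' `6 * (k - 1)` comparisons reach `P < alpha`. No multiple-testing
#' correction is applied (the criterion is a raw P threshold by design).
#'
#' @param scores Phase-score matrix from [phase_scores()].
#' @param alpha Per-test significance threshold (default 0.001).
#' @param k Number of k-means clusters (default 5).
#' @param seed Seed for k-means.
#' @param method `"welch"` (one-sided Welch two-sample t-test, default) or
#'   `"classic_anova"` (two-group one-way ANOVA, two-sided).
#' @param compare `"per_cluster"` (candidate vs each other cluster,
#'   default) or `"pooled"` (candidate vs all remaining cells pooled).
#' @return List of class `g0_report`: `g0_cell_ids` (empty unless all tests
#'   pass), `candidate_cluster`, `is_g0` (logical per cell), `p_values`
#'   (scores x comparisons), `cluster` (k-means label per cell).
#' @export
detect_g0 <- function(scores, alpha = 0.001, k = 5, seed = 1,
                      method = c("welch", "classic_anova"),
                      compare = c("per_cluster", "pooled")) {
  method <- match.arg(method)
  compare <- match.arg(compare)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L * k) warning("fewer than 2k cells; k-means may be unstable")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  km <- NULL
  for (attempt in 1:10) {
    km <- tryCatch(stats::kmeans(scores, centers = k, nstart = 10),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0L)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " non-empty clusters")
  grand <- rowMeans(km$centers)
  cand <- which.min(grand)
  others <- if (compare == "per_cluster") setdiff(seq_len(k), cand) else "pooled"
  p <- matrix(NA_real_, nrow = ncol(scores), ncol = length(others),
              dimnames = list(colnames(scores), as.character(others)))
  for (j in seq_len(ncol(scores))) {
    xc <- scores[km$cluster == cand, j]
    for (oi in seq_along(others)) {
      xo <- if (identical(others[oi], "pooled")) {
        scores[km$cluster != cand, j]
      } else {
        scores[km$cluster == others[oi], j]
      }
      p[j, oi] <- if (method == "welch") {
        tryCatch(stats::t.test(xc, xo, alternative = "less")$p.value,
                 error = function(e) 1)
      } else {
        g <- factor(rep(c("cand", "other"), c(length(xc), length(xo))))
        tryCatch(stats::oneway.test(c(xc, xo) ~ g, var.equal = TRUE)$p.value,
                 error = function(e) 1)
      }
    }
  }
  all_sig <- all(p < alpha)
  is_g0 <- if (all_sig) km$cluster == cand else rep(FALSE, n)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(g0_cell_ids = ids[is_g0],
                 candidate_cluster = unname(cand),
                 is_g0 = is_g0,
                 p_values = p,
                 cluster = km$cluster),
            class = "g0_report")
}

#' 3D spiral coordinates coupling cycle and differentiation pseudotime
#'
#' Projects the cell-cycle pseudotime onto the unit circle
#' (`x = cos(2*pi*t)`, `y = sin(2*pi*t)`) and uses the differentiation
#' pseudotime as the z axis, giving the spiral layout that couples the two
#' processes.
#'
#' @param cycle_pt Per-cell cycle pseudotime in \[0, 1); values outside are
#'   wrapped modulo 1 with a warning.
#' @param diff_pt Per-cell differentiation pseudotime.
#' @return Data frame with columns `x`, `y`, `z` (one row per cell).
#' @export
spiral_coordinates <- function(cycle_pt, diff_pt) {
  if (length(cycle_pt) != length(diff_pt)) stop("length mismatch")
  if (any(cycle_pt < 0 | cycle_pt >= 1)) {
    warning("cycle pseudotime outside [0, 1); wrapping modulo 1")
    cycle_pt <- cycle_pt %% 1
  }
  data.frame(x = cos(2 * pi * cycle_pt),
             y = sin(2 * pi * cycle_pt),
             z = diff_pt)
}
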