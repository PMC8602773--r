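#' Simulate a linear multi-stage differentiation trajectory
#'
#' Generates a log-scale expression matrix along a latent pseudotime:
#' monotone genes rise (or fall) linearly with pseudotime, switch-like
#' genes turn on or off at a random stage boundary via a steep sigmoid, and
#' the remaining genes are stationary noise. Gaussian noise is added on the
#' log scale, then low values are zeroed with probability `dropout_p`
#' (thresholded dropout), and negatives are clipped at 0. Stage labels are
#' equal quantile bins of the latent pseudotime. Fully deterministic given
#' `seed`.
#'
#' @param n_cells,n_stages,n_genes Fixture dimensions (defaults 150 / 3 /
#'   300).
#' @param frac_monotone,frac_switch Fractions of monotone and switch-like
#'   genes (defaults 0.3 each; remainder are noise genes).
#' @param noise_sd Gaussian noise sd on the log scale (default 0.5).
#' @param dropout_p Probability of zeroing a value below the dropout
#'   threshold (default 0.2).
#' @param dropout_threshold Log-expression level below which dropout can
#'   occur (default 2).
#' @param seed Integer seed.
#' @return List of class `trajectory_fixture`: `expr` (cells x genes, log
#'   scale, nonnegative), `true_pt` (latent pseudotime in \[0, 1\]),
#'   `true_stage` (integer 1..n_stages, monotone in `true_pt`),
#'   `gene_type` (per gene: monotone/switch/noise).
#' @export
simulate_linear <- function(n_cells = 150, n_stages = 3, n_genes = 300,
                            frac_monotone = 0.3, frac_switch = 0.3,
                            noise_sd = 0.5, dropout_p = 0.2,
                            dropout_threshold = 2, seed = 7) {
  if (frac_monotone + frac_switch > 1) stop("gene fractions exceed 1")
  if (n_stages < 2L) stop("need at least 2 stages")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  pt <- stats::runif(n_cells)
  stage <- as.integer(cut(pt, stats::quantile(pt, seq(0, 1, length.out = n_stages + 1)),
                          include.lowest = TRUE, labels = FALSE))
  n_mono <- round(n_genes * frac_monotone)
  n_switch <- round(n_genes * frac_switch)
  n_noise <- n_genes - n_mono - n_switch
  gene_type <- rep(c("monotone", "switch", "noise"),
                   c(n_mono, n_switch, n_noise))

  expr <- matrix(0, n_cells, n_genes)
  for (j in seq_len(n_genes)) {
    expr[, j] <- switch(
      gene_type[j],
      monotone = {
        a <- stats::runif(1, 3, 8) * sample(c(-1, 1), 1)
        b <- stats::runif(1, 0, 2)
        base <- a * pt + b
        if (a < 0) base <- base - a   # keep the clean signal nonnegative
        base
      },
      switch = {
        boundary <- sample(seq_len(n_stages - 1L), 1) / n_stages
        amp <- stats::runif(1, 3, 8)
        direction <- sample(c(-1, 1), 1)
        s <- amp / (1 + exp(-(pt - boundary) / 0.05))
        if (direction < 0) amp - s else s
      },
      noise = stats::runif(1, 0, 4)
    )
  }
  expr <- expr + matrix(stats::rnorm(n_cells * n_genes, sd = noise_sd),
                        n_cells, n_genes)
  drop_mask <- expr < dropout_threshold &
    matrix(stats::runif(n_cells * n_genes) < dropout_p, n_cells, n_genes)
  expr[drop_mask] <- 0
  expr[expr < 0] <- 0
  dimnames(expr) <- list(sprintf("cell_%03d", seq_len(n_cells)),
                         sprintf("gene_%03d", seq_len(n_genes)))
  structure(list(expr = expr, true_pt = pt, true_stage = stage,
                 gene_type = gene_type),
            class = "trajectory_fixture")
}

#' Simulate a branching trajectory
#'
#' Same construction as [simulate_linear()], but cells with pseudotime past
#' `branch_at` are split into two arms (balanced Bernoulli assignment) with
#' disjoint arm-specific marker programs: half of the switch genes turn on
#' past the branch point only in arm 1, the other half only in arm 2.
#'
#' @inheritParams simulate_linear
#' @param branch_at Pseudotime of the branch point, in (0, 1).
#' @return A `trajectory_fixture` with an extra `branch_id` field (0 before
#'   the branch, 1 or 2 on the arms).
#' @export
simulate_branch <- function(n_cells = 150, n_stages = 3, n_genes = 300,
                            frac_monotone = 0.3, frac_switch = 0.3,
                            noise_sd = 0.5, dropout_p = 0.2,
                            dropout_threshold = 2, branch_at = 0.5, seed = 7) {
  if (branch_at <= 0 || branch_at >= 1) stop("branch_at must be in (0, 1)")
  fix <- simulate_linear(n_cells, n_stages, n_genes, frac_monotone,
                         frac_switch, noise_sd = 0, dropout_p = 0,
                         dropout_threshold = dropout_threshold, seed = seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed + 104729)   # independent stream for the branch layer

  pt <- fix$true_pt
  post <- pt > branch_at
  branch_id <- integer(n_cells)
  branch_id[post] <- sample(1:2, sum(post), replace = TRUE)
  sw <- which(fix$gene_type == "switch")
  arm1 <- sw[seq_len(floor(length(sw) / 2))]
  arm2 <- setdiff(sw, arm1)
  expr <- fix$expr
  # arm markers: strong sigmoid activation past the branch, own arm only
  for (j in c(arm1, arm2)) {
    arm <- if (j %in% arm1) 1L else 2L
    amp <- stats::runif(1, 4, 8)
    act <- amp / (1 + exp(-(pt - branch_at) / 0.05))
    on_cells <- branch_id == arm
    expr[, j] <- 0
    expr[on_cells, j] <- act[on_cells]
  }
  expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                        nrow(expr), ncol(expr))
  drop_mask <- expr < dropout_threshold &
    matrix(stats::runif(length(expr)) < dropout_p, nrow(expr), ncol(expr))
  expr[drop_mask] <- 0
  expr[expr < 0] <- 0
  fix$expr <- expr
  fix$branch_id <- branch_id
  fix
}

#' Simulate cell-cycle phase-score fixtures
#'
#' Draws the six phase scores from `N(mu_cycling, sd)` for cycling cells
#' and `N(mu_g0, sd)` for quiescent cells, recording the ground-truth mask.
#'
#' @param n_cycling,n_g0 Group sizes.
#' @param mu_cycling,mu_g0 Group means (must satisfy
#'   `mu_cycling > mu_g0`).
#' @param sd Common standard deviation.
#' @param seed Integer seed.
#' @return List: `scores` (cells x 6 matrix), `true_g0_mask` (logical).
#' @export
simulate_cycle_scores <- function(n_cycling = 40, n_g0 = 20,
                                  mu_cycling = 5, mu_g0 = 1,
                                  sd = 0.2, seed = 2) {
  if (mu_cycling <= mu_g0) stop("mu_cycling must exceed mu_g0")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n <- n_cycling + n_g0
  mask <- c(rep(FALSE, n_cycling), rep(TRUE, n_g0))
  mu <- ifelse(mask, mu_g0, mu_cycling)
  scores <- matrix(stats::rnorm(n * 6, mean = mu, sd = sd), n, 6)
  scores[scores < 0] <- 0
  dimnames(scores) <- list(sprintf("cell_%03d", seq_len(n)),
                           c("G1", "S", "G1S", "G2", "M", "G2M"))
  list(scores = scores, true_g0_mask = mask)
}
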