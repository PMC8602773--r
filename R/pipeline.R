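#' Run the full pseudotime pipeline
#'
#' End-to-end driver: load (or accept) an expression matrix, log-transform,
#' restrict to a development-associated gene set, dispersion-filter, infer
#' the consensus pseudotime, build the transition matrix and PCA embedding,
#' rank genes and fit per-gene hidden-state tracks, and, when the optional
#' inputs are present, evaluate against stage labels and run G0 detection /
#' spiral coupling. All tabular outputs are written as UTF-8 TSV into
#' `out_dir` together with an echo of the configuration.
#'
#' @param expr Numeric matrix (cells x genes) or path to a TSV/CSV/MTX file.
#' @param out_dir Output directory (created if needed).
#' @param orientation Disk orientation when `expr` is a path.
#' @param gene_set Character vector of gene ids, or path to a plain list /
#'   GMT file (first set used); `NULL` skips gene-set selection.
#' @param already_log Input is already on log2 scale.
#' @param disp_cutoff Dispersion-filter cutoff (default 10); `NULL` skips
#'   the filter.
#' @param k_ref,k_merge,restarts,seed,root_cell Passed to
#'   [consensus_pseudotime()]. `k_merge = NULL` means `max(k_ref)..N`.
#' @param score_threshold dCor/MIC selection threshold (default 0.5).
#' @param n_states Hidden states per gene (2 or 3).
#' @param labels Optional per-cell stage labels (vector, or path to a
#'   two-column TSV cell_id/stage) for evaluation; stage order is the
#'   sorted unique order unless a factor is supplied.
#' @param phase_sets Optional named list of six phase gene lists (or GMT
#'   path) enabling G0 detection.
#' @param cycle_pt Optional per-cell cycle pseudotime in \[0, 1) (vector or
#'   single-column TSV path) enabling the spiral export.
#' @param g0_alpha Significance threshold for G0 detection.
#' @return (Invisibly) a list with the in-memory results: `pseudotime`,
#'   `fit`, `transition`, `embedding`, `gene_scores`, `tracks`, `modules`,
#'   plus `evaluation`, `g0`, `spiral` when computed.
#' @export
run_pipeline <- function(expr, out_dir,
                         orientation = "cells_by_genes",
                         gene_set = NULL, already_log = TRUE,
                         disp_cutoff = 10,
                         k_ref = 3:7, k_merge = NULL, restarts = 10,
                         seed = 1, root_cell = NULL,
                         score_threshold = 0.5, n_states = 2,
                         labels = NULL, phase_sets = NULL, cycle_pt = NULL,
                         g0_alpha = 0.001) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage_wrap <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logf(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }

  mat <- stage_wrap("load", {
    if (is.character(expr)) read_expression(expr, orientation) else expr
  })
  mat <- stage_wrap("preprocess", {
    m <- log_transform(mat, already_log = already_log)
    if (!is.null(gene_set)) {
      gs <- if (is.character(gene_set) && length(gene_set) == 1L &&
                file.exists(gene_set)) {
        if (tolower(tools::file_ext(gene_set)) == "gmt") {
          read_gmt(gene_set)[[1L]]
        } else read_gene_list(gene_set)
      } else gene_set
      m <- select_gene_set(m, gs)
    }
    if (!is.null(disp_cutoff)) m <- dispersion_filter(m, cutoff = disp_cutoff)
    m
  })

  fit <- stage_wrap("pseudotime", {
    consensus_pseudotime(mat, k_ref = k_ref, k_merge = k_merge,
                         restarts = restarts, seed = seed,
                         root_cell = root_cell)
  })
  pt <- fit$scores
  write_tsv(data.frame(cell_id = names(pt), score = pt, rank = rank(pt)),
            file.path(out_dir, "pseudotime.tsv"))

  t_mat <- stage_wrap("transitions", {
    transition_matrix(fit$paths, fit$assignments, n_cells = nrow(mat))
  })
  emb <- embed_transitions(t_mat)
  utils::write.table(t_mat, file.path(out_dir, "transition_matrix.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = rownames(mat) %||% FALSE)
  write_tsv(data.frame(cell_id = rownames(mat) %||% seq_len(nrow(mat)),
                       PC1 = emb[, 1L], PC2 = emb[, 2L]),
            file.path(out_dir, "embedding.tsv"))

  gene_scores <- stage_wrap("genes", rank_genes(mat, pt, threshold = score_threshold))
  write_tsv(gene_scores, file.path(out_dir, "gene_scores.tsv"))

  kept <- gene_scores$gene_id[gene_scores$kept]
  tracks <- NULL; modules <- NULL
  if (length(kept) >= 2L) {
    ord <- order(pt)
    tracks <- stage_wrap("hmm", {
      ts <- lapply(kept, function(g) fit_gene_hmm(mat[ord, g], n_states = n_states))
      names(ts) <- kept
      ts
    })
    modules <- order_gene_modules(tracks)
    states <- modules$states
    colnames(states) <- names(pt)[ord]
    utils::write.table(states, file.path(out_dir, "gene_states.tsv"),
                       sep = "\t", quote = FALSE)
    write_tsv(data.frame(gene_id = names(modules$modules),
                         module = modules$modules),
              file.path(out_dir, "modules.tsv"))
  } else {
    logf("hmm", "skipped: fewer than 2 genes passed the score threshold")
  }

  res <- list(pseudotime = pt, fit = fit, transition = t_mat,
              embedding = emb, gene_scores = gene_scores,
              tracks = tracks, modules = modules)

  if (!is.null(labels)) {
    lab <- if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      tab <- utils::read.delim(labels, header = TRUE)
      stats::setNames(tab[[2L]], tab[[1L]])[names(pt)]
    } else labels
    res$evaluation <- stage_wrap("evaluate", {
      ev <- evaluate_ordering(pt, stage_to_int(lab))
      write_tsv(ev, file.path(out_dir, "evaluation.tsv"))
      ev
    })
  }

  if (!is.null(phase_sets)) {
    ps <- if (is.character(phase_sets) && length(phase_sets) == 1L) {
      read_gmt(phase_sets)
    } else phase_sets
    res$g0 <- stage_wrap("g0", {
      sc <- phase_scores(mat, ps)
      write_tsv(data.frame(cell_id = rownames(sc), sc, check.names = FALSE),
                file.path(out_dir, "phase_scores.tsv"))
      rep_ <- detect_g0(sc, alpha = g0_alpha, seed = seed)
      write_tsv(data.frame(cell_id = rownames(sc), is_g0 = rep_$is_g0,
                           cluster = rep_$cluster),
                file.path(out_dir, "g0_report.tsv"))
      rep_
    })
  }

  if (!is.null(cycle_pt)) {
    cp <- if (is.character(cycle_pt) && length(cycle_pt) == 1L) {
      tab <- utils::read.delim(cycle_pt, header = TRUE)
      as.numeric(tab[[ncol(tab)]])
    } else cycle_pt
    res$spiral <- stage_wrap("spiral", {
      sp <- spiral_coordinates(cp, pt)
      write_tsv(data.frame(cell_id = names(pt), sp),
                file.path(out_dir, "spiral.tsv"))
      sp
    })
  }

  cfg <- list(orientation = orientation, already_log = already_log,
              disp_cutoff = disp_cutoff, k_ref = paste(range(k_ref), collapse = ":"),
              restarts = restarts, seed = seed,
              score_threshold = score_threshold, n_states = n_states,
              g0_alpha = g0_alpha)
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(as.character(v), collapse = ","), character(1L)), sep = " = "),
    file.path(out_dir, "run_config.txt"))
  logf("done", "all outputs written to ", out_dir)
  invisible(res)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map arbitrary stage labels to integers following sorted-unique (or factor
# level) order
stage_to_int <- function(lab) {
  if (is.factor(lab)) return(as.integer(lab))
  if (is.numeric(lab)) return(as.integer(lab))
  as.integer(factor(lab, levels = unique(sort(lab))))
}
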