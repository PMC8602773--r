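#' Read an expression matrix from disk
#'
#' Reads a dense TSV/CSV table (header row, first column holds identifiers)
#' or a MatrixMarket triplet file with plain-text row/column identifier
#' sidecars, and returns a cells-as-rows numeric matrix regardless of the
#' on-disk orientation.
#'
#' @param path Path to a `.tsv`/`.txt` (tab), `.csv` (comma) or `.mtx`
#'   (MatrixMarket triplet) file.
#' @param orientation Either `"cells_by_genes"` (rows on disk are cells) or
#'   `"genes_by_cells"` (rows on disk are genes; the matrix is transposed
#'   after reading).
#' @param genes,barcodes For MTX input only: paths to one-id-per-line text
#'   files naming the rows and columns of the triplet file. Default to
#'   `genes.txt` and `barcodes.txt` next to `path`.
#' @return A numeric matrix with cells as rows (rownames = cell ids,
#'   colnames = gene ids). Missing MTX entries are 0. Duplicate gene ids
#'   are resolved by keeping the copy with the highest mean (with a
#'   warning); duplicate cell ids are an error.
#' @export
read_expression <- function(path,
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            genes = NULL, barcodes = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    if (is.null(genes)) genes <- file.path(dir, "genes.txt")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.txt")
    rid <- readLines(genes)
    cid <- readLines(barcodes)
    # MTX convention here: rows = genes, columns = barcodes/cells
    if (length(rid) != nrow(m) || length(cid) != ncol(m)) {
      stop("sidecar id files do not match MTX dimensions (",
           nrow(m), " x ", ncol(m), ")")
    }
    rownames(m) <- rid
    colnames(m) <- cid
    mat <- t(m)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, row.names = NULL,
                             colClasses = "character", comment.char = "")
    ids <- tab[[1L]]
    body <- tab[, -1L, drop = FALSE]
    num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    if (nrow(body) == 1L) num <- matrix(num, nrow = 1L)
    colnames(num) <- colnames(tab)[-1L]   # duplicates intact (vapply repairs)
    bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("non-numeric value at row ", bad[1L, 1L], " (id '", ids[bad[1L, 1L]],
           "'), column '", colnames(body)[bad[1L, 2L]], "'")
    }
    rownames(num) <- ids
    mat <- num
    if (orientation == "genes_by_cells") mat <- t(mat)
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop("duplicate cell ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  mat <- dedup_genes(mat)
  mat
}

# keep, for each duplicated gene id, the copy with the highest mean
dedup_genes <- function(mat) {
  g <- colnames(mat)
  if (is.null(g) || !anyDuplicated(g)) return(mat)
  warning("duplicate gene ids; keeping the copy with the highest mean")
  mu <- colMeans(mat)
  keep <- unlist(lapply(split(seq_along(g), g), function(ix) ix[which.max(mu[ix])]),
                 use.names = FALSE)
  mat[, sort(keep), drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Writes with 17 significant digits so that [read_expression()] round-trips
#' to bit-identical doubles.
#'
#' @param expr Numeric matrix, cells as rows.
#' @param path Output path.
#' @param id_column Header for the identifier column.
#' @export
write_expression <- function(expr, path, id_column = "cell_id") {
  body <- apply(expr, 2L, function(v) sprintf("%.17g", v))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(expr))
  out <- cbind(rownames(expr), body)
  colnames(out) <- c(id_column, colnames(expr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform expression values
#'
#' Applies `log2(x + 1)`, the standard transform for TPM/FPKM input.
#'
#' @param expr Numeric matrix of nonnegative values.
#' @param already_log If `TRUE` the matrix is returned unchanged (input is
#'   assumed to be on log scale already).
#' @return Matrix on log2 scale.
#' @export
log_transform <- function(expr, already_log = FALSE) {
  if (already_log) return(expr)
  if (any(expr < 0)) stop("negative expression values cannot be log-transformed")
  log2(expr + 1)
}

#' Restrict an expression matrix to a gene set
#'
#' Column-subsets the matrix to genes in `genes`, preserving the original
#' column order. Membership is case-sensitive.
#'
#' @param expr Numeric matrix, cells as rows.
#' @param genes Character vector of gene identifiers (e.g. a development-
#'   associated GO gene list).
#' @return The column subset of `expr`.
#' @export
select_gene_set <- function(expr, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set")
  keep <- colnames(expr) %in% genes
  if (!any(keep)) {
    stop("no overlap between the ", ncol(expr), " matrix genes and the ",
         length(genes), " gene-set members")
  }
  expr[, keep, drop = FALSE]
}

#' Filter genes by dispersion ratio
#'
#' Keeps genes whose dispersion statistic is at least `cutoff`. The default
#' statistic is the variance-to-mean ratio (sample variance / mean), the
#' usual scRNA-seq "dispersion"; `cv` (sd/mean) and `inv_cv` (mean/sd) are
#' available for comparison. Genes with zero mean are always dropped.
#'
#' @param expr Numeric matrix, cells as rows; needs >= 2 cells.
#' @param cutoff Minimum dispersion to keep a gene (default 10).
#' @param statistic One of `"vmr"` (variance/mean, default), `"cv"`
#'   (sd/mean), `"inv_cv"` (mean/sd).
#' @return Filtered matrix with attribute `"dispersion"` holding the
#'   per-gene statistic for all input genes (NA where the mean is 0, or the
#'   sd is 0 for `inv_cv`).
#' @export
dispersion_filter <- function(expr, cutoff = 10,
                              statistic = c("vmr", "cv", "inv_cv")) {
  statistic <- match.arg(statistic)
  if (nrow(expr) < 2L) stop("dispersion needs at least 2 cells")
  mu <- colMeans(expr)
  v <- apply(expr, 2L, stats::var)
  disp <- switch(statistic,
                 vmr = v / mu,
                 cv = sqrt(v) / mu,
                 inv_cv = mu / sqrt(v))
  disp[mu == 0] <- NA_real_
  if (statistic == "inv_cv") disp[v == 0] <- NA_real_
  keep <- !is.na(disp) & disp >= cutoff
  if (!any(keep)) {
    stop("dispersion filter removed all ", ncol(expr),
         " genes; consider a cutoff below ", cutoff)
  }
  out <- expr[, keep, drop = FALSE]
  attr(out, "dispersion") <- disp
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one element per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1L, 40L))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  out
}

#' Read a plain gene list (one id per line)
#'
#' @param path Text file path.
#' @return Character vector of unique, non-empty gene ids.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}
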