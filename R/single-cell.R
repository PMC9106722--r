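# Single-cell containers, QC, normalization, anchor-covariance shift,
# transgene census and pseudobulk/bulk concordance.

#' Construct a single-cell count matrix
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse).
#' @param genes Character vector of gene ids (rows).
#' @param cells Character vector of cell barcodes (columns).
#' @param cell_labels Population label per cell.
#' @param condition Condition tag for the whole matrix.
#' @param mito_genes Optional logical mask (per gene) of mitochondrial
#'   genes; default: ids with a case-insensitive `mt-` prefix.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, genes, cells, cell_labels,
                        condition = "condition1", mito_genes = NULL) {
  if (!methods::is(counts, "CsparseMatrix"))
    counts <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                          "CsparseMatrix")
  counts <- methods::as(counts, "dMatrix")
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells))
    stop_pausekit("counts dimensions do not match genes/cells")
  if (length(cell_labels) != length(cells))
    stop_pausekit("cell_labels must cover all cells")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop_pausekit("counts must be non-negative integers")
  if (anyDuplicated(genes)) stop_pausekit("duplicate gene ids")
  if (is.null(mito_genes)) mito_genes <- grepl("^mt-", genes, ignore.case = TRUE)
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, genes = as.character(genes),
                 cells = as.character(cells),
                 cell_labels = as.character(cell_labels),
                 condition = condition, mito_genes = mito_genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells (%s)\n",
              length(x$genes), length(x$cells), x$condition))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

subset_cells <- function(mat, keep) {
  cell_matrix(mat$counts[, keep, drop = FALSE], mat$genes,
              mat$cells[keep], mat$cell_labels[keep],
              condition = mat$condition, mito_genes = mat$mito_genes)
}

#' Quality-control filter on cells
#'
#' A cell is excluded when it has fewer than `min_genes` genes with UMI > 0
#' or more than `max_mito_fraction` of its UMIs from mitochondrial genes;
#' boundary cells (exactly at either threshold) are kept.
#'
#' @param mat A [cell_matrix].
#' @param min_genes Minimum detected genes (default 200).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (default 0.80).
#' @return A list: `matrix` (filtered [cell_matrix]) and `report` (data
#'   frame of removed barcodes with `reason` `low_genes`, `high_mito` or
#'   both, `;`-separated).
#' @export
qc_filter_cells <- function(mat, min_genes = 200L, max_mito_fraction = 0.80) {
  detected <- Matrix::colSums(mat$counts > 0)
  total <- Matrix::colSums(mat$counts)
  mito <- if (any(mat$mito_genes))
    Matrix::colSums(mat$counts[mat$mito_genes, , drop = FALSE]) else
    numeric(length(total))
  mito_frac <- ifelse(total > 0, mito / total, 1)
  low <- detected < min_genes
  high <- mito_frac > max_mito_fraction
  drop <- low | high
  if (all(drop)) stop_pausekit("QC removed every cell")
  reason <- paste0(ifelse(low, "low_genes", ""),
                   ifelse(low & high, ";", ""),
                   ifelse(high, "high_mito", ""))
  report <- data.frame(barcode = mat$cells[drop], reason = reason[drop],
                       detected_genes = as.integer(detected[drop]),
                       mito_fraction = mito_frac[drop],
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(matrix = subset_cells(mat, !drop), report = report)
}

#' Total-count normalization per cell
#'
#' Each cell is scaled to `scale_total` summed counts; optionally `log(1+x)`
#' transformed.
#'
#' @param mat A [cell_matrix] (every cell total must be positive).
#' @param scale_total Target per-cell total (default 10000).
#' @param log_transform Apply `log1p` after scaling.
#' @return A sparse genes x cells matrix with attributes `scale_total` and
#'   `logged` recording the expression scale.
#' @export
normalize_cells <- function(mat, scale_total = 10000, log_transform = FALSE) {
  total <- Matrix::colSums(mat$counts)
  if (any(total <= 0))
    stop_pausekit(sprintf("zero-total cell(s): %s",
                          paste(mat$cells[total <= 0], collapse = ", ")))
  x <- mat$counts %*% Matrix::Diagonal(x = scale_total / total)
  dimnames(x) <- dimnames(mat$counts)
  if (log_transform) x <- log1p(x)
  x <- methods::as(x, "CsparseMatrix")
  attr(x, "scale_total") <- scale_total
  attr(x, "logged") <- log_transform
  x
}

#' Anchor-gene covariance shift between conditions
#'
#' For every gene, the sample covariance (n-1 denominator) with the anchor
#' gene is computed across the selected cells of each condition on
#' total-count-normalized (by default un-logged) expression; the shift is
#' `cov(condition 1) - cov(condition 2)` and genes whose absolute shift
#' exceeds `threshold` are flagged.
#'
#' @param mat1,mat2 [cell_matrix] objects for the two conditions.
#' @param anchor Anchor gene id (must be present in both).
#' @param threshold Absolute covariance-difference flagging threshold
#'   (default 30, on the normalized expression scale).
#' @param populations Optional character vector restricting cells to these
#'   population labels (e.g. the luminal subset).
#' @param normalize Total-count-normalize each cell before the covariance
#'   (default); `FALSE` uses raw counts.
#' @param scale_total,log_transform Expression scale, recorded in the output
#'   attributes.
#' @return A data frame of class `covariance_shift`: `gene_id`,
#'   `cov_condition1`, `cov_condition2`, `delta_cov`, `flagged`; attributes
#'   record the scale and cell counts.
#' @export
anchor_covariance_shift <- function(mat1, mat2, anchor, threshold = 30,
                                    populations = NULL, normalize = TRUE,
                                    scale_total = 10000,
                                    log_transform = FALSE) {
  for (m in list(mat1, mat2))
    if (!anchor %in% m$genes)
      stop_pausekit(sprintf("anchor gene %s absent from a condition", anchor))
  shared <- intersect(mat1$genes, mat2$genes)
  pick <- function(mat) {
    keep <- if (is.null(populations)) rep(TRUE, length(mat$cells))
            else mat$cell_labels %in% populations
    if (sum(keep) < 3L)
      stop_pausekit("fewer than 3 cells after population masking")
    subset_cells(mat, keep)
  }
  covs <- function(mat) {
    x <- if (normalize)
      normalize_cells(mat, scale_total = scale_total,
                      log_transform = log_transform)
    else mat$counts
    x <- x[shared, , drop = FALSE]
    a <- as.numeric(x[anchor, ])
    n <- length(a)
    ac <- a - mean(a)
    as.numeric(x %*% ac) / (n - 1)
  }
  m1 <- pick(mat1); m2 <- pick(mat2)
  c1 <- covs(m1); c2 <- covs(m2)
  delta <- c1 - c2
  out <- data.frame(gene_id = shared, cov_condition1 = c1,
                    cov_condition2 = c2, delta_cov = delta,
                    flagged = abs(delta) > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "scale_total") <- if (normalize) scale_total else NA_real_
  attr(out, "logged") <- log_transform
  attr(out, "expression_scale") <-
    if (!normalize) "counts"
    else paste0("per-", format(scale_total, scientific = FALSE),
                if (log_transform) " log1p" else "")
  attr(out, "threshold") <- threshold
  attr(out, "n_cells") <- c(ncol(m1$counts), ncol(m2$counts))
  class(out) <- c("covariance_shift", "data.frame")
  out
}

#' Transgene-positive cell census per population
#'
#' @param mat A [cell_matrix].
#' @param transgene Transgene id; a cell is positive when its UMI count is
#'   greater than 0.
#' @return Data frame: `population`, `n_cells`, `n_positive`,
#'   `percent_positive` (rounded to one decimal), sorted by population.
#' @examples
#' # 93 basal cells of which 17 transgene-positive -> 18.3%
#' @export
transgene_census <- function(mat, transgene) {
  if (!transgene %in% mat$genes)
    stop_pausekit(sprintf("transgene %s absent from gene list", transgene))
  pos <- as.numeric(mat$counts[transgene, ]) > 0
  pops <- sort(unique(mat$cell_labels))
  n_cells <- vapply(pops, function(p) sum(mat$cell_labels == p), 0L)
  n_pos <- vapply(pops, function(p) sum(pos[mat$cell_labels == p]), 0L)
  data.frame(population = pops, n_cells = as.integer(n_cells),
             n_positive = as.integer(n_pos),
             percent_positive = round(100 * n_pos / n_cells, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pseudobulk vs bulk expression concordance
#'
#' Sums UMIs over all cells per gene and correlates `log(sc_sum + 1)` with
#' `log(bulk + 1)` (Pearson) over genes expressed (> 0) in both assays; a
#' gene is "expressed" in an assay when its count there is greater than 0.
#'
#' @param mat A [cell_matrix].
#' @param bulk_counts Named numeric vector (or data frame with `gene_id`,
#'   `count`) of bulk raw read counts.
#' @return A list: `r` (Pearson correlation on the log scale), `n_both`,
#'   `n_sc_only`, `n_bulk_only`, `n_shared` (gene universe after
#'   intersection).
#' @export
pseudobulk_concordance <- function(mat, bulk_counts) {
  if (is.data.frame(bulk_counts))
    bulk_counts <- setNames(bulk_counts$count, bulk_counts$gene_id)
  shared <- intersect(mat$genes, names(bulk_counts))
  if (length(shared) < 10L)
    stop_pausekit("fewer than 10 shared genes between sc and bulk")
  sc_sum <- Matrix::rowSums(mat$counts[shared, , drop = FALSE])
  bulk <- as.numeric(bulk_counts[shared])
  sc_on <- sc_sum > 0; bk_on <- bulk > 0
  both <- sc_on & bk_on
  r <- stats::cor(log(sc_sum[both] + 1), log(bulk[both] + 1),
                  method = "pearson")
  list(r = r, n_both = sum(both), n_sc_only = sum(sc_on & !bk_on),
       n_bulk_only = sum(!sc_on & bk_on), n_shared = length(shared))
}

#' Write a cell matrix as MatrixMarket + genes/barcodes/labels TSVs
#'
#' @param mat A [cell_matrix].
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`, `labels.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- mat$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(mat$genes, file.path(dir, "genes.tsv"))
  writeLines(mat$cells, file.path(dir, "barcodes.tsv"))
  write_tsv(data.frame(barcode = mat$cells, population = mat$cell_labels),
            file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read a cell matrix written by [write_cell_matrix()]
#'
#' @param dir Directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#'   optionally `labels.tsv`.
#' @param condition Condition tag to attach.
#' @return A [cell_matrix].
#' @export
read_cell_matrix <- function(dir, condition = "condition1") {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  lab_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(lab_path)) {
    lab <- read_tsv(lab_path)
    setNames(lab$population, lab$barcode)[cells]
  } else rep("all", length(cells))
  cell_matrix(counts, genes, cells, unname(labels), condition = condition)
}
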