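#' Quality-control filtering of a count matrix
#'
#' Applies the standard droplet-QC filters in a fixed order: genes detected
#' in fewer than `min_cells_per_gene` cells are dropped first, then cells
#' are filtered on the gene-filtered matrix. A cell is retained when its
#' total count lies in `[min_counts, max_counts]` (inclusive), it detects at
#' least `min_genes_per_cell` genes, and its mitochondrial fraction is
#' strictly below `max_mito` ("below 25%").
#'
#' @param m sparse gene x barcode count matrix with dimnames.
#' @param min_cells_per_gene keep genes detected in at least this many cells.
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param min_counts,max_counts inclusive bounds on per-cell total counts.
#' @param max_mito strict upper bound on the mitochondrial count fraction.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return list with `counts` (filtered matrix) and `report` (a `pci_qc`
#'   data.frame of per-cell metrics, pass flags and exclusion reasons, with
#'   the per-gene cell frequencies in `attr(, "gene_cells")`).
#' @export
qc_filter <- function(m, min_cells_per_gene = 10, min_genes_per_cell = 200,
                      min_counts = 300, max_counts = 5000, max_mito = 0.25,
                      mito_prefix = "MT-") {
  m <- .as_count_matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) {
    warning("empty count matrix: nothing to filter")
  }
  gene_cells <- Matrix::rowSums(m > 0)
  keep_gene <- gene_cells >= min_cells_per_gene
  mf <- m[keep_gene, , drop = FALSE]

  totals <- Matrix::colSums(mf)
  n_genes <- Matrix::colSums(mf > 0)
  is_mito <- if (nrow(mf) > 0) startsWith(rownames(mf), mito_prefix) else logical(0)
  if (!any(is_mito) && ncol(mf) > 0)
    warning(sprintf("no gene matches mito_prefix '%s'; mitochondrial fraction set to 0",
                    mito_prefix))
  mito_frac <- if (any(is_mito))
    Matrix::colSums(mf[is_mito, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(mf))

  reasons <- character(ncol(mf))
  add_reason <- function(reasons, bad, tag)
    ifelse(bad, ifelse(nzchar(reasons), paste(reasons, tag, sep = ";"), tag), reasons)
  reasons <- add_reason(reasons, totals < min_counts, "low_counts")
  reasons <- add_reason(reasons, totals > max_counts, "high_counts")
  reasons <- add_reason(reasons, n_genes < min_genes_per_cell, "few_genes")
  reasons <- add_reason(reasons, mito_frac >= max_mito, "high_mito")
  pass <- !nzchar(reasons)

  report <- data.frame(barcode = colnames(mf), total_counts = as.numeric(totals),
                       n_genes = as.integer(n_genes), mito_frac = as.numeric(mito_frac),
                       pass = pass, reason = reasons, stringsAsFactors = FALSE)
  attr(report, "gene_cells") <- setNames(as.integer(gene_cells), rownames(m))
  attr(report, "genes_kept") <- sum(keep_gene)
  class(report) <- c("pci_qc", "data.frame")
  list(counts = mf[, pass, drop = FALSE], report = report)
}

#' @export
print.pci_qc <- function(x, ...) {
  cat(sprintf("QC report: %d/%d cells pass (%d genes kept)\n",
              sum(x$pass), nrow(x), attr(x, "genes_kept")))
  if (any(!x$pass)) {
    tab <- sort(table(unlist(strsplit(x$reason[!x$pass], ";"))), decreasing = TRUE)
    for (r in names(tab)) cat(sprintf("  %-12s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Log-normalise counts for per-cell total expression
#'
#' Each entry becomes `ln(1 + count / cell_total * scale_factor)`
#' (scale factor 10,000 by default), preserving the sparsity pattern.
#'
#' @param m sparse count matrix; every cell must have total count > 0.
#' @param scale_factor per-cell scaling target.
#' @return a sparse `dgCMatrix` of normalised values with
#'   `attr(, "scale_factor")` set.
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  m <- .as_count_matrix(m)
  totals <- Matrix::colSums(m)
  if (any(totals == 0) && ncol(m) > 0)
    stop("cells with zero total counts present; run qc_filter() first",
         call. = FALSE)
  nm <- m
  if (length(nm@x))
    nm@x <- log1p(nm@x / rep.int(totals, diff(nm@p)) * scale_factor)
  attr(nm, "scale_factor") <- scale_factor
  nm
}

#' Select highly variable genes
#'
#' Ranks genes by the residual of their log-variance from a mean-binned
#' trend (20 equal-occupancy bins of the per-gene mean of the normalised
#' values), so highly dispersed genes are ranked relative to genes of
#' similar abundance. Ties break lexicographically on the gene id, making
#' the ranking deterministic.
#'
#' @param nm normalised matrix from [lognormalize()].
#' @param n number of genes to return (capped at the gene count).
#' @param n_bins equal-occupancy mean bins for the variance trend.
#' @return character vector of gene ids in rank order.
#' @export
select_hvg <- function(nm, n = 5000, n_bins = 20) {
  means <- Matrix::rowMeans(nm)
  sq <- Matrix::rowMeans(nm^2)
  vars <- pmax(sq - means^2, 0) * ncol(nm) / max(ncol(nm) - 1, 1)
  disp <- log(vars + 1e-12)
  n_bins <- max(1L, min(n_bins, nrow(nm)))
  bin <- ceiling(rank(means, ties.method = "first") / (nrow(nm) / n_bins))
  trend <- tapply(disp, bin, median)
  resid <- disp - trend[as.character(bin)]
  resid[vars == 0] <- -Inf   # constant genes always rank last
  ord <- order(-resid, rownames(nm))
  rownames(nm)[ord][seq_len(min(n, nrow(nm)))]
}
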