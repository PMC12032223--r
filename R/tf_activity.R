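#' Pseudobulk the cancer/stromal/doublet classes per clinical group
#'
#' Sums raw counts over all cells of each class (cancer singlets, stromal
#' singlets, cancer-stromal doublets, as called by the classifier) within
#' each clinical group: with 3 groups populated this yields the 9-column
#' pseudo-sample layout. Empty class-group combinations are dropped with a
#' warning.
#'
#' @param m raw count matrix.
#' @param ann annotation giving each barcode's `group`.
#' @param calls `pci_calls` table.
#' @param cancer_type,stromal_type class labels of the two singlet types.
#' @return genes x pseudo-sample matrix; column names `class.group`, with
#'   `attr(, "n_cells")` giving member-cell counts.
#' @export
pseudobulk <- function(m, ann, calls, cancer_type = "Cancer",
                       stromal_type = "Fibroblast") {
  dlabel <- doublet_label(cancer_type, stromal_type)
  group_of <- setNames(ann$group, ann$barcode)
  calls <- calls[calls$barcode %in% colnames(m), ]
  calls$group <- unname(group_of[calls$barcode])
  classes <- c(cancer_type, stromal_type, dlabel)
  groups <- unique(ann$group)
  cols <- list(); n_cells <- integer(0)
  for (cl in classes) for (g in groups) {
    bc <- calls$barcode[calls$label == cl & calls$group == g]
    nm_col <- paste(cl, g, sep = ".")
    if (!length(bc)) {
      warning(sprintf("pseudobulk column '%s' empty; dropped", nm_col))
      next
    }
    cols[[nm_col]] <- Matrix::rowSums(m[, bc, drop = FALSE])
    n_cells[nm_col] <- length(bc)
  }
  .assert(length(cols) > 0, "no pseudobulk columns could be formed")
  out <- do.call(cbind, cols)
  attr(out, "n_cells") <- n_cells
  out
}

.validate_regulons <- function(regulons, genes) {
  .assert(!anyDuplicated(regulons[, c("tf", "target")]),
          "duplicate (tf, target) rows in regulon table")
  .assert(all(regulons$sign %in% c(-1, 1)), "regulon signs must be +1 or -1")
  present <- regulons[regulons$target %in% genes, , drop = FALSE]
  cnt <- table(present$tf)
  drop <- setdiff(unique(regulons$tf), names(cnt)[cnt >= 2])
  if (length(drop))
    warning(sprintf("TF(s) with < 2 targets in the matrix dropped: %s",
                    paste(drop, collapse = ", ")))
  present[present$tf %in% names(cnt)[cnt >= 2], , drop = FALSE]
}

#' Score TF activity with univariate linear models
#'
#' For each transcription factor, regresses the expression vector `y` on
#' the TF's signed regulon weight vector `w` (+1/-1 on targets, 0
#' elsewhere) by ordinary least squares with intercept over all genes; the
#' activity score is the t-statistic of the slope, computed per TF
#' independently via the closed form `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with `r` the Pearson correlation of `y` and `w`. A constant `y` or `w`
#' yields score 0; perfect fits are capped at `1e8` in magnitude.
#'
#' @param y numeric expression vector named by gene, or a genes x
#'   observation matrix (each column scored).
#' @param regulons data.frame (tf, target, sign); TFs keep >= 2 targets
#'   after intersection with the genes of `y`.
#' @return a `pci_tf_activity` TF x observation matrix of t-statistics with
#'   `attr(, "df")` the residual degrees of freedom.
#' @export
ulm_scores <- function(y, regulons) {
  Y <- if (is.matrix(y) || inherits(y, "Matrix")) as.matrix(y)
       else matrix(y, ncol = 1, dimnames = list(names(y), "y"))
  .assert(!is.null(rownames(Y)), "expression input must be named by gene")
  .assert(nrow(Y) >= 3, "univariate linear model needs >= 3 genes")
  reg <- .validate_regulons(regulons, rownames(Y))
  tfs <- sort(unique(reg$tf))
  .assert(length(tfs) > 0, "no TF has >= 2 targets in the expression input")
  n <- nrow(Y)
  W <- matrix(0, n, length(tfs), dimnames = list(rownames(Y), tfs))
  W[cbind(match(reg$target, rownames(Y)), match(reg$tf, tfs))] <- reg$sign

  w_sd <- apply(W, 2, sd)
  if (any(w_sd == 0))
    warning(sprintf("constant weight vector for TF(s) %s; score set to 0",
                    paste(tfs[w_sd == 0], collapse = ", ")))
  y_sd <- apply(Y, 2, sd)
  Ws <- sweep(sweep(W, 2, colMeans(W)), 2, ifelse(w_sd > 0, w_sd, Inf), "/")
  Ys <- sweep(sweep(Y, 2, colMeans(Y)), 2, ifelse(y_sd > 0, y_sd, Inf), "/")
  r <- crossprod(Ws, Ys) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  t_stat[!is.finite(t_stat)] <- sign(r[!is.finite(t_stat)]) * 1e8
  t_stat <- pmin(pmax(t_stat, -1e8), 1e8)
  structure(t_stat, df = n - 2, class = c("pci_tf_activity", class(t_stat)))
}

#' Normalise pseudobulk columns and score TF activity
#'
#' Library-size normalises each pseudobulk column (counts per million,
#' log1p) so the activity score reflects composition rather than
#' sequencing depth, then applies [ulm_scores()].
#'
#' @param pb pseudobulk matrix from [pseudobulk()].
#' @param regulons regulon table.
#' @param normalize apply CPM + log1p first (default).
#' @return TF x pseudo-sample `pci_tf_activity` matrix.
#' @export
tf_activity_scores <- function(pb, regulons, normalize = TRUE) {
  if (normalize) {
    pb <- sweep(as.matrix(pb), 2, pmax(colSums(pb), 1), "/") * 1e6
    pb <- log1p(pb)
  }
  ulm_scores(pb, regulons)
}

#' TF activity for a differential-expression contrast
#'
#' Restricts the DEG table to its significant genes (`p_adj < alpha`) and
#' scores each TF by the univariate linear model of the significant genes'
#' log2 fold-changes on the regulon weights.
#'
#' @param deg_table a `pci_deg` table.
#' @param regulons regulon table.
#' @param alpha significance threshold on the adjusted p-value.
#' @return a one-column `pci_tf_activity` matrix named by the contrast, or
#'   `NULL` (with a warning) when fewer than 3 significant genes overlap
#'   regulon targets.
#' @export
differential_tf <- function(deg_table, regulons, alpha = 0.05) {
  sig <- deg_table[deg_table$p_adj < alpha, ]
  overlap <- intersect(sig$gene, regulons$target)
  if (length(overlap) < 3) {
    warning("fewer than 3 significant genes overlap regulon targets; no scores")
    return(NULL)
  }
  y <- setNames(sig$log2FC, sig$gene)
  out <- ulm_scores(y, regulons)
  colnames(out) <- deg_table$comparison[1]
  out
}

#' Top TFs per observation
#'
#' Per observation (pseudo-sample or contrast), returns the top `n` TFs by
#' absolute score, keeping the sign; ties break lexicographically on the
#' TF id. When the activity matrix carries degrees of freedom, TFs are
#' first restricted to significant ones (|t| above the two-sided 0.05
#' critical value). The union across observations is attached for heatmap
#' export.
#'
#' @param activity a `pci_tf_activity` matrix.
#' @param n TFs per observation.
#' @param sig_only restrict to significant TFs when df is available.
#' @return list with `per_observation` (named list of data.frames tf,
#'   score) and `union` (character).
#' @export
top_tfs <- function(activity, n = 25, sig_only = TRUE) {
  df <- attr(activity, "df")
  crit <- if (sig_only && !is.null(df) && df > 0) qt(0.975, df) else 0
  per_obs <- lapply(seq_len(ncol(activity)), function(j) {
    s <- activity[, j]
    s <- s[abs(s) > crit]
    ord <- order(-abs(s), names(s))
    k <- min(n, length(s))
    data.frame(tf = names(s)[ord][seq_len(k)], score = s[ord][seq_len(k)],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(per_obs) <- colnames(activity)
  list(per_observation = per_obs,
       union = sort(unique(unlist(lapply(per_obs, `[[`, "tf")))))
}
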