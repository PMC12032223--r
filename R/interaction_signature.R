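#' Differential expression between two cell sets
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalised expression with
#' Benjamini-Hochberg adjustment across the tested genes. When both groups
#' have at most `exact_max` cells the p-value comes from exhaustive
#' enumeration of all group assignments (handling ties exactly); otherwise
#' the normal approximation with tie correction and continuity correction
#' is used. The log2 fold-change is taken between group means of the
#' `expm1`-transformed normalised values with a small pseudocount
#' (switchable to plain normalised means via `fc_mode`).
#'
#' @param nm normalised gene x cell matrix.
#' @param cells_a,cells_b barcodes of the two groups (each >= 3 cells).
#' @param pseudocount added to both group means before the fold-change log.
#' @param comparison label stored with every row.
#' @param fc_mode `"expm1"` (default) or `"normalized"`.
#' @param exact_max largest group size for exact enumeration.
#' @return a `pci_deg` data.frame: gene, log2FC, p, p_adj, direction,
#'   comparison.
#' @export
deg <- function(nm, cells_a, cells_b, pseudocount = 1e-9,
                comparison = "A_vs_B", fc_mode = c("expm1", "normalized"),
                exact_max = 8) {
  fc_mode <- match.arg(fc_mode)
  cells_a <- intersect(cells_a, colnames(nm))
  cells_b <- intersect(cells_b, colnames(nm))
  .assert(length(cells_a) >= 3 && length(cells_b) >= 3,
          "both groups need >= 3 cells (got %d and %d)",
          length(cells_a), length(cells_b))
  x <- as.matrix(nm[, c(cells_a, cells_b), drop = FALSE])
  n1 <- length(cells_a); n2 <- length(cells_b); n <- n1 + n2
  ind <- seq_len(n1)

  if (max(n1, n2) <= exact_max) {
    splits <- utils::combn(n, n1)
    p <- apply(x, 1, function(v) {
      r <- rank(v)
      w_obs <- sum(r[ind])
      e <- n1 * (n + 1) / 2
      w_all <- colSums(matrix(r[splits], nrow = n1))
      mean(abs(w_all - e) >= abs(w_obs - e) - 1e-12)
    })
  } else {
    p <- apply(x, 1, function(v) {
      r <- rank(v)
      w <- sum(r[ind])
      mu <- n1 * (n + 1) / 2
      u <- unique(r)
      tt <- tabulate(match(r, u))
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      min(1, 2 * pnorm(-abs(z)))
    })
  }

  ma <- rowMeans(x[, ind, drop = FALSE])
  mb <- rowMeans(x[, -ind, drop = FALSE])
  if (fc_mode == "expm1") {
    ma <- rowMeans(expm1(x[, ind, drop = FALSE]))
    mb <- rowMeans(expm1(x[, -ind, drop = FALSE]))
  }
  log2fc <- log2((ma + pseudocount) / (mb + pseudocount))
  structure(data.frame(gene = rownames(x), log2FC = log2fc, p = p,
                       p_adj = p.adjust(p, method = "BH"),
                       direction = ifelse(log2fc > 0, "up",
                                          ifelse(log2fc < 0, "down", "none")),
                       comparison = comparison, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("pci_deg", "data.frame"))
}

#' @export
print.pci_deg <- function(x, ...) {
  cat(sprintf("DEG table '%s': %d genes, %d significant (p_adj < 0.05)\n",
              x$comparison[1], nrow(x), sum(x$p_adj < 0.05)))
  invisible(x)
}

#' Doublet-specific interaction gene signature
#'
#' Intersects the LDA-derived gene list with the genes differentially
#' expressed in the doublets against *both* constituent singlet
#' populations: up-genes must be significantly up versus the cancer
#' singlets and versus the stromal singlets; down-genes analogously. The
#' combined signature is their union.
#'
#' @param lda_genes character vector of LDA-ranked genes for the group.
#' @param deg_vs_cancer,deg_vs_stromal `pci_deg` tables for doublets vs
#'   cancer singlets and doublets vs stromal singlets (log2FC oriented as
#'   doublet over singlet); must share the gene universe.
#' @param alpha adjusted-p threshold (strict).
#' @return a `pci_signature` list: `up`, `down`, `combined` (sorted).
#' @export
doublet_specific_signature <- function(lda_genes, deg_vs_cancer,
                                       deg_vs_stromal, alpha = 0.05) {
  .assert(setequal(deg_vs_cancer$gene, deg_vs_stromal$gene),
          "DEG tables must share one gene universe")
  if (!length(lda_genes))
    return(structure(list(up = character(0), down = character(0),
                          combined = character(0)), class = "pci_signature"))
  sig_dir <- function(tab, dir) {
    s <- tab$p_adj < alpha & (if (dir == "up") tab$log2FC > 0 else tab$log2FC < 0)
    tab$gene[s]
  }
  up <- sort(intersect(lda_genes,
                       intersect(sig_dir(deg_vs_cancer, "up"),
                                 sig_dir(deg_vs_stromal, "up"))))
  down <- sort(intersect(lda_genes,
                         intersect(sig_dir(deg_vs_cancer, "down"),
                                   sig_dir(deg_vs_stromal, "down"))))
  structure(list(up = up, down = down, combined = sort(union(up, down))),
            class = "pci_signature")
}

#' @export
print.pci_signature <- function(x, ...) {
  cat(sprintf("Doublet-specific signature: %d up + %d down = %d genes\n",
              length(x$up), length(x$down), length(x$combined)))
  invisible(x)
}
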