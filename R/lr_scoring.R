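#' Mean expression and detection fraction per clinical group
#'
#' For each clinical group, computes the mean normalised expression `X` of
#' every gene over the group's cancer-stromal doublet cells and the
#' fraction `pct` of those cells detecting the gene (count > 0).
#'
#' @param nm normalised gene x cell matrix.
#' @param calls `pci_calls` table identifying doublets and their labels.
#' @param ann annotation giving each barcode's `group`.
#' @param label doublet class to profile (default `"Cancer+Fibroblast"`).
#' @return a `pci_groupexpr` list: `X` (genes x groups), `pct` (genes x
#'   groups), `n_cells` per group.
#' @export
group_mean_expression <- function(nm, calls, ann,
                                  label = doublet_label("Cancer", "Fibroblast")) {
  group_of <- setNames(ann$group, ann$barcode)
  dbl <- calls[calls$is_doublet & calls$label == label &
                 calls$barcode %in% colnames(nm), ]
  .assert(nrow(dbl) > 0, "no '%s' doublets called", label)
  dbl$group <- unname(group_of[dbl$barcode])
  groups <- unique(ann$group)
  keep <- vapply(groups, function(g) sum(dbl$group == g) > 0, TRUE)
  if (any(!keep))
    warning(sprintf("group(s) without doublets excluded: %s",
                    paste(groups[!keep], collapse = ", ")))
  groups <- groups[keep]
  X <- sapply(groups, function(g)
    Matrix::rowMeans(nm[, dbl$barcode[dbl$group == g], drop = FALSE]))
  pct <- sapply(groups, function(g)
    Matrix::rowMeans(nm[, dbl$barcode[dbl$group == g], drop = FALSE] > 0))
  structure(list(X = as.matrix(X), pct = as.matrix(pct),
                 n_cells = vapply(groups, function(g) sum(dbl$group == g), 0L)),
            class = "pci_groupexpr")
}

#' Per-cluster enrichment z-scores
#'
#' For each gene, standardises its per-cluster mean expression across the
#' clusters: `Z = (X - mean(X)) / std(X)` with the mean and standard
#' deviation taken across the clusters (population denominator `n` by
#' default; a sample `n - 1` denominator is available). Genes whose means
#' are identical across clusters get `Z = 0` in every cluster, so flat
#' genes fail the downstream score filter instead of propagating NaN.
#'
#' @param X genes x clusters matrix of mean expression (>= 2 clusters).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return matrix of z-scores, same shape as `X`.
#' @export
enrichment_z <- function(X, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  .assert(ncol(X) >= 2, "enrichment z-scores need >= 2 clusters (std undefined for one)")
  mu <- rowMeans(X)
  dev <- X - mu
  denom <- if (sd_type == "population") ncol(X) else ncol(X) - 1
  s <- sqrt(rowSums(dev^2) / denom)
  Z <- dev / ifelse(s > 0, s, Inf)   # s == 0 -> Z = 0
  dimnames(Z) <- dimnames(X)
  Z
}

#' Ligand-receptor interaction score
#'
#' Euclidean norm of the ligand and receptor enrichment z-scores,
#' `sqrt(Z_L^2 + Z_R^2)`; symmetric in its arguments.
#'
#' @param z_l,z_r enrichment z-scores (vectorised).
#' @return non-negative interaction scores.
#' @export
interaction_score <- function(z_l, z_r) {
  .assert(all(is.finite(z_l)) && all(is.finite(z_r)),
          "interaction_score requires finite inputs")
  sqrt(z_l^2 + z_r^2)
}

#' Score and filter ligand-receptor pairs per cluster
#'
#' Builds the per-cluster ligand-receptor table with enrichment z-scores
#' and interaction scores, and applies the five retention conditions:
#' mean ligand expression > 0, mean receptor expression > 0, interaction
#' score strictly > `min_score`, and ligand and receptor each detected in
#' at least `min_pct` of the cluster's doublet cells (inclusive).
#'
#' @param pairs data.frame with `ligand` and `receptor` gene ids; pairs
#'   with either gene absent from the expression matrix are skipped with a
#'   message.
#' @param ge a `pci_groupexpr` from [group_mean_expression()].
#' @param min_score strict lower bound on the interaction score.
#' @param min_pct inclusive lower bound on the detection fraction.
#' @param sd_type passed to [enrichment_z()].
#' @return a `pci_lr` data.frame with one row per (cluster, pair):
#'   cluster, ligand, receptor, X_L, X_R, pct_L, pct_R, Z_L, Z_R,
#'   Z_interaction and the five filter verdicts plus combined `pass`.
#' @export
filter_lrp <- function(pairs, ge, min_score = 1.5, min_pct = 0.05,
                       sd_type = "population") {
  stopifnot(inherits(ge, "pci_groupexpr"))
  genes <- rownames(ge$X)
  ok <- pairs$ligand %in% genes & pairs$receptor %in% genes
  if (any(!ok))
    message(sprintf("%d pair(s) skipped: ligand or receptor absent from matrix",
                    sum(!ok)))
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) {
    empty <- data.frame(cluster = character(0), ligand = character(0),
                        receptor = character(0), X_L = numeric(0),
                        X_R = numeric(0), pct_L = numeric(0),
                        pct_R = numeric(0), Z_L = numeric(0), Z_R = numeric(0),
                        Z_interaction = numeric(0),
                        ligand_expressed = logical(0),
                        receptor_expressed = logical(0),
                        score_pass = logical(0), pct_L_pass = logical(0),
                        pct_R_pass = logical(0), pass = logical(0),
                        stringsAsFactors = FALSE)
    class(empty) <- c("pci_lr", "data.frame")
    return(empty)
  }
  Z <- enrichment_z(ge$X, sd_type = sd_type)
  out <- list()
  for (cl in colnames(ge$X)) {
    z_l <- Z[pairs$ligand, cl]; z_r <- Z[pairs$receptor, cl]
    df <- data.frame(
      cluster = cl, ligand = pairs$ligand, receptor = pairs$receptor,
      X_L = ge$X[pairs$ligand, cl], X_R = ge$X[pairs$receptor, cl],
      pct_L = ge$pct[pairs$ligand, cl], pct_R = ge$pct[pairs$receptor, cl],
      Z_L = z_l, Z_R = z_r,
      Z_interaction = interaction_score(z_l, z_r),
      stringsAsFactors = FALSE)
    df$ligand_expressed <- df$X_L > 0
    df$receptor_expressed <- df$X_R > 0
    df$score_pass <- df$Z_interaction > min_score
    df$pct_L_pass <- df$pct_L >= min_pct
    df$pct_R_pass <- df$pct_R >= min_pct
    df$pass <- df$ligand_expressed & df$receptor_expressed & df$score_pass &
      df$pct_L_pass & df$pct_R_pass
    out[[cl]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pci_lr", "data.frame")
  res
}

#' @export
print.pci_lr <- function(x, ...) {
  tab <- table(x$cluster[x$pass])
  cat(sprintf("LR interactions: %d scored rows, %d pass filters (%s)\n",
              nrow(x), sum(x$pass),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Aggregate cells into pseudo-sample observation units
#'
#' Randomly partitions the given cells into `n_units` bins (seeded) and
#' returns the per-bin mean of the supplied expression matrix — the
#' observation units over which [active_triples()] correlations are taken.
#'
#' @param nm normalised gene x cell matrix.
#' @param cells barcodes to aggregate.
#' @param n_units number of units.
#' @param seed integer seed.
#' @return genes x units matrix.
#' @export
make_expression_units <- function(nm, cells, n_units = 30, seed = 1L) {
  cells <- intersect(cells, colnames(nm))
  .assert(length(cells) >= n_units, "need at least one cell per unit")
  set.seed(seed)
  bin <- sample(rep_len(seq_len(n_units), length(cells)))
  out <- sapply(seq_len(n_units), function(b)
    Matrix::rowMeans(nm[, cells[bin == b], drop = FALSE]))
  colnames(out) <- sprintf("unit%02d", seq_len(n_units))
  as.matrix(out)
}

#' Call active ligand-receptor-pathway triples
#'
#' For every ligand-receptor pair and pathway with at least 5 target genes
#' present, computes the Spearman correlation between ligand and receptor
#' and the mean Spearman correlation between the receptor and the
#' pathway's targets across the observation units. Significance comes from
#' a seeded permutation null (the receptor's values are shuffled across
#' units, breaking both correlations; the test statistic is the smaller of
#' the two correlations), with Benjamini-Hochberg q-values over all
#' triples. A triple is active when `q <= alpha_q` and both correlations
#' are positive.
#'
#' @param expr genes x observation-unit matrix (>= 10 units), e.g. from
#'   [make_expression_units()].
#' @param pairs data.frame with `ligand`, `receptor`.
#' @param pathways named list of target gene-id vectors.
#' @param alpha_q activity threshold on the q-value.
#' @param n_perm permutations (>= 1; >= 500 recommended).
#' @param seed integer seed.
#' @param cluster optional cluster label stored with every row.
#' @return a `pci_triples` data.frame: cluster, ligand, receptor, pathway,
#'   rho_LR, rho_RT, p, q, active.
#' @export
active_triples <- function(expr, pairs, pathways, alpha_q = 0.01,
                           n_perm = 1000, seed = 1L, cluster = NA_character_) {
  .assert(n_perm >= 1, "n_perm must be >= 1")
  expr <- as.matrix(expr)
  n <- ncol(expr)
  .assert(n >= 10, "need >= 10 observation units, got %d", n)

  genes_needed <- unique(c(pairs$ligand, pairs$receptor, unlist(pathways)))
  genes_needed <- intersect(genes_needed, rownames(expr))
  ranks <- t(apply(expr[genes_needed, , drop = FALSE], 1, rank))
  sds <- apply(ranks, 1, sd)
  const <- sds == 0
  scaled <- (ranks - rowMeans(ranks)) / ifelse(const, Inf, sds)

  set.seed(seed)
  perm <- replicate(n_perm, sample.int(n))

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[i]; rec <- pairs$receptor[i]
    if (!lig %in% rownames(scaled) || !rec %in% rownames(scaled)) next
    if (const[lig] || const[rec]) { skipped <- skipped + 1L; next }
    lv <- scaled[lig, ]; rv <- scaled[rec, ]
    rv_perm <- matrix(rv[perm], nrow = n)
    for (pw in names(pathways)) {
      targets <- setdiff(intersect(pathways[[pw]], rownames(scaled)),
                         c(lig, rec))
      targets <- targets[!const[targets]]
      if (length(targets) < 5) next
      tbar <- colMeans(scaled[targets, , drop = FALSE])
      rho_lr <- sum(lv * rv) / (n - 1)
      rho_rt <- sum(tbar * rv) / (n - 1)
      stat <- min(rho_lr, rho_rt)
      stat_perm <- pmin(colSums(lv * rv_perm), colSums(tbar * rv_perm)) / (n - 1)
      p <- (1 + sum(stat_perm >= stat)) / (1 + n_perm)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cluster, ligand = lig, receptor = rec, pathway = pw,
        rho_LR = rho_lr, rho_RT = rho_rt, p = p, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) skipped: constant ligand or receptor", skipped))
  if (!length(rows))
    return(structure(data.frame(cluster = character(0), ligand = character(0),
                                receptor = character(0), pathway = character(0),
                                rho_LR = numeric(0), rho_RT = numeric(0),
                                p = numeric(0), q = numeric(0),
                                active = logical(0), stringsAsFactors = FALSE),
                     class = c("pci_triples", "data.frame")))
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res$active <- res$q <= alpha_q & res$rho_LR > 0 & res$rho_RT > 0
  class(res) <- c("pci_triples", "data.frame")
  res
}

#' @export
print.pci_triples <- function(x, ...) {
  cat(sprintf("LRPw triples: %d scored, %d active (q <= threshold)\n",
              nrow(x), sum(x$active)))
  invisible(x)
}

#' Ligand-receptor pairs found by both scoring methods
#'
#' Set intersection of two ligand-receptor tables keyed on (ligand,
#' receptor, cluster) — typically the interaction-score pass table and the
#' active-triple table.
#'
#' @param method1,method2 data.frames with `ligand`, `receptor` and
#'   optionally `cluster` columns.
#' @return data.frame of the shared (cluster, ligand, receptor) keys.
#' @export
overlap_lrp <- function(method1, method2) {
  key <- function(d) paste(if ("cluster" %in% names(d)) d$cluster else "all",
                           d$ligand, d$receptor, sep = "\r")
  k1 <- unique(key(method1)); k2 <- unique(key(method2))
  shared <- intersect(k1, k2)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  data.frame(cluster = vapply(parts, `[`, "", 1),
             ligand = vapply(parts, `[`, "", 2),
             receptor = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}
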