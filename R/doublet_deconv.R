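#' Rank marker genes per cell type
#'
#' One-vs-rest Wilcoxon rank-sum z-statistic per gene and type, computed on
#' normalised expression with tie correction. Genes are ranked by the
#' statistic, ties broken by log-fold-change (in-type minus out-of-type mean)
#' and then lexicographically by gene id.
#'
#' @param nm normalised gene x cell matrix.
#' @param ann annotation data.frame with `barcode` and `cell_type`; cells
#'   with `NA` cell type are ignored. Types with fewer than 3 cells are
#'   excluded with a warning.
#' @param top_n markers kept per type.
#' @return a `pci_markers` list: per type a data.frame (gene, stat, lfc),
#'   sorted; `attr(, "types")` lists the types ranked.
#' @export
marker_genes <- function(nm, ann, top_n = 100) {
  ann <- ann[!is.na(ann$cell_type) & ann$barcode %in% colnames(nm), ]
  sizes <- table(ann$cell_type)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning(sprintf("excluding type(s) with < 3 cells: %s",
                    paste(small, collapse = ", ")))
    ann <- ann[!ann$cell_type %in% small, ]
    sizes <- sizes[!names(sizes) %in% small]
  }
  .assert(length(sizes) >= 2, "need >= 2 cell types with >= 3 cells")

  x <- as.matrix(nm[, ann$barcode, drop = FALSE])
  n <- ncol(x)
  ranks <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  ties <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    r <- rank(x[g, ])
    ranks[g, ] <- r
    tt <- tabulate(match(r, unique(r)))
    ties[g] <- sum(tt^3 - tt)
  }
  out <- list()
  for (ty in names(sizes)) {
    ind <- ann$cell_type == ty
    n1 <- sum(ind); n2 <- n - n1
    w <- rowSums(ranks[, ind, drop = FALSE])
    mu <- n1 * (n + 1) / 2
    v <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
    z <- ifelse(v > 0, (w - mu) / sqrt(v), 0)
    lfc <- rowMeans(x[, ind, drop = FALSE]) - rowMeans(x[, !ind, drop = FALSE])
    ord <- order(-z, -lfc, rownames(x))
    k <- min(top_n, nrow(x))
    out[[ty]] <- data.frame(gene = rownames(x)[ord][seq_len(k)],
                            stat = z[ord][seq_len(k)],
                            lfc = lfc[ord][seq_len(k)],
                            stringsAsFactors = FALSE)
  }
  structure(out, types = names(sizes), class = "pci_markers")
}

#' @export
print.pci_markers <- function(x, ...) {
  cat(sprintf("Marker catalog: %d cell types, %s genes each\n", length(x),
              paste(range(vapply(x, nrow, 0L)), collapse = "-")))
  for (ty in names(x))
    cat(sprintf("  %-12s %s ...\n", ty, paste(head(x[[ty]]$gene, 5), collapse = ", ")))
  invisible(x)
}

#' Generate synthetic doublets from annotated singlets
#'
#' For the `T` annotated cell types, builds all `T` homotypic plus
#' `T(T-1)/2` heterotypic classes; each synthetic doublet is the elementwise
#' sum of two distinct sampled singlet count vectors of the class's types.
#'
#' @param m count matrix (genes x cells).
#' @param ann annotation with `barcode`, `cell_type`.
#' @param per_class synthetic doublets per class (>= 1).
#' @param seed integer seed.
#' @return a `pci_synth` list: `counts` (genes x synthetic barcodes),
#'   `labels` (class per column), `provenance` (source barcodes).
#' @export
make_synthetic_doublets <- function(m, ann, per_class = 100, seed = 1L) {
  .assert(per_class >= 1, "per_class must be >= 1")
  ann <- ann[!is.na(ann$cell_type) & ann$barcode %in% colnames(m), ]
  types <- sort(unique(ann$cell_type))
  set.seed(seed)
  classes <- list()
  for (i in seq_along(types)) for (j in i:length(types))
    classes[[length(classes) + 1]] <- c(types[i], types[j])

  cols <- list(); labels <- character(0); prov <- list()
  for (cl in classes) {
    a <- ann$barcode[ann$cell_type == cl[1]]
    b <- ann$barcode[ann$cell_type == cl[2]]
    lab <- doublet_label(cl[1], cl[2])
    if ((cl[1] == cl[2] && length(a) < 2) ||
        (cl[1] != cl[2] && (length(a) < 1 || length(b) < 1))) {
      warning(sprintf("class %s skipped: insufficient source cells", lab))
      next
    }
    s1 <- sample(a, per_class, replace = TRUE)
    s2 <- sample(b, per_class, replace = TRUE)
    if (cl[1] == cl[2]) {
      clash <- which(s1 == s2)
      for (k in clash) s2[k] <- sample(setdiff(b, s1[k]), 1)
    }
    cols[[length(cols) + 1]] <- m[, s1, drop = FALSE] + m[, s2, drop = FALSE]
    labels <- c(labels, rep(lab, per_class))
    prov[[length(prov) + 1]] <- data.frame(source1 = s1, source2 = s2,
                                           label = lab, stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  colnames(counts) <- sprintf("SYN%05d", seq_along(labels))
  structure(list(counts = counts, labels = labels,
                 provenance = do.call(rbind, prov)),
            class = "pci_synth")
}

#' Train the singlet/doublet random-forest classifier
#'
#' A multiclass random forest (500 trees, sqrt(p) features per split) over
#' the union of the marker-catalog genes, trained on raw counts with equal
#' numbers of singlet and synthetic-doublet instances (the larger side is
#' downsampled, seeded).
#'
#' @param m count matrix holding the annotated singlets.
#' @param ann annotation for the singlets (`barcode`, `cell_type`).
#' @param synth synthetic doublets from [make_synthetic_doublets()].
#' @param markers marker catalog from [marker_genes()].
#' @param seed integer seed.
#' @param num_trees forest size.
#' @return a `pci_classifier` with the fitted forest, feature list and
#'   class levels.
#' @export
train_classifier <- function(m, ann, synth, markers, seed = 1L,
                             num_trees = 500) {
  features <- unique(unlist(lapply(markers, `[[`, "gene")))
  missing <- setdiff(features, rownames(m))
  if (length(missing)) {
    warning(sprintf("%d marker feature(s) absent from matrix; dropped",
                    length(missing)))
    features <- setdiff(features, missing)
  }
  .assert(length(features) > 0, "no marker features present in the matrix")
  ann <- ann[!is.na(ann$cell_type) & ann$barcode %in% colnames(m), ]
  .assert(nrow(ann) > 0 && length(synth$labels) > 0,
          "both singlet and synthetic-doublet classes must be non-empty")

  set.seed(seed)
  n_keep <- min(nrow(ann), length(synth$labels))
  s_idx <- sample(seq_len(nrow(ann)), n_keep)
  d_idx <- sample(seq_along(synth$labels), n_keep)

  x <- rbind(t(as.matrix(m[features, ann$barcode[s_idx], drop = FALSE])),
             t(as.matrix(synth$counts[features, d_idx, drop = FALSE])))
  y <- factor(c(ann$cell_type[s_idx], synth$labels[d_idx]))
  df <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                        mtry = floor(sqrt(length(features))),
                        probability = TRUE, seed = seed, num.threads = 1)
  structure(list(model = fit, features = features, classes = levels(y),
                 singlet_types = sort(unique(ann$cell_type))),
            class = "pci_classifier")
}

#' Classify every barcode as singlet or doublet
#'
#' Applies the trained forest to all barcodes; the call probability is the
#' forest's class-vote fraction for the winning label.
#'
#' @param m count matrix to classify.
#' @param classifier from [train_classifier()].
#' @return a `pci_calls` data.frame: barcode, label, is_doublet, type1,
#'   type2, probability.
#' @export
classify_barcodes <- function(m, classifier) {
  if (ncol(m) == 0) {
    return(structure(data.frame(barcode = character(0), label = character(0),
                                is_doublet = logical(0), type1 = character(0),
                                type2 = character(0), probability = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("pci_calls", "data.frame")))
  }
  .assert(all(classifier$features %in% rownames(m)),
          "matrix lacks features the classifier was trained on")
  x <- data.frame(t(as.matrix(m[classifier$features, , drop = FALSE])),
                  check.names = FALSE)
  pr <- stats::predict(classifier$model, data = x, num.threads = 1)$predictions
  win <- max.col(pr, ties.method = "first")
  label <- colnames(pr)[win]
  parts <- strsplit(label, "+", fixed = TRUE)
  structure(data.frame(
    barcode = colnames(m), label = label,
    is_doublet = lengths(parts) == 2,
    type1 = vapply(parts, `[`, "", 1),
    type2 = vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, ""),
    probability = pr[cbind(seq_along(win), win)],
    stringsAsFactors = FALSE), class = c("pci_calls", "data.frame"))
}

#' @export
print.pci_calls <- function(x, ...) {
  cat(sprintf("Doublet calls: %d barcodes, %d called doublets (%.1f%%)\n",
              nrow(x), sum(x$is_doublet), 100 * mean(x$is_doublet)))
  invisible(x)
}

#' Test doublet-type enrichment against a random-pairing null
#'
#' The enrichment score of a doublet type is its observed count divided by
#' its expected count under independent pairing of singlet type labels
#' (label frequencies estimated from the called singlets). The null
#' distribution is built from `n_sim` seeded simulations that draw the same
#' number of doublets by independent label pairing. With two or more
#' samples (`mode = "per_sample"`), per-sample observed enrichments are
#' compared to the per-sample simulated ones by a one-sided Wilcoxon
#' rank-sum test; with a single sample or `mode = "pooled"`, a one-sided
#' empirical p-value is used. Because doublet counts are small integers,
#' ties between the observed and simulated enrichments are common and the
#' default empirical p counts them half (mid-p), which keeps null p-values
#' approximately uniform; `p_type = "conservative"` gives the classical
#' `(1 + #sims >= observed) / (1 + n_sim)` instead.
#'
#' @param calls a `pci_calls` table with at least one called doublet.
#' @param ann annotation giving each barcode's `sample`.
#' @param n_sim null simulations (>= 1).
#' @param seed integer seed.
#' @param mode `"auto"` (per-sample when >= 2 samples hold called doublets),
#'   `"pooled"`, or `"per_sample"`.
#' @param p_type `"midp"` (default) or `"conservative"` empirical p-value.
#' @return a `pci_enrichment` data.frame: type, count, expected, enrichment,
#'   p_value.
#' @export
doublet_enrichment_test <- function(calls, ann, n_sim = 1000, seed = 1L,
                                    mode = c("auto", "pooled", "per_sample"),
                                    p_type = c("midp", "conservative")) {
  mode <- match.arg(mode)
  p_type <- match.arg(p_type)
  .assert(n_sim >= 1, "n_sim must be >= 1")
  .assert(any(calls$is_doublet), "no called doublets to test")
  set.seed(seed)
  sample_of <- setNames(ann$sample, ann$barcode)
  calls$sample <- unname(sample_of[calls$barcode])

  sing <- calls[!calls$is_doublet, ]
  dbl <- calls[calls$is_doublet, ]
  types <- sort(unique(sing$label))
  freq <- table(factor(sing$label, types)) / nrow(sing)

  pair_expected <- function(lab, n_pairs, p) {
    parts <- strsplit(lab, "+", fixed = TRUE)
    vapply(parts, function(q) {
      pp <- p[q[1]] * p[q[2]]
      n_pairs * if (q[1] == q[2]) pp else 2 * pp
    }, 0)
  }
  sim_counts <- function(n_pairs, p, labs) {
    t1 <- sample(names(p), n_pairs, replace = TRUE, prob = p)
    t2 <- sample(names(p), n_pairs, replace = TRUE, prob = p)
    table(factor(doublet_label(t1, t2), labs))
  }

  labs <- sort(unique(dbl$label))
  obs <- table(factor(dbl$label, labs))
  expected <- pair_expected(labs, nrow(dbl), freq)
  enrichment <- as.numeric(obs) / expected

  dbl_samples <- unique(dbl$sample)
  use_per_sample <- mode == "per_sample" ||
    (mode == "auto" && length(dbl_samples) >= 2)

  if (use_per_sample) {
    obs_s <- matrix(NA_real_, length(labs), length(dbl_samples),
                    dimnames = list(labs, dbl_samples))
    sim_s <- array(NA_real_, c(length(labs), length(dbl_samples), n_sim))
    for (j in seq_along(dbl_samples)) {
      s <- dbl_samples[j]
      sing_j <- sing[sing$sample == s, ]
      if (nrow(sing_j) == 0) next
      p_j <- table(factor(sing_j$label, types)) / nrow(sing_j)
      n_j <- sum(dbl$sample == s)
      exp_j <- pair_expected(labs, n_j, p_j)
      obs_s[, j] <- as.numeric(table(factor(dbl$label[dbl$sample == s], labs))) / exp_j
      for (k in seq_len(n_sim))
        sim_s[, j, k] <- as.numeric(sim_counts(n_j, p_j, labs)) / exp_j
    }
    p_value <- vapply(seq_along(labs), function(i) {
      o <- obs_s[i, ]; o <- o[is.finite(o)]
      s <- as.numeric(sim_s[i, , ]); s <- s[is.finite(s)]
      suppressWarnings(stats::wilcox.test(o, s, alternative = "greater")$p.value)
    }, 0)
  } else {
    sim <- matrix(0, length(labs), n_sim, dimnames = list(labs, NULL))
    for (k in seq_len(n_sim))
      sim[, k] <- as.numeric(sim_counts(nrow(dbl), freq, labs)) / expected
    p_value <- vapply(seq_along(labs), function(i) {
      if (p_type == "conservative")
        (1 + sum(sim[i, ] >= enrichment[i])) / (1 + n_sim)
      else  # mid-p: ties counted half, calibrated for discrete counts
        (0.5 + sum(sim[i, ] > enrichment[i]) +
           0.5 * sum(sim[i, ] == enrichment[i])) / (1 + n_sim)
    }, 0)
  }
  structure(data.frame(type = labs, count = as.integer(obs),
                       expected = expected, enrichment = enrichment,
                       p_value = p_value, stringsAsFactors = FALSE),
            class = c("pci_enrichment", "data.frame"))
}

#' Filter the doublet-type table
#'
#' Retains heterotypic doublet types with observed count at least
#' `min_count` and enrichment p-value below `alpha`.
#'
#' @param enrichment a `pci_enrichment` table.
#' @param min_count minimum observed count (inclusive).
#' @param alpha strict p-value threshold.
#' @param heterotypic_only drop homotypic types.
#' @return the filtered rows.
#' @export
filter_doublet_calls <- function(enrichment, min_count = 10, alpha = 0.05,
                                 heterotypic_only = TRUE) {
  if (nrow(enrichment) == 0) return(enrichment)
  parts <- strsplit(enrichment$type, "+", fixed = TRUE)
  het <- vapply(parts, function(p) length(p) == 2 && p[1] != p[2], TRUE)
  keep <- enrichment$count >= min_count & enrichment$p_value < alpha &
    (het | !heterotypic_only)
  enrichment[keep, , drop = FALSE]
}

#' Per-group physical-interaction network
#'
#' One undirected network per clinical group: nodes are cell types, edges
#' are retained doublet types, with the raw in-group count and the count
#' normalised by the number of cells in the group and scaled (x10,000 by
#' default).
#'
#' @param filtered filtered doublet-type table from [filter_doublet_calls()].
#' @param calls the full `pci_calls` table (for per-group doublet counts).
#' @param ann annotation giving each barcode's `group`.
#' @param scale normalisation scale factor.
#' @return a `pci_network`: named list of per-group edge data.frames
#'   (type1, type2, count, normalized).
#' @export
interaction_network <- function(filtered, calls, ann, scale = 10000) {
  group_of <- setNames(ann$group, ann$barcode)
  .assert(all(calls$barcode %in% names(group_of)),
          "calls contain barcodes with no group annotation")
  groups <- unique(ann$group)
  out <- list()
  for (g in groups) {
    n_cells <- sum(ann$barcode %in% calls$barcode & ann$group == g)
    .assert(n_cells > 0, "group '%s' has no cells", g)
    dbl <- calls[calls$is_doublet & group_of[calls$barcode] == g &
                   calls$label %in% filtered$type, ]
    cnt <- table(dbl$label)
    cnt <- cnt[cnt > 0]
    parts <- if (length(cnt)) strsplit(names(cnt), "+", fixed = TRUE) else list()
    out[[g]] <- data.frame(
      type1 = vapply(parts, `[`, "", 1), type2 = vapply(parts, `[`, "", 2),
      count = as.integer(cnt),
      normalized = as.numeric(cnt) / n_cells * scale,
      stringsAsFactors = FALSE)
  }
  structure(out, class = "pci_network")
}

#' @export
print.pci_network <- function(x, ...) {
  for (g in names(x))
    cat(sprintf("%s: %d interaction edge(s), top: %s\n", g, nrow(x[[g]]),
                if (nrow(x[[g]])) paste0(x[[g]]$type1[which.max(x[[g]]$count)], "+",
                                         x[[g]]$type2[which.max(x[[g]]$count)]) else "-"))
  invisible(x)
}
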