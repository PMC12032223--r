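# Two-stage LDA topic modelling of singlet and doublet gene counts.
# The variational engine lives in src/lda_vb.cpp; these wrappers own the
# TopicModel contract (column-normalised gene-topic matrix, per-cell
# topic probabilities) and the two-stage freezing logic.

.lda_check_counts <- function(counts) {
  .assert(inherits(counts, "sparseMatrix") || is.matrix(counts),
          "counts must be a matrix")
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  .assert(all(m@x >= 0) && all(m@x == round(m@x)),
          "LDA consumes non-negative integer counts; pass raw counts, not normalised values")
  m
}

.lda_engine <- function(counts, k, n_fixed = 0L, log_beta_fixed = NULL,
                        seed = 1L, max_iter = 200, tol = 1e-4,
                        update_beta = TRUE, inner_iter = 100,
                        lambda_init = NULL) {
  m <- .lda_check_counts(counts)
  .assert(k >= 1, "k must be >= 1")
  if (is.null(log_beta_fixed))
    log_beta_fixed <- matrix(0, nrow(m), 0)
  if (is.null(lambda_init))
    lambda_init <- matrix(0, nrow(m), 0)
  set.seed(seed)
  res <- .lda_vb_cpp(m@i, m@p, m@x, nrow(m), ncol(m), as.integer(k),
                     as.integer(n_fixed), log_beta_fixed,
                     alpha = 1 / k, eta = 1 / k,
                     max_iter = as.integer(max_iter), tol = tol,
                     inner_iter = as.integer(inner_iter),
                     update_beta = update_beta, lambda_init = lambda_init)
  res$gene_topic <- res$beta
  dimnames(res$gene_topic) <- list(rownames(m), paste0("topic", seq_len(k)))
  gm <- t(res$gamma)
  res$topic_cell <- sweep(gm, 2, colSums(gm), "/")
  dimnames(res$topic_cell) <- list(paste0("topic", seq_len(k)), colnames(m))
  res
}

#' Choose the topic count by held-out perplexity
#'
#' Splits cells into a training and a held-out set and fits an LDA model
#' per candidate `k` on the training cells. Held-out cells are scored by
#' document completion: each held-out cell's counts are split in half
#' (binomially, seeded), the topic mixture is estimated from one half
#' under the fitted topics, and the per-token perplexity is evaluated on
#' the other half — full fold-in would reward overfitted topic sets.
#' Returns the `k` minimising held-out perplexity (smallest `k` on ties)
#' with the full score table attached.
#'
#' @param counts integer gene x cell count matrix (typically the combined
#'   singlet + doublet matrix).
#' @param k_range candidate topic counts (default 2..20).
#' @param holdout held-out cell fraction.
#' @param seed integer seed (controls the split and each fit's init).
#' @param tie_tol relative perplexity difference treated as a tie when
#'   picking the smallest tied `k`.
#' @param ... further arguments to the fitting engine (`max_iter`, `tol`).
#' @return a `pci_kscan` list: `k` (chosen), `table` (k, perplexity,
#'   n_iter).
#' @export
perplexity_scan <- function(counts, k_range = 2:20, holdout = 0.2,
                            seed = 1L, tie_tol = 0.005, ...) {
  .assert(length(k_range) >= 1, "k_range must be non-empty")
  m <- .lda_check_counts(counts)
  .assert(ncol(m) >= 10, "need >= 10 cells for a perplexity scan")
  set.seed(seed)
  n_test <- max(1L, round(holdout * ncol(m)))
  test_idx <- sort(sample(ncol(m), n_test))
  train <- m[, -test_idx, drop = FALSE]
  test <- as.matrix(m[, test_idx, drop = FALSE])
  fold_in <- matrix(rbinom(length(test), as.vector(test), 0.5),
                    nrow(test), dimnames = dimnames(test))
  score_half <- test - fold_in

  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    fit <- .lda_engine(train, k, seed = seed, ...)
    held <- .lda_engine(methods::as(fold_in, "CsparseMatrix"), k, n_fixed = k,
                        log_beta_fixed = log(pmax(fit$gene_topic, 1e-300)),
                        seed = seed, update_beta = FALSE)
    pred <- fit$gene_topic %*% held$topic_cell   # V x D word probabilities
    ll <- sum(score_half * log(pmax(pred, 1e-300)))
    data.frame(k = k, perplexity = exp(-ll / max(sum(score_half), 1)),
               n_iter = fit$n_iter)
  })
  tab <- do.call(rbind, rows)
  # smallest k whose perplexity ties the minimum; continuous scores never
  # tie exactly, so scores within tie_tol (relative) of the minimum count
  # as tied
  best <- tab$k[which(tab$perplexity <= (1 + tie_tol) * min(tab$perplexity))[1]]
  structure(list(k = best, table = tab), class = "pci_kscan")
}

#' @export
print.pci_kscan <- function(x, ...) {
  cat(sprintf("Perplexity scan over k = %s: chose k = %d\n",
              paste(range(x$table$k), collapse = ".."), x$k))
  invisible(x)
}

#' Fit the singlet-stage LDA model
#'
#' Fits a k-topic LDA (batch variational Bayes, symmetric priors `1/k`,
#' convergence when the relative score change drops below `tol` or after
#' `max_iter` passes) to the singlet cells — in the intended workflow the
#' cancer and stromal singlets.
#'
#' @param counts integer gene x cell count matrix of the singlet cells.
#' @param k topic count (>= 2).
#' @param seed integer seed.
#' @param max_iter maximum variational passes.
#' @param tol relative score-change convergence tolerance.
#' @return a `pci_topics` model: `k`, `gene_topic` (genes x topics, columns
#'   sum to 1), `topic_cell` (topics x cells, columns sum to 1),
#'   `stage = "singlet"`.
#' @export
fit_singlet_lda <- function(counts, k, seed = 1L, max_iter = 200, tol = 1e-4) {
  .assert(k >= 2, "k must be >= 2")
  res <- .lda_engine(counts, k, seed = seed, max_iter = max_iter, tol = tol)
  structure(list(k = as.integer(k), gene_topic = res$gene_topic,
                 topic_cell = res$topic_cell, stage = "singlet",
                 n_singlet_topics = as.integer(k), extra_topics = integer(0),
                 scores = res$scores, perplexity = res$perplexity),
            class = "pci_topics")
}

#' Fit the doublet-stage LDA model with additional topics
#'
#' Fits a `k + extra`-topic model to the doublet cells. The first `k`
#' gene-topic columns are taken from the singlet model and, by default,
#' held fixed, so that doublet-specific expression has to be absorbed by
#' the `extra` free topics; cells receive probabilities over all `k +
#' extra` topics. With `freeze = FALSE` the singlet topics only warm-start
#' the fit and all topics are updated. With `extra = 0` the doublets are
#' simply scored under the frozen singlet model.
#'
#' @param counts integer gene x cell count matrix of the doublet cells;
#'   gene universe must equal the singlet model's.
#' @param singlet_model a `pci_topics` from [fit_singlet_lda()].
#' @param extra additional doublet-specific topics (default 20).
#' @param seed integer seed.
#' @param freeze hold the singlet topics fixed (default) or warm-start.
#' @param max_iter,tol convergence controls.
#' @param seed_groups optional named vector mapping each doublet barcode
#'   to a seeding stratum (typically its sample of origin); each
#'   stratum's summed residual then seeds one extra topic, which is
#'   robust when interaction programs differ between samples or clinical
#'   groups.
#' @return a `pci_topics` model with `stage = "doublet"` and
#'   `extra_topics` marking the doublet-specific topic indices.
#' @export
fit_doublet_lda <- function(counts, singlet_model, extra = 20, seed = 1L,
                            freeze = TRUE, max_iter = 200, tol = 1e-4,
                            seed_groups = NULL) {
  stopifnot(inherits(singlet_model, "pci_topics"))
  m <- .lda_check_counts(counts)
  mism <- union(setdiff(rownames(m), rownames(singlet_model$gene_topic)),
                setdiff(rownames(singlet_model$gene_topic), rownames(m)))
  .assert(length(mism) == 0,
          "gene universes differ between doublet matrix and singlet model: %s%s",
          paste(head(mism, 5), collapse = ", "),
          if (length(mism) > 5) sprintf(" (+%d more)", length(mism) - 5) else "")
  m <- m[rownames(singlet_model$gene_topic), , drop = FALSE]
  k <- singlet_model$k
  log_beta <- log(pmax(singlet_model$gene_topic, 1e-300))
  if (freeze) {
    # Residual-module init for the free topics: against frozen, already
    # well-fitted singlet topics a flat random start never wins tokens.
    # Each doublet cell is first scored under the frozen singlet topics
    # alone; the positive part of (observed - expected) counts is the
    # expression the singlet programs cannot explain. The genes carrying
    # most of that residual are clustered by residual co-expression across
    # cells (k-means, seeded), and each extra topic starts from one gene
    # module — an interaction program induced in many cells of a group is
    # exactly such a co-occurring module, so it seeds a single topic
    # instead of fragmenting over near-duplicate ones.
    lambda_init <- NULL
    if (extra > 0) {
      base <- .lda_engine(m, k, n_fixed = k, log_beta_fixed = log_beta,
                          seed = seed, update_beta = FALSE)
      theta <- base$topic_cell                       # k x D
      expected <- singlet_model$gene_topic %*% theta # V x D profile
      obs <- as.matrix(m)
      expected <- sweep(expected, 2, colSums(obs), "*")
      resid <- pmax(obs - expected, 0)
      rs <- rowSums(resid)
      if (!is.null(seed_groups)) {
        # one topic per seeding stratum (typically the sample of origin):
        # interaction programs are organised by sample/clinical group, so
        # each stratum's summed residual seeds a topic; same-program
        # strata produce near-duplicate topics that the ranking stage
        # merges by cosine similarity. Remaining topics start flat.
        sg <- factor(seed_groups[colnames(m)])
        lev <- levels(sg)
        lambda_init <- sapply(seq_len(extra), function(t) {
          w <- if (t <= length(lev))
            rowSums(resid[, sg == lev[t], drop = FALSE]) else numeric(nrow(m))
          w + 1 / (k + extra)
        })
        res <- .lda_engine(m, k + extra, n_fixed = k, log_beta_fixed = log_beta,
                           seed = seed, max_iter = max_iter, tol = tol,
                           update_beta = TRUE, lambda_init = lambda_init)
        model <- .pci_doublet_model(res, k, extra, freeze)
        model$gene_topic[, seq_len(k)] <- singlet_model$gene_topic
        return(model)
      }
      top <- order(-rs)[seq_len(min(500L, sum(rs > 0)))]
      n_mod <- min(extra, length(top))
      # k-means on the L2-normalised residual gene profiles: genes induced
      # together across the same cells (an interaction program) share a
      # profile direction and seed a common topic
      set.seed(seed)
      profile <- resid[top, , drop = FALSE]
      profile <- profile / pmax(sqrt(rowSums(profile^2)), 1e-12)
      cl <- if (n_mod > 1 && length(top) > n_mod)
        kmeans(profile, centers = n_mod, nstart = 5, iter.max = 50)$cluster
      else rep_len(seq_len(max(n_mod, 1)), length(top))
      lambda_init <- sapply(seq_len(extra), function(t) {
        w <- numeric(nrow(m))
        if (t <= n_mod) w[top[cl == t]] <- rs[top[cl == t]]
        w + 1 / (k + extra)
      })
    }
    res <- .lda_engine(m, k + extra, n_fixed = k, log_beta_fixed = log_beta,
                       seed = seed, max_iter = max_iter, tol = tol,
                       update_beta = extra > 0, lambda_init = lambda_init)
  } else {
    res <- .lda_engine(m, k + extra, seed = seed, max_iter = max_iter, tol = tol)
  }
  model <- .pci_doublet_model(res, k, extra, freeze)
  if (freeze)  # frozen topics are carried over bit-identically
    model$gene_topic[, seq_len(k)] <- singlet_model$gene_topic
  model
}

.pci_doublet_model <- function(res, k, extra, freeze) {
  structure(list(k = as.integer(k + extra), gene_topic = res$gene_topic,
                 topic_cell = res$topic_cell, stage = "doublet",
                 n_singlet_topics = as.integer(k),
                 extra_topics = if (extra > 0) seq(k + 1, k + extra) else integer(0),
                 scores = res$scores, perplexity = res$perplexity,
                 frozen = freeze),
            class = "pci_topics")
}

#' @export
print.pci_topics <- function(x, ...) {
  cat(sprintf("LDA topic model (%s stage): %d topics x %d genes x %d cells\n",
              x$stage, x$k, nrow(x$gene_topic), ncol(x$topic_cell)))
  if (length(x$extra_topics))
    cat(sprintf("  %d doublet-specific topics (%s)\n", length(x$extra_topics),
                if (isTRUE(x$frozen)) "singlet topics frozen" else "warm start"))
  invisible(x)
}

#' Rank genes within doublet-specific topics
#'
#' Each cell is assigned to the doublet-specific topic on which it places
#' the highest probability (the topic with "the highest probability score
#' for each doublet topic"). Because a variational fit with more free
#' topics than distinct interaction programs produces near-duplicate
#' topics, doublet-specific topics whose gene distributions have cosine
#' similarity above `merge_cos` are first merged (mass-weighted average,
#' reported under the lowest topic index). For each (merged) topic,
#' candidate genes are those whose gene-topic probability peaks in that
#' topic rather than in any singlet topic or other doublet topic; each
#' candidate is scored by the number of assigned cells in which it is
#' detected (count > 0). Genes seen in fewer than `min_cells` such cells
#' are removed and the top `top_n` by cell count are kept (probability
#' tie-break, then lexicographic).
#'
#' @param model a doublet-stage `pci_topics`.
#' @param counts the integer count matrix the model was fitted on.
#' @param min_cells minimum assigned cells detecting the gene.
#' @param top_n genes kept per topic.
#' @param merge_cos cosine-similarity threshold above which two
#'   doublet-specific topics are treated as one (set to 1 to disable).
#' @param peak_ratio margin by which a candidate gene's probability in its
#'   doublet topic must exceed its largest singlet-topic probability. A
#'   pure argmax (`peak_ratio = 1`) is extremely sensitive to sampling
#'   noise on flat genes, which would otherwise crowd the top list.
#' @return a `pci_ranking` data.frame: topic, gene, probability, n_cells.
#' @export
rank_topic_genes <- function(model, counts, min_cells = 5, top_n = 30,
                             merge_cos = 0.9, peak_ratio = 2) {
  stopifnot(inherits(model, "pci_topics"))
  .assert(model$stage == "doublet", "gene ranking is defined for doublet-stage models")
  m <- .lda_check_counts(counts)[rownames(model$gene_topic), , drop = FALSE]
  extras <- model$extra_topics
  if (!length(extras)) {
    warning("model has no doublet-specific topics; empty ranking")
    return(.empty_ranking())
  }

  # mass per extra topic (summed cell probability) for merge weighting
  mass <- rowSums(model$topic_cell[extras, , drop = FALSE])
  beta_x <- model$gene_topic[, extras, drop = FALSE]

  # single-link merge of near-duplicate doublet topics
  groups <- seq_along(extras)
  if (merge_cos < 1 && length(extras) > 1) {
    norms <- sqrt(colSums(beta_x^2))
    cs <- crossprod(beta_x) / outer(norms, norms)
    for (i in seq_along(extras)) for (j in seq_len(i - 1)) {
      if (cs[i, j] > merge_cos) groups[groups == groups[i]] <- groups[j]
    }
  }
  merged_ids <- sort(unique(groups))
  merged_beta <- sapply(merged_ids, function(gid) {
    idx <- which(groups == gid)
    w <- mass[idx] + 1e-12
    as.numeric(beta_x[, idx, drop = FALSE] %*% (w / sum(w)))
  })
  rownames(merged_beta) <- rownames(model$gene_topic)
  colnames(merged_beta) <- paste0("topic", extras[merged_ids])

  # cell -> merged doublet topic: sum member-topic probabilities
  cell_mass <- sapply(merged_ids, function(gid)
    colSums(model$topic_cell[extras[which(groups == gid)], , drop = FALSE]))
  assign <- max.col(as.matrix(cell_mass), ties.method = "first")

  # gene peaks over singlet topics + merged doublet topics; a candidate
  # must beat its best singlet-topic probability by peak_ratio
  sing <- model$gene_topic[, setdiff(seq_len(model$k), extras), drop = FALSE]
  sing_max <- if (ncol(sing)) apply(sing, 1, max) else rep(0, nrow(merged_beta))
  peak_mat <- cbind(sing, merged_beta)
  gene_peak <- max.col(peak_mat, ties.method = "first") - ncol(sing)
  best_extra <- apply(merged_beta, 1, max)
  gene_peak[best_extra < peak_ratio * sing_max] <- 0L

  out <- list()
  for (gi in seq_along(merged_ids)) {
    t_id <- extras[merged_ids[gi]]
    cells_t <- colnames(m)[assign == gi]
    cand <- rownames(model$gene_topic)[gene_peak == gi]
    if (length(cells_t) == 0 || length(cand) == 0) next
    detected <- Matrix::rowSums(m[cand, cells_t, drop = FALSE] > 0)
    prob <- merged_beta[cand, gi]
    keep <- detected >= min_cells
    if (!any(keep)) next
    df <- data.frame(topic = t_id, gene = cand[keep],
                     probability = prob[keep],
                     n_cells = as.integer(detected[keep]),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_cells, -df$probability, df$gene), ]
    out[[as.character(t_id)]] <- head(df, top_n)
  }
  if (!length(out)) {
    warning("no cells assigned to any doublet-specific topic; empty ranking")
    return(.empty_ranking())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cell_topic") <- setNames(extras[merged_ids[assign]], colnames(m))
  class(res) <- c("pci_ranking", "data.frame")
  res
}

.empty_ranking <- function() {
  structure(data.frame(topic = integer(0), gene = character(0),
                       probability = numeric(0), n_cells = integer(0),
                       stringsAsFactors = FALSE),
            class = c("pci_ranking", "data.frame"))
}

#' @export
print.pci_ranking <- function(x, ...) {
  cat(sprintf("Topic gene ranking: %d genes over %d doublet-specific topic(s)\n",
              nrow(x), length(unique(x$topic))))
  invisible(x)
}
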