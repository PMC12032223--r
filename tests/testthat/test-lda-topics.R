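# Small corpora drawn from known topic structure, built in code.
make_topic_corpus <- function(n_topics = 3, vocab = 60, docs = 120,
                              tokens = 80, seed = 1, mix = FALSE) {
  set.seed(seed)
  block <- vocab / n_topics
  beta <- matrix(1e-4, vocab, n_topics)
  for (t in seq_len(n_topics))
    beta[seq((t - 1) * block + 1, t * block), t] <- 1
  beta <- sweep(beta, 2, colSums(beta), "/")
  m <- sapply(seq_len(docs), function(d) {
    theta <- if (mix) as.numeric(rmultinom(1, 1, rep(1, n_topics))) else {
      z <- rgamma(n_topics, 0.3); z / sum(z)
    }
    rmultinom(1, tokens, beta %*% theta)
  })
  rownames(m) <- sprintf("w%02d", seq_len(vocab))
  colnames(m) <- sprintf("d%03d", seq_len(docs))
  toy_counts(m, genes = rownames(m), barcodes = colnames(m))
}

test_that("perplexity scan recovers a small known topic count", {
  m <- make_topic_corpus(n_topics = 3, seed = 2, mix = TRUE)
  scan <- perplexity_scan(m, k_range = 2:6, seed = 1)
  expect_lte(scan$k, 5)
  p3 <- scan$table$perplexity[scan$table$k == 3]
  expect_lte(p3, 1.05 * min(scan$table$perplexity))

  expect_equal(perplexity_scan(m, k_range = 4, seed = 1)$k, 4)
  expect_error(perplexity_scan(m, k_range = integer(0)), "non-empty")

  s2 <- perplexity_scan(m, k_range = 2:6, seed = 1)
  expect_identical(scan$table, s2$table)   # fixed seed, identical score table
})

test_that("singlet LDA satisfies its normalisation contracts", {
  m <- make_topic_corpus(n_topics = 2, vocab = 40, docs = 60, seed = 3)
  fit <- fit_singlet_lda(m, k = 2, seed = 1)
  expect_equal(unname(colSums(fit$gene_topic)), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(colSums(fit$topic_cell)), rep(1, 60), tolerance = 1e-8)
  expect_true(all(fit$gene_topic >= 0 & fit$gene_topic <= 1))
  expect_error(fit_singlet_lda(m / 2, k = 2), "integer")
  expect_error(fit_singlet_lda(m, k = 1), "k must be")
})

test_that("two planted disjoint programs are recovered at k = 2", {
  m <- make_topic_corpus(n_topics = 2, vocab = 40, docs = 150, tokens = 120,
                         seed = 4, mix = TRUE)
  fit <- fit_singlet_lda(m, k = 2, seed = 1)
  top10 <- apply(fit$gene_topic, 2, function(b)
    rownames(m)[order(-b)][1:10])
  expect_length(intersect(top10[, 1], top10[, 2]), 0)
  prog1 <- sprintf("w%02d", 1:20); prog2 <- sprintf("w%02d", 21:40)
  hits <- max(length(intersect(top10[, 1], prog1)),
              length(intersect(top10[, 1], prog2)))
  expect_gte(hits, 8)   # >= 80% of a topic's top-10 from one program
})

test_that("a degenerate one-profile corpus gives near-empirical topic distributions", {
  set.seed(5)
  doc <- rmultinom(1, 200, rep(1, 30))
  m <- toy_counts(matrix(rep(doc, 40), 30, 40))
  fit <- fit_singlet_lda(m, k = 2, seed = 1)
  emp <- Matrix::rowSums(m) / sum(m)
  for (t in 1:2)
    expect_lt(sum(abs(fit$gene_topic[, t] - emp)) / 2, 0.1)  # total variation
})

test_that("doublet stage freezes singlet topics and flags universe mismatches", {
  m <- make_topic_corpus(n_topics = 2, vocab = 40, docs = 60, seed = 6)
  sfit <- fit_singlet_lda(m, k = 2, seed = 1)
  m2 <- make_topic_corpus(n_topics = 2, vocab = 40, docs = 30, seed = 7)
  dfit <- fit_doublet_lda(m2, sfit, extra = 3, seed = 1)
  expect_equal(dfit$k, 5)
  expect_identical(dfit$extra_topics, 3:5)
  # frozen topics bit-identical between the stages
  expect_identical(unname(dfit$gene_topic[, 1:2]), unname(sfit$gene_topic))

  bad <- m2; rownames(bad)[1] <- "zzz"
  expect_error(fit_doublet_lda(bad, sfit, extra = 2), "universes differ")

  # extra = 0 scores the doublets under the frozen singlet model
  d0 <- fit_doublet_lda(m2, sfit, extra = 0, seed = 1)
  expect_equal(d0$k, 2)
  expect_identical(unname(d0$gene_topic), unname(sfit$gene_topic))
  expect_equal(unname(colSums(d0$topic_cell)), rep(1, 30), tolerance = 1e-8)
})

test_that("without planted interaction signal extra topics stay small", {
  cfg <- tiny_sim_config(seed = 31, interaction_program_size = 0,
                         interaction_down_size = 0,
                         n_singlets_per_sample = 250)
  sim <- simulate_pci_dataset(cfg)
  comp <- sim$truth$composition
  ann <- sim$annotation
  sing <- ann$barcode[!is.na(ann$cell_type) &
                        ann$cell_type %in% c("Cancer", "Fibroblast")]
  dbl <- comp$barcode[comp$class == "doublet" &
                        comp$label == "Cancer+Fibroblast"]
  sfit <- fit_singlet_lda(sim$counts[, sing], k = 5, seed = 1)
  dfit <- fit_doublet_lda(sim$counts[, dbl], sfit, extra = 20, seed = 1)
  extra_mass <- colSums(dfit$topic_cell[dfit$extra_topics, , drop = FALSE])
  expect_lt(median(extra_mass), median(1 - extra_mass))
})

test_that("a planted interaction program lands in a doublet-specific topic", {
  cfg <- tiny_sim_config(seed = 33, n_singlets_per_sample = 250)
  sim <- simulate_pci_dataset(cfg)
  comp <- sim$truth$composition
  ann <- sim$annotation
  sing <- ann$barcode[!is.na(ann$cell_type) &
                        ann$cell_type %in% c("Cancer", "Fibroblast")]
  dbl <- comp$barcode[comp$class == "doublet" &
                        comp$label == "Cancer+Fibroblast"]
  sfit <- fit_singlet_lda(sim$counts[, sing], k = 5, seed = 1)
  dfit <- fit_doublet_lda(sim$counts[, dbl], sfit, extra = 20, seed = 1)
  programs <- lapply(sim$truth$planted$programs, `[[`, "up")
  best <- 0
  for (t in dfit$extra_topics) {
    top10 <- rownames(dfit$gene_topic)[order(-dfit$gene_topic[, t])][1:10]
    for (p in programs)
      best <- max(best, length(intersect(top10, p)) / 10)
  }
  expect_gte(best, 0.5)
})

test_that("topic gene ranking applies the cell-count and size filters exactly", {
  # hand-built doublet-stage model: 1 singlet + 2 extra topics, 50 genes
  genes <- sprintf("g%02d", 1:50)
  cells <- sprintf("c%02d", 1:12)
  mk_model <- function(n_owned) {
    gene_topic <- matrix(1e-6, 50, 3, dimnames = list(genes, NULL))
    gene_topic[seq_len(n_owned), 2] <- (n_owned:1)  # topic 2 owns g01..g<n>
    gene_topic[41:50, 1] <- 1                       # singlet topic owns rest
    gene_topic[50, 3] <- 5
    gene_topic <- sweep(gene_topic, 2, colSums(gene_topic), "/")
    topic_cell <- matrix(0, 3, 12, dimnames = list(NULL, cells))
    topic_cell[2, ] <- 0.9; topic_cell[1, ] <- 0.1
    structure(list(k = 3L, gene_topic = gene_topic, topic_cell = topic_cell,
                   stage = "doublet", n_singlet_topics = 1L,
                   extra_topics = 2:3, frozen = TRUE), class = "pci_topics")
  }
  counts <- matrix(0, 50, 12, dimnames = list(genes, cells))
  counts[1:40, ] <- 1
  counts["g01", 5:12] <- 0   # g01 detected in 4 cells -> dropped
  counts["g02", 6:12] <- 0   # g02 detected in 5 cells -> kept
  rk <- rank_topic_genes(mk_model(25), toy_counts(counts, genes, cells),
                         merge_cos = 1)
  expect_false("g01" %in% rk$gene)
  expect_true("g02" %in% rk$gene)
  expect_equal(nrow(rk), 24)          # 25 owned, one below the cell floor
  expect_true(all(diff(rk$n_cells) <= 0))
  rk40 <- rank_topic_genes(mk_model(40), toy_counts(counts, genes, cells),
                           merge_cos = 1)
  expect_equal(nrow(rk40), 30)        # 39 qualifying genes truncate to 30
  expect_equal(rk40$n_cells[1], 12L)
})
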