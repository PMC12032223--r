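# One shared small-but-separable dataset for the classifier tests.
deconv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_pci_dataset(tiny_sim_config(seed = 13,
                                                  n_singlets_per_sample = 200))
      qf <- qc_filter(sim$counts, min_counts = 0, max_counts = Inf,
                      min_genes_per_cell = 0)
      ann <- sim$annotation[sim$annotation$barcode %in% colnames(qf$counts), ]
      cache <<- list(sim = sim, counts = qf$counts, ann = ann,
                     nm = lognormalize(qf$counts))
    }
    cache
  }
})

test_that("marker ranking matches a brute-force rank-sum oracle", {
  set.seed(4)
  x <- matrix(rpois(50 * 90, 3), 50, 90,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:90)))
  ann <- data.frame(barcode = colnames(x),
                    cell_type = rep(c("A", "B", "C"), each = 30))
  x[1, ann$cell_type == "A"] <- x[1, ann$cell_type == "A"] + 20  # A-only gene
  nm <- lognormalize(toy_counts(x, genes = rownames(x), barcodes = colnames(x)))
  cat_ <- marker_genes(nm, ann, top_n = 10)

  expect_equal(cat_[["A"]]$gene[1], "g01")

  # independent naive reimplementation of the same statistic
  oracle <- function(nm, ann, ty, top_n) {
    xx <- as.matrix(nm[, ann$barcode])
    ind <- ann$cell_type == ty
    n1 <- sum(ind); n2 <- sum(!ind); n <- n1 + n2
    stats <- apply(xx, 1, function(v) {
      r <- rank(v)
      w <- sum(r[ind])
      tt <- table(r)
      v2 <- (n1 * n2 / 12) * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
      if (v2 <= 0) 0 else (w - n1 * (n + 1) / 2) / sqrt(v2)
    })
    lfc <- rowMeans(xx[, ind]) - rowMeans(xx[, !ind])
    rownames(xx)[order(-stats, -lfc, rownames(xx))][seq_len(top_n)]
  }
  for (ty in c("A", "B", "C"))
    expect_identical(cat_[[ty]]$gene, oracle(nm, ann, ty, 10))
})

test_that("marker ranking edge cases: few genes, small types", {
  f <- deconv_fixture()
  small_nm <- f$nm[1:20, ]
  cat_ <- marker_genes(small_nm, f$ann, top_n = 100)
  expect_true(all(vapply(cat_, nrow, 0L) == 20))  # fewer genes than top_n

  ann2 <- f$ann
  idx <- which(ann2$cell_type == "Tcell")
  ann2$cell_type[idx[-(1:2)]] <- NA  # leave 2 Tcells
  expect_warning(marker_genes(f$nm, ann2), "Tcell")
})

test_that("synthetic doublets cover all type combinations and conserve counts", {
  f <- deconv_fixture()
  synth <- make_synthetic_doublets(f$counts, f$ann, per_class = 5, seed = 1)
  expect_setequal(unique(synth$labels),
                  c("Cancer+Cancer", "Cancer+Fibroblast", "Cancer+Tcell",
                    "Fibroblast+Fibroblast", "Fibroblast+Tcell",
                    "Tcell+Tcell"))   # 3 + 3*2/2 classes
  expect_true(all(synth$provenance$source1 != synth$provenance$source2 |
                    synth$labels != doublet_label(synth$provenance$source1,
                                                  synth$provenance$source1)))
  # conservation: each vector equals the sum of its recorded sources
  for (i in sample(ncol(synth$counts), 5)) {
    expect_equal(as.numeric(synth$counts[, i]),
                 as.numeric(f$counts[, synth$provenance$source1[i]] +
                              f$counts[, synth$provenance$source2[i]]))
  }

  one <- f$ann[f$ann$cell_type == "Cancer", ]
  s1 <- make_synthetic_doublets(f$counts, one, per_class = 3, seed = 1)
  expect_identical(unique(s1$labels), "Cancer+Cancer")
})

test_that("classifier is deterministic and calls constructed doublets correctly", {
  f <- deconv_fixture()
  mk <- marker_genes(f$nm, f$ann, top_n = 30)
  synth <- make_synthetic_doublets(f$counts, f$ann, per_class = 40, seed = 2)
  clf <- train_classifier(f$counts, f$ann, synth, mk, seed = 2, num_trees = 200)
  c1 <- classify_barcodes(f$counts, clf)
  c2 <- classify_barcodes(f$counts, clf)
  expect_identical(c1, c2)
  expect_true(all(c1$probability >= 0 & c1$probability <= 1))

  # barcodes that are literal sums of two singlets of types A and B
  ca <- f$ann$barcode[f$ann$cell_type == "Cancer"][1:10]
  fb <- f$ann$barcode[f$ann$cell_type == "Fibroblast"][1:10]
  sums <- f$counts[, ca] + f$counts[, fb]
  colnames(sums) <- sprintf("mix%02d", 1:10)
  calls <- classify_barcodes(sums, clf)
  expect_gte(mean(calls$label == "Cancer+Fibroblast"), 0.8)

  empty <- classify_barcodes(f$counts[, 0], clf)
  expect_equal(nrow(empty), 0)
})

test_that("training rejects an empty feature set and warns on missing markers", {
  f <- deconv_fixture()
  mk <- marker_genes(f$nm, f$ann, top_n = 5)
  synth <- make_synthetic_doublets(f$counts, f$ann, per_class = 5, seed = 1)
  bad <- f$counts[setdiff(rownames(f$counts),
                          unique(unlist(lapply(mk, `[[`, "gene")))), ]
  expect_error(suppressWarnings(train_classifier(bad, f$ann, synth, mk, seed = 1)),
               "no marker features")
})

test_that("enrichment scores are calibrated under the random-pairing null", {
  hits <- 0; n_types <- 0; enr <- c()
  for (s in 1:20) {
    set.seed(s)
    labels <- null_pair_labels(600, 150, c("A", "B", "C", "D"))
    calls <- calls_from_labels(labels)
    ann <- data.frame(barcode = calls$barcode, sample = "S1")
    res <- doublet_enrichment_test(calls, ann, n_sim = 200, seed = s,
                                   mode = "pooled")
    hits <- hits + sum(res$p_value < 0.05)
    n_types <- n_types + nrow(res)
    enr <- c(enr, res$enrichment)
  }
  expect_lte(hits / n_types, 0.10)
  expect_lt(abs(mean(enr) - 1), 3 * sd(enr) / sqrt(length(enr)))
})

test_that("a planted doublet-type excess is detected", {
  set.seed(9)
  labels <- c(null_pair_labels(600, 50, c("A", "B", "C", "D")),
              rep(doublet_label("A", "B"), 60))   # 5x excess of A+B
  calls <- calls_from_labels(labels)
  ann <- data.frame(barcode = calls$barcode, sample = "S1")
  res <- doublet_enrichment_test(calls, ann, n_sim = 500, seed = 1,
                                 mode = "pooled")
  ab <- res[res$type == "A+B", ]
  expect_gt(ab$enrichment, 1)
  expect_lt(ab$p_value, 0.05)
  expect_error(doublet_enrichment_test(calls, ann, n_sim = 0), "n_sim")
})

test_that("null p-values are approximately uniform (KS) across simulated datasets", {
  pvals <- c()
  for (s in 1:200) {
    set.seed(1000 + s)
    labels <- null_pair_labels(4500, 450, c("A", "B", "C", "D", "E"))
    calls <- calls_from_labels(labels)
    ann <- data.frame(barcode = calls$barcode, sample = "S1")
    res <- doublet_enrichment_test(calls, ann, n_sim = 200, seed = s,
                                   mode = "pooled")
    pvals <- c(pvals, res$p_value)
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("doublet-type filter applies the three stated conditions exactly", {
  tab <- structure(data.frame(
    type = c("A+B", "A+A", "B+C", "C+D"),
    count = c(12L, 50L, 9L, 15L),
    expected = 1, enrichment = 2,
    p_value = c(0.01, 0.001, 0.001, 0.2), stringsAsFactors = FALSE),
    class = c("pci_enrichment", "data.frame"))
  kept <- filter_doublet_calls(tab)
  expect_identical(kept$type, "A+B")
  expect_equal(nrow(filter_doublet_calls(tab[0, ])), 0)
  all_kept <- filter_doublet_calls(tab, min_count = 0, alpha = 1.000001,
                                   heterotypic_only = FALSE)
  expect_identical(all_kept, tab)
})

test_that("interaction networks normalise per-group counts as stated", {
  # 3,500-cell group with 7 retained A+B doublets -> normalised count 20
  labels <- c(rep("A", 2000), rep("B", 1493), rep(doublet_label("A", "B"), 7))
  calls <- calls_from_labels(labels)
  ann <- data.frame(barcode = calls$barcode, group = "G1")
  filtered <- data.frame(type = doublet_label("A", "B"))
  net <- interaction_network(filtered, calls, ann)
  expect_equal(net$G1$count, 7L)
  expect_equal(net$G1$normalized, 20)
  # scale 1 with a single-cell group equals the raw count
  ann2 <- data.frame(barcode = calls$barcode[1], group = "solo")
  net2 <- interaction_network(filtered, calls[1, ], ann2, scale = 1)
  expect_equal(nrow(net2$solo), 0)   # no doublet of that type -> edge absent
})
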