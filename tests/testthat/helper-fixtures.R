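# Shared fixtures: all built in code, sized for fast unit tests.

# a small but complete simulated dataset (5 types, 400 genes)
tiny_sim_config <- function(seed = 42, ...) {
  args <- modifyList(
    list(n_cell_types = 3, n_genes = 400, n_markers_per_type = 10,
         n_samples = 3, n_singlets_per_sample = 120,
         doublet_fraction = 0.15, interaction_program_size = 8,
         interaction_down_size = 4, lr_pairs = 3, lr_decoys = 5,
         targets_per_pathway = 6, n_tfs = 3, targets_per_tf = 12,
         n_mito_genes = 8, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# toy count matrix with named dims
toy_counts <- function(values, genes = NULL, barcodes = NULL) {
  m <- as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- barcodes %||% sprintf("c%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a pci_calls table directly from labels
calls_from_labels <- function(labels, barcodes = sprintf("b%04d", seq_along(labels))) {
  parts <- strsplit(labels, "+", fixed = TRUE)
  structure(data.frame(
    barcode = barcodes, label = labels,
    is_doublet = lengths(parts) == 2,
    type1 = vapply(parts, `[`, "", 1),
    type2 = vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, ""),
    probability = 1, stringsAsFactors = FALSE),
    class = c("pci_calls", "data.frame"))
}

# labels drawn under the independent random-pairing null
null_pair_labels <- function(n_singlets, n_doublets, types, probs = NULL) {
  probs <- probs %||% rep(1 / length(types), length(types))
  sing <- sample(types, n_singlets, replace = TRUE, prob = probs)
  t1 <- sample(types, n_doublets, replace = TRUE, prob = probs)
  t2 <- sample(types, n_doublets, replace = TRUE, prob = probs)
  c(sing, doublet_label(t1, t2))
}
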