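#' Per-type expression rate profiles
#'
#' Builds one expression-rate vector per cell type over a shared baseline:
#' every type shares the same gamma-distributed baseline rates, and each
#' type's disjoint marker block is elevated `marker_fold`-fold. Genes carrying
#' planted structure (interaction programs, ligand-receptor pairs, pathway
#' targets, regulon targets) have their baseline floored at the mean rate so
#' that perturbations act on expressed genes.
#'
#' @param config a [sim_config()] object.
#' @return a `pci_profiles` list: `rates` (gene x type matrix, strictly
#'   positive), `markers` (per-type marker gene ids, pairwise disjoint),
#'   `gene_ids`, `baseline`.
#' @export
make_type_profiles <- function(config) {
  stopifnot(inherits(config, "pci_sim_config"))
  layout <- .sim_gene_layout(config)   # also enforces the sizing precondition
  gene_ids <- .sim_gene_ids(config)
  types <- .sim_type_names(config)
  set.seed(config$seed)

  baseline <- rgamma(config$n_genes, shape = 0.4, rate = 2) + 0.01
  planted <- c(layout$program_up, layout$program_down, layout$lr,
               layout$pw, layout$tf)
  baseline[planted] <- pmax(baseline[planted], 3 * mean(baseline))
  baseline[layout$markers] <- pmax(baseline[layout$markers], mean(baseline))

  rates <- matrix(baseline, nrow = config$n_genes, ncol = config$n_cell_types,
                  dimnames = list(gene_ids, types))
  markers <- vector("list", config$n_cell_types)
  names(markers) <- types
  for (t in seq_len(config$n_cell_types)) {
    idx <- layout$markers[seq((t - 1) * config$n_markers_per_type + 1,
                              t * config$n_markers_per_type)]
    rates[idx, t] <- rates[idx, t] * config$marker_fold
    markers[[t]] <- gene_ids[idx]
  }
  structure(list(rates = rates, markers = markers, gene_ids = gene_ids,
                 baseline = baseline),
            class = "pci_profiles")
}

# Deterministic planted structure over the gene layout: interaction programs
# per group, ligand-receptor pairs with a downstream pathway each, and signed
# TF regulons with a group-specific activity sign.
.plant_structure <- function(config) {
  layout <- .sim_gene_layout(config)
  gene_ids <- .sim_gene_ids(config)
  groups <- unique(unname(config$group_of_sample))
  ng <- length(groups)

  take <- function(block, i, size) {
    if (size == 0) return(character(0))
    gene_ids[block[seq((i - 1) * size + 1, i * size)]]
  }
  programs <- lapply(seq_len(ng), function(i) list(
    up = take(layout$program_up, i, config$interaction_program_size),
    down = take(layout$program_down, i, config$interaction_down_size)))
  names(programs) <- groups

  lr <- NULL
  if (config$lr_pairs > 0) {
    lg <- gene_ids[layout$lr[seq(1, 2 * config$lr_pairs, by = 2)]]
    rg <- gene_ids[layout$lr[seq(2, 2 * config$lr_pairs, by = 2)]]
    lr <- data.frame(
      ligand = lg, receptor = rg,
      group = groups[((seq_len(config$lr_pairs) - 1) %% ng) + 1],
      pathway = sprintf("PW_PLANT%02d", seq_len(config$lr_pairs)),
      stringsAsFactors = FALSE)
  }
  pathways <- lapply(seq_len(config$lr_pairs), function(i)
    take(layout$pw, i, config$targets_per_pathway))
  names(pathways) <- lr$pathway

  regulons <- NULL
  tf_truth <- NULL
  if (config$n_tfs > 0) {
    sign_pattern <- rep(c(1L, 1L, 1L, -1L, -1L),
                        length.out = config$targets_per_tf)
    regulons <- do.call(rbind, lapply(seq_len(config$n_tfs), function(i)
      data.frame(tf = sprintf("TF%02d", i),
                 target = take(layout$tf, i, config$targets_per_tf),
                 sign = sign_pattern, stringsAsFactors = FALSE)))
    tf_truth <- data.frame(
      tf = sprintf("TF%02d", seq_len(config$n_tfs)),
      group = groups[((seq_len(config$n_tfs) - 1) %% ng) + 1],
      sign = rep_len(c(1L, -1L), config$n_tfs),
      stringsAsFactors = FALSE)
  }
  list(programs = programs, lr_pairs = lr, pathway_targets = pathways,
       regulons = regulons, tf_activity = tf_truth)
}

.draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (is.infinite(dispersion)) rpois(n, mu) else rnbinom(n, mu = mu, size = dispersion)
}

.sim_tissue <- function(group, n) {
  if (group == "CR") sample(c("peritoneum", "omentum", "ovary"), n,
                            replace = TRUE, prob = c(0.6, 0.25, 0.15))
  else rep("peritoneum", n)
}

#' Simulate singlet cells
#'
#' Draws per-cell counts from a negative-binomial model: cell of type `t`
#' with library size `L` has gene means `L * rates[, t] / sum(rates[, t])`
#' and per-gene dispersion `nb_dispersion` (`Inf` gives the Poisson limit).
#' Library sizes are log-normal with mean `library_size_mean` and CV
#' `library_size_cv`. Types are assigned uniformly within each sample.
#'
#' Group-level planted biology is applied to the gene means before
#' sampling: in each sample's clinical group, the group's planted
#' ligand-receptor pairs (and their pathway targets) are scaled by a
#' shared per-cell log-normal activity factor, and the group's planted
#' regulons scale their concordant targets up 3-fold and discordant
#' targets down 3-fold. Doublets built by summing these singlets inherit
#' the same group biology, so only the interaction programs (applied in
#' [simulate_doublets()]) are doublet-specific.
#'
#' @param profiles from [make_type_profiles()].
#' @param config the [sim_config()] used to build `profiles`.
#' @param planted planted structure; defaults to the configuration's own
#'   deterministic layout.
#' @return list with `counts` (sparse gene x barcode dgCMatrix),
#'   `annotation` (barcode, cell_type, sample, group, tissue) and `truth`
#'   (composition table plus marker sets).
#' @export
simulate_singlets <- function(profiles, config, planted = .plant_structure(config)) {
  stopifnot(inherits(profiles, "pci_profiles"))
  set.seed(stage_seed(config$seed, "simulate"))
  types <- colnames(profiles$rates)
  samples <- names(config$group_of_sample)
  n <- config$n_singlets_per_sample

  if (n == 0 || config$n_samples == 0) {
    counts <- .as_count_matrix(
      Matrix::Matrix(0L, nrow = config$n_genes, ncol = 0, sparse = TRUE),
      genes = profiles$gene_ids, barcodes = character(0))
    ann <- data.frame(barcode = character(0), cell_type = character(0),
                      sample = character(0), group = character(0),
                      tissue = character(0), stringsAsFactors = FALSE)
    truth <- list(composition = data.frame(barcode = character(0),
                                           class = character(0),
                                           type1 = character(0),
                                           type2 = character(0),
                                           label = character(0),
                                           stringsAsFactors = FALSE),
                  markers = profiles$markers)
    return(list(counts = counts, annotation = ann, truth = truth))
  }

  prob <- sweep(profiles$rates, 2, colSums(profiles$rates), "/")
  blocks <- vector("list", length(samples))
  ann <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    type_of <- sample(types, n, replace = TRUE)
    libs <- if (config$library_size_cv > 0) {
      sdlog <- sqrt(log(1 + config$library_size_cv^2))
      rlnorm(n, log(config$library_size_mean) - sdlog^2 / 2, sdlog)
    } else rep(config$library_size_mean, n)
    mu <- prob[, type_of, drop = FALSE] * rep(libs, each = config$n_genes)

    # group-level planted biology (inherited by doublets via summation)
    g <- unname(config$group_of_sample[samples[s]])
    gi <- function(id) match(id, profiles$gene_ids)
    lr_g <- planted$lr_pairs[planted$lr_pairs$group == g, , drop = FALSE]
    if (!is.null(lr_g) && nrow(lr_g)) {
      for (p in seq_len(nrow(lr_g))) {
        # per-cell pathway activity; the dispersion (sdlog 1.5) is chosen so
        # that the activity signal stands above counting noise and the
        # planted receptor-target Spearman correlation across pseudo-sample
        # units exceeds 0.5
        a <- rlnorm(n, 0, 1.5)
        mu[gi(lr_g$ligand[p]), ] <- mu[gi(lr_g$ligand[p]), ] * 3 * a
        mu[gi(lr_g$receptor[p]), ] <- mu[gi(lr_g$receptor[p]), ] * 3 * a
        tg <- gi(planted$pathway_targets[[lr_g$pathway[p]]])
        mu[tg, ] <- mu[tg, , drop = FALSE] * rep(2 * a, each = length(tg))
      }
    }
    tf_g <- if (!is.null(planted$tf_activity))
      planted$tf_activity[planted$tf_activity$group == g, , drop = FALSE]
    else NULL
    if (!is.null(tf_g) && nrow(tf_g)) {
      for (p in seq_len(nrow(tf_g))) {
        reg <- planted$regulons[planted$regulons$tf == tf_g$tf[p], ]
        up <- gi(reg$target[reg$sign == tf_g$sign[p]])
        dn <- gi(reg$target[reg$sign == -tf_g$sign[p]])
        mu[up, ] <- mu[up, , drop = FALSE] * 3
        mu[dn, ] <- mu[dn, , drop = FALSE] / 3
      }
    }
    cnt <- .draw_counts(as.numeric(mu), config$nb_dispersion)
    blocks[[s]] <- matrix(cnt, nrow = config$n_genes)
    ann[[s]] <- data.frame(
      barcode = sprintf("C%05d-%s", seq_len(n), samples[s]),
      cell_type = type_of, sample = samples[s],
      group = unname(config$group_of_sample[samples[s]]),
      tissue = .sim_tissue(config$group_of_sample[[samples[s]]], n),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann)
  counts <- .as_count_matrix(
    Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE),
    genes = profiles$gene_ids, barcodes = ann$barcode)
  truth <- list(
    composition = data.frame(barcode = ann$barcode, class = "singlet",
                             type1 = ann$cell_type, type2 = NA_character_,
                             label = ann$cell_type, stringsAsFactors = FALSE),
    markers = profiles$markers)
  list(counts = counts, annotation = ann, truth = truth)
}

#' Canonical unordered doublet label
#'
#' @param a,b cell type names (vectorised).
#' @return `"A+B"` with the two types in lexicographic order.
#' @export
doublet_label <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "+")
}

#' Simulate biological doublets with planted interaction effects
#'
#' Each doublet is the elementwise sum of two sampled singlet count vectors
#' from the same sample. On the summed profile, the barcode's clinical
#' group's interaction program is then applied before count resampling:
#' program genes are multiplied by `interaction_fold` (up) or zeroed
#' (down). Perturbed genes are re-drawn from the negative binomial at the
#' perturbed mean; unperturbed genes keep the exact singlet sum, so the
#' group-level ligand-receptor and regulon biology planted in the
#' singlets ([simulate_singlets()]) is inherited unchanged and the
#' interaction programs are the only doublet-specific signal.
#'
#' @param singlets output of [simulate_singlets()] (the singlet pool).
#' @param config the [sim_config()].
#' @param planted planted structure as built by `simulate_pci_dataset()`;
#'   defaults to the configuration's own deterministic layout.
#' @return list with `counts`, `annotation`, `truth` (composition with type
#'   pairs, perturbed-gene record, planted structure).
#' @export
simulate_doublets <- function(singlets, config, planted = .plant_structure(config)) {
  .assert(ncol(singlets$counts) > 0 || config$doublet_fraction == 0,
          "singlet pool is empty")
  set.seed(stage_seed(config$seed, "simulate") + 1L)
  n_d <- round(config$doublet_fraction * config$n_singlets_per_sample)
  gene_ids <- rownames(singlets$counts)
  samples <- names(config$group_of_sample)

  if (n_d == 0) {
    counts <- .as_count_matrix(
      Matrix::Matrix(0L, nrow = length(gene_ids), ncol = 0, sparse = TRUE),
      genes = gene_ids, barcodes = character(0))
    return(list(counts = counts,
                annotation = singlets$annotation[0, ],
                truth = list(composition = singlets$truth$composition[0, ],
                             planted = planted)))
  }
  .assert(config$n_cell_types >= 2 || config$cancer_stromal_bias == 0,
          "heterotypic doublets requested (cancer_stromal_bias > 0) but only one cell type is configured")

  idx <- function(g) match(g, gene_ids)
  disp <- config$nb_dispersion
  blocks <- list(); ann <- list(); comp <- list()
  for (s in samples) {
    g <- unname(config$group_of_sample[s])
    in_s <- singlets$annotation$sample == s
    bcs <- singlets$annotation$barcode[in_s]
    type_of <- singlets$annotation$cell_type[in_s]
    freq <- table(type_of) / length(type_of)
    types_here <- names(freq)
    m <- matrix(0, nrow = length(gene_ids), ncol = n_d)
    rows <- vector("list", n_d)
    prog <- planted$programs[[g]]
    for (i in seq_len(n_d)) {
      pair <- if (runif(1) < config$cancer_stromal_bias &&
                  all(c("Cancer", "Fibroblast") %in% types_here))
        c("Cancer", "Fibroblast")
      else sample(types_here, 2, replace = TRUE, prob = as.numeric(freq))
      if (pair[1] == pair[2]) {
        pool <- bcs[type_of == pair[1]]
        src <- sample(pool, 2)
      } else {
        src <- c(sample(bcs[type_of == pair[1]], 1),
                 sample(bcs[type_of == pair[2]], 1))
      }
      d <- as.numeric(singlets$counts[, src[1]]) +
           as.numeric(singlets$counts[, src[2]])
      if (!is.null(prog) && length(prog$up))
        d[idx(prog$up)] <- .draw_counts(config$interaction_fold * d[idx(prog$up)], disp)
      if (!is.null(prog) && length(prog$down))
        d[idx(prog$down)] <- 0
      m[, i] <- d
      rows[[i]] <- data.frame(
        barcode = sprintf("D%04d-%s", i, s), class = "doublet",
        type1 = pair[1], type2 = pair[2],
        label = doublet_label(pair[1], pair[2]),
        source1 = src[1], source2 = src[2], stringsAsFactors = FALSE)
    }
    comp[[s]] <- do.call(rbind, rows)
    blocks[[s]] <- m
    ann[[s]] <- data.frame(
      barcode = comp[[s]]$barcode, cell_type = NA_character_, sample = s,
      group = g, tissue = .sim_tissue(g, n_d), stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  counts <- .as_count_matrix(Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE),
                             genes = gene_ids, barcodes = ann$barcode)
  list(counts = counts, annotation = ann,
       truth = list(composition = comp, planted = planted))
}

#' Ligand-receptor pair table with planted and decoy rows
#'
#' @param config a [sim_config()].
#' @param truth planted structure (from a simulated dataset's `truth` or
#'   [simulate_doublets()] output); its `lr_pairs` rows are included and
#'   flagged.
#' @param extra_pairs optional user data.frame (ligand, receptor) appended
#'   after validation; self-pairs are rejected.
#' @return data.frame (ligand, receptor, planted).
#' @export
make_lr_table <- function(config, truth, extra_pairs = NULL) {
  planted <- truth$planted %||% truth
  lr <- planted$lr_pairs
  set.seed(stage_seed(config$seed, "simulate") + 2L)
  layout <- .sim_gene_layout(config)
  gene_ids <- .sim_gene_ids(config)
  pool <- gene_ids[layout$baseline]
  decoys <- NULL
  if (config$lr_decoys > 0) {
    .assert(length(pool) >= 2 * config$lr_decoys,
            "not enough unplanted genes for %d decoy pairs", config$lr_decoys)
    picked <- sample(pool, 2 * config$lr_decoys)
    decoys <- data.frame(ligand = picked[seq(1, length(picked), 2)],
                         receptor = picked[seq(2, length(picked), 2)],
                         stringsAsFactors = FALSE)
  }
  out <- rbind(
    if (!is.null(lr)) data.frame(ligand = lr$ligand, receptor = lr$receptor,
                                 planted = TRUE, stringsAsFactors = FALSE),
    if (!is.null(decoys)) cbind(decoys, planted = FALSE))
  if (!is.null(extra_pairs)) {
    .assert(all(extra_pairs$ligand != extra_pairs$receptor),
            "self-pairs (ligand == receptor) are not allowed")
    out <- rbind(out, data.frame(ligand = extra_pairs$ligand,
                                 receptor = extra_pairs$receptor,
                                 planted = FALSE, stringsAsFactors = FALSE))
  }
  .assert(all(out$ligand != out$receptor), "self-pairs generated; internal error")
  rownames(out) <- NULL
  out
}

#' Signed TF-target regulon table
#'
#' @inheritParams make_lr_table
#' @return data.frame (tf, target, sign) with >= 2 targets per TF.
#' @export
make_regulons <- function(config, truth) {
  planted <- truth$planted %||% truth
  reg <- planted$regulons
  .assert(!is.null(reg), "configuration has no planted regulons (n_tfs = 0)")
  counts <- table(reg$tf)
  .assert(all(counts >= 2),
          "regulon(s) with fewer than 2 targets: %s (univariate linear model undefined)",
          paste(names(counts)[counts < 2], collapse = ", "))
  reg
}

#' Pathway gene sets (planted plus decoys)
#'
#' One pathway per planted ligand-receptor pair (its correlated downstream
#' targets) plus decoy sets of unplanted genes.
#'
#' @inheritParams make_lr_table
#' @param n_decoys decoy pathways.
#' @param decoy_size genes per decoy pathway.
#' @return named list of gene-id character vectors (each >= 5 genes).
#' @export
make_pathways <- function(config, truth, n_decoys = 10, decoy_size = 8) {
  planted <- truth$planted %||% truth
  .assert(decoy_size >= 5 && config$targets_per_pathway >= 5,
          "pathway gene sets must have >= 5 genes")
  set.seed(stage_seed(config$seed, "simulate") + 3L)
  layout <- .sim_gene_layout(config)
  gene_ids <- .sim_gene_ids(config)
  pool <- gene_ids[layout$baseline]
  out <- planted$pathway_targets
  for (i in seq_len(n_decoys))
    out[[sprintf("PW_DECOY%02d", i)]] <- sample(pool, decoy_size)
  out
}

#' Simulate a complete desk-scale dataset with ground truth
#'
#' Runs profile construction, singlet and doublet simulation, and builds the
#' ligand-receptor table, regulon table and pathway sets. The returned truth
#' records every barcode's composition, the planted interaction programs per
#' group (up/down), the planted ligand-receptor pairs and their pathways,
#' and the planted TF activity signs.
#'
#' @param config a [sim_config()].
#' @return a `pci_sim` list: `counts`, `annotation`, `truth`, `lr_table`,
#'   `regulons`, `pathways`, `config`.
#' @export
simulate_pci_dataset <- function(config = sim_config()) {
  profiles <- make_type_profiles(config)
  planted <- .plant_structure(config)
  sing <- simulate_singlets(profiles, config, planted)
  dbl <- simulate_doublets(sing, config, planted)
  counts <- cbind(sing$counts, dbl$counts)
  annotation <- rbind(sing$annotation, dbl$annotation)
  sing_comp <- sing$truth$composition
  if (nrow(sing_comp)) sing_comp[, c("source1", "source2")] <- NA_character_
  comp <- rbind(sing_comp, dbl$truth$composition)
  rownames(comp) <- NULL
  truth <- list(composition = comp, markers = profiles$markers,
                planted = planted)
  structure(list(counts = counts, annotation = annotation, truth = truth,
                 lr_table = make_lr_table(config, truth),
                 regulons = make_regulons(config, truth),
                 pathways = make_pathways(config, truth),
                 config = config),
            class = "pci_sim")
}

#' @export
print.pci_sim <- function(x, ...) {
  n_dbl <- sum(x$truth$composition$class == "doublet")
  cat(sprintf("Synthetic PCI dataset: %d genes x %d barcodes (%d singlets, %d doublets)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$counts) - n_dbl, n_dbl))
  cat(sprintf("  samples: %s\n", paste(names(x$config$group_of_sample),
                                       collapse = ", ")))
  cat(sprintf("  LR table: %d pairs (%d planted); %d regulons; %d pathways\n",
              nrow(x$lr_table), sum(x$lr_table$planted),
              length(unique(x$regulons$tf)), length(x$pathways)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
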