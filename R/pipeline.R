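#' Pipeline configuration
#'
#' Declarative configuration for [run_all()]: one seed, the stage
#' parameters (all thresholds default to their standard values), optional
#' input paths (used instead of simulation when the `simulate` stage is
#' disabled) and stage toggles. Serialises to YAML via [write_config()]
#' with a byte-identical write/read/write round trip.
#'
#' @param seed single integer seed; every stage derives its own seed from
#'   it via [stage_seed()].
#' @param stages stages to run, a prefix-closed subset of
#'   `c("simulate", "qc", "deconv", "lda", "lrscore", "signature", "tf")`.
#' @param sim named overrides passed to [sim_config()].
#' @param qc,deconv,lda,lrscore,signature,tf named per-stage parameter
#'   overrides (see the stage functions for meanings and defaults).
#' @param input optional named input paths (`counts_mtx`, `genes`,
#'   `barcodes`, `annotation`, `lr_table`, `regulons`, `pathways`) read
#'   when `simulate` is not among `stages`.
#' @return a `pci_config` list.
#' @export
pci_config <- function(seed = 1L, stages = .pci_stages, sim = list(),
                       qc = list(), deconv = list(), lda = list(),
                       lrscore = list(), signature = list(), tf = list(),
                       input = list()) {
  defaults <- list(
    qc = list(min_cells_per_gene = 10, min_genes_per_cell = 200,
              min_counts = 300, max_counts = 5000, max_mito = 0.25,
              mito_prefix = "MT-", n_hvg = 5000),
    deconv = list(top_n_markers = 100, per_class = 100, n_sim = 1000,
                  min_count = 10, alpha = 0.05, heterotypic_only = TRUE,
                  network_scale = 10000),
    lda = list(k = 5, extra = 20, scan = FALSE, k_range = 2:10,
               max_iter = 200, tol = 1e-4, min_cells = 5, top_n = 30),
    lrscore = list(min_score = 1.5, min_pct = 0.05, alpha_q = 0.01,
                   n_perm = 50000, n_units = 30),
    signature = list(alpha = 0.05),
    tf = list(top_n = 25))
  bad <- setdiff(stages, .pci_stages)
  .assert(length(bad) == 0, "unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- list(seed = as.integer(seed), stages = stages, sim = sim,
              qc = modifyList(defaults$qc, qc),
              deconv = modifyList(defaults$deconv, deconv),
              lda = modifyList(defaults$lda, lda),
              lrscore = modifyList(defaults$lrscore, lrscore),
              signature = modifyList(defaults$signature, signature),
              tf = modifyList(defaults$tf, tf),
              input = input)
  class(cfg) <- "pci_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pci_config`.
#' @param path YAML file path.
#' @return `read_config` returns the `pci_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pci_config")
}

#' Hash of a configuration
#'
#' FNV-1a over the canonical JSON serialisation; stamped into every
#' artefact directory for provenance.
#'
#' @param config a `pci_config`.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  .fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

.log_line <- function(log, stage, key, value) {
  rbind(log, data.frame(stage = stage, key = key, value = as.character(value),
                        stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, qc, deconv, lda,
#' lrscore, signature, tf — each stage consuming the previous one's
#' in-memory results; any prefix of the stage list is runnable, and a
#' stage whose prerequisite is disabled stops with a clear message. All
#' randomness derives from `config$seed` via [stage_seed()]. When `outdir`
#' is given, per-stage tables, a structured log of record counts, the
#' configuration and its hash are written there (no timestamps, so a
#' repeated run yields an identical artefact directory).
#'
#' @param config a [pci_config()].
#' @param outdir optional artefact directory.
#' @return a `pci_run` list with each stage's results and the log.
#' @export
run_all <- function(config = pci_config(), outdir = NULL) {
  stopifnot(inherits(config, "pci_config"))
  stages <- config$stages
  need <- function(stage, prereq, what) {
    .assert(prereq %in% stages,
            "stage '%s' requires the output of stage '%s' (%s); enable it or provide inputs",
            stage, prereq, what)
  }
  res <- list(config = config)
  log <- data.frame(stage = character(0), key = character(0),
                    value = character(0), stringsAsFactors = FALSE)

  ## -- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    sim <- simulate_pci_dataset(do.call(sim_config,
      modifyList(list(seed = stage_seed(config$seed, "simulate")), config$sim)))
    res$sim <- sim
    counts <- sim$counts; ann <- sim$annotation
    lr_table <- sim$lr_table; regulons <- sim$regulons; pathways <- sim$pathways
    log <- .log_line(log, "simulate", "cells", ncol(counts))
    log <- .log_line(log, "simulate", "doublets_planted",
                     sum(sim$truth$composition$class == "doublet"))
  } else {
    inp <- config$input
    .assert(all(c("counts_mtx", "annotation") %in% names(inp)),
            "stage 'qc' requires simulated or file inputs: set input$counts_mtx and input$annotation")
    counts <- read_counts(inp$counts_mtx,
                          genes = inp$genes %||% file.path(dirname(inp$counts_mtx), "genes.tsv"),
                          barcodes = inp$barcodes %||% file.path(dirname(inp$counts_mtx), "barcodes.tsv"))
    ann <- read_tsv_table(inp$annotation)
    lr_table <- if (!is.null(inp$lr_table)) read_tsv_table(inp$lr_table)
    regulons <- if (!is.null(inp$regulons)) read_tsv_table(inp$regulons)
    pathways <- if (!is.null(inp$pathways)) read_gmt(inp$pathways)
  }

  ## -- qc ------------------------------------------------------------------
  if ("qc" %in% stages) {
    p <- config$qc
    qf <- qc_filter(counts, min_cells_per_gene = p$min_cells_per_gene,
                    min_genes_per_cell = p$min_genes_per_cell,
                    min_counts = p$min_counts, max_counts = p$max_counts,
                    max_mito = p$max_mito, mito_prefix = p$mito_prefix)
    counts <- qf$counts
    ann <- ann[ann$barcode %in% colnames(counts), ]
    nm <- lognormalize(counts)
    hvg <- select_hvg(nm, n = p$n_hvg)
    res$qc <- list(report = qf$report, hvg = hvg, nm = nm, counts = counts,
                   annotation = ann)
    log <- .log_line(log, "qc", "cells_in", nrow(qf$report))
    log <- .log_line(log, "qc", "cells_out", ncol(counts))
    log <- .log_line(log, "qc", "genes_out", nrow(counts))
  }

  ## -- deconv --------------------------------------------------------------
  if ("deconv" %in% stages) {
    need("deconv", "qc", "normalised matrix")
    p <- config$deconv
    seed <- stage_seed(config$seed, "deconv")
    sing_ann <- ann[!is.na(ann$cell_type), ]
    markers <- marker_genes(nm, sing_ann, top_n = p$top_n_markers)
    synth <- make_synthetic_doublets(counts, sing_ann,
                                     per_class = p$per_class, seed = seed)
    clf <- train_classifier(counts, sing_ann, synth, markers, seed = seed)
    calls <- classify_barcodes(counts, clf)
    enrich <- doublet_enrichment_test(calls, ann, n_sim = p$n_sim, seed = seed)
    filtered <- filter_doublet_calls(enrich, min_count = p$min_count,
                                     alpha = p$alpha,
                                     heterotypic_only = p$heterotypic_only)
    network <- interaction_network(filtered, calls, ann, scale = p$network_scale)
    res$deconv <- list(markers = markers, calls = calls, enrichment = enrich,
                       filtered = filtered, network = network)
    log <- .log_line(log, "deconv", "called_doublets", sum(calls$is_doublet))
    log <- .log_line(log, "deconv", "doublet_types_kept", nrow(filtered))
  }

  ## -- shared doublet/singlet cell sets ------------------------------------
  cf_label <- doublet_label("Cancer", "Fibroblast")
  if (any(c("lda", "lrscore", "signature", "tf") %in% stages)) {
    need(intersect(stages, c("lda", "lrscore", "signature", "tf"))[1],
         "deconv", "doublet calls")
    group_of <- setNames(ann$group, ann$barcode)
    calls <- res$deconv$calls
    cf_dbl <- calls$barcode[calls$is_doublet & calls$label == cf_label]
    sing_cancer <- ann$barcode[!is.na(ann$cell_type) & ann$cell_type == "Cancer"]
    sing_fibro <- ann$barcode[!is.na(ann$cell_type) & ann$cell_type == "Fibroblast"]
    groups <- unique(ann$group)
  }

  ## -- lda -----------------------------------------------------------------
  if ("lda" %in% stages) {
    p <- config$lda
    seed <- stage_seed(config$seed, "lda")
    m_sing <- counts[, c(sing_cancer, sing_fibro), drop = FALSE]
    k <- p$k
    scan <- NULL
    if (isTRUE(p$scan)) {
      scan <- perplexity_scan(counts[, c(colnames(m_sing), cf_dbl), drop = FALSE],
                              k_range = p$k_range, seed = seed,
                              max_iter = p$max_iter, tol = p$tol)
      k <- scan$k
    }
    singlet_model <- fit_singlet_lda(m_sing, k = k, seed = seed,
                                     max_iter = p$max_iter, tol = p$tol)
    # One doublet model over all cancer-stromal doublets: interaction
    # programs land in doublet-specific topics, and each topic is
    # attributed to the clinical group contributing most of its cells.
    .assert(length(cf_dbl) >= 10, "fewer than 10 cancer-stromal doublets; cannot fit doublet LDA")
    sample_of <- setNames(ann$sample, ann$barcode)
    doublet_model <- fit_doublet_lda(counts[, cf_dbl, drop = FALSE],
                                     singlet_model, extra = p$extra,
                                     seed = seed, max_iter = p$max_iter,
                                     tol = p$tol,
                                     seed_groups = sample_of[cf_dbl])
    ranking <- rank_topic_genes(doublet_model, counts[, cf_dbl, drop = FALSE],
                                min_cells = p$min_cells, top_n = p$top_n)
    cell_topic <- attr(ranking, "cell_topic")
    topic_group <- vapply(unique(ranking$topic), function(t) {
      cells <- names(cell_topic)[cell_topic == t]
      tab <- table(group_of[cells])
      if (length(tab)) names(which.max(tab)) else NA_character_
    }, "")
    names(topic_group) <- unique(ranking$topic)
    per_group <- list()
    for (g in groups) {
      tps <- as.integer(names(topic_group)[!is.na(topic_group) & topic_group == g])
      per_group[[g]] <- list(
        topics = tps,
        ranking = ranking[ranking$topic %in% tps, , drop = FALSE],
        genes = sort(unique(ranking$gene[ranking$topic %in% tps])))
      log <- .log_line(log, "lda", paste0("genes_", g),
                       length(per_group[[g]]$genes))
    }
    res$lda <- list(k = k, scan = scan, singlet_model = singlet_model,
                    doublet_model = doublet_model, ranking = ranking,
                    topic_group = topic_group, per_group = per_group)
  }

  ## -- lrscore -------------------------------------------------------------
  if ("lrscore" %in% stages) {
    .assert(!is.null(lr_table), "lrscore needs a ligand-receptor table")
    p <- config$lrscore
    seed <- stage_seed(config$seed, "lrscore")
    ge <- group_mean_expression(nm, res$deconv$calls, ann, label = cf_label)
    lr <- filter_lrp(lr_table, ge, min_score = p$min_score, min_pct = p$min_pct)
    triples <- list()
    if (!is.null(pathways)) {
      for (g in colnames(ge$X)) {
        dbl_g <- cf_dbl[group_of[cf_dbl] == g]
        if (length(dbl_g) < p$n_units) next
        units <- make_expression_units(nm, dbl_g, n_units = p$n_units,
                                       seed = seed)
        triples[[g]] <- active_triples(units, lr_table, pathways,
                                       alpha_q = p$alpha_q, n_perm = p$n_perm,
                                       seed = seed, cluster = g)
      }
    }
    triples_all <- if (length(triples)) do.call(rbind, triples) else NULL
    overlap <- if (!is.null(triples_all))
      overlap_lrp(lr[lr$pass, ], triples_all[triples_all$active, ]) else NULL
    res$lrscore <- list(group_expression = ge, lr = lr,
                        triples = triples_all, overlap = overlap)
    log <- .log_line(log, "lrscore", "lrp_kept", sum(lr$pass))
    log <- .log_line(log, "lrscore", "triples_active",
                     if (!is.null(triples_all)) sum(triples_all$active) else 0)
  }

  ## -- signature -----------------------------------------------------------
  if ("signature" %in% stages) {
    need("signature", "lda", "per-group LDA gene lists")
    alpha <- config$signature$alpha
    signatures <- list(); degs <- list()
    for (g in names(res$lda$per_group)) {
      dbl_g <- cf_dbl[group_of[cf_dbl] == g]
      ca_g <- sing_cancer[group_of[sing_cancer] == g]
      fb_g <- sing_fibro[group_of[sing_fibro] == g]
      if (length(dbl_g) < 3 || length(ca_g) < 3 || length(fb_g) < 3) next
      d_ca <- deg(nm, dbl_g, ca_g, comparison = paste0(g, "_dbl_vs_cancer"))
      d_fb <- deg(nm, dbl_g, fb_g, comparison = paste0(g, "_dbl_vs_stromal"))
      signatures[[g]] <- doublet_specific_signature(
        res$lda$per_group[[g]]$genes, d_ca, d_fb, alpha = alpha)
      degs[[g]] <- list(vs_cancer = d_ca, vs_stromal = d_fb)
      log <- .log_line(log, "signature", paste0("genes_", g),
                       length(signatures[[g]]$combined))
    }
    res$signature <- list(signatures = signatures, degs = degs)
  }

  ## -- tf ------------------------------------------------------------------
  if ("tf" %in% stages) {
    .assert(!is.null(regulons), "tf stage needs a regulon table")
    p <- config$tf
    pb <- pseudobulk(counts, ann, res$deconv$calls)
    activity <- tf_activity_scores(pb, regulons)
    top <- top_tfs(activity, n = p$top_n)
    contrasts <- list()
    gs <- groups[vapply(groups, function(g)
      sum(group_of[cf_dbl] == g) >= 3, TRUE)]
    if (length(gs) >= 2) {
      combos <- utils::combn(gs, 2, simplify = FALSE)
      for (cb in combos) {
        d <- deg(nm, cf_dbl[group_of[cf_dbl] == cb[1]],
                 cf_dbl[group_of[cf_dbl] == cb[2]],
                 comparison = paste0(cb[1], "_vs_", cb[2]))
        sc <- differential_tf(d, regulons, alpha = config$signature$alpha)
        if (!is.null(sc)) contrasts[[paste0(cb[1], "_vs_", cb[2])]] <- sc
      }
    }
    res$tf <- list(pseudobulk = pb, activity = activity, top = top,
                   contrasts = contrasts)
    log <- .log_line(log, "tf", "pseudo_samples", ncol(pb))
    log <- .log_line(log, "tf", "tfs_scored", nrow(activity))
  }

  res$log <- log
  class(res) <- "pci_run"
  if (!is.null(outdir)) .write_run_artifacts(res, outdir)
  res
}

#' @export
print.pci_run <- function(x, ...) {
  cat(sprintf("PCI pipeline run (seed %d, stages: %s)\n", x$config$seed,
              paste(x$config$stages, collapse = ", ")))
  print(x$log, row.names = FALSE)
  invisible(x)
}

.write_run_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  write_config(cfg, file.path(outdir, "config.yaml"))
  jsonlite::write_json(list(config_hash = config_hash(cfg), seed = cfg$seed),
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE)
  write_tsv_table(res$log, file.path(outdir, "log.tsv"))
  if (!is.null(res$sim)) write_sim_dataset(res$sim, file.path(outdir, "sim"))
  if (!is.null(res$qc))
    write_tsv_table(res$qc$report, file.path(outdir, "qc_report.tsv"))
  if (!is.null(res$deconv)) {
    write_tsv_table(res$deconv$calls, file.path(outdir, "doublet_calls.tsv"))
    write_tsv_table(res$deconv$enrichment, file.path(outdir, "doublet_enrichment.tsv"))
    for (g in names(res$deconv$network))
      write_tsv_table(res$deconv$network[[g]],
                      file.path(outdir, sprintf("network_%s.tsv", g)))
  }
  if (!is.null(res$lda)) {
    rk <- do.call(rbind, lapply(names(res$lda$per_group), function(g)
      cbind(group = g, res$lda$per_group[[g]]$ranking)))
    if (!is.null(rk)) write_tsv_table(rk, file.path(outdir, "lda_rankings.tsv"))
    if (!is.null(res$lda$scan))
      write_tsv_table(res$lda$scan$table, file.path(outdir, "lda_kscan.tsv"))
  }
  if (!is.null(res$lrscore)) {
    write_tsv_table(res$lrscore$lr, file.path(outdir, "lr_interactions.tsv"))
    if (!is.null(res$lrscore$triples))
      write_tsv_table(res$lrscore$triples, file.path(outdir, "lr_triples.tsv"))
    if (!is.null(res$lrscore$overlap))
      write_tsv_table(res$lrscore$overlap, file.path(outdir, "lr_overlap.tsv"))
  }
  if (!is.null(res$signature)) {
    sig <- do.call(rbind, lapply(names(res$signature$signatures), function(g) {
      s <- res$signature$signatures[[g]]
      if (!length(s$combined)) return(NULL)
      data.frame(group = g, gene = s$combined,
                 direction = ifelse(s$combined %in% s$up, "up", "down"),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(sig)) write_tsv_table(sig, file.path(outdir, "signatures.tsv"))
  }
  if (!is.null(res$tf)) {
    act <- data.frame(tf = rownames(res$tf$activity),
                      as.data.frame(unclass(res$tf$activity)),
                      check.names = FALSE)
    write_tsv_table(act, file.path(outdir, "tf_activity.tsv"))
  }
  invisible(outdir)
}
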