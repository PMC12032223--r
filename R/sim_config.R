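#' Simulation configuration for the synthetic tumour-microenvironment dataset
#'
#' Builds the parameter set for [simulate_pci_dataset()]. The defaults are the
#' package's desk-scale study conditions: 5 cell types with 8-fold marker
#' elevation, 2,000 genes, 3 samples (one per clinical group CR/PR/PD),
#' 1,500 singlets and 150 planted doublets per sample, negative-binomial
#' counts, a 30-gene up-regulated and 10-gene down-regulated interaction
#' program per group, 6 planted co-expressed ligand-receptor pairs (2 per
#' group) each with a correlated downstream pathway, and 6 planted
#' transcription-factor regulons with group-specific activity.
#'
#' @param n_cell_types number of cell types. The first two are named
#'   `"Cancer"` and `"Fibroblast"`; downstream stages focus on this pair.
#' @param n_genes gene universe size.
#' @param n_markers_per_type markers per cell type; marker sets are pairwise
#'   disjoint and never overlap planted interaction genes.
#' @param marker_fold rate elevation of a marker in its own type over the
#'   shared baseline (>= 8 keeps cell types separable for the classifier).
#' @param n_samples number of samples (patients).
#' @param group_of_sample named character vector mapping sample id to
#'   clinical group; must cover every sample.
#' @param n_singlets_per_sample singlets simulated per sample.
#' @param doublet_fraction planted doublets per sample as a fraction of
#'   `n_singlets_per_sample`, in `[0, 1]`.
#' @param cancer_stromal_bias probability that a planted doublet is a
#'   Cancer-Fibroblast pair; remaining doublets pair two types drawn
#'   independently from the sample's singlet frequencies.
#' @param interaction_program_size genes per group whose expression is
#'   multiplied up in that group's doublets.
#' @param interaction_down_size genes per group zeroed in that group's
#'   doublets.
#' @param interaction_fold multiplicative up-perturbation applied to the
#'   summed doublet profile before count resampling.
#' @param lr_pairs planted co-expressed ligand-receptor pairs (total across
#'   groups, assigned round-robin).
#' @param lr_decoys decoy ligand-receptor rows added to the pair table.
#' @param targets_per_pathway downstream target genes per planted pathway.
#' @param n_tfs planted regulons; assigned round-robin to groups with
#'   alternating activity sign.
#' @param targets_per_tf signed targets per regulon (>= 2; a univariate
#'   linear model is undefined below that).
#' @param nb_dispersion negative-binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param library_size_mean expected per-cell total count.
#' @param library_size_cv coefficient of variation of per-cell library size
#'   (0 fixes the library size).
#' @param n_mito_genes genes flagged with the `MT-` name prefix so QC
#'   filters are exercisable.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `pci_sim_config` list with validated fields.
#' @export
sim_config <- function(n_cell_types = 5,
                       n_genes = 2000,
                       n_markers_per_type = 20,
                       marker_fold = 8,
                       n_samples = 3,
                       group_of_sample = NULL,
                       n_singlets_per_sample = 1500,
                       doublet_fraction = 0.1,
                       cancer_stromal_bias = 0.6,
                       interaction_program_size = 30,
                       interaction_down_size = 10,
                       interaction_fold = 4,
                       lr_pairs = 6,
                       lr_decoys = 20,
                       targets_per_pathway = 8,
                       n_tfs = 6,
                       targets_per_tf = 20,
                       nb_dispersion = 2,
                       library_size_mean = 1400,
                       library_size_cv = 0.3,
                       n_mito_genes = 20,
                       seed = 1L) {
  if (is.null(group_of_sample)) {
    groups <- rep_len(c("CR", "PR", "PD"), n_samples)
    group_of_sample <- setNames(groups, paste0("S", seq_len(n_samples)))
  }
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    n_genes = as.integer(n_genes),
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold = marker_fold,
    n_samples = as.integer(n_samples),
    group_of_sample = group_of_sample,
    n_singlets_per_sample = as.integer(n_singlets_per_sample),
    doublet_fraction = doublet_fraction,
    cancer_stromal_bias = cancer_stromal_bias,
    interaction_program_size = as.integer(interaction_program_size),
    interaction_down_size = as.integer(interaction_down_size),
    interaction_fold = interaction_fold,
    lr_pairs = as.integer(lr_pairs),
    lr_decoys = as.integer(lr_decoys),
    targets_per_pathway = as.integer(targets_per_pathway),
    n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    n_mito_genes = as.integer(n_mito_genes),
    seed = as.integer(seed)
  )
  class(cfg) <- "pci_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  .assert(cfg$doublet_fraction >= 0 && cfg$doublet_fraction <= 1,
          "doublet_fraction must lie in [0, 1], got %g", cfg$doublet_fraction)
  counts <- c("n_cell_types", "n_genes", "n_markers_per_type", "n_samples",
              "n_singlets_per_sample", "interaction_program_size",
              "interaction_down_size", "lr_pairs", "lr_decoys", "n_tfs",
              "targets_per_tf", "targets_per_pathway", "n_mito_genes")
  for (f in counts) .assert(cfg[[f]] >= 0, "%s must be non-negative", f)
  .assert(cfg$n_cell_types >= 1, "n_cell_types must be >= 1")
  .assert(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(cfg$library_size_mean > 0, "library_size_mean must be positive")
  .assert(length(cfg$group_of_sample) == cfg$n_samples &&
            !is.null(names(cfg$group_of_sample)),
          "group_of_sample must name a group for every one of the %d samples",
          cfg$n_samples)
  .assert(cfg$targets_per_tf >= 2,
          "targets_per_tf must be >= 2: a regulon with fewer targets cannot support a univariate linear model")
  invisible(cfg)
}

#' @export
print.pci_sim_config <- function(x, ...) {
  cat("Synthetic PCI dataset configuration\n")
  cat(sprintf("  %d cell types x %d genes; %d samples (%s)\n",
              x$n_cell_types, x$n_genes, x$n_samples,
              paste(unique(x$group_of_sample), collapse = "/")))
  cat(sprintf("  %d singlets + %d doublets per sample; NB dispersion %g\n",
              x$n_singlets_per_sample,
              round(x$doublet_fraction * x$n_singlets_per_sample),
              x$nb_dispersion))
  cat(sprintf("  planted: %d+%d interaction genes/group, %d LR pairs, %d TFs\n",
              x$interaction_program_size, x$interaction_down_size,
              x$lr_pairs, x$n_tfs))
  invisible(x)
}

# Deterministic disjoint gene-block layout for all planted structure.
# Returns per-block index vectors into the gene universe.
.sim_gene_layout <- function(cfg) {
  groups <- unique(unname(cfg$group_of_sample))
  need <- c(
    markers = cfg$n_cell_types * cfg$n_markers_per_type,
    program_up = length(groups) * cfg$interaction_program_size,
    program_down = length(groups) * cfg$interaction_down_size,
    lr = cfg$lr_pairs * 2L,
    pw = cfg$lr_pairs * cfg$targets_per_pathway,
    tf = cfg$n_tfs * cfg$targets_per_tf,
    mito = cfg$n_mito_genes
  )
  .assert(sum(need) <= cfg$n_genes,
          paste0("gene universe too small: n_genes=%d but planted structure needs %d ",
                 "(n_cell_types*n_markers_per_type=%d plus programs, LR, TF and MT blocks)"),
          cfg$n_genes, sum(need), need[["markers"]])
  ends <- cumsum(need)
  starts <- c(1L, head(ends, -1) + 1L)
  blocks <- Map(seq, starts, ends)
  names(blocks) <- names(need)
  blocks$baseline <- if (ends[[length(ends)]] < cfg$n_genes)
    seq(ends[[length(ends)]] + 1L, cfg$n_genes) else integer(0)
  blocks
}

.sim_gene_ids <- function(cfg) {
  layout <- .sim_gene_layout(cfg)
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids[layout$mito] <- sprintf("MT-G%04d", layout$mito)
  ids
}

.sim_type_names <- function(cfg) {
  base <- c("Cancer", "Fibroblast", "Tcell", "Macrophage", "Bcell",
            "NKcell", "DC", "Endothelial", "Mast")
  if (cfg$n_cell_types <= length(base)) base[seq_len(cfg$n_cell_types)]
  else c(base, sprintf("Type%d", seq(length(base) + 1, cfg$n_cell_types)))
}
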