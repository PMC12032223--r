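test_that("type profiles have disjoint, elevated marker blocks", {
  cfg <- tiny_sim_config(seed = 1, n_genes = 200)
  pr <- make_type_profiles(cfg)
  expect_length(pr$markers, 3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(pr$markers[[i]], pr$markers[[j]]), 0)
  for (ty in colnames(pr$rates)) {
    mk <- pr$markers[[ty]]
    expect_true(all(pr$rates[mk, ty] >= 8 * pr$baseline[match(mk, pr$gene_ids)] - 1e-12))
  }
  expect_true(all(pr$rates > 0))

  one <- make_type_profiles(tiny_sim_config(seed = 1, n_cell_types = 1,
                                            n_genes = 150,
                                            n_markers_per_type = 5,
                                            cancer_stromal_bias = 0))
  expect_identical(one$markers[[1]], one$gene_ids[1:5])
})

test_that("profile construction rejects an undersized gene universe", {
  expect_error(make_type_profiles(tiny_sim_config(seed = 1, n_genes = 80,
                                                  n_markers_per_type = 20)),
               "n_genes")
})

test_that("negative-binomial singlets approach Poisson means in the dispersion limit", {
  cfg <- sim_config(n_cell_types = 2, n_genes = 60, n_markers_per_type = 5,
                    n_samples = 1, group_of_sample = c(S1 = "CR"),
                    n_singlets_per_sample = 2000, doublet_fraction = 0,
                    nb_dispersion = Inf, library_size_cv = 0,
                    interaction_program_size = 4, interaction_down_size = 2,
                    lr_pairs = 0, n_tfs = 0, n_mito_genes = 0, seed = 11)
  pr <- make_type_profiles(cfg)
  s <- simulate_singlets(pr, cfg)
  for (ty in colnames(pr$rates)) {
    cells <- s$annotation$barcode[s$annotation$cell_type == ty]
    mu <- pr$rates[, ty] / sum(pr$rates[, ty]) * cfg$library_size_mean
    emp <- Matrix::rowMeans(s$counts[, cells])
    big <- mu > 5   # relative error is only meaningful away from zero
    expect_lt(max(abs(emp[big] - mu[big]) / mu[big]), 0.05)
  }
})

test_that("simulation is byte-identical under a fixed seed and empty at zero cells", {
  cfg <- tiny_sim_config(seed = 7)
  a <- simulate_pci_dataset(cfg)
  b <- simulate_pci_dataset(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)

  cfg0 <- tiny_sim_config(seed = 1, n_cell_types = 2,
                          n_singlets_per_sample = 0)
  empty <- simulate_singlets(make_type_profiles(cfg0), cfg0)
  expect_equal(ncol(empty$counts), 0)
  expect_equal(nrow(empty$annotation), 0)
})

test_that("doublets are sums of their recorded sources outside perturbed genes", {
  sim <- simulate_pci_dataset(tiny_sim_config(seed = 3))
  comp <- sim$truth$composition
  dbl <- comp[comp$class == "doublet", ]
  expect_true(nrow(dbl) > 0)
  perturbed <- unlist(lapply(sim$truth$planted$programs,
                             function(p) c(p$up, p$down)))
  keep <- setdiff(rownames(sim$counts), perturbed)
  for (i in sample(nrow(dbl), 5)) {
    expect_equal(
      as.numeric(sim$counts[keep, dbl$barcode[i]]),
      as.numeric(sim$counts[keep, dbl$source1[i]] +
                   sim$counts[keep, dbl$source2[i]]))
  }
})

test_that("doublet_fraction of zero yields no doublets and heterotypic pairs need 2 types", {
  cfg0 <- tiny_sim_config(seed = 3, doublet_fraction = 0)
  sim0 <- simulate_pci_dataset(cfg0)
  expect_equal(sum(sim0$truth$composition$class == "doublet"), 0)

  cfg1 <- tiny_sim_config(seed = 1, n_cell_types = 1,
                          n_singlets_per_sample = 50, doublet_fraction = 0.2,
                          cancer_stromal_bias = 0.5)
  pr <- make_type_profiles(cfg1)
  s <- simulate_singlets(pr, cfg1)
  expect_error(simulate_doublets(s, cfg1), "heterotypic")
})

test_that("planted up-program genes at least double the unperturbed doublet mean", {
  sim <- simulate_pci_dataset(sim_config(seed = 21))
  comp <- sim$truth$composition
  group_of <- setNames(sim$annotation$group, sim$annotation$barcode)
  for (g in c("CR", "PR", "PD")) {
    up <- sim$truth$planted$programs[[g]]$up
    sel <- comp[comp$class == "doublet" & group_of[comp$barcode] == g, ]
    obs <- Matrix::rowMeans(sim$counts[up, sel$barcode, drop = FALSE])
    base <- Matrix::rowMeans(sim$counts[up, sel$source1, drop = FALSE] +
                               sim$counts[up, sel$source2, drop = FALSE])
    expect_true(all(obs > 2 * base))
    down <- sim$truth$planted$programs[[g]]$down
    expect_equal(sum(sim$counts[down, sel$barcode]), 0)
  }
})

test_that("ligand-receptor table has planted plus decoy rows and no self-pairs", {
  cfg <- tiny_sim_config(seed = 5)
  sim <- simulate_pci_dataset(cfg)
  lr <- sim$lr_table
  expect_equal(nrow(lr), cfg$lr_pairs + cfg$lr_decoys)
  expect_equal(sum(lr$planted), cfg$lr_pairs)
  expect_true(all(lr$ligand != lr$receptor))
  expect_true(all(c(lr$ligand, lr$receptor) %in% rownames(sim$counts)))
  expect_error(make_lr_table(cfg, sim$truth,
                             extra_pairs = data.frame(ligand = "G0001",
                                                      receptor = "G0001")),
               "self-pairs")
})

test_that("regulons are well-formed and reject degenerate target counts", {
  cfg <- tiny_sim_config(seed = 5)
  sim <- simulate_pci_dataset(cfg)
  reg <- sim$regulons
  expect_equal(nrow(reg), cfg$n_tfs * cfg$targets_per_tf)
  expect_true(all(reg$sign %in% c(-1L, 1L)))
  expect_true(all(table(reg$tf) >= 10))
  expect_error(sim_config(targets_per_tf = 1), "univariate")
})

test_that("GMT files round-trip and planted pathway targets track the receptor", {
  sim <- simulate_pci_dataset(sim_config(seed = 21))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim$pathways, path)
  expect_identical(read_gmt(path), sim$pathways)
  expect_true(all(lengths(sim$pathways) >= 5))

  nm <- lognormalize(sim$counts)
  ann <- sim$annotation
  pl <- sim$truth$planted$lr_pairs
  rho <- vapply(seq_len(nrow(pl)), function(i) {
    cells <- ann$barcode[!is.na(ann$cell_type) & ann$group == pl$group[i]]
    un <- make_expression_units(nm, cells, n_units = 30, seed = 1)
    tg <- sim$truth$planted$pathway_targets[[pl$pathway[i]]]
    mean(vapply(tg, function(t)
      cor(un[pl$receptor[i], ], un[t, ], method = "spearman"), 0))
  }, 0)
  expect_gt(mean(rho), 0.5)
  expect_true(all(rho > 0.2))
})

test_that("doublet totals dominate singlet totals and perturbed genes avoid markers", {
  sim <- simulate_pci_dataset(tiny_sim_config(seed = 9))
  comp <- sim$truth$composition
  tot <- Matrix::colSums(sim$counts)
  expect_gt(median(tot[comp$barcode[comp$class == "doublet"]]),
            median(tot[comp$barcode[comp$class == "singlet"]]))
  perturbed <- unlist(lapply(sim$truth$planted$programs,
                             function(p) c(p$up, p$down)))
  expect_length(intersect(perturbed, unlist(sim$truth$markers)), 0)
  expect_false(anyDuplicated(comp$barcode) > 0)
  expect_setequal(comp$barcode, colnames(sim$counts))
})
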