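make_groupexpr <- function(X, pct) {
  structure(list(X = X, pct = pct,
                 n_cells = setNames(rep(10L, ncol(X)), colnames(X))),
            class = "pci_groupexpr")
}

test_that("group mean expression matches a brute-force oracle", {
  set.seed(8)
  x <- matrix(rexp(40 * 50), 40, 50,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:50)))
  x[x < 0.7] <- 0
  nm <- as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  groups <- rep(c("CR", "PR", "PD"), length.out = 50)
  calls <- calls_from_labels(rep(doublet_label("Cancer", "Fibroblast"), 50),
                             barcodes = colnames(x))
  ann <- data.frame(barcode = colnames(x), group = groups)
  ge <- group_mean_expression(nm, calls, ann)
  for (g in c("CR", "PR", "PD")) {
    expect_equal(ge$X[, g], rowMeans(x[, groups == g]), tolerance = 1e-12)
    expect_equal(ge$pct[, g], rowMeans(x[, groups == g] > 0), tolerance = 1e-12)
  }
  # one cell per group -> means equal the values; pct counts detection
  nm1 <- toy_counts(matrix(c(1, 0, 2, 5, 3, 0), 2), genes = c("a", "b"))
  calls1 <- calls_from_labels(rep(doublet_label("Cancer", "Fibroblast"), 3),
                              barcodes = colnames(nm1))
  ann1 <- data.frame(barcode = colnames(nm1), group = c("CR", "PR", "PD"))
  ge1 <- group_mean_expression(lognormalize(nm1), calls1, ann1)
  expect_equal(unname(ge1$pct["b", ]), c(0, 1, 0))
})

test_that("enrichment z-scores match the stated formula and an oracle", {
  Z <- enrichment_z(matrix(c(0, 0, 3), 1))
  expect_equal(as.numeric(Z), c(-0.7071, -0.7071, 1.4142), tolerance = 1e-4)
  expect_equal(as.numeric(enrichment_z(matrix(c(2, 2, 2), 1))), c(0, 0, 0))

  set.seed(3)
  X <- matrix(rexp(1000 * 3), 1000, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- enrichment_z(X)
  expect_lt(max(abs(rowSums(Z))), 1e-9)
  for (i in sample(1000, 200)) {   # brute-force oracle per row
    mu <- mean(X[i, ]); s <- sqrt(mean((X[i, ] - mu)^2))
    expect_equal(as.numeric(Z[i, ]), (X[i, ] - mu) / s, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  Zs <- enrichment_z(X, sd_type = "sample")
  expect_equal(Zs[1, 1], (X[1, 1] - mean(X[1, ])) / sd(X[1, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(enrichment_z(matrix(1, 5, 1)), "2 clusters")
})

test_that("interaction scores are Euclidean norms", {
  expect_equal(interaction_score(0, 0), 0)
  expect_equal(interaction_score(3, 4), 5)
  expect_equal(interaction_score(-1.2, 0.5), 1.3, tolerance = 1e-12)
  expect_equal(interaction_score(2, -1), interaction_score(-1, 2))
  expect_error(interaction_score(NA, 1), "finite")
})

test_that("the five-condition LRP filter honours its boundary semantics", {
  genes <- c("L1", "R1", "L2", "R2", "L3", "R3")
  # cluster means engineered so that per-gene z-scores are known:
  # rows (x, 0, 0) give Z = (1.4142, -0.7071, -0.7071) in cluster A
  X <- rbind(L1 = c(2, 0, 0), R1 = c(2, 0, 0),    # score 2 in A, X > 0
             L2 = c(0, 2, 2), R2 = c(2, 0, 0),    # L2 zero mean in A
             L3 = c(1.5, 0, 0), R3 = c(1, 1, 1))  # Z_L 1.414, Z_R 0
  colnames(X) <- c("A", "B", "C")
  pct <- X * 0 + 1
  pct["L1", "A"] <- 0.05                          # exactly at the threshold
  ge <- make_groupexpr(X, pct)
  pairs <- data.frame(ligand = c("L1", "L2", "L3"),
                      receptor = c("R1", "R2", "R3"))
  res <- filter_lrp(pairs, ge)
  a <- res[res$cluster == "A", ]
  expect_true(a$pass[a$ligand == "L1"])           # pct == 0.05 retained
  expect_false(a$pass[a$ligand == "L2"])          # zero ligand mean excluded
  expect_false(a$pass[a$ligand == "L3"])          # score exactly... check below
  expect_equal(a$Z_interaction[a$ligand == "L3"], sqrt(2), tolerance = 1e-9)

  # a pair at score exactly 1.5 is excluded (strict >)
  X2 <- rbind(L = c(2, 0, 0), R = c(1, 1, 1))
  colnames(X2) <- c("A", "B", "C")
  ge2 <- make_groupexpr(X2, matrix(1, 2, 3, dimnames = dimnames(X2)))
  r2 <- filter_lrp(data.frame(ligand = "L", receptor = "R"), ge2,
                   min_score = sqrt(2))
  expect_false(any(r2$pass[r2$cluster == "A"]))

  # raising min_score never adds pairs (monotonicity)
  loose <- filter_lrp(pairs, ge, min_score = 1)
  strict <- filter_lrp(pairs, ge, min_score = 1.9)
  expect_true(all(!loose$pass | !xor(loose$pass, strict$pass) | !strict$pass))
  expect_true(all(strict$pass <= loose$pass))

  # absent genes are skipped with a message
  expect_message(filter_lrp(data.frame(ligand = "nope", receptor = "R1"), ge),
                 "skipped")
})

test_that("active triples detect planted correlation and respect the null", {
  set.seed(11)
  n_units <- 30
  mk_expr <- function(correlated) {
    z <- rnorm(n_units)
    vals <- rbind(
      L = if (correlated) z + rnorm(n_units, sd = 0.5) else rnorm(n_units),
      R = if (correlated) z + rnorm(n_units, sd = 0.5) else rnorm(n_units))
    tg <- t(sapply(1:6, function(i)
      if (correlated) z + rnorm(n_units, sd = 0.5) else rnorm(n_units)))
    rownames(tg) <- sprintf("T%d", 1:6)
    out <- rbind(vals, tg) + 5
    colnames(out) <- sprintf("u%02d", seq_len(n_units))
    out
  }
  expr <- mk_expr(TRUE)
  tr <- active_triples(expr, data.frame(ligand = "L", receptor = "R"),
                       list(PW = sprintf("T%d", 1:6)), n_perm = 1000, seed = 1)
  expect_true(tr$active)
  expect_gt(tr$rho_LR, 0.5)
  expect_gte(tr$q, tr$p)

  null <- mk_expr(FALSE)
  tr0 <- active_triples(null, data.frame(ligand = "L", receptor = "R"),
                        list(PW = sprintf("T%d", 1:6)), n_perm = 1000, seed = 1)
  expect_false(tr0$active)

  expect_error(active_triples(expr, data.frame(ligand = "L", receptor = "R"),
                              list(PW = sprintf("T%d", 1:6)), n_perm = 0),
               "n_perm")
  const <- expr; const["R", ] <- 1
  expect_warning(
    out <- active_triples(const, data.frame(ligand = "L", receptor = "R"),
                          list(PW = sprintf("T%d", 1:6)), n_perm = 500, seed = 1),
    "constant")
  expect_equal(nrow(out), 0)
})

test_that("overlap of the two scoring methods is a keyed set intersection", {
  t1 <- data.frame(cluster = c("CR", "CR"), ligand = c("A", "C"),
                   receptor = c("B", "D"))
  t2 <- data.frame(cluster = c("CR", "CR"), ligand = c("C", "E"),
                   receptor = c("D", "F"))
  ov <- overlap_lrp(t1, t2)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$ligand, "C")
  expect_equal(nrow(overlap_lrp(t1, t1)), 2)
  expect_equal(nrow(overlap_lrp(t1, t2[0, ])), 0)
})
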