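# File I/O: Matrix Market counts with gene/barcode sidecars, annotation and
# pair tables as TSV, pathway sets as GMT, ground truth as JSON.

#' Read a count matrix from Matrix Market + sidecar files
#'
#' Expects the 1-based `matrix coordinate integer general` layout with a
#' `genes.tsv` and `barcodes.tsv` sidecar (one identifier per line, first
#' column used). Dimension or index violations raise a parse error naming
#' the offending file line.
#'
#' @param mtx path to the `.mtx` file.
#' @param genes,barcodes sidecar paths; default to `genes.tsv` /
#'   `barcodes.tsv` next to `mtx`.
#' @return sparse `dgCMatrix` with gene/barcode dimnames.
#' @export
read_counts <- function(mtx, genes = file.path(dirname(mtx), "genes.tsv"),
                        barcodes = file.path(dirname(mtx), "barcodes.tsv")) {
  for (f in c(mtx, genes, barcodes))
    .assert(file.exists(f), "file not found: %s", f)
  lines <- readLines(mtx, n = 100L)
  .assert(length(lines) > 0 && startsWith(lines[1], "%%MatrixMarket"),
          "%s line 1: missing %%%%MatrixMarket header", mtx)
  .assert(grepl("matrix coordinate (integer|real) general", lines[1]),
          "%s line 1: unsupported layout '%s'", mtx, lines[1])
  n_comment <- which(!startsWith(lines, "%"))[1] - 1L
  .assert(!is.na(n_comment), "%s: no dimension line found", mtx)
  dims <- suppressWarnings(as.numeric(strsplit(trimws(lines[n_comment + 1]),
                                               "\\s+")[[1]]))
  .assert(length(dims) == 3 && !anyNA(dims),
          "%s line %d: malformed dimension line", mtx, n_comment + 1)

  body <- data.table::fread(mtx, skip = n_comment + 1L, header = FALSE,
                            colClasses = "numeric", fill = TRUE)
  .assert(nrow(body) >= dims[3],
          "%s: truncated at line %d (expected %d entries, found %d)",
          mtx, n_comment + 1L + nrow(body) + 1L, dims[3], nrow(body))
  body <- body[seq_len(dims[3]), ]
  bad <- which(!stats::complete.cases(body) |
                 body[[1]] < 1 | body[[1]] > dims[1] |
                 body[[2]] < 1 | body[[2]] > dims[2])
  .assert(length(bad) == 0,
          "%s line %d: entry index out of declared bounds %dx%d",
          mtx, n_comment + 1L + bad[1], dims[1], dims[2])

  g <- data.table::fread(genes, header = FALSE)[[1]]
  b <- data.table::fread(barcodes, header = FALSE)[[1]]
  .assert(length(g) == dims[1],
          "%s: %d gene ids but matrix declares %d rows", genes, length(g), dims[1])
  .assert(length(b) == dims[2],
          "%s: %d barcodes but matrix declares %d columns", barcodes, length(b), dims[2])
  m <- Matrix::sparseMatrix(i = body[[1]], j = body[[2]], x = body[[3]],
                            dims = dims[1:2])
  .as_count_matrix(m, genes = g, barcodes = b)
}

#' Write a count matrix as Matrix Market + sidecars
#'
#' @param m sparse count matrix with dimnames.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts <- function(m, dir) {
  m <- .as_count_matrix(m)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tm <- as(m, "TsparseMatrix")
  path <- file.path(dir, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x))), path)
  if (length(tm@x))
    data.table::fwrite(data.table::data.table(i = tm@i + 1L, j = tm@j + 1L,
                                              x = as.integer(tm@x)),
                       path, sep = " ", col.names = FALSE, append = TRUE)
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write a TSV table
#'
#' Thin wrappers around [data.table::fread()]/[data.table::fwrite()]
#' returning plain data.frames, used for annotation, ligand-receptor and
#' regulon tables.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", "")))
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write GMT gene sets
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#'
#' @param path file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits the MTX + sidecars, annotation TSV, ligand-receptor TSV, regulon
#' TSV, pathway GMT and the ground truth as JSON.
#'
#' @param sim a `pci_sim` from [simulate_pci_dataset()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pci_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, dir)
  write_tsv_table(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv_table(sim$lr_table, file.path(dir, "lr_table.tsv"))
  write_tsv_table(sim$regulons, file.path(dir, "regulons.tsv"))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
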