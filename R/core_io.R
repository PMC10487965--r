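## Domain containers ---------------------------------------------------------

#' Construct a validated count matrix with cell and gene metadata
#'
#' The central container of the package: a genes x cells UMI count matrix
#' (sparse) together with per-cell metadata (sample, experimental group,
#' annotated cell type, optional subcluster label) and per-gene metadata.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse); must carry unique rownames (gene symbols)
#'   and colnames (cell barcodes).
#' @param cell_meta data.frame with one row per cell; must contain columns
#'   `barcode`, `sample_id`, `group` and `cell_type`. `group` levels follow
#'   the study design: Ctrl, DKD, DM, ARB, SGLT2i, HKC.
#' @param gene_meta optional data.frame with one row per gene (column
#'   `symbol` plus annotation columns such as `chromosome`).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta, gene_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene symbols as rownames and barcodes as colnames")
  x <- counts@x
  if (any(x < 0) || any(x != round(x)))
    stop("validation error: counts must be non-negative integers")
  if (anyDuplicated(rownames(counts)))
    stop("validation error: duplicate gene symbols")
  if (anyDuplicated(colnames(counts)))
    stop("validation error: duplicate cell barcodes")
  stopifnot(is.data.frame(cell_meta))
  need <- c("barcode", "sample_id", "group", "cell_type")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stop("cell_meta missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(counts), cell_meta$barcode)
  if (length(absent))
    stop("validation error: barcodes absent from cell metadata: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), , drop = FALSE]
  rownames(cell_meta) <- cell_meta$barcode
  if (is.null(gene_meta))
    gene_meta <- data.frame(symbol = rownames(counts), stringsAsFactors = FALSE)
  if (!all(rownames(counts) %in% gene_meta$symbol))
    stop("validation error: genes absent from gene metadata")
  gene_meta <- gene_meta[match(rownames(counts), gene_meta$symbol), , drop = FALSE]
  rownames(gene_meta) <- gene_meta$symbol
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:     ", paste(names(table(x$cell_meta$group)), collapse = ", "), "\n")
  cat("  cell types: ", paste(names(table(x$cell_meta$cell_type)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or cell
#'
#' @param x a `count_matrix`
#' @param genes,cells character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @return a `count_matrix` restricted to the selection.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  count_matrix(x$counts[genes, cells, drop = FALSE],
               x$cell_meta[x$cell_meta$barcode %in% colnames(x$counts[, cells, drop = FALSE]), ,
                           drop = FALSE],
               x$gene_meta)
}

## 10x-style MTX triple ------------------------------------------------------

#' Read a 10x-style MTX triple plus a cell-metadata TSV
#'
#' Reads a MatrixMarket coordinate matrix (1-based indices per the standard)
#' with its features and barcodes sidecar files, joins the per-barcode
#' metadata table and returns a validated [count_matrix()].
#'
#' @param matrix_path path to `matrix.mtx` (MatrixMarket coordinate integer).
#' @param features_path path to `features.tsv` (first column = gene symbol).
#' @param barcodes_path path to `barcodes.tsv` (one barcode per line).
#' @param cell_meta_path path to a TSV with header keyed by `barcode`.
#' @return a `count_matrix`.
#' @export
load_counts <- function(matrix_path, features_path, barcodes_path, cell_meta_path) {
  for (p in c(matrix_path, features_path, barcodes_path, cell_meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (file.size(matrix_path) == 0L) stop("format error: empty matrix file")
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("format error: ", conditionMessage(e)))
  feats <- utils::read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  bars <- readLines(barcodes_path)
  bars <- bars[nzchar(bars)]
  if (nrow(m) != nrow(feats) || ncol(m) != length(bars))
    stop(sprintf("format error: MTX is %d x %d but %d features / %d barcodes given",
                 nrow(m), ncol(m), nrow(feats), length(bars)))
  dimnames(m) <- list(feats[[1L]], bars)
  meta <- utils::read.delim(cell_meta_path, stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

#' Write a count matrix as a 10x-style MTX triple plus metadata TSV
#'
#' @param x a `count_matrix`
#' @param dir output directory (created if missing); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `cell_meta.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(symbol = rownames(x$counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## GMT gene-set collections --------------------------------------------------

#' Read a GMT gene-set collection (Broad dialect)
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are collapsed; duplicate set names are an
#' error; empty sets are an error.
#'
#' @param path path to a `.gmt` file.
#' @return a named list of character vectors with class
#'   `gene_set_collection`; descriptions kept as an attribute.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("format error: line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("validation error: duplicate set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character gene vectors (unique names, non-empty
#'   sets).
#' @param description optional character vector parallel to `sets`.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("validation error: duplicate set name")
  if (any(!vapply(sets, length, 1L))) stop("validation error: empty gene set")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, description = description, class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

## Gene catalogs and ligand-receptor databases -------------------------------

#' Read a per-gene annotation catalog from TSV
#'
#' Columns: `symbol`, logical flags `is_mito_encoded`, `is_mito_mrna`,
#' `is_mang`, `is_tf`, and `slc_family` / `chromosome` character columns
#' (empty string = none). Enforces that every mitochondrially encoded mRNA
#' gene is mitochondrially encoded.
#'
#' @param path path to the TSV (header row required).
#' @return data.frame with class `gene_catalog`.
#' @export
load_gene_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "is_mito_encoded", "is_mito_mrna", "is_mang", "is_tf")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  for (f in c("is_mito_encoded", "is_mito_mrna", "is_mang", "is_tf"))
    d[[f]] <- as.logical(d[[f]])
  if (any(d$is_mito_mrna & !d$is_mito_encoded))
    stop("validation error: is_mito_mrna implies is_mito_encoded")
  if (anyDuplicated(d$symbol)) stop("validation error: duplicate catalog symbols")
  class(d) <- c("gene_catalog", "data.frame")
  d
}

#' The bundled mouse mitochondrial gene catalog
#'
#' The 37 genes encoded on the mouse mitochondrial genome (mm10 chrM
#' annotation): 13 mRNA-coding genes, 2 rRNAs and 22 tRNAs.
#'
#' @return a `gene_catalog` restricted to the mitochondrial genome.
#' @export
mouse_mito_catalog <- function() {
  load_gene_catalog(system.file("extdata", "mouse_mito_catalog.tsv",
                                package = "mitostate", mustWork = TRUE))
}

#' Read a ligand-receptor interaction database from TSV
#'
#' Columns: `pathway`, `ligand`, `receptor`, `category` (secreted, contact
#' or ECM). Multi-subunit ligands/receptors are `+`-separated gene symbols;
#' their ensemble expression is summarised by the geometric mean.
#'
#' @param path path to the TSV (header row required).
#' @return data.frame with class `lr_database`.
#' @export
load_lr_database <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lr_database(d)
}

#' Construct/validate a ligand-receptor database
#' @param d data.frame with columns pathway, ligand, receptor, category
#' @return a validated `lr_database`
#' @export
lr_database <- function(d) {
  need <- c("pathway", "ligand", "receptor", "category")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("LR database missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(d$pathway))) stop("validation error: empty pathway name")
  if (any(!nzchar(d$ligand)) || any(!nzchar(d$receptor)))
    stop("validation error: every row needs at least one ligand and one receptor gene")
  class(d) <- c("lr_database", "data.frame")
  d
}
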