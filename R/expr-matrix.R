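#' Construct an expression matrix with per-cell individual labels
#'
#' An `expr_matrix` holds a genes-by-cells matrix of non-negative,
#' library-size-normalized expression values (TPM-like units) together with
#' the individual (donor/subject) each cell was sampled from. The individual
#' labels are what make the object usable for hierarchical modelling: cells
#' from the same individual are correlated and the individual, not the cell,
#' is the independent experimental unit.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. All values
#'   must be finite and non-negative.
#' @param individual_of_cell Character vector, one individual id per cell.
#'   At least two distinct individuals are required.
#' @param gene_ids,cell_ids Optional unique identifiers; default to the
#'   dimnames of `values` or generated labels.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `cell_ids` and `individual_of_cell`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4)
#' x <- expr_matrix(m, c("a", "a", "b", "b"))
#' n_genes(x)
expr_matrix <- function(values, individual_of_cell, gene_ids = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- gene_ids %||% rownames(values) %||% paste0("gene", seq_len(nrow(values)))
  cell_ids <- cell_ids %||% colnames(values) %||% paste0("cell", seq_len(ncol(values)))
  individual_of_cell <- as.character(individual_of_cell)
  x <- structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         individual_of_cell = individual_of_cell),
    class = "expr_matrix"
  )
  validate_expr_matrix(x)
}

validate_expr_matrix <- function(x) {
  v <- x$values
  if (!all(is.finite(v))) {
    abort("Expression values must be finite; missing values are not accepted.")
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Expression values must be non-negative; first negative at gene %s, cell %s.",
                  x$gene_ids[bad[1]], x$cell_ids[bad[2]]))
  }
  if (anyDuplicated(x$gene_ids)) {
    abort(paste0("Duplicated gene ids: ",
                 paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(x$cell_ids)) {
    abort(paste0("Duplicated cell ids: ",
                 paste(unique(x$cell_ids[duplicated(x$cell_ids)]), collapse = ", ")))
  }
  if (length(x$gene_ids) != nrow(v) || length(x$cell_ids) != ncol(v)) {
    abort("gene_ids/cell_ids lengths must match the matrix dimensions.")
  }
  if (length(x$individual_of_cell) != ncol(v)) {
    abort("`individual_of_cell` must supply exactly one label per cell.")
  }
  if (length(unique(x$individual_of_cell)) < 2) {
    abort("At least two distinct individuals are required.")
  }
  rownames(x$values) <- x$gene_ids
  colnames(x$values) <- x$cell_ids
  x
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expr_matrix
#' @export
n_cells <- function(x) ncol(x$values)

#' @rdname expr_matrix
#' @export
individuals <- function(x) unique(x$individual_of_cell)

#' Cell-level metadata of an expression matrix or simulated dataset
#'
#' @param x An `expr_matrix` or `sim_dataset`.
#' @return A tibble with one row per cell (`cell_id`, `individual_id`, and
#'   `phenotype` when present).
#' @export
cell_metadata <- function(x) UseMethod("cell_metadata")

#' @export
cell_metadata.expr_matrix <- function(x) {
  out <- tibble(cell_id = x$cell_ids, individual_id = x$individual_of_cell)
  if (!is.null(x$phenotype_of_cell)) out$phenotype <- x$phenotype_of_cell
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, %d individuals\n",
              n_genes(x), n_cells(x), length(individuals(x))))
  invisible(x)
}

# Gene subsetting, used by the pruning step.
subset_genes <- function(x, idx) {
  x$values <- x$values[idx, , drop = FALSE]
  x$gene_ids <- x$gene_ids[idx]
  validate_expr_matrix(x)
}

#' Read an expression matrix and its cell metadata
#'
#' Reads a genes-by-cells expression table in either dense form (CSV/TSV,
#' genes in rows, first column the gene id, header row of cell ids) or
#' MatrixMarket coordinate form (`.mtx` plus `genes.tsv` / `barcodes.tsv`
#' sidecar files in the same directory), together with a tab-separated cell
#' metadata table with header `cell_id`, `individual_id` and optionally
#' `phenotype`. Cells are returned in metadata order; any disagreement
#' between the matrix's and the metadata's cell sets is an error that names
#' the offending ids. MatrixMarket indices are 1-based per the standard;
#' the conversion is confined to this reader.
#'
#' @param matrix_path Path to the dense table or the `.mtx` file.
#' @param metadata_path Path to the metadata TSV.
#' @param format `"dense"` or `"mtx"`.
#' @param genes_path,barcodes_path Optional explicit sidecar paths for
#'   `format = "mtx"`; default to `genes.tsv` and `barcodes.tsv` next to the
#'   matrix file.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            format = c("dense", "mtx"),
                            genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            cell_id = readr::col_character(),
                            individual_id = readr::col_character(),
                            .default = readr::col_guess()))
  if (!all(c("cell_id", "individual_id") %in% names(meta))) {
    abort("Metadata must have columns `cell_id` and `individual_id`.")
  }
  if (anyDuplicated(meta$cell_id)) {
    abort("Metadata contains duplicated cell ids.")
  }

  if (format == "dense") {
    delim <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
    tab <- readr::read_delim(matrix_path, delim = delim, show_col_types = FALSE)
    gene_ids <- as.character(tab[[1]])
    num <- tab[, -1, drop = FALSE]
    if (!all(vapply(num, is.numeric, logical(1)))) {
      abort("Dense input must be numeric after the gene-id column.")
    }
    m <- as.matrix(num)
    if (anyNA(m)) {
      abort("Dense input contains missing values; they are rejected, not imputed.")
    }
    rownames(m) <- gene_ids
  } else {
    dir <- dirname(matrix_path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    mm <- Matrix::readMM(matrix_path)
    gene_ids <- readr::read_tsv(genes_path, col_names = FALSE,
                                show_col_types = FALSE)[[1]]
    cell_ids <- readr::read_tsv(barcodes_path, col_names = FALSE,
                                show_col_types = FALSE)[[1]]
    if (nrow(mm) != length(gene_ids) || ncol(mm) != length(cell_ids)) {
      abort("MatrixMarket dimensions do not match the genes/barcodes sidecars.")
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(gene_ids, cell_ids)
  }

  matrix_cells <- colnames(m)
  missing_from_meta <- setdiff(matrix_cells, meta$cell_id)
  missing_from_matrix <- setdiff(meta$cell_id, matrix_cells)
  if (length(missing_from_meta) || length(missing_from_matrix)) {
    abort(paste0(
      "Cell sets of matrix and metadata disagree.",
      if (length(missing_from_meta))
        paste0(" In matrix but not metadata: ",
               paste(missing_from_meta, collapse = ", "), "."),
      if (length(missing_from_matrix))
        paste0(" In metadata but not matrix: ",
               paste(missing_from_matrix, collapse = ", "), ".")))
  }
  m <- m[, meta$cell_id, drop = FALSE]
  x <- expr_matrix(m, meta$individual_id,
                   gene_ids = rownames(m), cell_ids = meta$cell_id)
  if ("phenotype" %in% names(meta)) x$phenotype_of_cell <- meta$phenotype
  x
}

#' Write a simulated dataset to plain-text files
#'
#' Writes three files under a common prefix: the counts matrix
#' (`<prefix>_counts.csv` dense, or `<prefix>_counts.mtx` with
#' `genes.tsv`/`barcodes.tsv` sidecars), the cell metadata
#' (`<prefix>_cells.tsv` with `cell_id`, `individual_id`, `phenotype`) and
#' the per-gene truth table (`<prefix>_genes.tsv` with `gene_id`, `is_de`,
#' `applied_effect`). The counts/metadata pair round-trips through
#' [read_expression()].
#'
#' @param dataset A `sim_dataset` from [simulate_binary()] or
#'   [simulate_continuous()].
#' @param out_prefix Path prefix for the output files.
#' @param format `"dense"` or `"mtx"` for the counts matrix.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_simulated <- function(dataset, out_prefix, format = c("dense", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "sim_dataset"))
  counts <- dataset$counts
  paths <- c()
  if (format == "dense") {
    cpath <- paste0(out_prefix, "_counts.csv")
    tab <- as_tibble(counts, rownames = "gene_id")
    readr::write_csv(tab, cpath)
    paths["counts"] <- cpath
  } else {
    cpath <- paste0(out_prefix, "_counts.mtx")
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), cpath)
    gpath <- file.path(dirname(cpath), "genes.tsv")
    bpath <- file.path(dirname(cpath), "barcodes.tsv")
    readr::write_tsv(tibble(x = rownames(counts)), gpath, col_names = FALSE)
    readr::write_tsv(tibble(x = colnames(counts)), bpath, col_names = FALSE)
    paths[c("counts", "genes", "barcodes")] <- c(cpath, gpath, bpath)
  }
  mpath <- paste0(out_prefix, "_cells.tsv")
  readr::write_tsv(cell_metadata(dataset), mpath)
  paths["cells"] <- mpath
  tpath <- paste0(out_prefix, "_genes.tsv")
  readr::write_tsv(gene_truth(dataset), tpath)
  paths["genes_truth"] <- tpath
  invisible(paths)
}
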