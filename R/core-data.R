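#' @importFrom Matrix readMM writeMM colSums rowSums t
#' @importFrom rlang .data
#' @import methods
NULL

#' Construct a per-species single-cell dataset
#'
#' Bundles a sparse gene x cell count matrix with a per-cell annotation
#' table for one species. All species in an analysis must share an identical,
#' pre-harmonized gene namespace (same `gene_ids` in the same order).
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes x cells,
#'   with row and column names.
#' @param annotation data frame with one row per cell. Must contain `cell_id`;
#'   `species`, `clone`, `timepoint` are filled with defaults when absent.
#'   `n_umi`, `n_genes` and `mito_fraction` are (re)derived from the counts.
#' @param species species tag applied to all cells.
#' @param mito_prefix gene-ID prefix(es) marking mitochondrial genes, or a
#'   character vector of explicit mitochondrial gene IDs when
#'   `mito_genes` is given.
#' @param mito_genes optional explicit character vector of mitochondrial gene
#'   IDs; overrides prefix matching.
#' @return An object of class `species_dataset` with elements `species`,
#'   `counts` (dgCMatrix), `annotation` (tibble) and `lognorm` (NULL until
#'   [lognormalize()] is called).
#' @export
species_dataset <- function(counts, annotation = NULL, species = "unknown",
                            mito_prefix = "MT-", mito_genes = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene IDs as rownames and cell IDs as colnames")
  }
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene IDs: ", paste(utils::head(dup_g, 5), collapse = ", "))
  }
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) {
    stop("duplicate cell IDs: ", paste(utils::head(dup_c, 5), collapse = ", "))
  }
  x <- counts@x
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integral")

  if (is.null(annotation)) {
    annotation <- tibble::tibble(cell_id = cell_ids)
  }
  annotation <- tibble::as_tibble(annotation)
  if (!"cell_id" %in% names(annotation)) stop("annotation must have a cell_id column")
  if (anyDuplicated(annotation$cell_id)) stop("annotation has duplicated cell_id rows")
  missing_cells <- setdiff(cell_ids, annotation$cell_id)
  if (length(missing_cells)) {
    stop("cells present in matrix but missing from annotation: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  extra <- setdiff(annotation$cell_id, cell_ids)
  if (length(extra)) {
    stop("annotation rows for cells absent from matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  annotation <- annotation[match(cell_ids, annotation$cell_id), ]
  annotation$species <- species
  if (!"clone" %in% names(annotation)) annotation$clone <- "clone1"
  if (!"timepoint" %in% names(annotation)) annotation$timepoint <- NA_character_

  mt <- if (!is.null(mito_genes)) {
    gene_ids %in% mito_genes
  } else {
    Reduce(`|`, lapply(mito_prefix, function(p) startsWith(gene_ids, p)))
  }
  n_umi <- Matrix::colSums(counts)
  annotation$n_umi <- as.numeric(n_umi)
  annotation$n_genes <- as.numeric(Matrix::colSums(counts > 0))
  mito_umi <- if (any(mt)) Matrix::colSums(counts[mt, , drop = FALSE]) else rep(0, length(cell_ids))
  annotation$mito_fraction <- unname(ifelse(n_umi > 0,
                                            as.numeric(mito_umi) / n_umi, 0))

  structure(
    list(species = species, counts = counts, annotation = annotation,
         lognorm = NULL),
    class = "species_dataset"
  )
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("<species_dataset> %s: %d genes x %d cells%s\n",
              x$species, nrow(x$counts), ncol(x$counts),
              if (is.null(x$lognorm)) "" else " (log-normalized)"))
  invisible(x)
}

#' @export
dim.species_dataset <- function(x) dim(x$counts)

#' Keep a subset of cells of a dataset
#'
#' @param ds a `species_dataset`
#' @param cell_ids character vector of cell IDs to retain (order preserved)
#' @return the subset `species_dataset`
#' @export
subset_cells <- function(ds, cell_ids) {
  stopifnot(inherits(ds, "species_dataset"))
  missing <- setdiff(cell_ids, colnames(ds$counts))
  if (length(missing)) stop("unknown cell IDs: ", paste(utils::head(missing, 5), collapse = ", "))
  ds$counts <- ds$counts[, cell_ids, drop = FALSE]
  ds$annotation <- ds$annotation[match(cell_ids, ds$annotation$cell_id), ]
  if (!is.null(ds$lognorm)) ds$lognorm <- ds$lognorm[, cell_ids, drop = FALSE]
  ds
}

#' Read a species dataset from a directory
#'
#' Expects a Matrix Market count matrix (`matrix.mtx`) plus TSV gene
#' (`genes.tsv`, column `gene_id`) and cell (`cells.tsv`, column `cell_id`
#' and optional metadata columns) tables, each with a header row. Files may
#' hold the matrix in either orientation; set `cells_in_rows = TRUE` when
#' rows are cells.
#'
#' @param path directory containing the three files
#' @param species species tag
#' @param cells_in_rows logical; the on-disk matrix has cells as rows
#' @inheritParams species_dataset
#' @return a validated `species_dataset`
#' @export
read_dataset <- function(path, species, cells_in_rows = FALSE,
                         mito_prefix = "MT-", mito_genes = NULL) {
  files <- file.path(path, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("missing input files: ", paste(miss, collapse = ", "))
  m <- methods::as(Matrix::readMM(files[1]), "CsparseMatrix")
  genes <- utils::read.delim(files[2], stringsAsFactors = FALSE)
  cells <- utils::read.delim(files[3], stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes)) stop("genes.tsv must have a gene_id column")
  if (!"cell_id" %in% names(cells)) stop("cells.tsv must have a cell_id column")
  if (cells_in_rows) m <- Matrix::t(m)
  if (nrow(m) != nrow(genes)) {
    stop(sprintf("dimension mismatch: matrix has %d genes but genes.tsv %d rows",
                 nrow(m), nrow(genes)))
  }
  if (ncol(m) != nrow(cells)) {
    stop(sprintf("dimension mismatch: matrix has %d cells but cells.tsv %d rows",
                 ncol(m), nrow(cells)))
  }
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  species_dataset(m, tibble::as_tibble(cells), species = species,
                  mito_prefix = mito_prefix, mito_genes = mito_genes)
}

#' Write a species dataset to a directory
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` and `cells.tsv`.
#' Deterministic: fixed column order, `%.6g` float formatting.
#'
#' @param ds a `species_dataset`
#' @param path output directory (created if absent)
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "species_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
  write_tsv_det(data.frame(gene_id = rownames(ds$counts)),
                file.path(path, "genes.tsv"))
  write_tsv_det(as.data.frame(ds$annotation), file.path(path, "cells.tsv"))
  invisible(path)
}

# deterministic TSV writer: header row, no quotes, %.6g numeric format
write_tsv_det <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !all(df[[j]] == round(df[[j]]), na.rm = TRUE)) {
      df[[j]] <- sprintf("%.6g", df[[j]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Quality-filter cells
#'
#' Retains cells with strictly more than `min_genes` detected genes and a
#' mitochondrial fraction strictly below `max_mito`. The gene set is
#' unchanged.
#'
#' @param ds a `species_dataset`
#' @param min_genes minimum detected genes, exclusive (default 1000)
#' @param max_mito maximum mitochondrial fraction, exclusive (default 0.08)
#' @return the filtered `species_dataset`
#' @export
qc_filter <- function(ds, min_genes = 1000, max_mito = 0.08) {
  stopifnot(inherits(ds, "species_dataset"))
  keep <- ds$annotation$n_genes > min_genes & ds$annotation$mito_fraction < max_mito
  if (!any(keep)) warning("qc_filter removed all cells")
  subset_cells(ds, ds$annotation$cell_id[keep])
}

#' Library-size log-normalization
#'
#' `lognorm[g, c] = log1p(counts[g, c] / n_umi[c] * scale)`. Raw counts are
#' retained; the normalized matrix is stored in `$lognorm`.
#'
#' @param ds a `species_dataset`
#' @param scale target library size (default 1e4)
#' @return the dataset with `$lognorm` populated
#' @export
lognormalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "species_dataset"))
  depth <- ds$annotation$n_umi
  if (any(depth == 0)) {
    stop("cells with zero UMIs cannot be normalized: ",
         paste(utils::head(ds$annotation$cell_id[depth == 0], 5), collapse = ", "))
  }
  ln <- ds$counts
  ln@x <- log1p(ln@x / rep.int(depth, diff(ln@p)) * scale)
  ds$lognorm <- ln
  ds
}

#' Restrict datasets to their common gene set
#'
#' Strict intersection mode for inputs whose gene namespaces do not already
#' match: every dataset is subset to the intersection of all gene IDs, in the
#' order of the first dataset.
#'
#' @param datasets list of `species_dataset`
#' @return list of datasets on the shared gene set
#' @export
intersect_genes <- function(datasets) {
  shared <- Reduce(intersect, lapply(datasets, function(d) rownames(d$counts)))
  if (!length(shared)) stop("no shared genes across datasets")
  lapply(datasets, function(d) {
    d$counts <- d$counts[shared, , drop = FALSE]
    if (!is.null(d$lognorm)) d$lognorm <- d$lognorm[shared, , drop = FALSE]
    d
  })
}

# shared-namespace check used by cross-species stages
check_shared_genes <- function(datasets) {
  g1 <- rownames(datasets[[1]]$counts)
  for (d in datasets[-1]) {
    if (!identical(rownames(d$counts), g1)) {
      stop("datasets do not share an identical gene namespace; ",
           "run intersect_genes() first")
    }
  }
  invisible(g1)
}
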