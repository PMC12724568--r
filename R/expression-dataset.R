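#' Construct an expression dataset
#'
#' The central container of the package: a sparse cells-by-genes count matrix
#' together with per-cell annotations and, after [log_normalize()], a
#' log-normalized expression layer of the same shape. Cells are rows
#' internally; on-disk MatrixMarket triplets follow the 10x genes-by-cells
#' convention and are transposed on read.
#'
#' @param counts Non-negative integer matrix (cells x genes), dense or sparse.
#'   Row names are cell ids, column names gene ids; both must be unique.
#' @param cell_meta Data frame of per-cell annotations with a `cell_id`
#'   column. Recognised columns are `cluster`, `dataset_id`, `species`,
#'   `genotype` (`"WT"`, `"MUT"` or `NA`), `batch` and `region`; missing
#'   columns are filled with `NA`. Rows are aligned to the counts by
#'   `cell_id`.
#' @param norm Optional normalized layer (same dimensions as `counts`),
#'   normally produced by [log_normalize()] rather than supplied directly.
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts` (dgCMatrix), `norm` (dgCMatrix or `NULL`), `gene_ids`,
#'   `cell_ids` and `cell_meta` (a tibble).
#' @seealso [read_expression()], [log_normalize()], [qc_filter()]
#' @export
expression_dataset <- function(counts, cell_meta, norm = NULL) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry cell ids as rownames and gene ids as colnames",
         call. = FALSE)
  }
  cell_ids <- rownames(counts)
  gene_ids <- colnames(counts)
  if (anyDuplicated(gene_ids)) stop("duplicate gene id", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell id", call. = FALSE)
  if (length(counts@x) && min(counts@x) < 0) {
    stop("counts has negative entries", call. = FALSE)
  }
  cell_meta <- align_cell_meta(cell_meta, cell_ids)
  if (!is.null(norm)) {
    norm <- as_dgc(norm)
    stopifnot(identical(dim(norm), dim(counts)))
    dimnames(norm) <- dimnames(counts)
  }
  structure(
    list(counts = counts, norm = norm, gene_ids = gene_ids,
         cell_ids = cell_ids, cell_meta = cell_meta),
    class = "expression_dataset"
  )
}

meta_columns <- c("cluster", "dataset_id", "species", "genotype", "batch",
                  "region")

align_cell_meta <- function(cell_meta, cell_ids) {
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("cell_meta must contain a cell_id column", call. = FALSE)
  }
  if (anyDuplicated(cell_meta$cell_id)) {
    stop("duplicate cell_id in metadata", call. = FALSE)
  }
  missing_cols <- setdiff(meta_columns, names(cell_meta))
  for (col in missing_cols) cell_meta[[col]] <- NA_character_
  unmatched <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(unmatched)) {
    warning(length(unmatched),
            " cell(s) in matrix absent from metadata; annotated as NA",
            call. = FALSE)
  }
  out <- dplyr::left_join(tibble::tibble(cell_id = cell_ids), cell_meta,
                          by = "cell_id")
  gt <- out$genotype
  bad_gt <- !is.na(gt) & !gt %in% c("WT", "MUT")
  if (any(bad_gt)) {
    stop("genotype must be WT, MUT or NA", call. = FALSE)
  }
  dplyr::select(out, dplyr::all_of(c("cell_id", meta_columns)),
                dplyr::everything())
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$counts), " cells x ",
      ncol(x$counts), " genes\n", sep = "")
  cat("  norm layer: ", if (is.null(x$norm)) "absent" else "present", "\n",
      sep = "")
  cl <- table(x$cell_meta$cluster, useNA = "ifany")
  cat("  clusters: ",
      paste0(names(cl), " (", as.integer(cl), ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

#' Subset an expression dataset to a set of cells
#'
#' @param ds An [expression_dataset()].
#' @param cells Character vector of cell ids (or logical/integer index along
#'   cells) to keep.
#' @return An `expression_dataset` restricted to those cells, layers and
#'   metadata aligned.
#' @export
subset_cells <- function(ds, cells) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(cells)) {
    missing <- setdiff(cells, ds$cell_ids)
    if (length(missing)) {
      stop("unknown cell id(s): ", paste(utils::head(missing, 3),
                                         collapse = ", "), call. = FALSE)
    }
  }
  counts <- ds$counts[cells, , drop = FALSE]
  norm <- if (!is.null(ds$norm)) ds$norm[cells, , drop = FALSE]
  meta <- ds$cell_meta[match(rownames(counts), ds$cell_meta$cell_id), ]
  expression_dataset(counts, meta, norm = norm)
}

#' Cell ids belonging to a cluster
#'
#' @param ds An [expression_dataset()].
#' @param cluster Cluster label to look up in the cell metadata.
#' @return Character vector of cell ids.
#' @export
cluster_cells <- function(ds, cluster) {
  stopifnot(inherits(ds, "expression_dataset"))
  hit <- !is.na(ds$cell_meta$cluster) & ds$cell_meta$cluster == cluster
  if (!any(hit)) stop("cluster not found: ", cluster, call. = FALSE)
  ds$cell_meta$cell_id[hit]
}
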