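#' Read a 10x-style MatrixMarket triplet plus cell metadata
#'
#' Reads a coordinate-format MatrixMarket matrix stored genes-by-cells (the
#' dominant single-cell triplet dialect), transposes it to the internal
#' cells-by-rows orientation, and attaches per-cell metadata. Cells present
#' in the matrix but absent from the metadata receive `NA` annotations with
#' a warning; dimension mismatches between the matrix and the id files are
#' hard errors.
#'
#' @param matrix_path Path to the `.mtx` file (integer coordinate format,
#'   genes x cells).
#' @param genes_path,cells_path TSV files with one id per row (first column
#'   used), row counts matching the matrix dimensions.
#' @param meta_path TSV keyed by `cell_id` with annotation columns (see
#'   [expression_dataset()]).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, genes_path, cells_path, meta_path) {
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    stop("malformed MatrixMarket file '", matrix_path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  genes <- read_id_column(genes_path)
  cells <- read_id_column(cells_path)
  if (nrow(m) != length(genes)) {
    stop("matrix has ", nrow(m), " gene rows but ", length(genes),
         " gene ids in '", genes_path, "'", call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop("matrix has ", ncol(m), " cell columns but ", length(cells),
         " cell ids in '", cells_path, "'", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate gene id", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell id", call. = FALSE)
  counts <- Matrix::t(m)
  dimnames(counts) <- list(cells, genes)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  ds <- expression_dataset(counts, meta)
  message("read_expression: ", length(cells), " cells x ", length(genes),
          " genes from ", matrix_path)
  ds
}

read_id_column <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  as.character(tab[[1]])
}

#' Write an expression dataset as a MatrixMarket triplet plus metadata
#'
#' Inverse of [read_expression()]: counts are stored genes-by-cells in
#' integer coordinate MatrixMarket format alongside `genes.tsv`,
#' `barcodes.tsv` and `meta.tsv`. Round-tripping through
#' [read_expression()] is the identity on counts.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_expression <- function(ds, dir) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "barcodes.tsv"),
             meta = file.path(dir, "meta.tsv"))
  m <- Matrix::t(ds$counts)
  # writeMM emits "real" for dgCMatrix; counts are integral so coerce header
  Matrix::writeMM(m, paths[["matrix"]])
  writeLines(ds$gene_ids, paths[["genes"]])
  writeLines(ds$cell_ids, paths[["cells"]])
  write_table(ds$cell_meta, paths[["meta"]])
  invisible(paths)
}

#' Read a species-gene-to-family ortholog table
#'
#' The table maps each species gene to one or more reference (human-symbol)
#' ortholog families; many-to-many mappings are expected, so that paralogs
#' such as zebrafish pbx3a and pbx3b both resolve to the PBX3 family.
#' Duplicate rows are collapsed, and the number of genes per species mapping
#' to two or more families is reported.
#'
#' @param path TSV with columns `species`, `gene_id`, `family`.
#' @return A deduplicated tibble of class `ortholog_table` with those three
#'   columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  ortholog_table(tab)
}

#' Validate an in-memory ortholog table
#'
#' @param tab Data frame with columns `species`, `gene_id`, `family`.
#' @return A deduplicated tibble of class `ortholog_table`.
#' @export
ortholog_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("species", "gene_id", "family")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("ortholog table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::distinct(tab[, need])
  if (any(is.na(tab$family) | tab$family == "")) {
    stop("ortholog table has rows with empty family", call. = FALSE)
  }
  if (any(is.na(tab$gene_id) | tab$gene_id == "")) {
    stop("ortholog table has rows with empty gene_id", call. = FALSE)
  }
  multi <- tab |>
    dplyr::distinct(.data$species, .data$gene_id, .data$family) |>
    dplyr::count(.data$species, .data$gene_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::count(.data$species)
  if (nrow(multi)) {
    message("ortholog table: genes mapping to >=2 families: ",
            paste0(multi$species, "=", multi$n, collapse = ", "))
  }
  class(tab) <- c("ortholog_table", class(tab))
  tab
}

#' Write a result table as TSV
#'
#' Deterministic writer used by every stage: UTF-8, header always present
#' (also for empty tables), column order as given, reals carried at full
#' precision so a re-read reproduces values.
#'
#' @param records A data frame (possibly empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- dplyr::mutate(tibble::as_tibble(records),
                           dplyr::across(dplyr::where(is.factor),
                                         as.character))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' A flat key-value record collecting every tunable threshold of the
#' pipeline, with the defaults used throughout the package. Values supplied
#' in `...` override defaults; unknown keys are kept (modules may define
#' their own).
#'
#' @param ... Named overrides.
#' @param seed Integer seed used by any stage that draws random numbers.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    scale_factor = 1e4,
    n_hvg = 2000L,
    n_pcs = 30L,
    scale_clip = 10,
    min_fold = 1.28,
    max_p = 0.01,
    min_pct_diff = 0.10,
    min_pct = 0.10,
    lfc_floor = 0.25,
    conserved_min = 6L,
    species_specific_max = 1L,
    clade_min_fraction = 0.75,
    k_neighbors = 30L,
    n_dcs_kept = 10L,
    distance_dcs = 2L,
    bias_quantile = 0.25,
    n_perm = 1000L,
    alpha = 0.05,
    indicator_pka = 8.0
  )
  over <- list(...)
  defaults[names(over)] <- over
  quantiles <- c("bias_quantile", "min_pct", "min_pct_diff", "max_p",
                 "alpha", "clade_min_fraction")
  for (q in quantiles) {
    v <- defaults[[q]]
    if (!is.null(v) && (v <= 0 || v >= 1)) {
      stop(q, " must lie in (0, 1)", call. = FALSE)
    }
  }
  positive <- c("scale_factor", "n_hvg", "n_pcs", "min_fold", "lfc_floor",
                "conserved_min", "k_neighbors", "n_perm")
  for (p in positive) {
    v <- defaults[[p]]
    if (!is.null(v) && v <= 0) stop(p, " must be positive", call. = FALSE)
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of flat key-value pairs.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
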