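#' Anchor-gene correlation within a cluster
#'
#' Scores within-cell-type spatial heterogeneity by correlating every gene's
#' log-normalized expression with an anchor gene across the cells of one
#' cluster. Significance comes from a permutation null (the anchor values
#' are permuted `n_perm` times; the p value uses the add-one correction
#' `(1 + #{|r_perm| >= |r|}) / (n_perm + 1)`), avoiding a parametric null
#' under dropout. Cells with zero anchor counts are retained by default,
#' since dropout itself carries positional information.
#'
#' @param ds An [expression_dataset()]; [log_normalize()] is applied if
#'   needed.
#' @param cluster Cluster label (at least 5 cells).
#' @param anchor Anchor gene id; must be expressed (count > 0) in at least
#'   5 cells of the cluster.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Number of permutations.
#' @param alpha Significance gate for the `call` column.
#' @param seed Integer seed for the permutations.
#' @param anchor_positive_only If `TRUE`, restrict to cells with nonzero
#'   anchor counts.
#' @return A `regionalization_result` tibble: gene, r, p, n_cells, call
#'   (`correlated`, `anti_correlated`, or `none`).
#' @export
anchor_correlation <- function(ds, cluster, anchor,
                               method = c("pearson", "spearman"),
                               n_perm = 1000L, alpha = 0.05, seed = 1L,
                               anchor_positive_only = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  if (!anchor %in% ds$gene_ids) {
    stop("anchor gene not found: ", anchor, call. = FALSE)
  }
  if (is.null(ds$norm)) ds <- log_normalize(ds)
  cells <- cluster_cells(ds, cluster)
  if (length(cells) < 5) stop("cluster has fewer than 5 cells",
                              call. = FALSE)
  if (sum(ds$counts[cells, anchor] > 0) < 5) {
    stop("anchor expressed in fewer than 5 cells of the cluster",
         call. = FALSE)
  }
  if (anchor_positive_only) {
    cells <- cells[ds$counts[cells, anchor] > 0]
  }
  x <- as.matrix(ds$norm[cells, , drop = FALSE])
  a <- x[, anchor]
  if (method == "spearman") {
    x <- apply(x, 2, rank)
    a <- rank(a)
  }
  r <- suppressWarnings(as.vector(stats::cor(x, a)))
  r[is.na(r)] <- 0

  perms <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) sample(a), numeric(length(a)))
  })
  r_perm <- suppressWarnings(stats::cor(x, perms))   # genes x n_perm
  r_perm[is.na(r_perm)] <- 0
  exceed <- unname(rowSums(abs(r_perm) >= abs(r) - 1e-12))
  p <- (1 + exceed) / (n_perm + 1)

  out <- tibble::tibble(
    gene = ds$gene_ids, r = r, p = p, n_cells = length(cells),
    call = dplyr::case_when(p < alpha & r > 0 ~ "correlated",
                            p < alpha & r < 0 ~ "anti_correlated",
                            TRUE ~ "none"))
  class(out) <- c("regionalization_result", class(out))
  out
}

#' Regional contrast between two datasets
#'
#' Marker-style differential expression of one cluster between two regions
#' (e.g. colonic versus small-intestinal cells of the same type): the
#' cluster's cells from dataset A are tested against those from dataset B in
#' both directions, gated by the fold and significance rules (the
#' expressing-fraction gap is applied on the absolute gap).
#'
#' @param ds_a,ds_b [expression_dataset()]s for the two regions.
#' @param cluster Cluster label present in both.
#' @param thresholds A [marker_thresholds()].
#' @return A `marker_table`; `direction` `"up"` means higher in `ds_a`.
#' @export
regional_contrast <- function(ds_a, ds_b, cluster,
                              thresholds = marker_thresholds()) {
  stopifnot(inherits(ds_a, "expression_dataset"),
            inherits(ds_b, "expression_dataset"))
  cells_a <- cluster_cells(ds_a, cluster)
  cells_b <- cluster_cells(ds_b, cluster)
  if (length(cells_a) < 3 || length(cells_b) < 3) {
    stop("cluster has fewer than 3 cells in one region", call. = FALSE)
  }
  a <- subset_cells(ds_a, cells_a)
  b <- subset_cells(ds_b, cells_b)
  b$cell_meta$cell_id <- paste0("b:", b$cell_meta$cell_id)
  rownames(b$counts) <- b$cell_meta$cell_id
  b <- expression_dataset(b$counts, b$cell_meta)
  combined <- log_normalize(bind_datasets(a, b))
  stats <- marker_stats(combined, a$cell_ids, b$cell_ids,
                        thresholds$min_pct)
  finish_marker_table(stats, cluster, thresholds, both_directions = TRUE,
                      use_pct_diff = TRUE)
}

#' Join a regional contrast with anchor-correlation calls across species
#'
#' Resolves the genes of a two-region contrast (one species) and of an
#' anchor-correlation scan (another species) to ortholog families and joins
#' them: one row per family carrying the contrast direction and the
#' regionalization call, with `NA` where a family is present on one side
#' only. Under the convention that region A is the anchor-high region, a
#' family up in A and positively correlated with the anchor is `concordant`.
#'
#' @param contrast A `marker_table` from [regional_contrast()].
#' @param regional A `regionalization_result` from [anchor_correlation()].
#' @param orth An [ortholog_table()].
#' @param contrast_species,regional_species Species names (as in `orth`) of
#'   the two inputs.
#' @return A tibble: family, contrast_direction, regional_call, concordance.
#' @export
join_regional_programs <- function(contrast, regional, orth,
                                   contrast_species, regional_species) {
  to_family <- function(genes, species) {
    sub <- orth[orth$species == species, c("gene_id", "family")]
    hit <- genes %in% sub$gene_id
    if (any(!hit)) {
      warning(sum(!hit), " gene(s) of species '", species,
              "' without an ortholog family dropped", call. = FALSE)
    }
    sub[sub$gene_id %in% genes, ]
  }
  ctr <- to_family(contrast$gene, contrast_species) |>
    dplyr::left_join(contrast[, c("gene", "direction")],
                     by = c(gene_id = "gene")) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(contrast_direction =
                       if (length(unique(.data$direction)) == 1)
                         .data$direction[1] else "mixed")
  called <- dplyr::filter(regional, .data$call != "none")
  reg <- to_family(called$gene, regional_species) |>
    dplyr::left_join(called[, c("gene", "call")],
                     by = c(gene_id = "gene")) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(regional_call =
                       if (length(unique(.data$call)) == 1)
                         .data$call[1] else "mixed")
  dplyr::full_join(ctr, reg, by = "family") |>
    dplyr::mutate(concordance = dplyr::case_when(
      is.na(.data$contrast_direction) | is.na(.data$regional_call) ~
        NA_character_,
      .data$contrast_direction == "up" &
        .data$regional_call == "correlated" ~ "concordant",
      .data$contrast_direction == "down" &
        .data$regional_call == "anti_correlated" ~ "concordant",
      .data$contrast_direction == "mixed" |
        .data$regional_call == "mixed" ~ "ambiguous",
      TRUE ~ "discordant")) |>
    dplyr::arrange(.data$family)
}
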