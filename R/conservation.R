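#' Conservation-classification configuration
#'
#' Rules for turning per-dataset marker flags on ortholog families into
#' conservation classes: families flagged in at least `conserved_min` of
#' `n_datasets` are `conserved`; otherwise a family concentrated in one
#' clade (flagged fraction within the clade at least `clade_min_fraction`,
#' with at most `species_specific_max` flags outside it) is
#' `clade_conserved:<clade>`; a family flagged in exactly one dataset is
#' `species_specific`; anything else is `shared_partial`.
#'
#' @param conserved_min Minimum flagged datasets for `conserved`.
#' @param n_datasets Number of datasets considered.
#' @param species_specific_max Maximum out-of-clade flags tolerated by the
#'   clade rule (and the flag count defining `species_specific`).
#' @param clade_labels Named character vector mapping dataset id to clade;
#'   `NULL` disables clade classing.
#' @param clade_min_fraction Minimum flagged fraction within a clade.
#' @return A list of class `conservation_config`.
#' @export
conservation_config <- function(conserved_min = 6L, n_datasets = 8L,
                                species_specific_max = 1L,
                                clade_labels = NULL,
                                clade_min_fraction = 0.75) {
  if (!(1 <= species_specific_max && species_specific_max < conserved_min &&
          conserved_min <= n_datasets)) {
    stop("need 1 <= species_specific_max < conserved_min <= n_datasets",
         call. = FALSE)
  }
  structure(list(conserved_min = as.integer(conserved_min),
                 n_datasets = as.integer(n_datasets),
                 species_specific_max = as.integer(species_specific_max),
                 clade_labels = clade_labels,
                 clade_min_fraction = clade_min_fraction),
            class = "conservation_config")
}

#' Map per-dataset marker gene lists onto ortholog families
#'
#' A family is flagged for a dataset if any gene of that dataset's species
#' mapping to the family (including paralogs) appears in the dataset's
#' marker list. Marker genes with no family in the ortholog table are
#' dropped and counted in a warning.
#'
#' @param markers Named list (by dataset id) of marker gene-id vectors.
#' @param orth An [ortholog_table()].
#' @param species Named character vector mapping each dataset id to its
#'   species (must all be present in `orth`).
#' @return Logical family-by-dataset matrix over every family of the
#'   involved species.
#' @export
map_to_families <- function(markers, orth, species) {
  stopifnot(is.list(markers), !is.null(names(markers)))
  missing_sp <- setdiff(unname(species[names(markers)]), orth$species)
  if (length(missing_sp)) {
    stop("species absent from ortholog table: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  families <- sort(unique(orth$family[orth$species %in% species]))
  flags <- matrix(FALSE, length(families), length(markers),
                  dimnames = list(families, names(markers)))
  dropped <- 0L
  for (d in names(markers)) {
    sub <- orth[orth$species == species[[d]], ]
    genes <- markers[[d]]
    dropped <- dropped + sum(!genes %in% sub$gene_id)
    fams <- unique(sub$family[sub$gene_id %in% genes])
    flags[fams, d] <- TRUE
  }
  if (dropped > 0) {
    warning(dropped, " marker gene(s) without an ortholog family dropped",
            call. = FALSE)
  }
  flags
}

#' Classify conservation of ortholog families
#'
#' Applies the [conservation_config()] rules to a logical family-by-dataset
#' flag matrix. Invariant to dataset column order; `n_marked` is monotone
#' under adding flagged datasets.
#'
#' @param flags Logical family-by-dataset matrix (e.g. from
#'   [map_to_families()]); column count must equal `cfg$n_datasets`.
#' @param cfg A [conservation_config()].
#' @return A tibble with columns `family`, `n_marked`, `class`, and one
#'   logical column per dataset.
#' @export
classify_conservation <- function(flags, cfg = conservation_config()) {
  stopifnot(is.matrix(flags), is.logical(flags))
  if (ncol(flags) != cfg$n_datasets) {
    stop("flags has ", ncol(flags), " dataset columns but config expects ",
         cfg$n_datasets, call. = FALSE)
  }
  clades <- cfg$clade_labels
  if (!is.null(clades)) {
    unlabeled <- setdiff(colnames(flags), names(clades))
    if (length(unlabeled)) {
      stop("dataset(s) missing a clade label: ",
           paste(unlabeled, collapse = ", "), call. = FALSE)
    }
  }
  n_marked <- rowSums(flags)
  class <- character(nrow(flags))
  for (i in seq_len(nrow(flags))) {
    class[i] <- if (n_marked[i] >= cfg$conserved_min) "conserved"
    else {
      clade_hit <- NA_character_
      if (!is.null(clades)) {
        for (cl in unique(clades)) {
          inside <- colnames(flags)[clades[colnames(flags)] == cl]
          outside <- setdiff(colnames(flags), inside)
          if (sum(flags[i, inside]) / length(inside) >=
                cfg$clade_min_fraction &&
              sum(flags[i, outside]) <= cfg$species_specific_max) {
            clade_hit <- cl
            break
          }
        }
      }
      if (!is.na(clade_hit)) paste0("clade_conserved:", clade_hit)
      else if (n_marked[i] == 1) "species_specific"
      else "shared_partial"
    }
  }
  out <- tibble::tibble(family = rownames(flags),
                        n_marked = as.integer(n_marked), class = class)
  dplyr::bind_cols(out, tibble::as_tibble(flags))
}

#' Cell-type specificity index
#'
#' The percentage of a gene's expression attributable to the target cluster:
#' 100 times the per-cluster arithmetic mean of de-logged normalized
#' expression (`expm1(norm)`) in the target cluster, divided by the sum of
#' those means over all clusters. Sums to 100 over clusters whenever the
#' denominator is nonzero; `NA` otherwise.
#'
#' @param ds An [expression_dataset()] with `norm` present.
#' @param gene Gene id.
#' @param target_cluster Cluster label.
#' @return Percentage in \[0, 100\], or `NA` when the gene is unexpressed.
#' @export
specificity_index <- function(ds, gene, target_cluster) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$norm)) stop("norm layer required", call. = FALSE)
  clusters <- unique(ds$cell_meta$cluster)
  if (!target_cluster %in% clusters) {
    stop("cluster not found: ", target_cluster, call. = FALSE)
  }
  v <- expm1(ds$norm[, gene])
  means <- vapply(clusters, function(cl) {
    mean(v[ds$cell_meta$cluster == cl])
  }, numeric(1))
  denom <- sum(means)
  if (denom == 0) return(NA_real_)
  100 * means[[target_cluster]] / denom
}

cluster_mean_expr <- function(ds, genes) {
  clusters <- sort(unique(ds$cell_meta$cluster))
  v <- expm1(as.matrix(ds$norm[, genes, drop = FALSE]))
  t(vapply(clusters, function(cl) {
    colMeans(v[ds$cell_meta$cluster == cl, , drop = FALSE])
  }, numeric(length(genes))))  # clusters x genes
}

#' Build the cross-species conservation program table
#'
#' Runs [find_markers()] on the target cluster of every dataset, maps marker
#' lists onto ortholog families, classifies conservation, and attaches the
#' per-dataset specificity index and mean expression of each family's
#' best-expressed member gene. Families with no annotated gene in a species
#' carry `NA` there (an unannotated gene, distinct from a non-marker).
#' Rows are ordered deterministically by (class, family).
#'
#' @param datasets Named list (by dataset id) of [expression_dataset()]s.
#' @param orth An [ortholog_table()].
#' @param cfg A [conservation_config()].
#' @param thresholds A [marker_thresholds()].
#' @param target_cluster Cluster carrying the program (default `"best4"`).
#' @return A list of class `conservation_result` with elements `records`
#'   (tibble: family, n_marked, class, flags), `specificity` and `mean_expr`
#'   (family-by-dataset tibbles, `NA` where unannotated), and `markers`
#'   (the per-dataset marker tables).
#' @export
build_program_table <- function(datasets, orth,
                                cfg = conservation_config(),
                                thresholds = marker_thresholds(),
                                target_cluster = "best4") {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  species <- vapply(datasets, function(d) d$cell_meta$species[1],
                    character(1))
  marker_tabs <- lapply(datasets, find_markers, cluster = target_cluster,
                        thresholds = thresholds)
  marker_genes <- lapply(marker_tabs, function(m) m$gene)
  flags <- map_to_families(marker_genes, orth, species)
  records <- classify_conservation(flags, cfg) |>
    dplyr::filter(.data$n_marked >= 1L) |>   # only families some list flagged
    dplyr::arrange(.data$class, .data$family)

  fam_order <- records$family
  spec_mat <- matrix(NA_real_, length(fam_order), length(datasets),
                     dimnames = list(fam_order, names(datasets)))
  expr_mat <- spec_mat
  for (d in names(datasets)) {
    ds <- datasets[[d]]
    if (is.null(ds$norm)) ds <- log_normalize(ds)
    sub <- orth[orth$species == species[[d]] & orth$family %in% fam_order &
                  orth$gene_id %in% ds$gene_ids, ]
    if (!nrow(sub)) next
    cm <- cluster_mean_expr(ds, unique(sub$gene_id))
    target_mean <- cm[target_cluster, ]
    total_mean <- colSums(cm)
    spec_gene <- ifelse(total_mean > 0, 100 * target_mean / total_mean,
                        NA_real_)
    # per family, report the member gene with the highest target-cluster mean
    by_fam <- split(sub$gene_id, sub$family)
    for (fam in names(by_fam)) {
      g <- by_fam[[fam]]
      best <- g[which.max(target_mean[g])]
      spec_mat[fam, d] <- spec_gene[best]
      expr_mat[fam, d] <- target_mean[best]
    }
  }
  structure(list(
    records = records,
    specificity = dplyr::bind_cols(tibble::tibble(family = fam_order),
                                   tibble::as_tibble(spec_mat)),
    mean_expr = dplyr::bind_cols(tibble::tibble(family = fam_order),
                                 tibble::as_tibble(expr_mat)),
    markers = marker_tabs),
    class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  tab <- table(x$records$class)
  cat("<conservation_result> ", nrow(x$records), " families across ",
      ncol(x$specificity) - 1, " datasets\n  ", sep = "")
  cat(paste0(names(tab), ": ", as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
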