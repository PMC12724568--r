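#' Marker-test thresholds
#'
#' The filter set applied to marker tables: minimum fold change (the 1.28-fold
#' floor equals `exp(0.25)` natural-log units), a raw-p significance gate,
#' and expressing-fraction rules. Fold-change and percent-gap bounds are
#' inclusive ("at least"); the p gate is strict. The p threshold is applied
#' to the raw p value; Bonferroni-adjusted values are still reported, and
#' `p_adjust = "bonferroni"` or `"bh"` switches the gate onto adjusted p.
#'
#' @param min_fold Minimum fold change (> 1); must agree with `lfc_floor`
#'   within 0.01 on the exponentiated scale.
#' @param max_p Significance gate (strict `<`).
#' @param min_pct_diff Minimum `pct_in - pct_out` gap for one-vs-rest marker
#'   calls (not applied by [contrast_by_cluster()]).
#' @param min_pct A gene is tested only if expressed in at least this
#'   fraction of either group.
#' @param lfc_floor Natural-log fold-change floor (inclusive).
#' @param p_adjust `"none"` (gate raw p; default), `"bonferroni"`, or
#'   `"bh"` to gate on the adjusted p instead.
#' @return A list of class `marker_thresholds`.
#' @export
marker_thresholds <- function(min_fold = 1.28, max_p = 0.01,
                              min_pct_diff = 0.10, min_pct = 0.10,
                              lfc_floor = 0.25,
                              p_adjust = c("none", "bonferroni", "bh")) {
  p_adjust <- match.arg(p_adjust)
  if (min_fold <= 1) stop("min_fold must exceed 1", call. = FALSE)
  if (max_p <= 0 || max_p >= 1) stop("max_p must lie in (0,1)", call. = FALSE)
  if (abs(exp(lfc_floor) - min_fold) > 0.01) {
    stop("exp(lfc_floor) must match min_fold within 0.01", call. = FALSE)
  }
  structure(list(min_fold = min_fold, max_p = max_p,
                 min_pct_diff = min_pct_diff, min_pct = min_pct,
                 lfc_floor = lfc_floor, p_adjust = p_adjust),
            class = "marker_thresholds")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney test with tie correction: exact enumeration when the pooled
#' sample size is at most 10 and there are no ties, normal approximation
#' with continuity correction otherwise. Degenerate inputs with no rank
#' information (all values tied) return p = 1.
#'
#' @param x,y Numeric vectors for the two groups (non-empty).
#' @return Two-sided p value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(pooled) <= 10
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  min(1, p)
}

#' Log fold change on de-logged normalized means
#'
#' `lfc = ln((mean_in + 1) / (mean_out + 1))`, where each mean is the group
#' average of `expm1(norm)` for the gene. The +1 pseudocount keeps the value
#' finite when a group mean is zero; natural log fixes the base so that the
#' 0.25 threshold corresponds to the 1.28-fold floor (`exp(0.25) = 1.284`).
#'
#' @param ds An [expression_dataset()] with `norm` present.
#' @param group_in,group_out Character vectors of cell ids (non-empty).
#' @param gene Gene id.
#' @return Natural-log fold change (positive when up in `group_in`).
#' @export
log_fold_change <- function(ds, group_in, group_out, gene) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$norm)) stop("norm layer required", call. = FALSE)
  if (!length(group_in) || !length(group_out)) {
    stop("empty group", call. = FALSE)
  }
  v <- expm1(ds$norm[, gene])
  log((mean(v[group_in]) + 1) / (mean(v[group_out]) + 1))
}

#' Fraction of cells expressing a gene
#'
#' @param ds An [expression_dataset()].
#' @param cells Character vector of cell ids (non-empty).
#' @param gene Gene id.
#' @return Fraction of the cells with a nonzero count.
#' @export
pct_expressing <- function(ds, cells, gene) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!length(cells)) stop("empty cell set", call. = FALSE)
  mean(ds$counts[cells, gene] > 0)
}

#' Marker AUC
#'
#' Probability that a random value from group A exceeds a random value from
#' group B, counting ties as half: `U / (nA * nB)` from midranks. Satisfies
#' `auc_marker(a, b) + auc_marker(b, a) == 1` exactly.
#'
#' @param x,y Numeric vectors for groups A and B (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc_marker <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

# Vectorized two-group marker statistics over all genes of a dataset.
marker_stats <- function(ds, cells_in, cells_out, min_pct, with_auc = TRUE) {
  norm_in <- ds$norm[cells_in, , drop = FALSE]
  norm_out <- ds$norm[cells_out, , drop = FALSE]
  pct_in <- Matrix::colMeans(ds$counts[cells_in, , drop = FALSE] > 0)
  pct_out <- Matrix::colMeans(ds$counts[cells_out, , drop = FALSE] > 0)
  testable <- pmax(pct_in, pct_out) >= min_pct
  mean_in <- Matrix::colMeans(expm1(norm_in))
  mean_out <- Matrix::colMeans(expm1(norm_out))
  lfc <- log((mean_in + 1) / (mean_out + 1))
  idx <- which(testable)
  p <- rep(NA_real_, length(lfc))
  auc <- rep(NA_real_, length(lfc))
  for (j in idx) {
    xj <- norm_in[, j]
    yj <- norm_out[, j]
    p[j] <- rank_sum_test(xj, yj)
    if (with_auc) auc[j] <- auc_marker(xj, yj)
  }
  tibble::tibble(gene = ds$gene_ids, lfc = lfc, p = p,
                 pct_in = pct_in, pct_out = pct_out, auc = auc,
                 tested = testable)
}

finish_marker_table <- function(stats, cluster, thresholds, both_directions,
                                use_pct_diff) {
  tested <- dplyr::filter(stats, .data$tested)
  n_tested <- nrow(tested)
  tested$p_adj <- switch(thresholds$p_adjust,
                         bh = stats::p.adjust(tested$p, "BH"),
                         pmin(1, tested$p * n_tested))
  p_gate <- if (thresholds$p_adjust == "none") tested$p else tested$p_adj
  eps <- 1e-9   # inclusive bounds survive float error (0.6 - 0.5 < 0.1)
  keep <- p_gate < thresholds$max_p
  keep <- keep & if (both_directions)
    abs(tested$lfc) >= thresholds$lfc_floor - eps
  else tested$lfc >= thresholds$lfc_floor - eps
  if (use_pct_diff) {
    gap <- if (both_directions) abs(tested$pct_in - tested$pct_out)
           else tested$pct_in - tested$pct_out
    keep <- keep & gap >= thresholds$min_pct_diff - eps
  }
  out <- tested[keep, ] |>
    dplyr::mutate(cluster = cluster,
                  direction = ifelse(.data$lfc >= 0, "up", "down")) |>
    dplyr::arrange(.data$p, dplyr::desc(.data$lfc), .data$gene) |>
    dplyr::select(dplyr::all_of(c("gene", "cluster", "lfc", "p", "p_adj",
                                  "pct_in", "pct_out", "auc", "direction")))
  class(out) <- c("marker_table", class(out))
  out
}

#' One-vs-rest cluster markers
#'
#' Tests every gene of a cluster against all remaining cells with the
#' Wilcoxon rank-sum test on log-normalized values, and retains genes
#' passing the [marker_thresholds()] filters: fold change at least
#' `lfc_floor` (up-regulated), raw p below `max_p`, and expressing-fraction
#' gap at least `min_pct_diff`. Genes are tested only when expressed in at
#' least `min_pct` of either group. Output is ordered by (p, -lfc, gene) for
#' determinism and is invariant to cell and gene ordering.
#'
#' @param ds An [expression_dataset()] with `norm` (run [log_normalize()]
#'   first, or it is applied automatically).
#' @param cluster Cluster label to mark.
#' @param thresholds A [marker_thresholds()].
#' @return A `marker_table` tibble: gene, cluster, lfc, p, p_adj, pct_in,
#'   pct_out, auc, direction.
#' @export
find_markers <- function(ds, cluster, thresholds = marker_thresholds()) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$norm)) ds <- log_normalize(ds)
  cells_in <- cluster_cells(ds, cluster)
  cells_out <- setdiff(ds$cell_ids, cells_in)
  if (length(cells_in) < 3 || length(cells_out) < 3) {
    stop("need at least 3 cells in the cluster and its complement",
         call. = FALSE)
  }
  stats <- marker_stats(ds, cells_in, cells_out, thresholds$min_pct)
  finish_marker_table(stats, cluster, thresholds, both_directions = FALSE,
                      use_pct_diff = TRUE)
}

#' Wild-type versus mutant contrast within a cluster
#'
#' Restricts both genotypes to one cluster and tests WT against MUT, keeping
#' genes in both directions that pass the fold and significance gates; the
#' expressing-fraction gap rule is not applied in contrast mode (only the
#' `min_pct` testability rule and the fold floor).
#'
#' @param ds_wt,ds_mut [expression_dataset()]s for the two genotypes (may be
#'   the same object if it carries both genotypes in `cell_meta$genotype`).
#' @param cluster Cluster label present in both genotypes.
#' @param thresholds A [marker_thresholds()].
#' @return A `marker_table` with `direction` `"up"` for WT-high genes.
#' @export
contrast_by_cluster <- function(ds_wt, ds_mut, cluster,
                                thresholds = marker_thresholds()) {
  stopifnot(inherits(ds_wt, "expression_dataset"),
            inherits(ds_mut, "expression_dataset"))
  combined <- if (identical(ds_wt, ds_mut)) ds_wt else
    bind_datasets(ds_wt, ds_mut)
  if (is.null(combined$norm)) combined <- log_normalize(combined)
  meta <- combined$cell_meta
  wt <- meta$cell_id[!is.na(meta$genotype) & meta$genotype == "WT" &
                       meta$cluster == cluster]
  mut <- meta$cell_id[!is.na(meta$genotype) & meta$genotype == "MUT" &
                        meta$cluster == cluster]
  if (length(wt) < 3) stop("cluster '", cluster, "' has fewer than 3 cells ",
                           "in genotype WT", call. = FALSE)
  if (length(mut) < 3) stop("cluster '", cluster, "' has fewer than 3 cells ",
                            "in genotype MUT", call. = FALSE)
  stats <- marker_stats(combined, wt, mut, thresholds$min_pct)
  finish_marker_table(stats, cluster, thresholds, both_directions = TRUE,
                      use_pct_diff = FALSE)
}

#' Combine two expression datasets over the shared gene set
#'
#' @param a,b [expression_dataset()]s with identical gene universes (genes
#'   are intersected; an error is raised if the overlap is empty).
#' @return A combined `expression_dataset` (norm layers dropped; re-run
#'   [log_normalize()]).
#' @export
bind_datasets <- function(a, b) {
  genes <- intersect(a$gene_ids, b$gene_ids)
  if (!length(genes)) stop("datasets share no genes", call. = FALSE)
  if (length(intersect(a$cell_ids, b$cell_ids))) {
    stop("datasets share cell ids; make them unique first", call. = FALSE)
  }
  counts <- rbind(a$counts[, genes, drop = FALSE],
                  b$counts[, genes, drop = FALSE])
  meta <- dplyr::bind_rows(a$cell_meta, b$cell_meta)
  expression_dataset(counts, meta)
}
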