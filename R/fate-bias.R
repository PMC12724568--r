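#' Diffusion-map configuration
#'
#' Parameters of the diffusion-map embedding and fate-bias selection: a
#' k-nearest-neighbor graph in PC space (k = 30), a locally scaled Gaussian
#' kernel, ten diffusion components retained, distances measured in the
#' first two, and the top 25% of progenitors closest to the reference
#' centroid selected as biased.
#'
#' @param k_neighbors Neighbors per cell in the kNN graph.
#' @param n_input_pcs PCs used to build the graph.
#' @param n_dcs_kept Diffusion components returned (trivial component
#'   excluded).
#' @param distance_dcs Leading DCs used for centroid distances.
#' @param bias_quantile Fraction of each group selected as biased.
#' @param local_sigma_rank Neighbor rank defining each cell's local kernel
#'   scale (default `ceiling(k_neighbors / 2)`).
#' @param scale_by_eigenvalue If `TRUE`, scale each DC by its eigenvalue
#'   before distances are computed (off by default; distances are taken on
#'   raw eigenvector coordinates).
#' @return A list of class `diffusion_config`.
#' @export
diffusion_config <- function(k_neighbors = 30L, n_input_pcs = 30L,
                             n_dcs_kept = 10L, distance_dcs = 2L,
                             bias_quantile = 0.25,
                             local_sigma_rank = NULL,
                             scale_by_eigenvalue = FALSE) {
  local_sigma_rank <- local_sigma_rank %||% ceiling(k_neighbors / 2)
  if (distance_dcs > n_dcs_kept) {
    stop("distance_dcs must not exceed n_dcs_kept", call. = FALSE)
  }
  if (bias_quantile <= 0 || bias_quantile >= 1) {
    stop("bias_quantile must lie in (0, 1)", call. = FALSE)
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_input_pcs = as.integer(n_input_pcs),
                 n_dcs_kept = as.integer(n_dcs_kept),
                 distance_dcs = as.integer(distance_dcs),
                 bias_quantile = bias_quantile,
                 local_sigma_rank = as.integer(local_sigma_rank),
                 scale_by_eigenvalue = scale_by_eigenvalue),
            class = "diffusion_config")
}

#' Diffusion-map embedding
#'
#' Builds a symmetric kNN graph (union of directed kNN edges) in PC space,
#' weights edges with a locally scaled Gaussian kernel
#' `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` where `sigma_i` is the
#' distance to the cell's `local_sigma_rank`-th neighbor, density-normalizes
#' the kernel (divides by the product of row sums, the alpha = 1 anisotropic
#' construction), row-normalizes to a Markov matrix, and returns its right
#' eigenvectors 2..(n_dcs_kept + 1) ordered by decreasing eigenvalue. The
#' trivial constant eigenvector (eigenvalue 1) is excluded; signs are made
#' deterministic (largest-magnitude entry positive). The eigenproblem is
#' solved exactly via the symmetric conjugation of the Markov matrix.
#'
#' @param pcs Numeric matrix of cell coordinates (cells x PCs, rownames are
#'   cell ids), e.g. `embedding_result$pcs`; columns beyond `n_input_pcs`
#'   are ignored.
#' @param cfg A [diffusion_config()].
#' @return An object of class `diffusion_result`: list with `dcs` (cells x
#'   n_dcs_kept, columns `DC1..`), `eigenvalues` (decreasing, all < 1),
#'   `cell_ids`, `distances` (`NULL` until [centroid_distance()]), `biased`
#'   (`NULL` until [select_biased()]).
#' @export
diffusion_map <- function(pcs, cfg = diffusion_config()) {
  stopifnot(is.matrix(pcs), all(is.finite(pcs)))
  n <- nrow(pcs)
  if (n < cfg$k_neighbors + 1) {
    stop("need at least k_neighbors + 1 cells", call. = FALSE)
  }
  x <- pcs[, seq_len(min(ncol(pcs), cfg$n_input_pcs)), drop = FALSE]
  cell_ids <- rownames(pcs) %||% as.character(seq_len(n))

  d <- as.matrix(stats::dist(x))
  nn_rank <- apply(d, 1, function(row) rank(row, ties.method = "first"))
  nn_rank <- t(nn_rank)                     # rank 1 is the cell itself
  is_knn <- nn_rank >= 2 & nn_rank <= cfg$k_neighbors + 1
  adj <- is_knn | t(is_knn)                 # union of directed kNN edges
  sigma <- vapply(seq_len(n), function(i) {
    sort(d[i, -i])[cfg$local_sigma_rank]
  }, numeric(1))

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (comp$no > 1) {
    stop("kNN graph is disconnected; component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
         call. = FALSE)
  }

  w <- exp(-d^2 / outer(sigma, sigma))
  w[!adj] <- 0
  diag(w) <- 0
  q <- rowSums(w)
  w <- w / outer(q, q)                      # density normalization, alpha=1
  deg <- rowSums(w)
  # Right eigenvectors of P = D^-1 W via the symmetric S = D^-1/2 W D^-1/2
  s <- w / outer(sqrt(deg), sqrt(deg))
  es <- eigen(s, symmetric = TRUE)
  vec <- es$vectors / sqrt(deg)             # right eigenvectors of P
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), `/`)
  keep <- 1 + seq_len(cfg$n_dcs_kept)
  dcs <- vec[, keep, drop = FALSE]
  for (j in seq_len(ncol(dcs))) {
    if (dcs[which.max(abs(dcs[, j])), j] < 0) dcs[, j] <- -dcs[, j]
  }
  dimnames(dcs) <- list(cell_ids, paste0("DC", seq_len(ncol(dcs))))
  structure(list(dcs = dcs, eigenvalues = es$values[keep],
                 cell_ids = cell_ids, distances = NULL, biased = NULL,
                 config = cfg),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result> ", nrow(x$dcs), " cells x ", ncol(x$dcs),
      " DCs; eigenvalues ", sprintf("%.3f", x$eigenvalues[1]), " .. ",
      sprintf("%.3f", x$eigenvalues[length(x$eigenvalues)]), "\n", sep = "")
  invisible(x)
}

#' Euclidean distance to a reference-cluster centroid in DC space
#'
#' The centroid is the mean of the reference cells' first `distance_dcs`
#' diffusion components (DC1-DC2 by default); each query cell's distance is
#' the Euclidean norm of its offset from that centroid in the same
#' subspace. Invariant to global sign flips of any DC.
#'
#' @param dm A [diffusion_map()] result.
#' @param reference_cells Non-empty character vector of cell ids defining
#'   the centroid (e.g. the wild-type best4 cluster).
#' @param query_cells Cell ids to measure (default: all cells).
#' @param cfg A [diffusion_config()] (for `distance_dcs` and eigenvalue
#'   scaling); defaults to the one stored in `dm`.
#' @return The `diffusion_result` with `distances` filled (named numeric,
#'   over the query cells).
#' @export
centroid_distance <- function(dm, reference_cells, query_cells = NULL,
                              cfg = NULL) {
  stopifnot(inherits(dm, "diffusion_result"))
  cfg <- cfg %||% dm$config
  if (!length(reference_cells)) stop("empty reference set", call. = FALSE)
  missing <- setdiff(reference_cells, dm$cell_ids)
  if (length(missing)) stop("reference cell(s) not in embedding",
                            call. = FALSE)
  query_cells <- query_cells %||% dm$cell_ids
  dcs <- dm$dcs[, seq_len(cfg$distance_dcs), drop = FALSE]
  if (cfg$scale_by_eigenvalue) {
    dcs <- sweep(dcs, 2, dm$eigenvalues[seq_len(cfg$distance_dcs)], `*`)
  }
  centroid <- colMeans(dcs[reference_cells, , drop = FALSE])
  offs <- sweep(dcs[query_cells, , drop = FALSE], 2, centroid, `-`)
  dm$distances <- stats::setNames(sqrt(rowSums(offs^2)), query_cells)
  dm
}

#' Select the fate-biased top quantile of a group
#'
#' Returns the `ceiling(q * n)` cells of the group with the smallest
#' centroid distances; boundary ties are broken by cell id so the selection
#' is deterministic. `q = 1` returns the whole group, and selections are
#' nested in `q`.
#'
#' @param distances Named numeric vector of distances (e.g.
#'   `centroid_distance(...)$distances`).
#' @param group Non-empty character vector of cell ids, a subset of
#'   `names(distances)`.
#' @param q Selection quantile in (0, 1\].
#' @return Character vector of selected cell ids (sorted by distance then
#'   id).
#' @export
select_biased <- function(distances, group, q = 0.25) {
  if (!length(group)) stop("empty group", call. = FALSE)
  missing <- setdiff(group, names(distances))
  if (length(missing)) stop("group cell(s) without a distance",
                            call. = FALSE)
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]", call. = FALSE)
  d <- distances[group]
  ord <- order(d, names(d))
  names(d)[ord][seq_len(ceiling(q * length(group)))]
}

#' Differential expression around the fate-bias selection
#'
#' Emits the three contrasts of the fate-bias design on arbitrary cell sets
#' of one joint dataset: biased wild-type progenitors vs biased mutant
#' progenitors, and each selection vs the reference (e.g. wild-type best4)
#' cells. Gating follows contrast mode (fold floor and `min_pct`; no
#' expressing-fraction gap rule), both directions reported.
#'
#' @param ds The joint [expression_dataset()].
#' @param sel_wt,sel_mut,ref_cells Cell-id sets, each of size at least 3.
#' @param thresholds A [marker_thresholds()].
#' @return A `marker_table` tibble with an extra `contrast` column
#'   (`"wt_vs_mut"`, `"wt_vs_ref"`, `"mut_vs_ref"`); `direction` `"up"`
#'   means higher in the first-named set.
#' @export
bias_contrast <- function(ds, sel_wt, sel_mut, ref_cells,
                          thresholds = marker_thresholds()) {
  stopifnot(inherits(ds, "expression_dataset"))
  sets <- list(sel_wt = sel_wt, sel_mut = sel_mut, ref_cells = ref_cells)
  small <- names(sets)[vapply(sets, length, integer(1)) < 3]
  if (length(small)) {
    stop("cell set(s) with fewer than 3 cells: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  if (is.null(ds$norm)) ds <- log_normalize(ds)
  one <- function(a, b, tag) {
    st <- marker_stats(ds, a, b, thresholds$min_pct)
    tab <- finish_marker_table(st, cluster = tag, thresholds,
                               both_directions = TRUE, use_pct_diff = FALSE)
    dplyr::rename(tab, contrast = "cluster")
  }
  out <- dplyr::bind_rows(one(sel_wt, sel_mut, "wt_vs_mut"),
                          one(sel_wt, ref_cells, "wt_vs_ref"),
                          one(sel_mut, ref_cells, "mut_vs_ref"))
  class(out) <- c("marker_table", class(out))
  out
}
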