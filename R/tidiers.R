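#' Tidy a PCA embedding
#'
#' @param x An `embedding_result` from [run_pca()].
#' @param ... Unused.
#' @return A tibble with one row per component: component, variance,
#'   variance_share.
#' @export
tidy.embedding_result <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(component = paste0("PC", seq_along(ev)), variance = ev,
                 variance_share = ev / sum(ev))
}

#' @rdname tidy.embedding_result
#' @return For `glance()`: a one-row tibble with n_cells, n_pcs,
#'   total_variance, top_pc_share.
#' @export
glance.embedding_result <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(n_cells = nrow(x$pcs), n_pcs = length(ev),
                 total_variance = sum(ev), top_pc_share = ev[1] / sum(ev))
}

#' Tidy a diffusion-map embedding
#'
#' @param x A `diffusion_result` from [diffusion_map()].
#' @param ... Unused.
#' @return A tibble with one row per cell: cell_id, DC coordinates, and
#'   (when filled) distance and biased columns.
#' @export
tidy.diffusion_result <- function(x, ...) {
  out <- dplyr::bind_cols(tibble::tibble(cell_id = x$cell_ids),
                          tibble::as_tibble(x$dcs))
  if (!is.null(x$distances)) {
    out$distance <- unname(x$distances[out$cell_id])
  }
  if (!is.null(x$biased)) out$biased <- out$cell_id %in% x$biased
  out
}

#' @rdname tidy.diffusion_result
#' @return For `glance()`: one row with n_cells, n_dcs, top eigenvalue and
#'   spectral gap.
#' @export
glance.diffusion_result <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(n_cells = length(x$cell_ids), n_dcs = ncol(x$dcs),
                 lambda_1 = ev[1],
                 spectral_gap = ev[1] - ev[min(2, length(ev))])
}

#' Tidy hue-polynomial fits
#'
#' @param x A `hue_fit` from [fit_hue_polynomials()].
#' @param ... Unused.
#' @return A tibble of coefficients: predictor, term, estimate.
#' @export
tidy.hue_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    co <- stats::coef(f)
    tibble::tibble(predictor = nm, term = paste0("beta", seq_along(co) - 1),
                   estimate = unname(co))
  })
}

#' @rdname tidy.hue_fit
#' @return For `glance()`: one row per predictor with degree and R squared.
#' @export
glance.hue_fit <- function(x, ...) {
  tibble::tibble(predictor = names(x$r_squared), degree = x$degree,
                 r_squared = unname(x$r_squared),
                 zero_variance = x$zero_variance)
}
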