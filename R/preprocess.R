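#' Quality-control profile
#'
#' Thresholds for per-cell filtering. The two shipped profiles reflect the
#' two experimental designs supported out of the box: `"pbx3a"` caps UMIs at
#' 3000, `"meis1b"` at 3500; both remove cells with <= 200 detected genes or
#' UMIs, >= 3500 detected genes, or >= 20% mitochondrial content. Stated
#' bounds are inclusive on both sides: a cell with exactly 200 genes or
#' exactly 20% mitochondrial reads fails.
#'
#' @param profile `"pbx3a"` or `"meis1b"`, setting the UMI cap default.
#' @param min_genes,max_genes Detected-gene bounds (fail if `<= min` or
#'   `>= max`).
#' @param min_umis,max_umis UMI bounds (fail if `<= min` or `>= max`).
#' @param max_mito_pct Mitochondrial percentage cap (fail if `>=`).
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes.
#' @param ribo_genes Explicit character vector of ribosomal gene ids (used
#'   by [scale_regress()]; the shipped zebrafish list is in
#'   `system.file("extdata", "ribo_genes_zebrafish.txt", package = "iectools")`).
#' @return A list of class `qc_profile`.
#' @export
qc_profile <- function(profile = c("pbx3a", "meis1b"),
                       min_genes = 200L, max_genes = 3500L,
                       min_umis = 200L,
                       max_umis = NULL,
                       max_mito_pct = 20,
                       mito_prefix = "mt-",
                       ribo_genes = character()) {
  profile <- match.arg(profile)
  if (is.null(max_umis)) {
    max_umis <- if (profile == "pbx3a") 3000L else 3500L
  }
  if (min_genes >= max_genes) stop("min_genes must be < max_genes",
                                   call. = FALSE)
  if (min_umis >= max_umis) stop("min_umis must be < max_umis",
                                 call. = FALSE)
  structure(list(profile = profile, min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 min_umis = as.integer(min_umis),
                 max_umis = as.integer(max_umis),
                 max_mito_pct = max_mito_pct, mito_prefix = mito_prefix,
                 ribo_genes = ribo_genes),
            class = "qc_profile")
}

#' Default zebrafish ribosomal gene list
#'
#' @return Character vector of ribosomal protein gene ids shipped with the
#'   package.
#' @export
ribo_genes_zebrafish <- function() {
  readLines(system.file("extdata", "ribo_genes_zebrafish.txt",
                        package = "iectools"))
}

cell_qc_stats <- function(ds, mito_prefix = "mt-",
                          ribo_genes = character()) {
  counts <- ds$counts
  total <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito <- startsWith(ds$gene_ids, mito_prefix)
  ribo <- ds$gene_ids %in% ribo_genes
  mito_sum <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE])
              else rep(0, nrow(counts))
  ribo_sum <- if (any(ribo)) Matrix::rowSums(counts[, ribo, drop = FALSE])
              else rep(0, nrow(counts))
  tibble::tibble(cell_id = ds$cell_ids, total_umis = total,
                 detected_genes = detected,
                 mito_pct = ifelse(total > 0, 100 * mito_sum / total, 0),
                 ribo_pct = ifelse(total > 0, 100 * ribo_sum / total, 0))
}

#' Filter cells on quality-control thresholds
#'
#' Removes cells failing any rule of the [qc_profile()]: too few detected
#' genes or UMIs (inclusive lower bound), unusually high complexity
#' (inclusive upper bound on genes or UMIs), or elevated mitochondrial
#' content (inclusive). Per-rule failure counts are attached as the
#' `qc_report` attribute and reported via `message()`. Idempotent.
#'
#' @param ds An [expression_dataset()] with counts.
#' @param profile A [qc_profile()].
#' @return The filtered `expression_dataset`, with attribute `qc_report`
#'   (tibble of rule, n_failed).
#' @export
qc_filter <- function(ds, profile = qc_profile()) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(profile, "qc_profile"))
  st <- cell_qc_stats(ds, profile$mito_prefix, profile$ribo_genes)
  fails <- tibble::tibble(
    low_genes = st$detected_genes <= profile$min_genes,
    high_genes = st$detected_genes >= profile$max_genes,
    low_umis = st$total_umis <= profile$min_umis,
    high_umis = st$total_umis >= profile$max_umis,
    high_mito = st$mito_pct >= profile$max_mito_pct)
  report <- tibble::tibble(rule = names(fails),
                           n_failed = vapply(fails, sum, integer(1)))
  keep <- !Reduce(`|`, fails)
  if (!any(keep)) {
    stop("qc_filter removed every cell; failures per rule: ",
         paste0(report$rule, "=", report$n_failed, collapse = ", "),
         call. = FALSE)
  }
  message("qc_filter: kept ", sum(keep), "/", length(keep), " cells")
  out <- subset_cells(ds, ds$cell_ids[keep])
  attr(out, "qc_report") <- report
  out
}

#' Log-normalize counts
#'
#' Sets `norm[c, g] = ln(1 + scale * counts[c, g] / total[c])`, so that for
#' any cell with nonzero total, the de-logged values sum back to `scale`
#' (sum over genes of `expm1(norm)` equals `scale`). Cells with zero total
#' get an all-zero row and a warning.
#'
#' @param ds An [expression_dataset()].
#' @param scale Scale factor (default 1e4).
#' @return The dataset with its `norm` layer filled.
#' @export
log_normalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "expression_dataset"))
  counts <- ds$counts
  total <- Matrix::rowSums(counts)
  if (any(total == 0)) {
    warning(sum(total == 0), " cell(s) with zero total counts; norm set to 0",
            call. = FALSE)
  }
  norm <- counts
  if (length(norm@x)) {
    cell_of_entry <- norm@i + 1L            # dgCMatrix rows are cells
    denom <- total[cell_of_entry]
    norm@x <- log1p(norm@x * scale / denom) # zero-total cells have no entries
  }
  ds$norm <- norm
  ds
}

sparse_col_stats <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colMeans(m^2)
  var <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(var, 0))
}

#' Select highly variable genes
#'
#' Two rankings are provided. `"sd"` ranks genes by the standard deviation
#' of their log-normalized expression and takes the top `n`. `"vst"` fits a
#' mean-variance trend on the raw counts (degree-2 polynomial of
#' log10 variance on log10 mean), standardizes each gene's counts by the
#' trend-predicted sd, clips standardized values at `sqrt(n_cells)`, and
#' ranks genes by the variance of the clipped values.
#'
#' @param ds An [expression_dataset()] with `norm` present (for `"sd"`).
#' @param n Number of genes to select.
#' @param method `"sd"` or `"vst"`.
#' @return Character vector of selected gene ids, ranked.
#' @export
select_hvg <- function(ds, n = 2000L, method = c("sd", "vst")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  if (n >= length(ds$gene_ids)) {
    if (n > length(ds$gene_ids)) {
      warning("n exceeds the number of genes; returning all genes",
              call. = FALSE)
    }
    n <- length(ds$gene_ids)
  }
  score <- if (method == "sd") {
    if (is.null(ds$norm)) stop("norm layer required; run log_normalize()",
                               call. = FALSE)
    sqrt(sparse_col_stats(ds$norm)$var)
  } else {
    vst_score(ds$counts)
  }
  ord <- order(-score, ds$gene_ids)
  ds$gene_ids[ord[seq_len(n)]]
}

vst_score <- function(counts) {
  st <- sparse_col_stats(counts)
  usable <- st$mean > 0 & st$var > 0
  fit_sd <- rep(NA_real_, length(st$mean))
  if (sum(usable) >= 3) {
    lx <- log10(st$mean[usable])
    ly <- log10(st$var[usable])
    co <- stats::lm.fit(cbind(1, lx, lx^2), ly)$coefficients
    fit_sd[usable] <- sqrt(10^(co[1] + co[2] * lx + co[3] * lx^2))
  }
  n_cells <- nrow(counts)
  clip <- sqrt(n_cells)
  dense <- as.matrix(counts)
  z <- sweep(dense, 2, st$mean, `-`)
  z <- sweep(z, 2, fit_sd, `/`)
  z[, !usable | is.na(fit_sd)] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  apply(z, 2, stats::var)
}

#' Regress out covariates and scale
#'
#' For each gene, takes ordinary-least-squares residuals of the
#' log-normalized expression on per-cell mitochondrial and ribosomal
#' percentages (with intercept), z-scores the residuals across cells, and
#' clips at `+/- clip`. Constant covariates are dropped from the design with
#' a warning; zero-variance genes scale to all-zero columns.
#'
#' @param ds An [expression_dataset()] with `norm` present.
#' @param covariates Which covariates to regress out (subset of
#'   `c("mito_pct", "ribo_pct")`; empty vector for plain z-scoring).
#' @param clip Clipping bound on scaled residuals.
#' @param genes Optional gene subset (e.g. [select_hvg()] output).
#' @param profile A [qc_profile()] supplying `mito_prefix` and `ribo_genes`.
#' @return A dense cells-by-genes matrix of scaled residuals.
#' @export
scale_regress <- function(ds, covariates = c("mito_pct", "ribo_pct"),
                          clip = 10, genes = NULL,
                          profile = qc_profile()) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$norm)) stop("norm layer required; run log_normalize()",
                             call. = FALSE)
  covariates <- match.arg(covariates, c("mito_pct", "ribo_pct"),
                          several.ok = TRUE)
  st <- cell_qc_stats(ds, profile$mito_prefix, profile$ribo_genes)
  x <- as.matrix(ds$norm[, genes %||% ds$gene_ids, drop = FALSE])
  design <- matrix(1, nrow(x), 1)
  for (cv in covariates) {
    v <- st[[cv]]
    if (stats::sd(v) == 0) {
      warning("constant covariate dropped from design: ", cv, call. = FALSE)
    } else {
      design <- cbind(design, v)
    }
  }
  qr_d <- qr(design)
  resid <- x - design %*% qr.coef(qr_d, x)
  mu <- colMeans(resid)
  sd <- apply(resid, 2, stats::sd)
  scaled <- sweep(resid, 2, mu, `-`)
  ok <- sd > 0
  scaled[, ok] <- sweep(scaled[, ok, drop = FALSE], 2, sd[ok], `/`)
  scaled[, !ok] <- 0
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  scaled
}

#' Principal component analysis
#'
#' Top principal components of the column-centered matrix by singular value
#' decomposition. Signs are made deterministic: each component's
#' largest-magnitude gene loading is positive.
#'
#' @param scaled Dense cells-by-genes matrix (e.g. from [scale_regress()]).
#' @param n_pcs Number of components (reduced with a warning if it exceeds
#'   the matrix rank bound).
#' @return An object of class `embedding_result`: list with `pcs` (cells x
#'   n_pcs, rownames kept), `explained_variance` (per-PC variances,
#'   non-increasing), `loadings`, and `hvg_ids` (the column names used).
#' @export
run_pca <- function(scaled, n_pcs = 30L) {
  stopifnot(is.matrix(scaled), all(is.finite(scaled)))
  max_pcs <- min(dim(scaled)) - 1L
  if (n_pcs > max_pcs) {
    warning("n_pcs reduced to ", max_pcs, call. = FALSE)
    n_pcs <- max_pcs
  }
  pc <- stats::prcomp(scaled, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  structure(list(pcs = pc$x[, seq_len(n_pcs), drop = FALSE],
                 explained_variance = pc$sdev[seq_len(n_pcs)]^2,
                 loadings = pc$rotation,
                 hvg_ids = colnames(scaled)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  ev <- x$explained_variance
  cat("<embedding_result> ", nrow(x$pcs), " cells x ", ncol(x$pcs),
      " PCs; top-PC variance share ",
      sprintf("%.1f%%", 100 * ev[1] / sum(ev)), "\n", sep = "")
  invisible(x)
}

#' Embed a dataset end to end
#'
#' Convenience wrapper chaining [log_normalize()], [select_hvg()],
#' [scale_regress()] and [run_pca()] with the package defaults.
#'
#' @param ds An [expression_dataset()].
#' @param n_hvg,n_pcs Sizes of the variable-gene set and PC space.
#' @param hvg_method Passed to [select_hvg()].
#' @param profile A [qc_profile()] (for covariate gene sets).
#' @return An `embedding_result`.
#' @export
embed_dataset <- function(ds, n_hvg = 2000L, n_pcs = 30L,
                          hvg_method = "sd", profile = qc_profile()) {
  if (is.null(ds$norm)) ds <- log_normalize(ds)
  hvg <- select_hvg(ds, n = n_hvg, method = hvg_method)
  scaled <- scale_regress(ds, genes = hvg, profile = profile)
  run_pca(scaled, n_pcs = n_pcs)
}
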