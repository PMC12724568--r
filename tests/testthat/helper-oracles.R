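# Independent reference implementations used as test oracles. These are
# written against the published formulas, not against the package code.

# sRGB (0-255) -> CIE L*u*v* polar (L, C, H degrees), D65 white.
oracle_srgb_to_hcl <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  # D65 white from the CIE chromaticity coordinates (x, y) = (0.31271, 0.32902)
  xw <- 0.31271; yw <- 0.32902
  Xn <- xw / yw; Yn <- 1; Zn <- (1 - xw - yw) / yw
  y <- xyz[, 2] / Yn
  L <- ifelse(y > (6 / 29)^3, 116 * y^(1 / 3) - 16, (29 / 3)^3 * y)
  den <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  up <- ifelse(den > 0, 4 * xyz[, 1] / den, 0)
  vp <- ifelse(den > 0, 9 * xyz[, 2] / den, 0)
  dn <- Xn + 15 * Yn + 3 * Zn
  un <- 4 * Xn / dn; vn <- 9 * Yn / dn
  us <- 13 * L * (up - un); vs <- 13 * L * (vp - vn)
  C <- sqrt(us^2 + vs^2)
  H <- (atan2(vs, us) * 180 / pi) %% 360
  cbind(l = L, c = C, h = H)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration over all
# rank assignments (valid for untied data).
oracle_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx) {
    sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2
  })
  pl <- mean(all_u <= u_obs)
  pg <- mean(all_u >= u_obs)
  min(1, 2 * min(pl, pg))
}

# Build a small expression dataset from a dense count matrix.
make_ds <- function(counts, cluster, genotype = NA_character_,
                    dataset_id = "toy", species = "zebrafish") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  meta <- tibble::tibble(cell_id = rownames(counts),
                         cluster = rep_len(cluster, nrow(counts)),
                         dataset_id = dataset_id, species = species,
                         genotype = rep_len(genotype, nrow(counts)),
                         batch = dataset_id, region = NA_character_)
  expression_dataset(counts, meta)
}

# Random NB count matrix, genes x mean vector shared across cells.
nb_matrix <- function(n_cells, mu, dispersion = 0.5) {
  matrix(stats::rnbinom(n_cells * length(mu),
                        mu = rep(mu, each = n_cells),
                        size = 1 / dispersion),
         nrow = n_cells)
}

# Dense oracle for the diffusion map: builds the same locally scaled,
# density-normalized kernel from first principles and takes the right
# eigenvectors of the row-normalized Markov matrix with a general (dense,
# non-symmetric) eigendecomposition.
oracle_diffusion <- function(x, k, sigma_rank, n_dcs) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  sigma <- vapply(seq_len(n), function(i) sort(d[i, -i])[sigma_rank],
                  numeric(1))
  w <- exp(-d^2 / outer(sigma, sigma))
  w[!adj] <- 0
  diag(w) <- 0
  q <- rowSums(w)
  w <- w / outer(q, q)
  p <- w / rowSums(w)
  e <- eigen(p)
  ord <- order(-Re(e$values))
  vals <- Re(e$values[ord])
  vecs <- Re(e$vectors[, ord])
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
  list(markov = p, values = vals[1 + seq_len(n_dcs)],
       dcs = vecs[, 1 + seq_len(n_dcs), drop = FALSE])
}

boundary_ds <- function(fold) {
  # two clusters of 30 cells; gene "probe" built so that its de-logged
  # group means sit at the requested fold on the +1 pseudocount scale,
  # with a pct gap of exactly 0.1 and a decisive rank-sum p
  n <- 30
  m_out <- 1
  m_in <- fold * (m_out + 1) - 1
  norm <- matrix(0, 2 * n, 2)
  norm[, 1] <- c(rep(log1p(m_in), n), rep(log1p(m_out), n))
  norm[, 2] <- rep(log1p(1), 2 * n)
  counts <- matrix(1L, 2 * n, 2)
  counts[1:12, 1] <- 0L                       # pct_in = 18/30 = 0.6
  counts[n + seq_len(15), 1] <- 0L            # pct_out = 15/30 = 0.5
  dimnames(counts) <- list(sprintf("c%03d", seq_len(2 * n)),
                           c("probe", "other"))
  dimnames(norm) <- dimnames(counts)
  ds <- make_ds(counts, rep(c("best4", "rest"), each = n))
  ds$norm <- methods::as(norm, "CsparseMatrix")
  dimnames(ds$norm) <- dimnames(counts)
  ds
}
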