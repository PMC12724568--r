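#' Simulation specification
#'
#' Collects the parameters of the synthetic-data generators. Counts are drawn
#' from a Negative Binomial parameterized by mean and dispersion, with
#' lognormal per-cell library-size variation; planted best4-specific families
#' have their mean multiplied by `marker_fold` in the best4 cluster of a
#' subset of datasets. The defaults emulate the study design the downstream
#' analyses assume: eight datasets (four mammalian, four aquatic), six shared
#' intestinal epithelial clusters, a conserved best4+ program planted in at
#' least six of eight datasets, and species-specific markers planted in
#' exactly one.
#'
#' @param n_datasets Number of species datasets.
#' @param clusters Cluster names; must include `"best4"` and `"progenitor"`.
#' @param cells_per_cluster Cells per cluster per dataset (minimum 3).
#' @param n_families Total ortholog families simulated.
#' @param n_conserved Families planted as best4-specific in at least
#'   `conserved_min` datasets.
#' @param n_species_specific Families planted in exactly one dataset.
#' @param conserved_min Minimum number of datasets a conserved family is
#'   planted in.
#' @param paralog_rate Probability a family is represented by two paralogous
#'   genes in a species.
#' @param nb_mean_base Baseline Negative Binomial mean.
#' @param nb_dispersion Negative Binomial dispersion (`size = 1/dispersion`).
#' @param marker_fold Planted fold-up-regulation in the best4 cluster
#'   (must exceed 1 to plant any signal; 1 means no signal).
#' @param libsize_sdlog Lognormal sd of per-cell library-size factors.
#' @param regional_genes Number of genes planted to co-vary with the anchor
#'   in [simulate_regional()].
#' @param regional_sign_mix Fraction of regional genes anti-correlated with
#'   the anchor.
#' @param traj_n Cells per genotype along the progenitor-to-best4 trajectory
#'   in [simulate_trajectory_pair()] (minimum 40).
#' @param mutant_block_at Pseudotime in (0,1) at which the mutant trajectory
#'   truncates.
#' @param seed Integer seed; every generator is a pure function of
#'   `(spec, seed)`.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_datasets = 8L,
                     clusters = c("progenitor", "enterocyte", "goblet",
                                  "EEC", "best4", "tuft"),
                     cells_per_cluster = 40L,
                     n_families = 150L,
                     n_conserved = 20L,
                     n_species_specific = 10L,
                     conserved_min = 6L,
                     paralog_rate = 0.2,
                     nb_mean_base = 1,
                     nb_dispersion = 0.5,
                     marker_fold = 8,
                     libsize_sdlog = 0.3,
                     regional_genes = 40L,
                     regional_sign_mix = 0.5,
                     traj_n = 300L,
                     mutant_block_at = 0.5,
                     seed = 1L) {
  spec <- list(n_datasets = as.integer(n_datasets), clusters = clusters,
               cells_per_cluster = as.integer(cells_per_cluster),
               n_families = as.integer(n_families),
               n_conserved = as.integer(n_conserved),
               n_species_specific = as.integer(n_species_specific),
               conserved_min = as.integer(conserved_min),
               paralog_rate = paralog_rate, nb_mean_base = nb_mean_base,
               nb_dispersion = nb_dispersion, marker_fold = marker_fold,
               libsize_sdlog = libsize_sdlog,
               regional_genes = as.integer(regional_genes),
               regional_sign_mix = regional_sign_mix,
               traj_n = as.integer(traj_n),
               mutant_block_at = mutant_block_at, seed = as.integer(seed))
  if (spec$n_conserved + spec$n_species_specific > spec$n_families) {
    stop("n_conserved + n_species_specific must not exceed n_families",
         call. = FALSE)
  }
  if (spec$conserved_min > spec$n_datasets) {
    stop("conserved_min must not exceed n_datasets", call. = FALSE)
  }
  if (spec$mutant_block_at <= 0 || spec$mutant_block_at >= 1) {
    stop("mutant_block_at must lie in (0, 1)", call. = FALSE)
  }
  if (spec$marker_fold < 1) stop("marker_fold must be >= 1", call. = FALSE)
  if (spec$nb_dispersion <= 0 || spec$nb_mean_base <= 0) {
    stop("nb_mean_base and nb_dispersion must be positive", call. = FALSE)
  }
  structure(spec, class = "sim_spec")
}

nb_counts <- function(mu, dispersion) {
  # mu: cells x genes matrix of means (already library-size scaled)
  cnt <- stats::rnbinom(length(mu), mu = as.vector(mu),
                        size = 1 / dispersion)
  matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate a multi-species marker-conservation design
#'
#' Generates one count matrix per dataset with six shared clusters and a
#' planted best4-specific program: `n_conserved` ortholog families are
#' up-regulated `marker_fold`-fold in the best4 cluster of a random subset of
#' at least `conserved_min` datasets, and `n_species_specific` families in
#' exactly one dataset each. Datasets are labeled alternately as mammal and
#' aquatic clades, and each family may be represented by two paralogous genes
#' per species at `paralog_rate`, all recorded in the returned ortholog
#' table.
#'
#' @param spec A [sim_spec()].
#' @return A list with elements `datasets` (named list of
#'   [expression_dataset()]), `orth` (an [ortholog_table()]) and `truth`
#'   (list with `families`: tibble of family, class, planted datasets; and
#'   `genes`: tibble of per-dataset gene-to-family assignments).
#' @export
simulate_multispecies <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$cells_per_cluster < 3) {
    stop("cells_per_cluster must be at least 3", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    n_d <- spec$n_datasets
    dataset_ids <- sprintf("dataset%d", seq_len(n_d))
    species <- sprintf("species%d", seq_len(n_d))
    clades <- rep(c("mammal", "aquatic"), length.out = n_d)
    families <- sprintf("FAM%03d", seq_len(spec$n_families))
    class <- rep("background", spec$n_families)
    class[seq_len(spec$n_conserved)] <- "conserved"
    if (spec$n_species_specific > 0) {
      class[spec$n_conserved + seq_len(spec$n_species_specific)] <-
        "species_specific"
    }

    planted_in <- vector("list", spec$n_families)
    for (i in seq_len(spec$n_families)) {
      planted_in[[i]] <- switch(
        class[i],
        conserved = sort(sample(n_d, sample(spec$conserved_min:n_d, 1))),
        species_specific = sample(n_d, 1),
        integer(0))
    }

    base_mean <- stats::rlnorm(spec$n_families,
                               meanlog = log(spec$nb_mean_base), sdlog = 0.5)

    clusters <- spec$clusters
    n_cells <- spec$cells_per_cluster * length(clusters)
    orth_rows <- list()
    gene_rows <- list()
    datasets <- vector("list", n_d)
    names(datasets) <- dataset_ids

    for (d in seq_len(n_d)) {
      n_copies <- 1L + stats::rbinom(spec$n_families, 1L, spec$paralog_rate)
      fam_of_gene <- rep(seq_len(spec$n_families), n_copies)
      suffix <- unlist(lapply(n_copies, function(k) letters[seq_len(k)]))
      gene_ids <- paste0(species[d], "-",
                         tolower(families[fam_of_gene]), suffix)
      n_genes <- length(gene_ids)

      cluster_lab <- rep(clusters, each = spec$cells_per_cluster)
      mu <- matrix(rep(base_mean[fam_of_gene], each = n_cells),
                   nrow = n_cells,
                   dimnames = list(
                     sprintf("%s-c%04d", dataset_ids[d], seq_len(n_cells)),
                     gene_ids))
      planted_gene <- vapply(fam_of_gene, function(f) d %in% planted_in[[f]],
                             logical(1))
      best4_cells <- cluster_lab == "best4"
      mu[best4_cells, planted_gene] <-
        mu[best4_cells, planted_gene] * spec$marker_fold
      libsize <- stats::rlnorm(n_cells, 0, spec$libsize_sdlog)
      counts <- nb_counts(mu * libsize, spec$nb_dispersion)

      meta <- tibble::tibble(cell_id = rownames(mu), cluster = cluster_lab,
                             dataset_id = dataset_ids[d],
                             species = species[d], genotype = NA_character_,
                             batch = dataset_ids[d], region = NA_character_)
      datasets[[d]] <- expression_dataset(counts, meta)
      orth_rows[[d]] <- tibble::tibble(species = species[d],
                                       gene_id = gene_ids,
                                       family = families[fam_of_gene])
      gene_rows[[d]] <- tibble::tibble(dataset_id = dataset_ids[d],
                                       gene_id = gene_ids,
                                       family = families[fam_of_gene],
                                       planted = planted_gene)
    }

    truth <- list(
      families = tibble::tibble(
        family = families, class = class,
        planted_datasets = lapply(planted_in,
                                  function(i) dataset_ids[i])),
      genes = dplyr::bind_rows(gene_rows),
      clades = stats::setNames(clades, dataset_ids))
    list(datasets = datasets,
         orth = ortholog_table(dplyr::bind_rows(orth_rows)),
         truth = truth)
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Simulate a wild-type versus mutant secretory differentiation tree
#'
#' Emulates the joint embedding of all secretory derivatives in a
#' mutant-versus-wild-type design. Wild-type trunk cells sit on a latent
#' pseudotime t in [0,1] running from secretory progenitors to terminal
#' best4+ cells; mutant trunk cells are drawn only from t below
#' `mutant_block_at` with all terminal best4 markers forced to zero mean.
#' Both genotypes additionally form goblet and enteroendocrine branches
#' (unaffected by the mutation) that leave the trunk at an early branch
#' point, so the embedded manifold is a small tree rather than a single
#' chain, as in the tissue. Planted gene programs: progenitor-identity
#' genes (flat across progenitors, declining only at terminal
#' differentiation, identical between genotypes), terminal best4 markers
#' (rising sigmoidally late in t, the program the mutant cannot reach),
#' maturation-gradient genes (monotone in t, giving the continuum the
#' embedding recovers), branch-specific goblet/EEC programs, and constant
#' background genes. The per-genotype "biased" flag marks trunk progenitors
#' above the genotype's 75th percentile of pseudotime.
#'
#' @param spec A [sim_spec()]; uses `traj_n` (trunk cells per genotype;
#'   each branch gets a third of that), `mutant_block_at`, `nb_dispersion`
#'   and `libsize_sdlog`.
#' @return A list with `dataset` (a joint [expression_dataset()] with
#'   genotype metadata and clusters `progenitor`/`best4`/`goblet`/`EEC`)
#'   and `truth` (list with per-cell tibble `cells`: pseudotime, cluster,
#'   biased flag; and per-gene tibble `genes`: role).
#' @export
simulate_trajectory_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$traj_n < 40) stop("traj_n must be at least 40", call. = FALSE)
  withr::with_seed(spec$seed + 1L, {
    n <- spec$traj_n
    n_branch <- round(n / 3)
    branch_at <- 0.35

    one_genotype <- function(geno) {
      t_trunk <- if (geno == "WT") stats::runif(n)
                 else stats::runif(n, 0, spec$mutant_block_at)
      tibble::tibble(
        genotype = geno,
        lineage = c(rep("trunk", n), rep("goblet", n_branch),
                    rep("EEC", n_branch)),
        t = c(t_trunk, rep(branch_at, 2 * n_branch)),
        v = c(rep(0, n), stats::runif(2 * n_branch)))
    }
    cells <- dplyr::bind_rows(one_genotype("WT"), one_genotype("MUT"))
    cells$cell_id <- sprintf("%s-c%04d", tolower(cells$genotype),
                             stats::ave(seq_len(nrow(cells)),
                                        cells$genotype, FUN = seq_along))

    n_prog <- 50L; n_term <- 50L; n_ramp <- 300L
    n_gob <- 40L; n_eec <- 40L; n_bg <- 250L
    roles <- rep(c("progenitor", "terminal", "ramp", "goblet", "EEC",
                   "background"),
                 times = c(n_prog, n_term, n_ramp, n_gob, n_eec, n_bg))
    gene_ids <- sprintf("%s%03d",
                        rep(c("prog", "term", "ramp", "gob", "eec", "bg"),
                            times = c(n_prog, n_term, n_ramp, n_gob, n_eec,
                                      n_bg)),
                        unlist(lapply(c(n_prog, n_term, n_ramp, n_gob,
                                        n_eec, n_bg), seq_len)))

    amp_prog <- stats::rlnorm(n_prog, log(4), 0.3)
    amp_term <- stats::rlnorm(n_term, log(5), 0.3)
    amp_ramp <- stats::rlnorm(n_ramp, log(6), 0.3)
    amp_gob <- stats::rlnorm(n_gob, log(5), 0.3)
    amp_eec <- stats::rlnorm(n_eec, log(5), 0.3)
    ramp_up <- rep(c(TRUE, FALSE), length.out = n_ramp)
    mu_bg <- stats::rlnorm(n_bg, log(spec$nb_mean_base), 0.5)

    n_cells <- nrow(cells)
    t_all <- cells$t
    mu <- matrix(0, n_cells, length(gene_ids),
                 dimnames = list(cells$cell_id, gene_ids))
    # progenitor identity: flat until terminal decay (centered at t = 0.9)
    prog_shape <- 1 - sigmoid((t_all - 0.9) * 25)
    prog_shape[cells$lineage != "trunk"] <-
      pmax(0, 1 - cells$v[cells$lineage != "trunk"])  # decays along branches
    mu[, roles == "progenitor"] <- outer(prog_shape, amp_prog)
    term_shape <- sigmoid((t_all - 0.75) * 12)
    term_shape[cells$genotype == "MUT"] <- 0  # terminal program unreachable
    term_shape[cells$lineage != "trunk"] <- 0
    mu[, roles == "terminal"] <- outer(term_shape, amp_term)
    # gradient program: half linear ramps, half sigmoidal switches with
    # centers staggered along t (genes turn on/off at all stages, as in
    # real differentiation continua)
    n_lin <- n_ramp %/% 2
    lin_cols <- which(roles == "ramp")[seq_len(n_lin)]
    sw_cols <- setdiff(which(roles == "ramp"), lin_cols)
    mu[, lin_cols] <- outer(t_all, amp_ramp[seq_len(n_lin)] *
                              ramp_up[seq_len(n_lin)]) +
      outer(1 - t_all, amp_ramp[seq_len(n_lin)] * !ramp_up[seq_len(n_lin)])
    sw_center <- seq(0.05, 0.95, length.out = length(sw_cols))
    sw_up <- rep(c(1, -1), length.out = length(sw_cols))
    sw_shape <- sigmoid(outer(t_all, sw_center, `-`) * 8 *
                          rep(sw_up, each = n_cells))
    mu[, sw_cols] <- sw_shape *
      rep(amp_ramp[n_lin + seq_along(sw_cols)], each = n_cells)
    gob_shape <- ifelse(cells$lineage == "goblet", cells$v, 0)
    eec_shape <- ifelse(cells$lineage == "EEC", cells$v, 0)
    mu[, roles == "goblet"] <- outer(gob_shape, amp_gob)
    mu[, roles == "EEC"] <- outer(eec_shape, amp_eec)
    mu[, roles == "background"] <- matrix(rep(mu_bg, each = n_cells),
                                          nrow = n_cells)

    libsize <- stats::rlnorm(n_cells, 0, spec$libsize_sdlog)
    counts <- nb_counts(mu * libsize, spec$nb_dispersion)

    cluster <- dplyr::case_when(
      cells$lineage == "goblet" ~ "goblet",
      cells$lineage == "EEC" ~ "EEC",
      cells$genotype == "WT" & t_all >= 0.8 ~ "best4",
      TRUE ~ "progenitor")
    biased <- logical(n_cells)
    for (g in c("WT", "MUT")) {
      idx <- which(cells$genotype == g & cells$lineage == "trunk" &
                     cluster == "progenitor")
      biased[idx] <- t_all[idx] > stats::quantile(t_all[idx], 0.75)
    }

    meta <- tibble::tibble(cell_id = cells$cell_id, cluster = cluster,
                           dataset_id = "trajectory", species = "zebrafish",
                           genotype = cells$genotype, batch = "trajectory",
                           region = NA_character_)
    truth <- list(
      cells = tibble::tibble(cell_id = cells$cell_id,
                             genotype = cells$genotype,
                             lineage = cells$lineage,
                             pseudotime = t_all, branch_pos = cells$v,
                             cluster = cluster, biased = biased),
      genes = tibble::tibble(gene_id = gene_ids, role = roles))
    list(dataset = expression_dataset(counts, meta), truth = truth)
  })
}

#' Simulate within-cluster spatial regionalization
#'
#' Generates a single best4 cluster whose cells carry a latent spatial
#' position u ~ Uniform(0,1). The anchor gene's mean decreases strictly in
#' u; each planted regional gene's mean is monotone in u with a recorded
#' sign relative to the anchor (+1 co-varying, -1 opposing); all other genes
#' are independent of u.
#'
#' @param spec A [sim_spec()]; uses `regional_genes`, `regional_sign_mix`,
#'   `n_families` (total gene count), `nb_dispersion`, `libsize_sdlog`.
#' @param anchor Gene id to use for the anchor (default `"otop2"`).
#' @param n_cells Number of best4 cells to draw.
#' @return A list with `dataset` (an [expression_dataset()], all cells in
#'   cluster `best4`) and `truth` (per-gene tibble with `sign` in
#'   {+1, -1, 0} and per-cell tibble with latent `u`).
#' @export
simulate_regional <- function(spec, anchor = "otop2", n_cells = 300L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$regional_genes > spec$n_families) {
    stop("regional_genes must not exceed n_families", call. = FALSE)
  }
  withr::with_seed(spec$seed + 2L, {
    n_reg <- spec$regional_genes
    n_bg <- spec$n_families - n_reg
    gene_ids <- c(anchor,
                  sprintf("reg%03d", seq_len(n_reg)),
                  sprintf("bg%03d", seq_len(n_bg)))
    sign <- c(0L,  # anchor reported as 0: it is the reference itself
              rep(c(-1L, 1L),
                  times = c(round(n_reg * spec$regional_sign_mix),
                            n_reg - round(n_reg * spec$regional_sign_mix))),
              rep(0L, n_bg))
    u <- stats::runif(n_cells)
    cell_id <- sprintf("best4-c%04d", seq_len(n_cells))

    mu <- matrix(0, n_cells, length(gene_ids),
                 dimnames = list(cell_id, gene_ids))
    # the anchor emulates a strongly expressed regionalized marker (otop2 is
    # among the top best4+ markers); high expression keeps its own sampling
    # noise from attenuating every gene-anchor correlation
    anchor_amp <- 12
    mu[, 1] <- 1 + anchor_amp * (1 - u)         # anchor: decreasing in u
    amp <- stats::rlnorm(n_reg, log(7), 0.25)
    # balance the planted program compositionally: the summed mean of all
    # u-dependent genes (anchor included) is constant in u, so library-size
    # normalization does not couple unrelated genes to the anchor
    reg_sign <- sign[1 + seq_len(n_reg)]
    if (any(reg_sign < 0)) {
      amp[reg_sign < 0] <- amp[reg_sign < 0] *
        (sum(amp[reg_sign > 0]) + anchor_amp) / sum(amp[reg_sign < 0])
    }
    for (j in seq_len(n_reg)) {
      mu[, 1 + j] <- if (reg_sign[j] > 0) 0.3 + amp[j] * (1 - u)
                     else 0.3 + amp[j] * u
    }
    if (n_bg > 0) {
      # scan background = genes expressed within the cluster (moderate
      # means), as in a within-cell-type correlation scan
      mu_bg <- stats::rlnorm(n_bg, log(3), 0.4)
      mu[, 1 + n_reg + seq_len(n_bg)] <- matrix(rep(mu_bg, each = n_cells),
                                                nrow = n_cells)
    }
    libsize <- stats::rlnorm(n_cells, 0, spec$libsize_sdlog)
    counts <- nb_counts(mu * libsize, spec$nb_dispersion)
    meta <- tibble::tibble(cell_id = cell_id, cluster = "best4",
                           dataset_id = "regional", species = "zebrafish",
                           genotype = NA_character_, batch = "regional",
                           region = NA_character_)
    truth <- list(genes = tibble::tibble(gene_id = gene_ids, sign = sign),
                  cells = tibble::tibble(cell_id = cell_id, u = u))
    list(dataset = expression_dataset(counts, meta), truth = truth)
  })
}

#' Simulate a pH-indicator color time series
#'
#' Models luminal pH relaxing exponentially from `ph0` towards `ph_home`
#' with time constant `tau`, a two-form indicator whose base-form fraction
#' follows Henderson-Hasselbalch, f = 1 / (1 + 10^(pKa - pH)), and ROI
#' colors formed by mixing the acid- and base-form sRGB colors in linear
#' light, gamma-encoding, then adding a background offset and Gaussian
#' noise. Background ROIs carry the offset and noise only.
#'
#' @param ph0 Initial pH after the challenge.
#' @param ph_home Homeostatic pH the lumen returns to.
#' @param tau Relaxation time constant in minutes (> 0).
#' @param timepoints Imaging times in minutes (non-empty).
#' @param pKa Indicator pKa (phenol-red-like default 8.0).
#' @param acid_rgb,base_rgb sRGB triples (0-255) of the pure acid and base
#'   indicator forms.
#' @param bg_offset RGB triple added to every measurement (camera/background
#'   offset).
#' @param noise_sd Gaussian noise sd per channel on the ROI mean (small,
#'   because each measurement averages thousands of pixels).
#' @param n_animals Animals imaged per timepoint.
#' @param seed Integer seed.
#' @return A `color_series` tibble with columns `animal`, `time`, `roi_r/g/b`,
#'   `bg_r/g/b`, `condition`, and attributes `truth` (list with the pH curve
#'   and model parameters).
#' @export
simulate_ph_series <- function(ph0 = 4, ph_home = 7.5, tau = 5,
                               timepoints = seq(0, 30, by = 1),
                               pKa = 8.0,
                               acid_rgb = c(250, 220, 60),
                               base_rgb = c(235, 60, 150),
                               bg_offset = c(8, 10, 6),
                               noise_sd = 0.5, n_animals = 6L, seed = 1L) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!length(timepoints)) stop("timepoints must be non-empty", call. = FALSE)
  withr::with_seed(as.integer(seed) + 3L, {
    grid <- tidyr::expand_grid(animal = sprintf("animal%02d",
                                                seq_len(n_animals)),
                               time = sort(timepoints))
    ph <- ph_home + (ph0 - ph_home) * exp(-grid$time / tau)
    f <- 1 / (1 + 10^(pKa - ph))
    lin_acid <- srgb_decode(acid_rgb / 255)
    lin_base <- srgb_decode(base_rgb / 255)
    lin <- outer(1 - f, lin_acid) + outer(f, lin_base)
    enc <- srgb_encode(lin) * 255
    n <- nrow(grid)
    noise <- function() matrix(stats::rnorm(3 * n, 0, noise_sd), ncol = 3)
    roi <- enc + matrix(bg_offset, n, 3, byrow = TRUE) + noise()
    bg <- matrix(bg_offset, n, 3, byrow = TRUE) + noise()
    out <- tibble::tibble(animal = grid$animal, time = grid$time,
                          roi_r = roi[, 1], roi_g = roi[, 2],
                          roi_b = roi[, 3],
                          bg_r = bg[, 1], bg_g = bg[, 2], bg_b = bg[, 3],
                          condition = "simulated")
    attr(out, "truth") <- list(ph = ph, ph0 = ph0, ph_home = ph_home,
                               tau = tau, pKa = pKa, acid_rgb = acid_rgb,
                               base_rgb = base_rgb)
    class(out) <- c("color_series", class(out))
    out
  })
}
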