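toy_orth <- ortholog_table(tibble::tibble(
  species = c("zebrafish", "zebrafish", "zebrafish", "human", "human",
              "human"),
  gene_id = c("pbx3a", "pbx3b", "ca4b", "PBX3", "CA4", "DUAL"),
  family = c("PBX3", "PBX3", "CA4", "PBX3", "CA4", "PBX3")))

test_that("map_to_families applies the any-ortholog rule over paralogs", {
  flags <- suppressMessages(map_to_families(
    list(dz = c("pbx3a"), dh = c("CA4")),
    toy_orth, species = c(dz = "zebrafish", dh = "human")))
  expect_true(flags["PBX3", "dz"])     # one paralog suffices
  expect_false(flags["CA4", "dz"])
  expect_true(flags["CA4", "dh"])
  # a gene mapping to two families flags both
  orth2 <- ortholog_table(dplyr::bind_rows(
    toy_orth, tibble::tibble(species = "human", gene_id = "DUAL",
                             family = "CA4")))
  flags2 <- suppressMessages(map_to_families(
    list(dh = "DUAL"), orth2, species = c(dh = "human")))
  expect_true(all(flags2[c("PBX3", "CA4"), "dh"]))
  # empty marker list gives an all-false column
  flags3 <- suppressMessages(map_to_families(
    list(dz = character()), toy_orth, species = c(dz = "zebrafish")))
  expect_false(any(flags3[, "dz"]))
  # unmapped markers are dropped with a warning
  expect_warning(suppressMessages(map_to_families(
    list(dz = c("pbx3a", "novelgene")), toy_orth,
    species = c(dz = "zebrafish"))), "without an ortholog")
  expect_error(map_to_families(list(dx = "g"), toy_orth,
                               species = c(dx = "mouse")),
               "species absent")
})

test_that("classify_conservation applies the count and clade rules", {
  mk_flags <- function(...) {
    m <- rbind(...)
    colnames(m) <- sprintf("d%d", seq_len(ncol(m)))
    rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
    m
  }
  cfg <- conservation_config(conserved_min = 6L, n_datasets = 8L)
  flags <- mk_flags(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, rep(FALSE, 7)),
                    c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  out <- classify_conservation(flags, cfg)
  expect_equal(out$class, c("conserved", "species_specific",
                            "shared_partial"))
  expect_equal(out$n_marked, c(6L, 1L, 5L))
  # clade rule: 3 of 4 mammal datasets, at most one flag outside
  clades <- stats::setNames(rep(c("mammal", "aquatic"), each = 4),
                            sprintf("d%d", 1:8))
  cfg_cl <- conservation_config(clade_labels = clades)
  flags_cl <- mk_flags(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  out_cl <- classify_conservation(flags_cl, cfg_cl)
  expect_equal(out_cl$class, c("clade_conserved:mammal", "shared_partial"))
  # column order must not matter
  perm <- sample(8)
  out_perm <- classify_conservation(flags[, perm, drop = FALSE], cfg)
  expect_equal(out_perm$class, out$class)
  # missing clade labels are an error when clade classing is on
  expect_error(classify_conservation(flags_cl,
                                     conservation_config(
                                       clade_labels = clades[1:4])),
               "missing a clade label")
  expect_error(classify_conservation(flags[, 1:5], cfg), "dataset columns")
  expect_error(conservation_config(conserved_min = 9L, n_datasets = 8L),
               "species_specific_max")
})

test_that("n_marked is monotone under added datasets", {
  set.seed(8)
  base <- matrix(runif(40) < 0.4, 10, 4,
                 dimnames = list(sprintf("f%d", 1:10), sprintf("d%d", 1:4)))
  cfg4 <- conservation_config(conserved_min = 3L, n_datasets = 4L,
                              species_specific_max = 1L)
  cfg5 <- conservation_config(conserved_min = 3L, n_datasets = 5L,
                              species_specific_max = 1L)
  n4 <- classify_conservation(base, cfg4)$n_marked
  extra <- cbind(base, d5 = runif(10) < 0.4)
  n5 <- classify_conservation(extra, cfg5)$n_marked
  expect_true(all(n5 >= n4))
})

test_that("specificity index is a percentage decomposition of expression", {
  counts <- rbind(c(10, 4, 0), c(8, 4, 0), c(0, 4, 0), c(0, 4, 0),
                  c(0, 4, 0), c(0, 4, 0))
  colnames(counts) <- c("marker", "house", "silent")
  clusters <- c("best4", "best4", "EC", "goblet", "EEC", "tuft")
  rownames(counts) <- sprintf("c%d", 1:6)
  ds <- log_normalize(make_ds(counts, clusters))
  expect_equal(specificity_index(ds, "marker", "best4"), 100)
  expect_true(is.na(specificity_index(ds, "silent", "best4")))
  expect_error(specificity_index(ds, "marker", "paneth"),
               "cluster not found")
  # equal means across 6 clusters: 100/6 each (uniform library sizes)
  counts_eq <- matrix(4, 6, 2, dimnames = list(sprintf("c%d", 1:6),
                                               c("a", "b")))
  ds_eq <- log_normalize(make_ds(counts_eq, sprintf("cl%d", 1:6)))
  expect_equal(specificity_index(ds_eq, "a", "cl3"), 100 / 6,
               tolerance = 1e-3)
  # de-logged cluster means {3,1,0,2,0,2} -> 37.5% in the target
  means <- c(best4 = 3, EC = 1, goblet = 0, EEC = 2, tuft = 0,
             progenitor = 2)
  norm <- matrix(log1p(rep(means, each = 1)), ncol = 1,
                 dimnames = list(names(means), "g"))
  ds_m <- make_ds(matrix(1L, 6, 1, dimnames = dimnames(norm)),
                  names(means))
  ds_m$norm <- methods::as(norm, "CsparseMatrix")
  dimnames(ds_m$norm) <- dimnames(norm)
  ds_m$cell_meta$cluster <- names(means)
  expect_equal(specificity_index(ds_m, "g", "best4"), 37.5)
  # decomposition: summing over clusters gives 100
  set.seed(9)
  big <- make_ds(nb_matrix(60, rlnorm(20, 0.5, 0.7)),
                 rep(c("a", "b", "c"), each = 20))
  big <- log_normalize(big)
  for (g in sample(big$gene_ids, 5)) {
    tot <- sum(vapply(c("a", "b", "c"),
                      function(cl) specificity_index(big, g, cl),
                      numeric(1)))
    expect_equal(tot, 100, tolerance = 1e-6)
  }
})

test_that("build_program_table recovers planted conservation classes", {
  spec <- sim_spec(seed = 31L)
  sim <- simulate_multispecies(spec)
  res <- suppressWarnings(suppressMessages(build_program_table(
    sim$datasets, sim$orth,
    conservation_config(clade_labels = sim$truth$clades))))
  truth <- sim$truth$families
  joined <- dplyr::left_join(truth, res$records[, c("family", "class")],
                             by = "family", suffix = c("_true", "_called"))
  conserved <- joined[joined$class_true == "conserved", ]
  expect_gte(mean(conserved$class_called == "conserved", na.rm = TRUE), 0.9)
  speciesb <- joined[joined$class_true == "species_specific", ]
  expect_gte(mean(speciesb$class_called == "species_specific",
                  na.rm = TRUE), 0.9)
  background <- joined[joined$class_true == "background", ]
  expect_equal(sum(background$class_called == "conserved", na.rm = TRUE), 0)
  # specificity of conserved families concentrates in the target cluster,
  # well above the uniform 100/6 = 16.7% share (library normalization
  # damps the raw 8-fold planting, so the expected value is ~40%)
  spec_cons <- res$specificity[res$specificity$family %in%
                                 conserved$family, -1]
  expect_gt(mean(as.matrix(spec_cons), na.rm = TRUE), 30)
  # deterministic ordering by class then family
  expect_equal(res$records$family,
               res$records[order(res$records$class, res$records$family), ]$family)
})
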