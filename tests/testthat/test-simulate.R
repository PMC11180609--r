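test_that("simulation is fully determined by its seed", {
  cfg <- sim_config(n_genes = 30, n_pathways = 4, n_single = 8, n_double = 3,
                    planted = c(synergy = 1, epistasis = 1),
                    cells_per_condition = 5, n_control = 20, seed = 5)
  s1 <- simulate_perturb_data(cfg)
  s2 <- simulate_perturb_data(cfg)
  expect_identical(s1$dataset$expr, s2$dataset$expr)
  expect_identical(s1$truth$effects, s2$truth$effects)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("generated datasets satisfy the dataset contract", {
  sim <- sim_noise0()
  ds <- sim$dataset
  expect_s3_class(ds, "perturb_dataset")
  expect_gt(ds$n_control, 0)
  expect_true(all(ds$expr >= 0))
  expect_length(ds$unmeasured, 0)
  expect_identical(ds$conditions, canonical_condition(ds$conditions))
  # every planted condition exists with the configured number of cells
  cfg <- sim$truth$config
  for (k in names(sim$truth$effects))
    expect_equal(sum(ds$conditions == k), cfg$cells_per_condition)
  expect_equal(sum(ds$conditions == "ctrl"), cfg$n_control)
})

test_that("zero-noise condition means equal baseline plus planted effects", {
  sim <- sim_noise0()
  ds <- sim$dataset
  for (k in names(sim$truth$effects)[1:10]) {
    s <- summarize_condition(ds, k)
    expect_equal(unname(s$mean_delta), unname(sim$truth$effects[[k]]),
                 tolerance = 1e-10)
    # planted DE genes recovered exactly: top 20 by |effect|
    ord <- order(-abs(sim$truth$effects[[k]]), seq_along(ds$genes))
    expect_identical(head(s$top_de_genes, 20), ds$genes[ord[1:20]])
  }
})

test_that("full sharing makes same-pathway-clique effects identical", {
  cfg <- sim_config(n_genes = 30, n_pathways = 2, membership_density = 0.5,
                    n_single = 10, n_double = 2, planted = c(synergy = 1),
                    neighbor_share = 1, self_effect = 0, noise_sd = 0,
                    cells_per_condition = 5, n_control = 10,
                    pathway_genes = 10, seed = 9)
  sim <- simulate_perturb_data(cfg)
  memb <- sim$membership
  tg <- sim$truth$singles
  sets <- vapply(tg, function(g) paste(memb[[g]], collapse = ","), character(1))
  dup <- names(sets)[duplicated(sets) | duplicated(sets, fromLast = TRUE)]
  dup <- dup[sets[dup] != ""]
  expect_gt(length(dup), 1)
  grp <- split(dup, sets[dup])
  grp <- grp[[which(lengths(grp) > 1)[1]]]
  expect_equal(sim$truth$effects[[grp[1]]], sim$truth$effects[[grp[2]]],
               tolerance = 1e-12)
})

test_that("zero sharing decorrelates pathway neighbors", {
  cfg <- sim_config(n_genes = 80, n_pathways = 6, membership_density = 0.3,
                    n_single = 40, n_double = 2, planted = c(synergy = 1),
                    neighbor_share = 0, self_effect = 0, noise_sd = 0,
                    cells_per_condition = 2, n_control = 5, seed = 10)
  sim <- simulate_perturb_data(cfg)
  tg <- sim$truth$singles
  rs <- c()
  for (i in seq_along(tg)) for (j in seq_len(i - 1)) {
    if (length(intersect(sim$membership[[tg[i]]], sim$membership[[tg[j]]])))
      rs <- c(rs, cor(sim$truth$effects[[tg[i]]], sim$truth$effects[[tg[j]]]))
  }
  expect_gt(length(rs), 100)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("planted counts beyond the available pairs are fatal", {
  expect_error(sim_config(n_double = 3,
                          planted = c(synergy = 2, suppression = 2)),
               "exceed")
})

test_that("truth metrics score perfect, null and additive predictions", {
  sim <- sim_noise0()
  keys <- names(sim$truth$effects)[1:8]
  perfect <- sim$truth$effects[keys]
  tm <- truth_metrics(sim$truth, perfect)
  expect_equal(tm$pearson, rep(1, 8), tolerance = 1e-12)
  null_pred <- lapply(perfect, function(e) e * 0)
  tm0 <- truth_metrics(sim$truth, null_pred)
  expect_equal(tm0$pearson, rep(0, 8))
  add_pairs <- sim$truth$pairs[sim$truth$pairs$subtype == "additive", ]
  add_pred <- lapply(seq_len(nrow(add_pairs)), function(i)
    sim$truth$effects[[add_pairs$gene_a[i]]] +
      sim$truth$effects[[add_pairs$gene_b[i]]])
  names(add_pred) <- add_pairs$condition
  tma <- truth_metrics(sim$truth, add_pred)
  expect_equal(tma$pearson, rep(1, nrow(add_pairs)), tolerance = 1e-12)
  expect_true(all(tma$subtype == "additive"))
})

test_that("the optional count layer is integer and links to the log layer", {
  cfg <- sim_config(n_genes = 15, n_pathways = 3, n_single = 4, n_double = 2,
                    planted = c(synergy = 1), cells_per_condition = 3,
                    n_control = 10, nb_counts = TRUE, seed = 12)
  sim <- simulate_perturb_data(cfg)
  expect_false(is.null(sim$counts))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_equal(dim(sim$counts), dim(sim$dataset$expr))
})
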