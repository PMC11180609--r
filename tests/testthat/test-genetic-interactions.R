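test_that("combo regression recovers planted coefficients", {
  set.seed(31)
  K <- 60
  da <- rnorm(K); db <- rnorm(K)
  add <- fit_combo_model(da, db, da + db)
  expect_equal(c(add$c_a, add$c_b), c(1, 1), tolerance = 1e-8)
  expect_equal(add$fit_corr, 1, tolerance = 1e-10)
  sc <- fit_combo_model(da, db, 2 * da + 2 * db)
  expect_equal(c(sc$c_a, sc$c_b), c(2, 2), tolerance = 1e-8)
  # orthogonal singles, combo = half of one of them
  db_o <- db - sum(db * da) / sum(da^2) * da
  half <- fit_combo_model(da, db_o, 0.5 * da)
  expect_equal(c(half$c_a, half$c_b), c(0.5, 0), tolerance = 1e-8)
  # closed-form normal-equation oracle on random instances
  for (i in 1:10) {
    a <- rnorm(K); b <- rnorm(K); y <- rnorm(K)
    f <- fit_combo_model(a, b, y, gene_mask = seq_len(K))
    X <- cbind(a, b)
    ref <- solve(crossprod(X), crossprod(X, y))
    expect_equal(c(f$c_a, f$c_b), unname(drop(ref)), tolerance = 1e-8)
  }
  # collinear and zero singles are flagged degenerate
  expect_true(fit_combo_model(da, 2 * da, da)$degenerate)
  expect_true(fit_combo_model(da * 0, db, db)$degenerate)
  expect_false(add$degenerate)
})

test_that("subtype scores separate constructed interaction archetypes", {
  set.seed(32)
  K <- 80
  da <- rnorm(K); db <- rnorm(K)
  db <- db - sum(db * da) / sum(da^2) * da      # orthogonal singles
  novel <- rnorm(K)
  novel <- novel - sum(novel * da) / sum(da^2) * da
  novel <- novel - sum(novel * db) / sum(db^2) * db
  deltas <- list(A = da, B = db,
                 "A+B" = da + db)
  cases <- rbind(
    data.frame(gene_a = "A", gene_b = "B", kind = "additive"),
    data.frame(gene_a = "A", gene_b = "B", kind = "synergy"),
    data.frame(gene_a = "A", gene_b = "B", kind = "neomorphism"),
    data.frame(gene_a = "A", gene_b = "B", kind = "epistasis"))
  combos <- list(additive = da + db, synergy = 2 * (da + db),
                 neomorphism = novel / sqrt(sum(novel^2)) * sqrt(sum((da + db)^2)),
                 epistasis = da)
  fits <- do.call(rbind, lapply(names(combos), function(kind) {
    f <- fit_combo_model(da, db, combos[[kind]])
    data.frame(gene_a = "A", gene_b = "B", kind = kind,
               c_a = f$c_a, c_b = f$c_b, fit_corr = f$fit_corr,
               degenerate = f$degenerate, sim_corr = f$sim_corr,
               norm_a = f$norm_a, norm_b = f$norm_b, norm_ab = f$norm_ab)
  }))
  sc <- score_subtypes(fits)
  expect_gt(sc$synergy[sc$kind == "synergy"], max(sc$synergy[sc$kind != "synergy"]))
  expect_gt(sc$neomorphism[sc$kind == "neomorphism"],
            max(sc$neomorphism[sc$kind != "neomorphism"]))
  expect_gt(sc$epistasis[sc$kind == "epistasis"],
            max(sc$epistasis[sc$kind != "epistasis"]))
  # orthogonal combo: the least-squares fit explains almost nothing (the fit
  # mask is the DE-gene union, where exact orthogonality need not hold)
  expect_lt(abs(sc$fit_corr[sc$kind == "neomorphism"]), 0.2)
  # redundancy archetype: near-duplicate singles, combo equal to one single
  db_r <- da + 0.05 * rnorm(K)
  f_r <- fit_combo_model(da, db_r, da)
  red <- score_subtypes(data.frame(
    gene_a = "A", gene_b = "B", c_a = f_r$c_a, c_b = f_r$c_b,
    fit_corr = f_r$fit_corr, degenerate = f_r$degenerate,
    sim_corr = f_r$sim_corr, norm_a = f_r$norm_a, norm_b = f_r$norm_b,
    norm_ab = f_r$norm_ab))
  expect_gt(red$redundancy, 0.45)
  expect_gt(red$redundancy, max(sc$redundancy))
})

test_that("planted subtypes are perfectly ranked from noise-free profiles", {
  sim <- sim_noise0()
  keys <- c(sim$truth$singles, sim$truth$pairs$condition)
  deltas <- measured_deltas(sim$dataset, keys)
  tab <- gi_score_table(deltas)
  expect_equal(nrow(tab), nrow(sim$truth$pairs))
  for (st in perturbgraph:::gi_subtypes) {
    planted <- tab$condition %in%
      sim$truth$pairs$condition[sim$truth$pairs$subtype == st]
    ok <- perturbgraph:::gi_rankable(tab, st)
    bm <- benchmark_ranking(tab[[st]][ok], tab[[st]][ok], k = 5,
                            truth_positive = planted[ok])
    expect_equal(bm$precision_at_k, 1, info = st)
  }
})

test_that("ranking benchmark matches its definitions and the random null", {
  set.seed(33)
  n <- 120
  truth <- rnorm(n)
  # predicted == truth: top-10 accuracy 1; precision@10 = density in own top 10
  bm <- benchmark_ranking(truth, truth, k = 10)
  expect_equal(bm$topk_accuracy, 1)
  expect_equal(bm$precision_at_k, 1)          # upper decile of n=120 covers top 10
  # reversed ranking with positives in the truth's top decile
  bm_rev <- benchmark_ranking(-truth, truth, k = 10)
  expect_equal(bm_rev$topk_accuracy, 0)
  expect_equal(bm_rev$precision_at_k, 0)
  expect_error(benchmark_ranking(truth[1:5], truth[1:5], k = 10), "fewer pairs")
  # PR curve reaches full recall and has precisions in [0, 1]
  expect_equal(max(bm$pr_curve$recall), 1)
  expect_true(all(bm$pr_curve$precision >= 0 & bm$pr_curve$precision <= 1))
  # Monte-Carlo random ranking approaches m/n
  rr <- random_ranking_precision(100, 17, k = 10, draws = 1000, seed = 2)
  expect_lt(abs(rr$mean - rr$expected), 3 * rr$se)
})

test_that("gi_map enumerates unordered pairs and scores symmetrically", {
  m <- tiny_model()
  sim_small <- simulate_perturb_data(
    sim_config(n_genes = 20, n_pathways = 4, n_single = 8, n_double = 4,
               planted = c(synergy = 1), cells_per_condition = 5,
               n_control = 20, seed = 5))
  panel <- sim_small$truth$singles[1:4]
  tab <- gi_map(m, panel, sim_small$dataset, n_ctrl = 3)
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(tab$gene_a < tab$gene_b))    # canonical unordered pairs
  expect_true(all(is.finite(tab$uncertainty)))
  tab2 <- gi_map(m, rev(panel), sim_small$dataset, n_ctrl = 3)
  o1 <- tab[order(tab$condition), ]
  o2 <- tab2[order(tab2$condition), ]
  for (st in perturbgraph:::gi_subtypes)
    expect_equal(o1[[st]], o2[[st]], tolerance = 1e-12)
  expect_error(gi_map(m, c(panel, "NOPE"), sim_small$dataset),
               "no perturbation embedding")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gi_table(tab, f)
  expect_equal(nrow(utils::read.delim(f)), choose(4, 2))
})
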