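test_that("condition canonicalization sorts, deduplicates and is idempotent", {
  expect_equal(canonical_condition(c("ctrl", "FOSB+ctrl", "CEBPB+FOSB")),
               c("ctrl", "FOSB", "CEBPB+FOSB"))
  expect_equal(canonical_condition("FOSB+CEBPB"), "CEBPB+FOSB")
  expect_equal(canonical_condition("A+A+ctrl"), "A")
  expect_equal(canonical_condition(""), "ctrl")
  set.seed(1)
  toks <- c("ctrl", "A", "B", "C", "D")
  raw <- replicate(50, paste(sample(toks, sample(1:4, 1), replace = TRUE),
                             collapse = "+"))
  once <- canonical_condition(raw)
  expect_identical(canonical_condition(once), once)
})

test_that("count matrices are normalized to log1p CP10k; floats pass through", {
  counts <- rbind(c(1, 0), c(0, 2), c(4, 4))
  colnames(counts) <- c("g1", "g2")
  ds <- suppressWarnings(perturb_dataset(counts, rep("A+ctrl", 3)))
  # independent hand-computation of the stated normalization
  manual <- log1p(counts / rowSums(counts) * 1e4)
  expect_equal(unname(ds$expr), unname(manual), tolerance = 1e-12)
  flt <- matrix(c(0.5, 1.2, 0.3, 2.2), 2, 2)
  ds2 <- suppressWarnings(perturb_dataset(flt, rep("ctrl", 2)))
  expect_equal(unname(ds2$expr), flt)
})

test_that("MTX directory loading matches the in-memory constructor", {
  dir <- withr::local_tempdir()
  counts <- rbind(c(1, 0), c(0, 2), c(4, 4))   # 3 cells x 2 genes
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(c("gene_name", "g1", "g2"), file.path(dir, "genes.tsv"))
  writeLines(c("barcode\tcondition", "c1\tctrl", "c2\tA+ctrl", "c3\tB+A"),
             file.path(dir, "barcodes.tsv"))
  ds <- load_dataset(dir)
  expect_equal(ds$genes, c("g1", "g2"))
  expect_equal(ds$conditions, c("ctrl", "A", "A+B"))
  expect_equal(unname(ds$expr), unname(log1p(counts / rowSums(counts) * 1e4)))
  expect_error(load_dataset(dir, perturbation_field = "nope"), "available fields")
  unlink(file.path(dir, "matrix.mtx"))
  expect_error(load_dataset(dir), "no expression matrix")
})

test_that("MTX writer round-trips a dataset deterministically", {
  ds <- tiny_dataset()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset_mtx(ds, d1)
  write_dataset_mtx(ds, d2)
  for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  back <- load_dataset(d1)
  expect_equal(unname(back$expr), unname(ds$expr), tolerance = 1e-10)
  expect_equal(back$conditions, ds$conditions)
})

test_that("unmeasured perturbation targets are retained and flagged", {
  expr <- matrix(1, 4, 2, dimnames = list(NULL, c("g1", "g2")))
  ds <- perturb_dataset(expr, c("ctrl", "ctrl", "g1+ctrl", "gX+ctrl"),
                        normalize = "none")
  expect_equal(ds$unmeasured, "gX")
  expect_true("gX" %in% unlist(ds$pert_sets))
  expect_warning(perturb_dataset(expr, rep("g1+ctrl", 4), normalize = "none"),
                 "no control cells")
})

test_that("condition summaries: deltas, DE ranking and control invariance", {
  ds <- tiny_dataset()
  s <- summarize_condition(ds, "GA")
  expect_equal(unname(s$mean_delta), c(2, 0))
  expect_equal(s$top_de_genes[1], "GA")
  ctrl <- summarize_condition(ds, "ctrl")
  expect_identical(unname(ctrl$mean_delta), c(0, 0))
  expect_error(summarize_condition(ds, "nope"), "unknown condition")
  # planted effects: top-20 DE set equals the 20 largest |effect| entries
  sim <- sim_noise0()
  key <- sim$truth$singles[1]
  s2 <- summarize_condition(sim$dataset, key)
  e <- sim$truth$effects[[key]]
  brute <- sim$dataset$genes[order(-abs(e), seq_along(e))][1:20]
  expect_identical(utils::head(s2$top_de_genes, 20), brute)
})

test_that("splits are reproducible, leak-free and class-labeled", {
  ds <- random_dataset()
  sp1 <- make_split(ds, "single", seed = 4)
  sp2 <- make_split(ds, "single", seed = 4)
  expect_identical(sp1, sp2)
  expect_length(intersect(sp1$test, sp1$train), 0)
  expect_length(intersect(condition_cells(ds, sp1$test),
                          condition_cells(ds, sp1$train)), 0)
  expect_true(all(sp1$test_class == "single_unseen"))
  # combo mode: class equals the number of constituents seen in training
  for (seed in 1:6) {
    sp <- make_split(ds, "combo", fractions = c(train = 0.5, test = 0.5),
                     seed = seed)
    train_targets <- unique(unlist(lapply(sp$train, condition_targets)))
    for (k in sp$test) {
      tg <- condition_targets(k)
      expected <- if (length(tg) == 1) "single_unseen" else
        paste0("combo_seen", sum(tg %in% train_targets))
      expect_identical(unname(sp$test_class[k]), expected)
    }
  }
  expect_error(make_split(ds, "single", fractions = c(train = 0.9, test = 0.3)),
               "at most 1")
})

test_that("split plans round-trip through JSON", {
  ds <- random_dataset()
  sp <- make_split(ds, "combo", seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  back <- read_split(f)
  expect_equal(back$train, sp$train)
  expect_equal(back$test, sp$test)
  expect_equal(unname(back$test_class), unname(sp$test_class))
})
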