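#' Canonicalize a perturbation condition string
#'
#' Condition strings follow the common Perturb-seq dialect: \code{"ctrl"} for
#' unperturbed cells, \code{"GENE+ctrl"} for single-gene perturbations and
#' \code{"GENE1+GENE2"} for two-gene perturbations. Canonicalization drops
#' \code{"ctrl"} tokens, deduplicates, sorts alphabetically and joins with
#' \code{"+"}, so that \code{"A+B"} and \code{"B+A"} name the same condition.
#' The empty set canonicalizes to \code{"ctrl"}. The function is idempotent.
#'
#' @param x character vector of condition strings.
#' @return character vector of canonical condition keys.
#' @export
#' @examples
#' canonical_condition(c("ctrl", "FOSB+ctrl", "CEBPB+FOSB", "FOSB+CEBPB"))
canonical_condition <- function(x) {
  vapply(strsplit(as.character(x), "+", fixed = TRUE), function(tok) {
    tok <- sort(unique(tok[nzchar(tok) & tok != "ctrl"]))
    if (length(tok) == 0L) "ctrl" else paste(tok, collapse = "+")
  }, character(1))
}

#' Perturbation targets of a canonical condition key
#' @param key a single canonical condition key.
#' @return character vector of target gene identifiers (length 0 for "ctrl").
#' @export
condition_targets <- function(key) {
  if (identical(key, "ctrl")) character(0) else strsplit(key, "+", fixed = TRUE)[[1]]
}

#' Construct a perturbation dataset
#'
#' Container for a cells-by-genes expression matrix with per-cell perturbation
#' labels. Expression is expected on a log scale (non-negative floats). If the
#' matrix is integer-valued it is taken to be raw counts and is normalized to
#' counts-per-10k per cell followed by \code{log1p}; already-float matrices are
#' taken as normalized.
#'
#' Perturbed gene identifiers that do not match a column of the expression
#' matrix are retained (they still name a perturbation and can receive a
#' perturbation embedding) but flagged \code{unmeasured}; they are excluded
#' from expression-space metrics, never silently dropped.
#'
#' @param expression numeric matrix, N cells x K genes. Column names are gene
#'   identifiers (generated if absent).
#' @param conditions character vector of length N of condition strings (any
#'   dialect accepted by [canonical_condition()]).
#' @param normalize one of "auto", "none", "log1p_cp10k". "auto" normalizes
#'   only integer-valued matrices.
#' @return an object of class \code{perturb_dataset} with fields
#'   \code{expr} (N x K matrix), \code{genes}, \code{conditions} (canonical
#'   per-cell keys), \code{pert_sets} (list of per-cell target sets),
#'   \code{unmeasured} (targets absent from the expression columns) and
#'   \code{n_control}.
#' @export
perturb_dataset <- function(expression, conditions,
                            normalize = c("auto", "none", "log1p_cp10k")) {
  normalize <- match.arg(normalize)
  expression <- as.matrix(expression)
  if (!is.numeric(expression)) stop("expression must be numeric")
  if (length(conditions) != nrow(expression))
    stop("length(conditions) must equal nrow(expression)")
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("G", seq_len(ncol(expression)))
  is_counts <- all(expression >= 0) && all(expression == round(expression)) &&
    max(expression) > 0
  if (normalize == "log1p_cp10k" || (normalize == "auto" && is_counts)) {
    libsize <- rowSums(expression)
    libsize[libsize == 0] <- 1
    expression <- log1p(expression / libsize * 1e4)
  }
  keys <- canonical_condition(conditions)
  pert_sets <- lapply(keys, condition_targets)
  targets <- unique(unlist(pert_sets))
  unmeasured <- setdiff(targets, colnames(expression))
  n_control <- sum(keys == "ctrl")
  if (n_control == 0L)
    warning("dataset has no control cells; delta computation and training require controls")
  structure(list(
    expr = expression,
    genes = colnames(expression),
    conditions = keys,
    pert_sets = pert_sets,
    unmeasured = unmeasured,
    n_control = n_control
  ), class = "perturb_dataset")
}

#' @export
print.perturb_dataset <- function(x, ...) {
  cat(sprintf("perturb_dataset: %d cells x %d genes\n", nrow(x$expr), ncol(x$expr)))
  nc <- table(factor(vapply(x$pert_sets, length, integer(1))))
  cat(sprintf("  conditions: %d (%d control cells)\n",
              length(unique(x$conditions)), x$n_control))
  cat("  cells by perturbation-set size: ",
      paste(sprintf("M=%s: %d", names(nc), as.integer(nc)), collapse = ", "), "\n")
  if (length(x$unmeasured))
    cat("  unmeasured perturbation targets:", paste(x$unmeasured, collapse = ", "), "\n")
  invisible(x)
}

#' Condition keys present in a dataset
#' @param ds a perturb_dataset.
#' @param type "all", "single", "combo" or "ctrl".
#' @return character vector of canonical keys.
#' @export
dataset_conditions <- function(ds, type = c("all", "single", "combo", "ctrl")) {
  type <- match.arg(type)
  keys <- unique(ds$conditions)
  m <- vapply(keys, function(k) length(condition_targets(k)), integer(1))
  switch(type,
         all = keys,
         single = keys[m == 1L],
         combo = keys[m >= 2L],
         ctrl = keys[m == 0L])
}

#' Load a perturbation dataset from disk
#'
#' Supports two layouts: a MatrixMarket directory (\code{matrix.mtx} with genes
#' as rows and cells as columns, \code{genes.tsv}, \code{barcodes.tsv} whose
#' header or second column carries the per-cell condition), or an AnnData
#' \code{.h5ad} file, which is converted through the Python \code{anndata}
#' package if one is available on the PATH.
#'
#' @param path directory containing the MTX triplet, or an .h5ad file.
#' @param perturbation_field name of the per-cell annotation column carrying
#'   condition strings (default "condition").
#' @param ... passed to [perturb_dataset()].
#' @return a [perturb_dataset()].
#' @export
load_dataset <- function(path, perturbation_field = "condition", ...) {
  if (dir.exists(path)) {
    return(load_dataset_mtx(path, perturbation_field, ...))
  }
  if (grepl("\\.h5ad$", path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    tmp <- tempfile("h5ad_mtx_")
    code <- sprintf(paste0(
      "import anndata, scipy.io, scipy.sparse, numpy as np, os\n",
      "ad = anndata.read_h5ad(%s)\n",
      "os.makedirs(%s, exist_ok=True)\n",
      "X = scipy.sparse.csr_matrix(ad.X)\n",
      "scipy.io.mmwrite(os.path.join(%s,'matrix.mtx'), X.T)\n",
      "ad.var.to_csv(os.path.join(%s,'genes.tsv'), sep='\\t')\n",
      "ad.obs.to_csv(os.path.join(%s,'barcodes.tsv'), sep='\\t')\n"),
      deparse(path), deparse(tmp), deparse(tmp), deparse(tmp), deparse(tmp))
    status <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                       stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L))
      stop("reading .h5ad requires a Python interpreter with the anndata package; ",
           "conversion failed for ", path)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    return(load_dataset_mtx(tmp, perturbation_field, ...))
  }
  stop("path must be an MTX directory or an .h5ad file: ", path)
}

load_dataset_mtx <- function(dir, perturbation_field, ...) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no expression matrix found at ", mtx)
  m <- Matrix::readMM(mtx)            # genes x cells (CellRanger orientation)
  genes_f <- file.path(dir, "genes.tsv")
  cells_f <- file.path(dir, "barcodes.tsv")
  if (!file.exists(genes_f) || !file.exists(cells_f))
    stop("MTX directory must contain genes.tsv and barcodes.tsv")
  genes <- utils::read.delim(genes_f, header = looks_like_header(genes_f),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_f, header = looks_like_header(cells_f),
                             stringsAsFactors = FALSE)
  gene_ids <- if ("gene_name" %in% names(genes)) genes$gene_name else genes[[1]]
  if (perturbation_field %in% names(cells)) {
    cond <- cells[[perturbation_field]]
  } else if (!looks_like_header(cells_f) && ncol(cells) >= 2) {
    cond <- cells[[2]]
  } else {
    stop("perturbation field '", perturbation_field,
         "' not found; available fields: ", paste(names(cells), collapse = ", "))
  }
  x <- t(as.matrix(m))
  colnames(x) <- gene_ids
  perturb_dataset(x, cond, ...)
}

looks_like_header <- function(f) {
  first <- strsplit(readLines(f, n = 1L), "\t")[[1]]
  any(tolower(first) %in% c("gene", "gene_id", "gene_name", "barcode",
                            "cell", "condition", "perturbation"))
}

#' Write a dataset as an MTX triplet directory
#'
#' Emits \code{matrix.mtx} (genes x cells, real-valued), \code{genes.tsv} and
#' \code{barcodes.tsv} with a header carrying the condition column. Output is
#' deterministic: the same dataset always produces byte-identical files.
#'
#' @param ds a perturb_dataset.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset_mtx <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(ds$expr), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(c("gene_name", ds$genes), file.path(dir, "genes.tsv"))
  bc <- c("barcode\tcondition",
          sprintf("cell%d\t%s", seq_len(nrow(ds$expr)), ds$conditions))
  writeLines(bc, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

control_mean <- function(ds) {
  if (ds$n_control == 0L) stop("dataset has no control cells")
  colMeans(ds$expr[ds$conditions == "ctrl", , drop = FALSE])
}

#' Summarize a perturbation condition
#'
#' Computes the condition's mean expression, its differential expression over
#' the control mean (\code{mean_delta}), and the differential-expression
#' ranking of genes (by absolute mean delta on the log scale, ties broken by
#' gene index), which downstream metrics truncate to a top-k set.
#'
#' @param ds a perturb_dataset.
#' @param condition_key a condition string (canonicalized internally).
#' @return an object of class \code{condition_summary}: list with
#'   \code{condition}, \code{mean_expression}, \code{mean_delta},
#'   \code{n_cells}, \code{top_de_genes} (all K genes in rank order).
#' @export
summarize_condition <- function(ds, condition_key) {
  key <- canonical_condition(condition_key)
  idx <- which(ds$conditions == key)
  if (length(idx) == 0L) stop("unknown condition: ", key)
  mu <- colMeans(ds$expr[idx, , drop = FALSE])
  delta <- mu - control_mean(ds)
  condition_summary(key, mu, delta, length(idx), ds$genes)
}

condition_summary <- function(key, mean_expression, mean_delta, n_cells, genes) {
  ord <- order(-abs(mean_delta), seq_along(mean_delta))
  structure(list(
    condition = key,
    mean_expression = stats::setNames(mean_expression, genes),
    mean_delta = stats::setNames(mean_delta, genes),
    n_cells = n_cells,
    top_de_genes = genes[ord]
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, n = 10, ...) {
  cat(sprintf("condition_summary '%s' (%d cells)\n", x$condition, x$n_cells))
  top <- utils::head(x$top_de_genes, n)
  cat("  top DE genes (|mean delta|):\n")
  for (g in top) cat(sprintf("    %-12s %+0.3f\n", g, x$mean_delta[g]))
  invisible(x)
}

#' Write condition summaries as a TSV table
#' @param summaries a list of condition_summary objects.
#' @param path output file.
#' @export
write_condition_summaries <- function(summaries, path) {
  rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, gene = names(s$mean_delta),
               mean_expression = unname(s$mean_expression),
               mean_delta = unname(s$mean_delta),
               de_rank = match(names(s$mean_delta), s$top_de_genes),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a train/validation/test split over perturbation conditions
#'
#' Splitting is done at condition level so that held-out perturbations are
#' entirely unseen: every cell of a test single-gene condition is excluded
#' from training. Control cells always remain available to training. In
#' \code{combo} mode both single- and two-gene conditions are split, and each
#' two-gene test condition is labeled by how many of its constituent genes
#' appear as perturbation targets in the realized training conditions:
#' \code{combo_seen2} (both seen), \code{combo_seen1} (one of two unseen),
#' \code{combo_seen0} (two of two unseen). Held-out singles are labeled
#' \code{single_unseen}.
#'
#' @param ds a perturb_dataset.
#' @param mode "single" (split singles only) or "combo" (split singles and
#'   combos).
#' @param fractions named numeric: train/val/test fractions, summing to at
#'   most 1 (remainder goes to train).
#' @param seed integer seed; the plan is reproducible from it.
#' @return an object of class \code{split_plan}: list with \code{train},
#'   \code{val}, \code{test} (condition keys; train includes "ctrl"),
#'   \code{test_class} (named character), \code{seed}, \code{mode}.
#' @export
make_split <- function(ds, mode = c("single", "combo"),
                       fractions = c(train = 0.75, val = 0.0, test = 0.25),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (sum(fractions) > 1 + 1e-9) stop("fractions must sum to at most 1")
  fr_val <- if ("val" %in% names(fractions)) fractions[["val"]] else 0
  fr_test <- if ("test" %in% names(fractions)) fractions[["test"]] else
    stop("fractions must name a 'test' fraction")
  singles <- dataset_conditions(ds, "single")
  combos <- dataset_conditions(ds, "combo")
  if (mode == "combo" && length(combos) == 0L)
    stop("mode 'combo' requires at least one multi-gene condition")
  rng <- local({ set.seed(as.integer(seed)); NULL })
  split_pool <- function(pool) {
    pool <- sample(pool)
    n <- length(pool)
    n_test <- round(fr_test * n)
    n_val <- round(fr_val * n)
    list(test = pool[seq_len(n_test)],
         val = pool[n_test + seq_len(n_val)],
         train = pool[-seq_len(n_test + n_val)][
           seq_len(max(0L, n - n_test - n_val))])
  }
  s <- split_pool(singles)
  if (mode == "combo") {
    cmb <- split_pool(combos)
    train <- c(s$train, cmb$train); val <- c(s$val, cmb$val)
    test <- c(s$test, cmb$test)
  } else {
    train <- c(s$train, combos); val <- s$val; test <- s$test
  }
  train_targets <- unique(unlist(lapply(train, condition_targets)))
  cls <- vapply(test, function(k) {
    tg <- condition_targets(k)
    if (length(tg) == 1L) "single_unseen"
    else paste0("combo_seen", sum(tg %in% train_targets))
  }, character(1))
  structure(list(train = c("ctrl", train), val = val, test = test,
                 test_class = cls, seed = as.integer(seed), mode = mode),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (mode=%s, seed=%d): %d train / %d val / %d test conditions\n",
              x$mode, x$seed, length(x$train), length(x$val), length(x$test)))
  if (length(x$test)) print(table(x$test_class))
  invisible(x)
}

#' Cell indices belonging to a set of conditions
#' @param ds a perturb_dataset.
#' @param keys condition keys.
#' @return integer vector of row indices into \code{ds$expr}.
#' @export
condition_cells <- function(ds, keys) which(ds$conditions %in% keys)

#' Write / read a split plan as JSON
#' @param plan a split_plan.
#' @param path JSON file path.
#' @export
write_split <- function(plan, path) {
  obj <- list(mode = plan$mode, seed = plan$seed,
              train = plan$train, val = plan$val,
              test = lapply(seq_along(plan$test), function(i)
                list(condition = plan$test[i], class = unname(plan$test_class[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  test <- obj$test
  structure(list(train = obj$train, val = obj$val %||% character(0),
                 test = test$condition,
                 test_class = stats::setNames(test$class, test$condition),
                 seed = obj$seed, mode = obj$mode),
            class = "split_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
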