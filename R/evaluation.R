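# Prediction metrics. All metric functions take two condition_summary
# objects: the prediction and the measured truth. DE-gene sets used by the
# top-k metrics come from the measured truth, never from the prediction --
# except jaccard_de, where the predicted DE set is by definition
# model-derived.

top_k_genes <- function(summary, k) {
  if (k > length(summary$top_de_genes)) stop("k exceeds the number of genes")
  utils::head(summary$top_de_genes, k)
}

#' MSE over the truth's top differentially expressed genes
#'
#' Mean squared error of postperturbation expression restricted to the
#' measured condition's top-k DE genes (most genes barely move under
#' perturbation; restricting to DE genes makes the task discriminative).
#'
#' @param pred,truth condition_summary objects; truth from measured data.
#' @param k number of DE genes (default 20).
#' @return scalar MSE.
#' @export
mse_top_de <- function(pred, truth, k = 20) {
  genes <- top_k_genes(truth, k)
  mean((pred$mean_expression[genes] - truth$mean_expression[genes])^2)
}

#' Pearson correlation of differential expression over all genes
#'
#' Correlation between predicted and measured mean delta (expression change
#' over control) across every gene. Zero-variance inputs give 0 rather than
#' NaN.
#'
#' @param pred,truth condition_summary objects.
#' @return correlation in [-1, 1].
#' @export
pearson_delta <- function(pred, truth) {
  x <- pred$mean_delta; y <- truth$mean_delta[names(x)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Fraction of top DE genes predicted in the wrong direction
#'
#' Over the truth's top-k DE genes, the fraction whose predicted delta has a
#' different sign than the measured delta (sign(0) = 0, so a zero prediction
#' against a nonzero truth counts as a flip).
#'
#' @inheritParams mse_top_de
#' @return fraction in [0, 1].
#' @export
direction_flip_fraction <- function(pred, truth, k = 20) {
  genes <- top_k_genes(truth, k)
  mean(sign(pred$mean_delta[genes]) != sign(truth$mean_delta[genes]))
}

#' Jaccard similarity of predicted and measured top DE gene sets
#'
#' @inheritParams mse_top_de
#' @return Jaccard index in [0, 1].
#' @export
jaccard_de <- function(pred, truth, k = 20) {
  a <- top_k_genes(pred, k); b <- top_k_genes(truth, k)
  length(intersect(a, b)) / length(union(a, b))
}

#' Evaluate a model or baseline on the test conditions of a split
#'
#' For every test condition, predicts the mean postperturbation profile and
#' scores it against the measured condition summary: top-20-DE MSE (raw and
#' normalized per condition to the no-perturbation baseline), Pearson
#' correlation of deltas over all genes, direction-flip fraction and Jaccard
#' similarity of DE sets. Results are stratified by generalization class and
#' aggregated as mean with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 SEM over conditions).
#'
#' @param object what to evaluate: a fitted [gears()] model, a
#'   \code{linear_grn} object from [infer_grn()], or one of the strings
#'   \code{"no_perturbation"} / \code{"additive"} (the additive baseline sums
#'   the two measured single-gene deltas and falls back to no-perturbation
#'   for non-combo conditions).
#' @param ds the measured perturb_dataset.
#' @param split a split_plan whose \code{test} conditions are evaluated.
#' @param k DE-set size for the top-k metrics.
#' @param n_ctrl control cells sampled per prediction (gears models).
#' @param seed seed for control sampling.
#' @return object of class \code{metric_report}: list with
#'   \code{per_condition} (data.frame) and \code{aggregate} (data.frame of
#'   mean and 95% CI per class and overall).
#' @export
evaluate <- function(object, ds, split, k = 20, n_ctrl = 30, seed = 1L) {
  keys <- intersect(split$test, dataset_conditions(ds))
  if (length(keys) == 0L) stop("empty test split")
  cmean <- control_mean(ds)
  none <- function(key) condition_summary(key, cmean, cmean * 0, 0L, ds$genes)
  predict_one <- function(key) {
    if (inherits(object, "gears"))
      return(predict_condition_mean(object, key, ds, n_ctrl = n_ctrl, seed = seed))
    if (inherits(object, "linear_grn"))
      return(grn_linear_baseline(ds, key, grn = object))
    if (identical(object, "no_perturbation"))
      return(no_perturbation_baseline(ds, key))
    if (identical(object, "additive")) {
      tg <- condition_targets(key)
      if (length(tg) == 2L) {
        singles <- canonical_condition(paste0(tg, "+ctrl"))
        avail <- singles %in% ds$conditions
        if (all(avail))
          return(additive_baseline(summarize_condition(ds, singles[1]),
                                   summarize_condition(ds, singles[2])))
      }
      return(none(key))
    }
    stop("cannot evaluate object of class ", paste(class(object), collapse = "/"))
  }
  rows <- lapply(keys, function(key) {
    truth <- summarize_condition(ds, key)
    pred <- predict_one(key)
    base_mse <- mse_top_de(none(key), truth, k)
    m <- mse_top_de(pred, truth, k)
    data.frame(
      condition = key,
      class = if (key %in% names(split$test_class))
        unname(split$test_class[key]) else NA_character_,
      mse_top20 = m,
      mse_top20_normalized = if (base_mse > 0) m / base_mse else NA_real_,
      pearson_delta_allgenes = pearson_delta(pred, truth),
      direction_flip_fraction = direction_flip_fraction(pred, truth, k),
      jaccard_de = jaccard_de(pred, truth, k),
      stringsAsFactors = FALSE)
  })
  per_condition <- do.call(rbind, rows)
  structure(list(per_condition = per_condition,
                 aggregate = aggregate_metrics(per_condition)),
            class = "metric_report")
}

metric_cols <- c("mse_top20", "mse_top20_normalized", "pearson_delta_allgenes",
                 "direction_flip_fraction", "jaccard_de")

mean_ci <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  c(mean = mean(x), lo = mean(x) - 1.96 * se, hi = mean(x) + 1.96 * se, n = n)
}

aggregate_metrics <- function(per_condition) {
  strata <- c(list(overall = per_condition),
              split(per_condition, per_condition$class))
  do.call(rbind, lapply(names(strata), function(nm) {
    df <- strata[[nm]]
    out <- do.call(rbind, lapply(metric_cols, function(mc) {
      ci <- mean_ci(df[[mc]])
      data.frame(class = nm, metric = mc, mean = ci[["mean"]],
                 ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
                 n = as.integer(ci[["n"]]), stringsAsFactors = FALSE)
    }))
    out
  }))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report over %d test conditions\n", nrow(x$per_condition)))
  ov <- x$aggregate[x$aggregate$class == "overall", ]
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %-26s %6.3f  [%.3f, %.3f]\n",
                ov$metric[i], ov$mean[i], ov$ci_lo[i], ov$ci_hi[i]))
  cls <- setdiff(unique(x$aggregate$class), "overall")
  if (length(cls) > 1)
    cat("  classes:", paste(sprintf("%s (n=%d)", cls,
        x$aggregate$n[match(cls, x$aggregate$class)]), collapse = ", "), "\n")
  invisible(x)
}

#' Combine metric reports from models trained on different splits/seeds
#'
#' Aggregates the per-condition tables of several reports and recomputes the
#' mean and 95% CI over the reports' per-report means (the across-seed
#' uncertainty, as distinct from the across-condition CI within one report).
#'
#' @param reports list of metric_report objects.
#' @return data.frame: metric, mean, ci_lo, ci_hi, n_models.
#' @export
combine_metric_reports <- function(reports) {
  do.call(rbind, lapply(metric_cols, function(mc) {
    means <- vapply(reports, function(r)
      mean(r$per_condition[[mc]][is.finite(r$per_condition[[mc]])]), numeric(1))
    ci <- mean_ci(means)
    data.frame(metric = mc, mean = ci[["mean"]], ci_lo = ci[["lo"]],
               ci_hi = ci[["hi"]], n_models = length(reports),
               stringsAsFactors = FALSE)
  }))
}

#' Write a metric report as TSV (per condition) and JSON (aggregate)
#' @param report a metric_report.
#' @param tsv,json output paths (either may be NULL to skip).
#' @export
write_metric_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report$per_condition, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report$aggregate, json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}
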