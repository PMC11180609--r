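# Genetic-interaction scoring of two-gene perturbations. The combo delta is
# regressed on the two single deltas over the union of the three conditions'
# top-20 DE genes; the fitted coefficients (c_a, c_b) and the quality of the
# linear fit define five monotone subtype scores: synergy, suppression,
# neomorphism, redundancy and epistasis.

#' Regress a combo's expression change on its two singles'
#'
#' Least-squares fit delta_ab ~ c_a * delta_a + c_b * delta_b over the gene
#' mask (default: union of the top-20 DE genes of the three conditions).
#' Rank-deficient systems (collinear singles) take the minimum-norm solution;
#' pairs with collinear or near-zero singles are flagged \code{degenerate}
#' and excluded from regression-based subtype rankings downstream.
#'
#' @param delta_a,delta_b,delta_ab length-K named delta vectors (measured or
#'   predicted mean expression change over control).
#' @param gene_mask gene names or indices to fit over; NULL for the default
#'   DE-union mask.
#' @param k DE-set size per condition for the default mask.
#' @return list with \code{c_a}, \code{c_b}, \code{fit_corr} (Pearson between
#'   fitted and actual combo delta on the mask), \code{degenerate},
#'   \code{sim_corr} (cor(delta_a, delta_b) over all genes),
#'   \code{norm_a}, \code{norm_b}, \code{norm_ab} and \code{mask}.
#' @export
fit_combo_model <- function(delta_a, delta_b, delta_ab, gene_mask = NULL, k = 20) {
  stopifnot(length(delta_a) == length(delta_b),
            length(delta_a) == length(delta_ab))
  if (is.null(gene_mask)) {
    top <- function(d) order(-abs(d), seq_along(d))[seq_len(min(k, length(d)))]
    gene_mask <- sort(unique(c(top(delta_a), top(delta_b), top(delta_ab))))
  }
  a <- delta_a[gene_mask]; b <- delta_b[gene_mask]; y <- delta_ab[gene_mask]
  na <- sqrt(sum(delta_a^2)); nb <- sqrt(sum(delta_b^2))
  sim <- if (na > 0 && nb > 0) sum(delta_a * delta_b) / (na * nb) else 0
  degenerate <- na < 1e-10 || nb < 1e-10 || abs(sim) > 0.995
  X <- cbind(a, b)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  cf <- if (any(pos))
    sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  else c(0, 0)
  cf <- drop(cf)
  fitted <- drop(X %*% cf)
  fit_corr <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
    stats::cor(fitted, y) else 0
  list(c_a = cf[1], c_b = cf[2], fit_corr = fit_corr, degenerate = degenerate,
       sim_corr = sim, norm_a = na, norm_b = nb,
       norm_ab = sqrt(sum(delta_ab^2)), mask = gene_mask)
}

#' Score genetic-interaction subtypes from combo fits
#'
#' Takes a data.frame of per-pair fit results (one row per unordered gene
#' pair, with the columns returned by [fit_combo_model()]) and adds monotone
#' subtype scores (higher = more of that subtype):
#' \describe{
#'   \item{magnitude}{||(c_a, c_b)||_2, the fitted combined effect scale.}
#'   \item{synergy}{= magnitude; a combo exceeding the additive expectation
#'     fits with coefficients above 1.}
#'   \item{suppression}{= -magnitude - (1 - fit_corr); small coefficients
#'     with a good linear fit (a poor fit is neomorphic, not suppressed).}
#'   \item{neomorphism}{= -fit_corr; the combo is poorly explained by any
#'     linear combination of the singles.}
#'   \item{equality}{min(|c_a|,|c_b|)/max(|c_a|,|c_b|), the equality of the
#'     two genes' contributions.}
#'   \item{redundancy}{cor(delta_a, delta_b) * max(0, 1 - |d_ab|/(|d_a|+|d_b|)):
#'     interchangeable singles with a sub-additive combo.}
#'   \item{epistasis}{dominance ||c_a|-|c_b|| / magnitude, discounted by
#'     (1 - max(0, sim_corr)) and by max(0, fit_corr): one gene's effect
#'     masks the other's. The discounts keep the axis identifiable -- with
#'     interchangeable singles "which gene dominates" is undefined (the pair
#'     is redundant), and with a fit that explains nothing the coefficient
#'     ratio is noise (the pair is neomorphic).}
#' }
#'
#' @param fits data.frame with columns gene_a, gene_b, c_a, c_b, fit_corr,
#'   degenerate, sim_corr, norm_a, norm_b, norm_ab (e.g. rows of
#'   [fit_combo_model()] results).
#' @return the data.frame with score columns appended, of class
#'   \code{gi_score_table}.
#' @export
score_subtypes <- function(fits) {
  stopifnot(all(c("c_a", "c_b", "fit_corr", "sim_corr", "norm_a", "norm_b",
                  "norm_ab") %in% names(fits)))
  mag <- sqrt(fits$c_a^2 + fits$c_b^2)
  fits$magnitude <- mag
  fits$synergy <- mag
  fits$suppression <- -mag - (1 - fits$fit_corr)
  fits$neomorphism <- -fits$fit_corr
  hi <- pmax(abs(fits$c_a), abs(fits$c_b))
  lo <- pmin(abs(fits$c_a), abs(fits$c_b))
  fits$equality <- ifelse(hi > 1e-8, lo / hi, 0)
  fits$redundancy <- fits$sim_corr *
    pmax(0, 1 - fits$norm_ab / pmax(fits$norm_a + fits$norm_b, 1e-12))
  fits$epistasis <- ifelse(mag > 1e-8,
                           abs(abs(fits$c_a) - abs(fits$c_b)) / mag, 0) *
    (1 - pmax(0, fits$sim_corr)) * pmax(0, fits$fit_corr)
  class(fits) <- c("gi_score_table", class(fits))
  fits
}

gi_subtypes <- c("synergy", "suppression", "neomorphism", "redundancy",
                 "epistasis")

# regression-based axes exclude degenerate fits; redundancy does not use the
# regression so degenerate (collinear) pairs stay rankable on it.
gi_rankable <- function(table, subtype) {
  if (subtype == "redundancy") rep(TRUE, nrow(table)) else !table$degenerate
}

#' Score all two-gene conditions of a dataset or prediction set
#'
#' Builds the per-pair fit + subtype score table from a named list of delta
#' vectors: every condition key "A+B" is scored against the singles "A" and
#' "B" (which must be present in the list).
#'
#' @param deltas named list (or matrix with named rows) of mean-delta
#'   vectors, keyed by canonical condition.
#' @param k DE-set size for the fit mask.
#' @return a \code{gi_score_table} data.frame.
#' @export
gi_score_table <- function(deltas, k = 20) {
  if (is.matrix(deltas))
    deltas <- stats::setNames(lapply(seq_len(nrow(deltas)),
                                     function(i) deltas[i, ]), rownames(deltas))
  keys <- names(deltas)
  combos <- keys[vapply(keys, function(x) length(condition_targets(x)) == 2L,
                        logical(1))]
  rows <- lapply(combos, function(key) {
    tg <- condition_targets(key)
    if (!all(tg %in% keys)) return(NULL)
    fit <- fit_combo_model(deltas[[tg[1]]], deltas[[tg[2]]], deltas[[key]], k = k)
    data.frame(gene_a = tg[1], gene_b = tg[2], condition = key,
               c_a = fit$c_a, c_b = fit$c_b, fit_corr = fit$fit_corr,
               degenerate = fit$degenerate, sim_corr = fit$sim_corr,
               norm_a = fit$norm_a, norm_b = fit$norm_b, norm_ab = fit$norm_ab,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no scorable two-gene conditions found")
  score_subtypes(do.call(rbind, rows))
}

#' Rank-based benchmark of predicted genetic-interaction scores
#'
#' Truth-positive pairs are those whose truth score falls in the upper
#' quantile (default decile) of all pairs. precision@k is the fraction of the
#' k top-ranked predicted pairs that are truth-positive; top-k accuracy is
#' the overlap between the predicted and true top-k sets; the
#' precision-recall curve sweeps the predicted-score threshold.
#'
#' @param predicted_scores,truth_scores numeric vectors over the same pairs
#'   (higher = stronger interaction of the subtype).
#' @param k cut-off (default 10).
#' @param positive_quantile truth-calling quantile (default 0.9 = upper
#'   decile).
#' @param truth_positive optional logical vector overriding the quantile rule.
#' @return list with \code{precision_at_k}, \code{topk_accuracy},
#'   \code{pr_curve} (data.frame threshold/precision/recall), \code{k},
#'   \code{n_pairs}, \code{n_positive}.
#' @export
benchmark_ranking <- function(predicted_scores, truth_scores, k = 10,
                              positive_quantile = 0.9, truth_positive = NULL) {
  n <- length(predicted_scores)
  stopifnot(length(truth_scores) == n)
  if (n < k) stop("fewer pairs than k")
  if (is.null(truth_positive)) {
    thr <- stats::quantile(truth_scores, positive_quantile, names = FALSE)
    truth_positive <- truth_scores >= thr
  }
  ord_pred <- order(-predicted_scores, seq_len(n))
  ord_true <- order(-truth_scores, seq_len(n))
  topk_pred <- ord_pred[seq_len(k)]
  topk_true <- ord_true[seq_len(k)]
  pr <- lapply(unique(sort(predicted_scores, decreasing = TRUE)), function(thr) {
    called <- predicted_scores >= thr
    data.frame(threshold = thr,
               precision = if (any(called)) mean(truth_positive[called]) else 1,
               recall = if (any(truth_positive))
                 sum(called & truth_positive) / sum(truth_positive) else 0)
  })
  list(precision_at_k = mean(truth_positive[topk_pred]),
       topk_accuracy = length(intersect(topk_pred, topk_true)) / k,
       pr_curve = do.call(rbind, pr),
       k = k, n_pairs = n, n_positive = sum(truth_positive))
}

#' Expected precision@k of a random ranking
#'
#' Monte-Carlo estimate over random permutations of the pair order, matching
#' the random reference model used in ranking benchmarks; the analytic
#' expectation is m/n (truth-positive density).
#'
#' @param n_pairs number of pairs.
#' @param n_positive number of truth positives.
#' @param k cut-off.
#' @param draws number of random draws (default 1000).
#' @param seed RNG seed.
#' @return list(mean, se, expected = n_positive/n_pairs).
#' @export
random_ranking_precision <- function(n_pairs, n_positive, k = 10, draws = 1000,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  truth <- c(rep(TRUE, n_positive), rep(FALSE, n_pairs - n_positive))
  hits <- vapply(seq_len(draws),
                 function(i) mean(truth[sample(n_pairs, k)]), numeric(1))
  list(mean = mean(hits), se = stats::sd(hits) / sqrt(draws),
       expected = n_positive / n_pairs)
}

#' Predict and score all pairwise combinations of a gene panel
#'
#' Predicts postperturbation profiles for every single and every unordered
#' pair of the panel (n singles + n(n-1)/2 doubles) with a fitted model, then
#' fits and scores every pair for the five interaction subtypes. Pairs whose
#' genes were never perturbed in training and sit isolated in the
#' perturbation graph are not dropped; their prediction uncertainty column
#' flags them as low-confidence.
#'
#' @param model a fitted [gears()] model.
#' @param gene_panel character vector of n panel genes (must have
#'   perturbation embeddings).
#' @param ds dataset supplying control cells.
#' @param k DE-set size for fit masks.
#' @param n_ctrl,seed control sampling for the predictions.
#' @return a \code{gi_score_table} with one row per unordered pair and an
#'   \code{uncertainty} column.
#' @export
gi_map <- function(model, gene_panel, ds, k = 20, n_ctrl = 30, seed = 1L) {
  gene_panel <- unique(gene_panel)
  n <- length(gene_panel)
  if (n < 2) stop("panel needs at least 2 genes")
  missing <- setdiff(gene_panel, model$pert_genes)
  if (length(missing))
    stop("no perturbation embedding for panel genes: ",
         paste(missing, collapse = ", "))
  pairs <- t(utils::combn(gene_panel, 2))
  pair_keys <- canonical_condition(paste(pairs[, 1], pairs[, 2], sep = "+"))
  keys <- c(gene_panel, pair_keys)
  pd <- predict_deltas(model, keys)
  zh <- pd$z_hat
  sh <- pd$s
  deltas <- stats::setNames(lapply(seq_len(nrow(zh)), function(i) zh[i, ]), keys)
  tab <- gi_score_table(deltas, k = k)
  unc <- vapply(tab$condition, function(key) {
    i <- match(key, keys)
    aggregate_uncertainty(zh[i, ], sh[i, ], model$config$uncertainty_aggregate)
  }, numeric(1))
  tab$uncertainty <- unname(unc)
  tab
}

#' Write a genetic-interaction score table as TSV
#' @param table a gi_score_table.
#' @param path output file.
#' @export
write_gi_table <- function(table, path) {
  cols <- c("gene_a", "gene_b", "c_a", "c_b", "fit_corr", gi_subtypes,
            intersect("uncertainty", names(table)))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
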