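# Non-deep baselines: the no-perturbation predictor, the naive additive
# model for two-gene combinations, and a linear GRN-propagation model that
# infers a regulatory weight matrix and pushes a shift on the target genes
# through it.

#' No-perturbation baseline
#'
#' Predicts that perturbation changes nothing: the control mean is returned
#' for every condition. Its own top-k-DE MSE defines the normalization unit
#' for the normalized MSE metric.
#'
#' @param ds a perturb_dataset.
#' @param condition condition key (kept on the returned summary).
#' @return a condition_summary with zero mean_delta.
#' @export
no_perturbation_baseline <- function(ds, condition) {
  cmean <- control_mean(ds)
  condition_summary(canonical_condition(condition), cmean, cmean * 0, 0L, ds$genes)
}

#' Additive baseline for a two-gene combination
#'
#' Predicts the combo delta as the sum of the two measured single-gene deltas
#' (the additive null that genetic-interaction scoring measures deviations
#' from).
#'
#' @param summary_a,summary_b measured condition_summary objects of the two
#'   single-gene perturbations.
#' @return a condition_summary for the combined condition.
#' @export
additive_baseline <- function(summary_a, summary_b) {
  delta <- summary_a$mean_delta + summary_b$mean_delta[names(summary_a$mean_delta)]
  ctrl <- summary_a$mean_expression - summary_a$mean_delta
  key <- canonical_condition(paste(summary_a$condition, summary_b$condition,
                                   sep = "+"))
  condition_summary(key, ctrl + delta, delta, 0L, names(delta))
}

#' Infer a linear gene regulatory network from training cells
#'
#' Per-target ridge regression of each gene on all other genes over the
#' (training) cells; the top-q coefficients by magnitude are kept per target,
#' giving a sparse signed K x K influence matrix W with W[u, v] = the shift
#' in gene u per unit shift in gene v.
#'
#' @param ds a perturb_dataset.
#' @param cells cell indices to fit on (default all; pass the training
#'   partition to avoid leakage).
#' @param top_q regulators kept per target gene.
#' @param ridge_lambda ridge penalty.
#' @param steps default propagation step count carried on the object.
#' @return object of class \code{linear_grn}: list(W, steps, sd) where sd is
#'   the per-gene expression standard deviation used to scale shifts.
#' @export
infer_grn <- function(ds, cells = NULL, top_q = 20, ridge_lambda = 1, steps = 3) {
  x <- if (is.null(cells)) ds$expr else ds$expr[cells, , drop = FALSE]
  K <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  G <- crossprod(xc)                       # K x K Gram matrix
  W <- matrix(0, K, K, dimnames = list(ds$genes, ds$genes))
  for (u in seq_len(K)) {
    beta <- tryCatch(
      solve(G[-u, -u] + ridge_lambda * diag(K - 1), G[-u, u]),
      error = function(e) numeric(K - 1))
    keep <- order(-abs(beta))[seq_len(min(top_q, K - 1))]
    row <- numeric(K)
    row[-u][keep] <- beta[keep]
    W[u, ] <- row
  }
  structure(list(W = W, steps = steps,
                 sd = apply(x, 2, stats::sd)),
            class = "linear_grn")
}

#' @export
print.linear_grn <- function(x, ...) {
  cat(sprintf("linear_grn: %d genes, %d nonzero influences, %d propagation steps\n",
              nrow(x$W), sum(x$W != 0), x$steps))
  invisible(x)
}

#' GRN linear-propagation baseline
#'
#' Places an initial shift on the perturbation's target genes (+1 standard
#' deviation of each target's expression for activation screens; negated for
#' knockdown) and propagates it p steps through the inferred influence
#' matrix: delta = (I + W + ... + W^p) v0. Combos propagate the summed
#' initial vector. Targets absent from the expression matrix contribute zero
#' shift with a warning.
#'
#' @param ds a perturb_dataset.
#' @param condition condition key.
#' @param grn a [infer_grn()] object (inferred from all cells when NULL).
#' @param steps propagation step count p (default: the grn's).
#' @param direction "activation" (+1 sd shift) or "knockdown" (-1 sd).
#' @param cells training cells for GRN inference when grn is NULL.
#' @return a condition_summary.
#' @export
grn_linear_baseline <- function(ds, condition, grn = NULL, steps = NULL,
                                direction = c("activation", "knockdown"),
                                cells = NULL) {
  direction <- match.arg(direction)
  if (is.null(grn)) grn <- infer_grn(ds, cells = cells)
  if (is.null(steps)) steps <- grn$steps
  key <- canonical_condition(condition)
  targets <- condition_targets(key)
  v0 <- stats::setNames(numeric(length(ds$genes)), ds$genes)
  measured <- targets %in% ds$genes
  if (any(!measured))
    warning("unmeasured perturbation targets get zero initial shift: ",
            paste(targets[!measured], collapse = ", "))
  shift <- if (direction == "activation") 1 else -1
  v0[targets[measured]] <- shift * grn$sd[targets[measured]]
  delta <- v0
  cur <- v0
  for (i in seq_len(steps)) {
    cur <- drop(grn$W %*% cur)
    delta <- delta + cur
  }
  cmean <- control_mean(ds)
  condition_summary(key, cmean + delta, delta, 0L, ds$genes)
}
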