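# Training objectives. All three losses average first over genes (1/K), then
# over the cells of each perturbation (1/T_k), then over the perturbations of
# the minibatch (1/T). The error exponent (2+gamma) is applied to the
# magnitude |g - g_hat|: raw signed powers are ill-defined for fractional
# gamma and sign-canceling for odd ones, and a loss must be non-negative.

resolve_groups <- function(pred, groups) {
  if (is.null(groups)) groups <- rep(1L, nrow(pred))
  as.factor(groups)
}

per_group_mean <- function(values, groups) {
  mean(tapply(values, groups, mean))
}

#' Autofocus loss
#'
#' Mean of |g - g_hat|^(2+gamma) over genes and cells, averaged per
#' perturbation group and then over groups. Raising the exponent above 2
#' makes large (differentially expressed) errors dominate the objective; at
#' gamma = 0 it is exactly the per-perturbation-averaged MSE.
#'
#' @param pred,true numeric matrices (cells x genes) of predicted and true
#'   postperturbation expression; vectors are treated as one-cell matrices.
#' @param gamma non-negative exponent offset.
#' @param groups per-cell perturbation labels (default: one group).
#' @return scalar loss.
#' @export
autofocus_loss <- function(pred, true, gamma = 1, groups = NULL) {
  stopifnot(gamma >= 0)
  pred <- rbind(pred); true <- rbind(true)
  groups <- resolve_groups(pred, groups)
  per_cell <- rowMeans(abs(true - pred)^(2 + gamma))
  per_group_mean(per_cell, groups)
}

#' Direction-aware loss
#'
#' Penalizes predicting differential expression in the wrong direction:
#' per gene, [sign(g - g_ctrl) - sign(g_hat - g_ctrl)]^2, which takes values
#' in {0, 1, 4} (0 when signs agree, 1 when exactly one side is zero, 4 for
#' an outright sign flip), with sign(0) = 0. Averaged like the autofocus
#' loss.
#'
#' @inheritParams autofocus_loss
#' @param g_ctrl control expression: a length-K vector or a cells x genes
#'   matrix of paired control cells.
#' @return scalar loss.
#' @export
direction_loss <- function(pred, true, g_ctrl, groups = NULL) {
  pred <- rbind(pred); true <- rbind(true)
  ctrl <- if (is.matrix(g_ctrl)) g_ctrl else
    matrix(g_ctrl, nrow(pred), ncol(pred), byrow = TRUE)
  groups <- resolve_groups(pred, groups)
  per_cell <- rowMeans((sign(true - ctrl) - sign(pred - ctrl))^2)
  per_group_mean(per_cell, groups)
}

#' Uncertainty (Gaussian log-variance) loss
#'
#' Heteroscedastic variant of the autofocus loss: each gene's error term is
#' weighted by exp(-s_u) where s_u is the predicted log variance, plus the
#' regularizing term +s_u that keeps s from diverging (the loss would
#' otherwise be unbounded below in s). With s = 0 everywhere it equals the
#' autofocus loss exactly.
#'
#' @inheritParams autofocus_loss
#' @param s per-gene log variance: length-K vector or cells x genes matrix.
#' @param regularize include the +mean(s) term (default TRUE).
#' @return scalar loss.
#' @export
uncertainty_loss <- function(pred, true, s, gamma = 1, groups = NULL,
                             regularize = TRUE) {
  stopifnot(gamma >= 0)
  pred <- rbind(pred); true <- rbind(true)
  smat <- if (is.matrix(s)) s else matrix(s, nrow(pred), ncol(pred), byrow = TRUE)
  groups <- resolve_groups(pred, groups)
  term <- exp(-smat) * abs(true - pred)^(2 + gamma)
  if (regularize) term <- term + smat
  per_group_mean(rowMeans(term), groups)
}
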