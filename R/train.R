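#' Fit a graph-informed perturbation-outcome model
#'
#' \code{gears()} trains the full network end to end on the training
#' conditions of a split: gene and perturbation embedding tables refined by
#' one-step graph convolutions over the coexpression and pathway-similarity
#' graphs, sum-composition of perturbation sets, per-gene decoding with
#' cross-gene conditioning, and a per-gene log-variance head. The objective is
#' the autofocus loss (error magnitude raised to 2+gamma) plus lambda times
#' the direction-aware loss; with \code{use_uncertainty = TRUE} the autofocus
#' term is replaced by its heteroscedastic (log-variance-weighted) version.
#' Optimization is Adam on minibatches of perturbations; each training cell is
#' paired with a randomly sampled unperturbed control cell, and the model
#' learns only the perturbation effect added to that control profile.
#'
#' The direction term as defined is piecewise constant in the prediction
#' (sign() has zero derivative almost everywhere); its reported value uses the
#' exact formula while its training gradient flows through a tanh(z/tau)
#' relaxation of sign(z).
#'
#' @param ds a [perturb_dataset()].
#' @param split a [make_split()] plan; training uses its \code{train}
#'   conditions (controls are always available). Default: train on every
#'   condition.
#' @param g_gene coexpression [gene_graph()]; built from the training cells
#'   with defaults (H=20, delta=0.1) when NULL.
#' @param g_pert perturbation-similarity [gene_graph()]; built from
#'   \code{pathways} (H=20) when NULL.
#' @param pathways a [pathway_membership()] used when \code{g_pert} is NULL.
#' @param d embedding dimension.
#' @param hidden MLP hidden width (default d).
#' @param n_layers_gene,n_layers_pert graph-convolution depth over the
#'   coexpression and perturbation graphs. One layer pools the selected
#'   top-H neighborhood; a second layer reaches two hops, which helps
#'   never-perturbed genes whose direct neighbors are themselves sparsely
#'   perturbed.
#' @param epochs training epochs.
#' @param batch_conditions minibatch size T in perturbations.
#' @param cells_per_condition cells sampled per perturbation per step (T_k).
#' @param gamma autofocus exponent offset (error power is 2+gamma).
#' @param lambda weight of the direction-aware loss.
#' @param use_uncertainty optimize the log-variance-weighted loss.
#' @param lr Adam learning rate.
#' @param self_dropout probability, per minibatch target, of zeroing that
#'   target's own perturbation embedding during the step. Masked targets must
#'   be reconstructed from their graph neighbors, which trains exactly the
#'   pathway-sharing route used at prediction time for never-perturbed genes.
#' @param direction_tau temperature of the tanh sign relaxation.
#' @param use_edge_weights use edge weights in neighbor aggregation
#'   (FALSE averages neighbors uniformly).
#' @param h_gene,h_pert,delta graph-construction defaults used when graphs are
#'   built internally.
#' @param swa_epochs average the parameters of the final \code{swa_epochs}
#'   epochs (stochastic weight averaging; 0 disables). Averaging the tail of
#'   the trajectory damps minibatch noise in the converged phase.
#' @param patience early-stopping patience in epochs on the validation
#'   conditions (Inf disables; ignored when the split has no val conditions).
#' @param seed integer seed; fixes minibatch order, control pairing and
#'   initialization, making training reproducible on a single thread.
#' @param verbose print per-epoch losses.
#' @return an object of class \code{gears}: list with \code{params},
#'   \code{genes}, \code{pert_genes}, graphs, \code{config}, \code{history}
#'   (per-epoch data.frame), \code{ctrl_mean} and the split used.
#' @seealso [predict.gears()], [predict_condition_mean()], [evaluate()]
#' @export
gears <- function(ds, split = NULL, g_gene = NULL, g_pert = NULL,
                  pathways = NULL, d = 64, hidden = d,
                  n_layers_gene = 1, n_layers_pert = 1, epochs = 100,
                  batch_conditions = 16, cells_per_condition = 32,
                  gamma = 1, lambda = 0.1, use_uncertainty = FALSE,
                  lr = 1e-3, self_dropout = 0.3, direction_tau = 0.1,
                  use_edge_weights = TRUE,
                  h_gene = 20, h_pert = 20, delta = 0.1, swa_epochs = 0,
                  patience = Inf, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ds, "perturb_dataset"))
  if (ds$n_control == 0L) stop("training requires control cells")
  if (is.null(split))
    split <- structure(list(train = dataset_conditions(ds), val = character(0),
                            test = character(0), test_class = character(0),
                            seed = NA_integer_, mode = "all"),
                       class = "split_plan")
  train_keys <- setdiff(intersect(split$train, dataset_conditions(ds)), "ctrl")
  if (length(train_keys) == 0L) stop("empty training split")
  set.seed(as.integer(seed))
  train_cells <- condition_cells(ds, c("ctrl", train_keys))
  if (is.null(g_gene))
    g_gene <- build_coexpression_graph(ds, h_gene = h_gene, delta = delta,
                                       cells = train_cells)
  pert_genes <- union(ds$genes, ds$unmeasured)
  if (is.null(g_pert)) {
    if (is.null(pathways))
      stop("supply either g_pert or a pathway membership to build it from")
    g_pert <- build_perturbation_graph(pathways, pert_genes, h_pert = h_pert)
  } else {
    pert_genes <- union(pert_genes, g_pert$nodes)
  }
  K <- length(ds$genes)
  params <- gears_init_params(K, length(pert_genes), d, hidden,
                              n_layers_gene, n_layers_pert)
  Ag <- aggregation_matrix(g_gene, ds$genes, use_edge_weights)
  Ap <- aggregation_matrix(g_pert, pert_genes, use_edge_weights)

  cond_cells <- lapply(train_keys, function(k) which(ds$conditions == k))
  names(cond_cells) <- train_keys
  cond_idx <- lapply(train_keys, function(k) {
    idx <- match(condition_targets(k), pert_genes)
    if (anyNA(idx)) stop("training condition with unknown target: ", k)
    idx
  })
  ctrl_cells <- which(ds$conditions == "ctrl")
  val_keys <- intersect(split$val, dataset_conditions(ds))
  val_truth <- if (length(val_keys))
    lapply(val_keys, function(k) summarize_condition(ds, k)) else NULL
  cmean <- control_mean(ds)

  opt <- adam_state(params)
  p_exp <- 2 + gamma
  history <- data.frame()
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  n_cond <- length(train_keys)
  swa <- NULL
  swa_n <- 0L

  for (epoch in seq_len(epochs)) {
    ord <- sample(n_cond)
    ep <- c(autofocus = 0, direction = 0, uncertainty = 0, n = 0)
    for (start in seq(1, n_cond, by = batch_conditions)) {
      batch <- ord[start:min(start + batch_conditions - 1L, n_cond)]
      Tn <- length(batch)
      masked <- integer(0)
      step_params <- params
      if (self_dropout > 0) {
        btargets <- unique(unlist(cond_idx[batch]))
        masked <- btargets[stats::runif(length(btargets)) < self_dropout]
        if (length(masked)) step_params$x_pert[masked, ] <- 0
      }
      fw <- gears_forward(step_params, Ag, Ap, cond_idx[batch], use_edge_weights)
      dZhat <- matrix(0, Tn, K)
      dSmat <- if (use_uncertainty) matrix(0, Tn, K) else NULL
      l_auto <- l_dir <- l_unc <- 0
      for (t in seq_len(Tn)) {
        cells <- cond_cells[[batch[t]]]
        take <- if (length(cells) > cells_per_condition)
          sample(cells, cells_per_condition) else cells
        Tk <- length(take)
        Gm <- ds$expr[take, , drop = FALSE]
        Cm <- ds$expr[sample(ctrl_cells, Tk, replace = TRUE), , drop = FALSE]
        E <- Gm - (Cm + rep(fw$Zhat[t, ], each = Tk))
        absE <- abs(E)
        w <- if (use_uncertainty) rep(exp(-fw$Smat[t, ]), each = Tk) else 1
        l_auto <- l_auto + mean(absE^p_exp) / Tn
        # gradient of the (possibly variance-weighted) error term wrt z_hat
        dZhat[t, ] <- colSums(-p_exp * absE^(p_exp - 1) * sign(E) * w) /
          (Tn * Tk * K)
        if (use_uncertainty) {
          l_unc <- l_unc + mean(exp(-rep(fw$Smat[t, ], each = Tk)) *
                                  absE^p_exp + rep(fw$Smat[t, ], each = Tk)) / Tn
          dSmat[t, ] <- colSums(-exp(-rep(fw$Smat[t, ], each = Tk)) *
                                  absE^p_exp + 1) / (Tn * Tk * K)
        }
        sgn_true <- sign(Gm - Cm)
        l_dir <- l_dir + mean((sgn_true - rep(sign(fw$Zhat[t, ]), each = Tk))^2) / Tn
        if (lambda > 0) {
          th <- tanh(fw$Zhat[t, ] / direction_tau)
          dZhat[t, ] <- dZhat[t, ] + lambda *
            colSums(-2 * (sgn_true - rep(th, each = Tk))) *
            ((1 - th^2) / direction_tau) / (Tn * Tk * K)
        }
      }
      grads <- gears_backward(step_params, fw, dZhat, dSmat)
      if (length(masked)) grads$x_pert[masked, ] <- 0
      params <- adam_step(params, grads, opt, lr)
      ep["autofocus"] <- ep["autofocus"] + l_auto
      ep["direction"] <- ep["direction"] + l_dir
      ep["uncertainty"] <- ep["uncertainty"] + l_unc
      ep["n"] <- ep["n"] + 1
    }
    row <- data.frame(epoch = epoch,
                      autofocus = ep[["autofocus"]] / ep[["n"]],
                      direction = ep[["direction"]] / ep[["n"]],
                      uncertainty = ep[["uncertainty"]] / ep[["n"]])
    row$total <- (if (use_uncertainty) row$uncertainty else row$autofocus) +
      lambda * row$direction
    if (!is.null(val_truth)) {
      val_model <- mini_gears(params, ds, pert_genes, g_gene, g_pert, Ag, Ap,
                              d, cmean, use_edge_weights)
      zh <- predict_deltas(val_model, val_keys)$z_hat
      row$val_autofocus <- mean(vapply(seq_along(val_keys), function(i)
        mean(abs(val_truth[[i]]$mean_delta - zh[i, ])^p_exp), numeric(1)))
      if (row$val_autofocus < best$loss - 1e-12) {
        best <- list(loss = row$val_autofocus, params = params, epoch = epoch)
      } else if (is.finite(patience) && epoch - best$epoch >= patience) {
        history <- rbind(history, row)
        break
      }
    }
    history <- rbind(history, row)
    if (swa_epochs > 0 && epoch > epochs - swa_epochs) {
      swa_n <- swa_n + 1L
      swa <- if (is.null(swa)) params else
        Map(function(a, p) a + (p - a) / swa_n, swa, params)
    }
    if (verbose) cat(sprintf("epoch %3d  L=%.5f (auto %.5f dir %.5f)\n",
                             epoch, row$total, row$autofocus, row$direction))
  }
  if (!is.null(val_truth) && !is.null(best$params) && is.finite(patience)) {
    params <- best$params
  } else if (!is.null(swa)) {
    params <- swa
  }

  model <- mini_gears(params, ds, pert_genes, g_gene, g_pert, Ag, Ap, d,
                      cmean, use_edge_weights)
  model$config <- utils::modifyList(model$config, list(
    hidden = hidden, n_layers_gene = n_layers_gene,
    n_layers_pert = n_layers_pert,
    epochs = epochs, gamma = gamma, lambda = lambda,
    use_uncertainty = use_uncertainty, lr = lr, self_dropout = self_dropout,
    swa_epochs = swa_epochs, seed = as.integer(seed),
    batch_conditions = batch_conditions,
    cells_per_condition = cells_per_condition, direction_tau = direction_tau))
  model$history <- history
  model$split <- split
  model
}

# assemble a gears object around a parameter set
mini_gears <- function(params, ds, pert_genes, g_gene, g_pert, Ag, Ap, d,
                       cmean, use_edge_weights) {
  structure(list(
    params = params, genes = ds$genes, pert_genes = pert_genes,
    g_gene = g_gene, g_pert = g_pert, Ag = Ag, Ap = Ap,
    ctrl_mean = cmean,
    config = list(d = d, use_edge_weights = use_edge_weights,
                  uncertainty_aggregate = "top_de"),
    history = NULL, split = NULL
  ), class = "gears")
}

adam_state <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e$t <- 0L
  e
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

#' @export
print.gears <- function(x, ...) {
  cat(sprintf("gears model: %d genes, %d perturbation embeddings, d=%d\n",
              length(x$genes), length(x$pert_genes), x$config$d))
  cat(sprintf("  graphs: coexpression %d edges, perturbation-similarity %d edges\n",
              nrow(x$g_gene$edges), nrow(x$g_pert$edges)))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs; final loss %.5f\n",
                max(x$history$epoch), utils::tail(x$history$total, 1)))
  invisible(x)
}

#' @export
summary.gears <- function(object, ...) {
  print(object)
  if (!is.null(object$split) && length(object$split$test)) {
    cat("  split: ")
    print(object$split)
  }
  np <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("  %d trainable parameters in %d tensors\n",
              np, length(object$params)))
  invisible(object)
}

#' @export
coef.gears <- function(object, ...) {
  list(gene_embeddings = object$params$x_gene,
       perturbation_embeddings = object$params$x_pert)
}

#' @export
plot.gears <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("model has no training history")
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "gears training", ...)
  graphics::lines(h$epoch, h$autofocus, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("total", "autofocus"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(h)
}

#' @export
residuals.gears <- function(object, ds, conditions = NULL, ...) {
  if (missing(ds)) stop("residuals.gears needs the dataset: residuals(model, ds)")
  if (is.null(conditions))
    conditions <- setdiff(intersect(object$split$train, dataset_conditions(ds)),
                          "ctrl")
  zh <- predict_deltas(object, conditions)$z_hat
  res <- t(vapply(conditions, function(k)
    summarize_condition(ds, k)$mean_delta, numeric(length(object$genes))))
  res - zh
}
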