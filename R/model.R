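# Network internals. All dense math is base R matrix algebra; parameters are
# stored row-major (rows = entities, columns = latent dims), and every linear
# layer with weight W (out x in) acts as X %*% t(W) + b.

relu <- function(x) (x > 0) * x

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# Parameter initialization. Embeddings start small so that perturbations never
# seen in training contribute little beyond their graph neighborhood; decoder
# heads start near zero so the initial prediction is close to the control
# profile. Graph-convolution stacks deeper than one layer get numbered
# parameter tensors (gg2_self, ...).
gears_init_params <- function(K, Kp, d, hidden = d, n_layers_gene = 1,
                              n_layers_pert = 1) {
  params <- list(
    x_gene = init_mat(K, d, 0.1),
    x_pert = init_mat(Kp, d, 0.05),
    gg_self = init_mat(d, d, sqrt(2 / d)),
    gg_nbr  = init_mat(d, d, sqrt(2 / d)),
    gg_b    = numeric(d),
    gp_self = init_mat(d, d, sqrt(2 / d)),
    gp_nbr  = init_mat(d, d, sqrt(2 / d)),
    gp_b    = numeric(d))
  for (l in seq_len(max(0, n_layers_gene - 1)) + 1) {
    params[[paste0("gg", l, "_self")]] <- init_mat(d, d, sqrt(2 / d))
    params[[paste0("gg", l, "_nbr")]] <- init_mat(d, d, sqrt(2 / d))
    params[[paste0("gg", l, "_b")]] <- numeric(d)
  }
  for (l in seq_len(max(0, n_layers_pert - 1)) + 1) {
    params[[paste0("gp", l, "_self")]] <- init_mat(d, d, sqrt(2 / d))
    params[[paste0("gp", l, "_nbr")]] <- init_mat(d, d, sqrt(2 / d))
    params[[paste0("gp", l, "_b")]] <- numeric(d)
  }
  params <- c(params, list(
    c_W1 = init_mat(hidden, d, sqrt(2 / d)), c_b1 = numeric(hidden),
    c_W2 = init_mat(d, hidden, sqrt(1 / hidden)), c_b2 = numeric(d),
    pp_W1 = init_mat(hidden, d, sqrt(2 / d)), pp_b1 = numeric(hidden),
    pp_W2 = init_mat(d, hidden, sqrt(1 / hidden)), pp_b2 = numeric(d),
    out_W = init_mat(K, d, 0.01), out_b = numeric(K),
    cg_W1 = init_mat(hidden, K, sqrt(1 / K)), cg_b1 = numeric(hidden),
    cg_W2 = init_mat(d, hidden, sqrt(1 / hidden)), cg_b2 = numeric(d),
    cgh_w = init_mat(K, d, 0.01), cgz_w = rep(1, K), cg_b = numeric(K),
    unc_W = init_mat(K, d, 0.01), unc_b = numeric(K)
  ))
  params
}

# ordered parameter-name prefixes of a GNN stack ("gg", "gg2", ...)
gnn_prefixes <- function(base, params) {
  out <- base
  l <- 2
  while (!is.null(params[[paste0(base, l, "_self")]])) {
    out <- c(out, paste0(base, l))
    l <- l + 1
  }
  out
}

# multi-layer graph convolution; returns the top-layer activations plus a
# per-layer cache for backprop
gnn_stack_forward <- function(params, base, x, A) {
  layers <- list()
  for (pre in gnn_prefixes(base, params)) {
    fw <- gnn_forward(x, A, params[[paste0(pre, "_self")]],
                      params[[paste0(pre, "_nbr")]], params[[paste0(pre, "_b")]])
    fw$x_in <- x
    layers[[pre]] <- fw
    x <- fw$h
  }
  list(h = x, layers = layers)
}

gnn_stack_backward <- function(params, base, stack, A, dh, grads) {
  prefixes <- rev(gnn_prefixes(base, params))
  for (pre in prefixes) {
    fw <- stack$layers[[pre]]
    bk <- gnn_backward(fw$x_in, A, params[[paste0(pre, "_self")]],
                       params[[paste0(pre, "_nbr")]], fw, dh)
    grads[[paste0(pre, "_self")]] <- bk$dW_self
    grads[[paste0(pre, "_nbr")]] <- bk$dW_nbr
    grads[[paste0(pre, "_b")]] <- bk$db
    dh <- bk$dx
  }
  grads$dx <- dh
  grads
}

#' Encode gene identities over the coexpression graph
#'
#' Graph convolution (one step per configured layer, default one): each
#' gene's embedding is transformed and combined with the
#' (edge-weight-normalized) mean of its selected neighbors' transformed
#' embeddings, followed by a ReLU. An isolated node's output depends only on
#' its own embedding at any depth.
#'
#' @param model a fitted or initialized \code{gears} object.
#' @param graph a coexpression [gene_graph()] (default: the one stored in the
#'   model).
#' @return K x d matrix of contextualized gene embeddings.
#' @export
encode_genes <- function(model, graph = model$g_gene) {
  A <- aggregation_matrix(graph, model$genes, model$config$use_edge_weights)
  gnn_stack_forward(model$params, "gg", model$params$x_gene, A)$h
}

#' Encode perturbation identities over the pathway-similarity graph
#'
#' Same one-step graph convolution as [encode_genes()] but over the
#' perturbation similarity graph, using the perturbation embedding table
#' (which covers measured genes and unmeasured perturbation targets).
#'
#' @inheritParams encode_genes
#' @param graph a perturbation-similarity [gene_graph()].
#' @return Kp x d matrix of contextualized perturbation embeddings.
#' @export
encode_perturbations <- function(model, graph = model$g_pert) {
  A <- aggregation_matrix(graph, model$pert_genes, model$config$use_edge_weights)
  gnn_stack_forward(model$params, "gp", model$params$x_pert, A)$h
}

gnn_forward <- function(x, A, W_self, W_nbr, b) {
  nbr <- as.matrix(A %*% x)
  pre <- x %*% t(W_self) + nbr %*% t(W_nbr) + rep(b, each = nrow(x))
  list(h = relu(pre), pre = pre, nbr = nbr)
}

#' Compose a perturbation set into a single perturbation state
#'
#' Sums the contextualized perturbation embeddings of the set's members
#' (permutation-invariant, extends to any set size) and passes the sum through
#' the composition MLP. An empty set gives the zero pre-MLP sum.
#'
#' @param model a \code{gears} object.
#' @param pert_set character vector of perturbation target identifiers.
#' @param h_pert Kp x d matrix of contextualized perturbation embeddings
#'   (default: computed from the model).
#' @return length-d numeric vector.
#' @export
compose_perturbations <- function(model, pert_set, h_pert = encode_perturbations(model)) {
  idx <- match(pert_set, model$pert_genes)
  if (anyNA(idx))
    stop("no perturbation embedding for: ",
         paste(pert_set[is.na(idx)], collapse = ", "))
  s <- if (length(idx)) colSums(h_pert[idx, , drop = FALSE]) else
    numeric(model$config$d)
  p <- model$params
  a1 <- relu(drop(p$c_W1 %*% s) + p$c_b1)
  drop(p$c_W2 %*% a1) + p$c_b2
}

# Batched forward pass over T conditions. pert_idx: list of integer vectors
# (indices into pert_genes; may be empty). Returns a cache for backward().
gears_forward <- function(params, Ag, Ap, pert_idx, use_edge_weights = TRUE) {
  K <- nrow(params$x_gene); d <- ncol(params$x_gene); Tn <- length(pert_idx)
  gg <- gnn_stack_forward(params, "gg", params$x_gene, Ag)
  gp <- gnn_stack_forward(params, "gp", params$x_pert, Ap)
  # sum-compose each condition's perturbation embeddings
  S <- matrix(0, Tn, d)
  for (t in seq_len(Tn)) if (length(pert_idx[[t]]))
    S[t, ] <- colSums(gp$h[pert_idx[[t]], , drop = FALSE])
  c_pre1 <- S %*% t(params$c_W1) + rep(params$c_b1, each = Tn)
  c_a1 <- relu(c_pre1)
  Hc <- c_a1 %*% t(params$c_W2) + rep(params$c_b2, each = Tn)
  gidx <- rep(seq_len(K), times = Tn)
  cidx <- rep(seq_len(Tn), each = K)
  X <- gg$h[gidx, , drop = FALSE] + Hc[cidx, , drop = FALSE]
  pp_pre1 <- X %*% t(params$pp_W1) + rep(params$pp_b1, each = nrow(X))
  pp_a1 <- relu(pp_pre1)
  Hpp <- pp_a1 %*% t(params$pp_W2) + rep(params$pp_b2, each = nrow(X))
  z_vec <- rowSums(Hpp * params$out_W[gidx, , drop = FALSE]) + params$out_b[gidx]
  Zt <- t(matrix(z_vec, nrow = K))                     # T x K
  cg_pre1 <- Zt %*% t(params$cg_W1) + rep(params$cg_b1, each = Tn)
  cg_a1 <- relu(cg_pre1)
  Hcg <- cg_a1 %*% t(params$cg_W2) + rep(params$cg_b2, each = Tn)
  Zhat <- Zt * rep(params$cgz_w, each = Tn) + Hcg %*% t(params$cgh_w) +
    rep(params$cg_b, each = Tn)
  s_vec <- rowSums(Hpp * params$unc_W[gidx, , drop = FALSE]) + params$unc_b[gidx]
  Smat <- t(matrix(s_vec, nrow = K))                   # T x K (log variance)
  list(Zhat = Zhat, Smat = Smat, Zt = Zt, K = K, Tn = Tn,
       gg = gg, gp = gp, S = S, c_pre1 = c_pre1, c_a1 = c_a1, Hc = Hc,
       gidx = gidx, cidx = cidx, X = X, pp_pre1 = pp_pre1, pp_a1 = pp_a1,
       Hpp = Hpp, cg_pre1 = cg_pre1, cg_a1 = cg_a1, Hcg = Hcg,
       pert_idx = pert_idx, Ag = Ag, Ap = Ap)
}

# Analytic gradients for the batched forward pass. dZhat, dSmat: T x K.
gears_backward <- function(params, cache, dZhat, dSmat = NULL) {
  K <- cache$K; Tn <- cache$Tn
  gidx <- cache$gidx; cidx <- cache$cidx
  g <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  g$cg_b <- colSums(dZhat)
  g$cgz_w <- colSums(dZhat * cache$Zt)
  g$cgh_w <- t(dZhat) %*% cache$Hcg
  dHcg <- dZhat %*% params$cgh_w
  dZt <- dZhat * rep(params$cgz_w, each = Tn)
  g$cg_W2 <- t(dHcg) %*% cache$cg_a1
  g$cg_b2 <- colSums(dHcg)
  dcg_a1 <- (dHcg %*% params$cg_W2) * (cache$cg_pre1 > 0)
  g$cg_W1 <- t(dcg_a1) %*% cache$Zt
  g$cg_b1 <- colSums(dcg_a1)
  dZt <- dZt + dcg_a1 %*% params$cg_W1
  dz_vec <- as.vector(t(dZt))
  tmp <- dz_vec * cache$Hpp
  g$out_W <- rowsum(tmp, gidx)
  g$out_b <- drop(rowsum(matrix(dz_vec), gidx))
  dHpp <- dz_vec * params$out_W[gidx, , drop = FALSE]
  if (!is.null(dSmat)) {
    ds_vec <- as.vector(t(dSmat))
    g$unc_W <- rowsum(ds_vec * cache$Hpp, gidx)
    g$unc_b <- drop(rowsum(matrix(ds_vec), gidx))
    dHpp <- dHpp + ds_vec * params$unc_W[gidx, , drop = FALSE]
  }
  g$pp_W2 <- t(dHpp) %*% cache$pp_a1
  g$pp_b2 <- colSums(dHpp)
  dpp_a1 <- (dHpp %*% params$pp_W2) * (cache$pp_pre1 > 0)
  g$pp_W1 <- t(dpp_a1) %*% cache$X
  g$pp_b1 <- colSums(dpp_a1)
  dX <- dpp_a1 %*% params$pp_W1
  dHg <- rowsum(dX, gidx)
  dHc <- rowsum(dX, cidx)
  g$c_W2 <- t(dHc) %*% cache$c_a1
  g$c_b2 <- colSums(dHc)
  dc_a1 <- (dHc %*% params$c_W2) * (cache$c_pre1 > 0)
  g$c_W1 <- t(dc_a1) %*% cache$S
  g$c_b1 <- colSums(dc_a1)
  dS <- dc_a1 %*% params$c_W1
  dHp <- matrix(0, nrow(params$x_pert), ncol(params$x_pert))
  for (t in seq_len(Tn)) {
    idx <- cache$pert_idx[[t]]
    if (length(idx)) dHp[idx, ] <- dHp[idx, , drop = FALSE] +
        rep(dS[t, ], each = length(idx))
  }
  g <- gnn_stack_backward(params, "gg", cache$gg, cache$Ag, dHg, g)
  g$x_gene <- g$dx
  g <- gnn_stack_backward(params, "gp", cache$gp, cache$Ap, dHp, g)
  g$x_pert <- g$dx
  g$dx <- NULL
  g[names(params)]
}

gnn_backward <- function(x, A, W_self, W_nbr, fwd, dh) {
  dpre <- dh * (fwd$pre > 0)
  list(dW_self = t(dpre) %*% x,
       dW_nbr = t(dpre) %*% fwd$nbr,
       db = colSums(dpre),
       dx = dpre %*% W_self + as.matrix(Matrix::t(A) %*% (dpre %*% W_nbr)))
}

#' Predict the outcome of a perturbation for one control cell
#'
#' Runs the full network: contextualized gene and perturbation embeddings,
#' sum-composition of the perturbation set, per-gene post-perturbation
#' embeddings, gene-specific linear readout to a perturbation effect z, a
#' cross-gene embedding of the whole effect vector conditioning a second
#' gene-specific decoder to the final effect zhat, and per-gene log-variance
#' s. The predicted postperturbation profile is \code{g_hat = z_hat + g_ctrl}.
#' The perturbation set \code{character(0)} (or key "ctrl") bypasses the
#' network: the prediction for an unperturbed cell is the cell itself.
#'
#' @param object a \code{gears} model.
#' @param pert_set character vector of target genes (or a condition key).
#' @param g_ctrl expression vector of an unperturbed control cell (length K).
#' @param ... unused.
#' @return an object of class \code{prediction_result}: list with
#'   \code{condition}, \code{g_hat}, \code{z_hat}, \code{s} (per-gene log
#'   variance) and \code{uncertainty} (scalar aggregate of s).
#' @export
predict.gears <- function(object, pert_set, g_ctrl = object$ctrl_mean, ...) {
  if (length(pert_set) == 1L && grepl("+", pert_set, fixed = TRUE))
    pert_set <- condition_targets(canonical_condition(pert_set))
  if (length(pert_set) == 1L && pert_set == "ctrl") pert_set <- character(0)
  K <- length(object$genes)
  stopifnot(length(g_ctrl) == K)
  key <- if (length(pert_set) == 0L) "ctrl" else
    canonical_condition(paste(pert_set, collapse = "+"))
  if (length(pert_set) == 0L) {
    return(structure(list(condition = "ctrl",
                          g_hat = stats::setNames(as.numeric(g_ctrl), object$genes),
                          z_hat = stats::setNames(numeric(K), object$genes),
                          s = stats::setNames(numeric(K), object$genes),
                          uncertainty = 0),
                     class = "prediction_result"))
  }
  idx <- match(pert_set, object$pert_genes)
  if (anyNA(idx))
    stop("no perturbation embedding for: ",
         paste(pert_set[is.na(idx)], collapse = ", "))
  fw <- gears_forward(object$params, object$Ag, object$Ap, list(idx),
                      object$config$use_edge_weights)
  z_hat <- drop(fw$Zhat)
  s <- drop(fw$Smat)
  structure(list(
    condition = key,
    g_hat = stats::setNames(z_hat + as.numeric(g_ctrl), object$genes),
    z_hat = stats::setNames(z_hat, object$genes),
    s = stats::setNames(s, object$genes),
    uncertainty = aggregate_uncertainty(z_hat, s, object$config$uncertainty_aggregate)
  ), class = "prediction_result")
}

# scalar uncertainty: mean log-variance over the top-20 predicted DE genes
# (mirrors the autofocus principle), or over all genes.
aggregate_uncertainty <- function(z_hat, s, mode = c("top_de", "all"), k = 20) {
  mode <- match.arg(mode)
  if (mode == "all") return(mean(s))
  ord <- order(-abs(z_hat), seq_along(z_hat))
  mean(s[ord[seq_len(min(k, length(s)))]])
}

#' @export
print.prediction_result <- function(x, n = 8, ...) {
  cat(sprintf("prediction_result '%s' (uncertainty %.3f)\n", x$condition, x$uncertainty))
  ord <- order(-abs(x$z_hat))[seq_len(min(n, length(x$z_hat)))]
  for (i in ord)
    cat(sprintf("  %-12s z_hat %+0.3f  g_hat %0.3f\n",
                names(x$z_hat)[i], x$z_hat[i], x$g_hat[i]))
  invisible(x)
}

# batched prediction of perturbation effect vectors for many conditions;
# returns T x K matrix of z_hat (and S). Conditions given as condition keys.
predict_deltas <- function(object, keys, chunk = 64L) {
  K <- length(object$genes)
  Z <- matrix(0, length(keys), K, dimnames = list(keys, object$genes))
  S <- Z
  nonctrl <- which(keys != "ctrl")
  for (start in seq(1, length(nonctrl), by = chunk)) {
    take <- nonctrl[start:min(start + chunk - 1L, length(nonctrl))]
    idxs <- lapply(keys[take], function(k) {
      idx <- match(condition_targets(k), object$pert_genes)
      if (anyNA(idx)) stop("no perturbation embedding for targets of ", k)
      idx
    })
    fw <- gears_forward(object$params, object$Ag, object$Ap, idxs,
                        object$config$use_edge_weights)
    Z[take, ] <- fw$Zhat
    S[take, ] <- fw$Smat
  }
  list(z_hat = Z, s = S)
}

#' Predicted mean postperturbation profile for a condition
#'
#' Averages [predict.gears()] over \code{n_ctrl} randomly sampled unperturbed
#' control cells (the network's effect vector is deterministic given the
#' perturbation set; sampling controls sets the baseline the effect is added
#' to).
#'
#' @param model a \code{gears} model.
#' @param pert_set targets or condition key.
#' @param ds the perturb_dataset supplying control cells.
#' @param n_ctrl number of control cells to sample (capped at the number
#'   available).
#' @param seed RNG seed for the control sample.
#' @return a \code{condition_summary} whose \code{mean_delta} is relative to
#'   the dataset's control mean.
#' @export
predict_condition_mean <- function(model, pert_set, ds, n_ctrl = 30, seed = 1L) {
  ctrl_idx <- which(ds$conditions == "ctrl")
  if (length(ctrl_idx) == 0L) stop("dataset has no control cells")
  set.seed(as.integer(seed))
  take <- sample(ctrl_idx, min(n_ctrl, length(ctrl_idx)))
  base <- colMeans(ds$expr[take, , drop = FALSE])
  pr <- predict(model, pert_set, g_ctrl = base)
  mu <- pr$g_hat
  condition_summary(pr$condition, mu, mu - control_mean(ds),
                    n_cells = length(take), genes = ds$genes)
}
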