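# Independent reference implementations shared by the unit and end-to-end
# tests. These deliberately use plain loops and the textbook formulas, never
# the package's own vectorized code paths.

brute_coexpression <- function(x, H, delta) {
  K <- ncol(x)
  rho <- suppressWarnings(cor(x))
  rho[!is.finite(rho)] <- 0
  out <- NULL
  for (u in seq_len(K)) {
    s <- rho[u, ]; s[u] <- -Inf
    cand <- which(s > delta)
    cand <- cand[order(-s[cand], cand)]
    cand <- head(cand, H)
    if (length(cand))
      out <- rbind(out, data.frame(source = colnames(x)[u],
                                   target = colnames(x)[cand],
                                   weight = unname(s[cand])))
  }
  out
}

brute_jaccard_graph <- function(memb, genes, H) {
  out <- NULL
  for (u in genes) {
    s <- vapply(genes, function(v) jaccard_similarity(memb, u, v), numeric(1))
    s[u] <- -Inf
    cand <- which(s > 0)
    cand <- cand[order(-s[cand], cand)]
    cand <- head(cand, H)
    if (length(cand))
      out <- rbind(out, data.frame(source = u, target = genes[cand],
                                   weight = unname(s[cand])))
  }
  out
}

# loop-level reimplementation of the full network forward pass
oracle_forward <- function(params, g_gene, g_pert, genes, pert_set, g_ctrl) {
  relu <- function(x) pmax(x, 0)
  gnn <- function(x, graph, Ws, Wn, b) {
    K <- nrow(x)
    h <- matrix(0, K, ncol(x))
    for (u in seq_len(K)) {
      e <- graph$edges[graph$edges$source == graph$nodes[u], ]
      agg <- rep(0, ncol(x))
      if (nrow(e)) {
        w <- abs(e$weight) / sum(abs(e$weight))
        for (j in seq_len(nrow(e)))
          agg <- agg + w[j] * x[match(e$target[j], graph$nodes), ]
      }
      h[u, ] <- relu(Ws %*% x[u, ] + Wn %*% agg + b)
    }
    h
  }
  mlp <- function(v, W1, b1, W2, b2) drop(W2 %*% relu(drop(W1 %*% v) + b1)) + b2
  hg <- gnn(params$x_gene, g_gene, params$gg_self, params$gg_nbr, params$gg_b)
  hp <- gnn(params$x_pert, g_pert, params$gp_self, params$gp_nbr, params$gp_b)
  S <- rep(0, ncol(params$x_pert))
  for (p in pert_set) S <- S + hp[match(p, g_pert$nodes), ]
  hP <- mlp(S, params$c_W1, params$c_b1, params$c_W2, params$c_b2)
  K <- length(genes)
  z <- s <- numeric(K)
  hpp <- matrix(0, K, length(hP))
  for (u in seq_len(K)) {
    hpp[u, ] <- mlp(hg[u, ] + hP, params$pp_W1, params$pp_b1,
                    params$pp_W2, params$pp_b2)
    z[u] <- sum(params$out_W[u, ] * hpp[u, ]) + params$out_b[u]
  }
  hcg <- mlp(z, params$cg_W1, params$cg_b1, params$cg_W2, params$cg_b2)
  zhat <- numeric(K)
  for (u in seq_len(K)) {
    zhat[u] <- params$cgz_w[u] * z[u] + sum(params$cgh_w[u, ] * hcg) +
      params$cg_b[u]
    s[u] <- sum(params$unc_W[u, ] * hpp[u, ]) + params$unc_b[u]
  }
  list(z_hat = zhat, g_hat = zhat + g_ctrl, s = s)
}

manual_model <- function(genes, g_gene, g_pert, d = 2, seed = 21,
                         ctrl = rep(1, length(genes))) {
  set.seed(seed)
  params <- perturbgraph:::gears_init_params(length(genes),
                                             length(g_pert$nodes), d)
  Ag <- perturbgraph:::aggregation_matrix(g_gene, genes)
  Ap <- perturbgraph:::aggregation_matrix(g_pert, g_pert$nodes)
  perturbgraph:::mini_gears(params, list(genes = genes), g_pert$nodes,
                            g_gene, g_pert, Ag, Ap, d,
                            setNames(ctrl, genes), TRUE)
}

k3_graphs <- function(genes = c("A", "B", "C")) {
  eg <- data.frame(source = c("A", "B"), target = c("B", "A"),
                   weight = c(0.8, 0.8))
  ep <- data.frame(source = c("A", "C"), target = c("C", "A"),
                   weight = c(0.5, 0.5))
  list(g = gene_graph(genes, eg, "coexpression"),
       p = gene_graph(genes, ep, "perturbation_similarity"))
}
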