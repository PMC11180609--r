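# Shared fixtures, all generated in code.

# tiny deterministic dataset: 2 genes, known condition means (non-integer
# values so no reader mistakes it for raw counts)
tiny_dataset <- function() {
  expr <- rbind(
    c(1.5, 1.5), c(1.5, 1.5),  # ctrl, mean (1.5, 1.5)
    c(3.5, 1.5), c(3.5, 1.5),  # condition A, delta (2, 0)
    c(1.5, 2.5), c(1.5, 2.5))  # condition B, delta (0, 1)
  colnames(expr) <- c("GA", "GB")
  perturb_dataset(expr, c("ctrl", "ctrl", "GA+ctrl", "GA+ctrl",
                          "GB+ctrl", "GB+ctrl"), normalize = "none")
}

# small random dataset with singles and combos for split/graph tests
random_dataset <- function(K = 12, n_ctrl = 10, cells = 4, seed = 99) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(K))
  singles <- genes[1:6]
  combos <- c("g01+g02", "g03+g04", "g05+g06", "g01+g03")
  conds <- c(rep("ctrl", n_ctrl),
             rep(paste0(singles, "+ctrl"), each = cells),
             rep(combos, each = cells))
  expr <- matrix(abs(rnorm(length(conds) * K, 2, 1)), ncol = K,
                 dimnames = list(NULL, genes))
  perturb_dataset(expr, conds, normalize = "none")
}

# memoised default-size simulation at zero noise (shared by GI tests)
sim_noise0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_perturb_data(sim_config(noise_sd = 0, seed = 11))
    cache
  }
})

# a small untrained model over a simulated dataset
tiny_model <- function(sim = NULL, d = 4, seed = 5) {
  if (is.null(sim)) {
    cfg <- sim_config(n_genes = 20, n_pathways = 4, n_single = 8, n_double = 4,
                      planted = c(synergy = 1), cells_per_condition = 5,
                      n_control = 20, seed = seed)
    sim <- simulate_perturb_data(cfg)
  }
  gears(sim$dataset, pathways = sim$membership, d = d, epochs = 1,
        seed = seed)
}

measured_deltas <- function(ds, keys) {
  out <- lapply(keys, function(k) summarize_condition(ds, k)$mean_delta)
  names(out) <- keys
  out
}

# shuffled-edge ablation of a perturbation graph (same out-degrees)
shuffle_graph <- function(g, seed) {
  set.seed(seed)
  e <- g$edges
  e$target <- sample(g$nodes, nrow(e), replace = TRUE)
  while (any(bad <- e$target == e$source))
    e$target[bad] <- sample(g$nodes, sum(bad), replace = TRUE)
  gene_graph(g$nodes, e, g$kind)
}
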