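test_that("the forward pass matches a loop-level oracle on a K=3, d=2 model", {
  gr <- k3_graphs()
  m <- manual_model(c("A", "B", "C"), gr$g, gr$p)
  # make outputs non-trivial
  set.seed(22)
  for (nm in c("out_W", "cgh_w", "unc_W"))
    m$params[[nm]] <- matrix(rnorm(length(m$params[[nm]]), 0, 0.5),
                             nrow(m$params[[nm]]))
  m$params$out_b <- c(0.1, -0.2, 0.3)
  g_ctrl <- c(1, 2, 0.5)
  for (ps in list("A", c("A", "B"), c("A", "B", "C"))) {
    pr <- predict(m, ps, g_ctrl = g_ctrl)
    ref <- oracle_forward(m$params, gr$g, gr$p, m$genes, ps, g_ctrl)
    expect_equal(unname(pr$z_hat), ref$z_hat, tolerance = 1e-10)
    expect_equal(unname(pr$g_hat), ref$g_hat, tolerance = 1e-10)
    expect_equal(unname(pr$s), ref$s, tolerance = 1e-10)
  }
})

test_that("zero decoder heads give the control profile exactly", {
  gr <- k3_graphs()
  m <- manual_model(c("A", "B", "C"), gr$g, gr$p)
  for (nm in c("out_W", "out_b", "cgh_w", "cg_b"))
    m$params[[nm]] <- m$params[[nm]] * 0
  m$params$cgz_w <- rep(1, 3)      # zhat = z = 0 through the zeroed readout
  g_ctrl <- c(0.3, 1.7, 2.2)
  pr <- predict(m, c("A", "C"), g_ctrl = g_ctrl)
  expect_identical(unname(pr$z_hat), c(0, 0, 0))
  expect_identical(unname(pr$g_hat), g_ctrl)
})

test_that("predictions are additive in the control profile", {
  gr <- k3_graphs()
  m <- manual_model(c("A", "B", "C"), gr$g, gr$p, seed = 31)
  p1 <- predict(m, "A", g_ctrl = c(1, 1, 1))
  p2 <- predict(m, "A", g_ctrl = c(2, 0, 5))
  expect_identical(p1$z_hat, p2$z_hat)
  expect_equal(unname(p2$g_hat - p1$g_hat), c(1, -1, 4))
})

test_that("composition is permutation-invariant and sums pre-MLP", {
  gr <- k3_graphs()
  m <- manual_model(c("A", "B", "C"), gr$g, gr$p, seed = 41)
  hp <- encode_perturbations(m)
  expect_identical(compose_perturbations(m, c("A", "B"), hp),
                   compose_perturbations(m, c("B", "A"), hp))
  pr1 <- predict(m, c("A", "B", "C"))
  pr2 <- predict(m, c("C", "B", "A"))
  expect_identical(pr1$z_hat, pr2$z_hat)
  # identity composition MLP returns the (non-negative) perturbation embedding
  d <- m$config$d
  m$params$c_W1 <- diag(d); m$params$c_b1 <- rep(0, d)
  m$params$c_W2 <- diag(d); m$params$c_b2 <- rep(0, d)
  expect_equal(compose_perturbations(m, "A", hp),
               hp[match("A", m$pert_genes), ], tolerance = 1e-12)
  expect_error(predict(m, "ZZZ"), "no perturbation embedding")
})

test_that("graph encoders are local: only neighbors influence a node", {
  genes <- c("A", "B", "C")
  eg <- data.frame(source = "A", target = "B", weight = 1)
  g <- gene_graph(genes, eg, "coexpression")
  p <- gene_graph(genes, eg[0, ], "perturbation_similarity")
  m <- manual_model(genes, g, p, seed = 51)
  h0 <- encode_genes(m)
  m2 <- m; m2$params$x_gene[2, ] <- m2$params$x_gene[2, ] + 1   # B: neighbor of A
  h2 <- encode_genes(m2)
  expect_false(isTRUE(all.equal(h0[1, ], h2[1, ])))
  m3 <- m; m3$params$x_gene[3, ] <- m3$params$x_gene[3, ] + 1   # C: not a neighbor
  h3 <- encode_genes(m3)
  expect_identical(h0[1, ], h3[1, ])
  # edgeless graph with identity self-transform: h = relu(x)
  m4 <- m
  m4$params$gg_self <- diag(m$config$d); m4$params$gg_nbr[] <- 0
  m4$params$gg_b[] <- 0
  m4$g_gene <- p; m4$Ag <- perturbgraph:::aggregation_matrix(p, genes)
  expect_equal(encode_genes(m4), pmax(m4$params$x_gene, 0), tolerance = 1e-12)
})

test_that("a chain-graph node aggregates exactly one hand-rolled step", {
  genes <- sprintf("n%02d", 1:10)
  e <- data.frame(source = genes[-10], target = genes[-1], weight = 1)
  g <- gene_graph(genes, e, "coexpression")
  p <- gene_graph(genes, e, "perturbation_similarity")
  m <- manual_model(genes, g, p, d = 3, seed = 61)
  h <- encode_genes(m)
  x <- m$params$x_gene
  ref5 <- pmax(m$params$gg_self %*% x[5, ] + m$params$gg_nbr %*% x[6, ] +
                 m$params$gg_b, 0)
  expect_equal(h[5, ], drop(ref5), tolerance = 1e-12)
  hp <- encode_perturbations(m)
  refp <- pmax(m$params$gp_self %*% m$params$x_pert[5, ] +
                 m$params$gp_nbr %*% m$params$x_pert[6, ] + m$params$gp_b, 0)
  expect_equal(hp[5, ], drop(refp), tolerance = 1e-12)
})

test_that("outputs stay finite across random models and inputs", {
  set.seed(71)
  for (i in 1:100) {
    K <- sample(3:8, 1)
    genes <- paste0("g", seq_len(K))
    ne <- sample(0:(K * 2), 1)
    e <- if (ne > 0) {
      src <- sample(genes, ne, replace = TRUE)
      tgt <- sample(genes, ne, replace = TRUE)
      keep <- src != tgt
      unique(data.frame(source = src[keep], target = tgt[keep],
                        weight = runif(sum(keep), -1, 1)))
    } else data.frame(source = character(0), target = character(0),
                      weight = numeric(0))
    g <- gene_graph(genes, e, "coexpression")
    p <- gene_graph(genes, e, "perturbation_similarity")
    m <- manual_model(genes, g, p, d = sample(2:4, 1), seed = 1000 + i)
    ps <- sample(genes, sample(1:K, 1))
    pr <- predict(m, ps, g_ctrl = abs(rnorm(K, 2)))
    expect_true(all(is.finite(pr$g_hat)), info = paste("model", i))
    expect_true(all(is.finite(pr$s)))
    expect_true(is.finite(pr$uncertainty))
  }
})

test_that("never-perturbed genes with pathway neighbors get informed predictions", {
  sim <- simulate_perturb_data(
    sim_config(n_genes = 30, n_pathways = 4, membership_density = 0.4,
               n_single = 8, n_double = 2, planted = c(synergy = 1),
               cells_per_condition = 5, n_control = 20, seed = 3))
  m <- gears(sim$dataset, pathways = sim$membership, d = 6, epochs = 3, seed = 3)
  unseen <- setdiff(m$g_pert$edges$source, sim$truth$singles)[1]
  expect_false(is.na(unseen))
  pr <- predict(m, unseen)
  expect_true(all(is.finite(pr$g_hat)))
  hp <- encode_perturbations(m)
  expect_gt(max(abs(hp[match(unseen, m$pert_genes), ] -
                      m$params$x_pert[match(unseen, m$pert_genes), ])), 0)
})

test_that("condition-mean prediction is seeded and linear in sampled controls", {
  sim <- sim_noise0()
  m <- tiny_model()
  ds <- sim$dataset
  m2 <- gears(ds, pathways = sim$membership, d = 4, epochs = 1, seed = 2)
  key <- sim$truth$singles[1]
  s1 <- predict_condition_mean(m2, key, ds, n_ctrl = 5, seed = 9)
  s2 <- predict_condition_mean(m2, key, ds, n_ctrl = 5, seed = 9)
  expect_identical(s1$mean_delta, s2$mean_delta)
  # n_ctrl covering every control: mean g_hat = z_hat + control mean
  all_ctrl <- predict_condition_mean(m2, key, ds, n_ctrl = ds$n_control, seed = 1)
  pr <- predict(m2, key, g_ctrl = perturbgraph:::control_mean(ds))
  expect_equal(all_ctrl$mean_expression, pr$g_hat, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a 3-gene toy", {
  gr <- k3_graphs()
  genes <- c("A", "B", "C")
  set.seed(81)
  params <- perturbgraph:::gears_init_params(3, 3, 2)
  # keep every pre-activation off the ReLU kink, where the one-sided
  # finite-difference slope would disagree with any subgradient choice
  for (nm in grep("_b[12]?$", names(params), value = TRUE))
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), 0, 0.05)
  Ag <- perturbgraph:::aggregation_matrix(gr$g, genes)
  Ap <- perturbgraph:::aggregation_matrix(gr$p, genes)
  pidx <- list(c(1L, 2L), 3L)
  Gs <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(3), 1, 3))
  Cs <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(3), 1, 3))
  gamma <- 1; p_exp <- 2 + gamma
  objective <- function(params) {
    fw <- perturbgraph:::gears_forward(params, Ag, Ap, pidx)
    L <- 0
    for (t in 1:2) {
      Tk <- nrow(Gs[[t]])
      E <- Gs[[t]] - (Cs[[t]] + rep(fw$Zhat[t, ], each = Tk))
      s <- rep(fw$Smat[t, ], each = Tk)
      L <- L + mean(exp(-s) * abs(E)^p_exp + s) / 2
    }
    L
  }
  fw <- perturbgraph:::gears_forward(params, Ag, Ap, pidx)
  dZ <- matrix(0, 2, 3); dS <- matrix(0, 2, 3)
  for (t in 1:2) {
    Tk <- nrow(Gs[[t]])
    E <- Gs[[t]] - (Cs[[t]] + rep(fw$Zhat[t, ], each = Tk))
    w <- rep(exp(-fw$Smat[t, ]), each = Tk)
    dZ[t, ] <- colSums(-p_exp * abs(E)^(p_exp - 1) * sign(E) * w) / (2 * Tk * 3)
    dS[t, ] <- colSums(-exp(-rep(fw$Smat[t, ], each = Tk)) * abs(E)^p_exp + 1) /
      (2 * Tk * 3)
  }
  gr_an <- perturbgraph:::gears_backward(params, fw, dZ, dS)
  eps <- 1e-6
  set.seed(82)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (objective(pp) - objective(pm)) / (2 * eps)
      expect_lt(abs(fd - gr_an[[nm]][i]), 1e-6 + 1e-4 * abs(fd))
    }
  }
})
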