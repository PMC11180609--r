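# Synthetic Perturb-seq generator with planted ground truth. Perturbation
# effect vectors are built from shared pathway factors, so genes annotated to
# the same pathways have correlated effects -- the structure the
# perturbation-similarity graph is meant to exploit. Two-gene conditions are
# additive except for planted pairs transformed per genetic-interaction
# subtype.

#' Simulation configuration
#'
#' Defaults describe a desk-scale activation screen: 100 genes, 40 single-
#' and 30 two-gene conditions (5 planted pairs per interaction subtype, the
#' rest additive), 50 cells per condition plus 500 controls, Gaussian noise
#' with sd 0.2 on the log-expression scale.
#'
#' @param n_genes K measured genes.
#' @param n_pathways number of pathway terms.
#' @param membership_density probability a gene carries a given pathway
#'   annotation.
#' @param n_single,n_double number of single-/two-gene conditions.
#' @param cells_per_condition,n_control cells per perturbed condition and
#'   control cells.
#' @param effect_scale sd of pathway-factor entries.
#' @param pathway_genes genes affected by each pathway factor.
#' @param neighbor_share fraction of a perturbation's effect vector inherited
#'   from its pathway factors (the rest is gene-individual); 1 makes
#'   same-pathway perturbations identical (up to the self effect), 0 makes
#'   them independent.
#' @param self_effect direct expression shift of the perturbed gene itself
#'   (activation).
#' @param planted named counts of planted pairs per subtype.
#' @param synergy_factor,suppression_factor combo = factor * (sum of
#'   singles) for those subtypes.
#' @param noise_sd Gaussian noise sd on log expression.
#' @param nb_counts also generate a negative-binomial raw-count layer.
#' @param seed RNG seed; the seed fully determines the output.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 100, n_pathways = 10, membership_density = 0.15,
                       n_single = 40, n_double = 30, cells_per_condition = 50,
                       n_control = 500, effect_scale = 1, pathway_genes = 20,
                       neighbor_share = 0.85, self_effect = 1,
                       planted = c(synergy = 5, suppression = 5,
                                   neomorphism = 5, redundancy = 5,
                                   epistasis = 5),
                       synergy_factor = 2, suppression_factor = 0.35,
                       noise_sd = 0.2,
                       nb_counts = FALSE, seed = 1L) {
  planted <- unlist(planted)
  cfg <- as.list(environment())
  stopifnot(n_genes > 0, n_single > 0, cells_per_condition > 0, n_control > 0,
            neighbor_share >= 0, neighbor_share <= 1, noise_sd >= 0)
  bad <- setdiff(names(planted),
                 c("synergy", "suppression", "neomorphism", "redundancy",
                   "epistasis"))
  if (length(bad)) stop("unknown planted subtypes: ", paste(bad, collapse = ", "))
  if (sum(planted) > n_double)
    stop("planted pair counts exceed the number of two-gene conditions")
  structure(cfg, class = "sim_config")
}

#' Simulate a Perturb-seq-like dataset with known ground truth
#'
#' Draws a synthetic pathway membership; gives each single perturbation a
#' true effect vector that mixes its pathway factors (weight
#' \code{neighbor_share}) with an individual component, plus a direct
#' activation of the target gene; makes two-gene conditions additive except
#' planted pairs, which are transformed per subtype (synergy: scaled-up sum;
#' suppression: scaled-down sum; neomorphism: component orthogonal to both
#' singles; redundancy: a pair whose singles are naturally near-duplicates
#' (shared pathways) with a sub-additive combo equal to one single;
#' epistasis: combo equals one single's effect, singles dissimilar). Planted
#' non-redundancy pairs use singles with dissimilar effects, since with
#' near-identical singles several subtypes become indistinguishable (a combo
#' equal to one of two interchangeable singles is redundancy, not epistasis).
#' Per-gene baselines are
#' shifted so every condition mean stays positive without clipping (clipping
#' would break planted additivity). Cells are condition mean plus Gaussian
#' noise on the log scale.
#'
#' @param config a [sim_config()].
#' @return list with \code{dataset} (a [perturb_dataset()]),
#'   \code{membership} (a [pathway_membership()]) and \code{truth}: list with
#'   \code{effects} (named list of true per-condition delta vectors),
#'   \code{pairs} (data.frame gene_a/gene_b/condition/subtype),
#'   \code{singles} (targets), \code{baseline} and \code{config}.
#' @export
simulate_perturb_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed))
  K <- config$n_genes
  genes <- sprintf("G%03d", seq_len(K))
  pathways <- sprintf("PW%02d", seq_len(config$n_pathways))

  memb <- lapply(genes, function(g)
    pathways[stats::runif(config$n_pathways) < config$membership_density])
  names(memb) <- genes
  membership <- pathway_membership(memb)

  sparse_vec <- function() {
    v <- numeric(K)
    idx <- sample(K, min(config$pathway_genes, K))
    v[idx] <- stats::rnorm(length(idx), 0, config$effect_scale)
    v
  }
  factors <- lapply(pathways, function(p) sparse_vec())
  names(factors) <- pathways

  annotated <- genes[lengths(membership) > 0]
  pool <- if (length(annotated) >= config$n_single) annotated else genes
  targets <- sample(pool, config$n_single)

  single_effect <- function(g) {
    terms <- membership[[g]]
    base <- if (length(terms))
      Reduce(`+`, factors[terms]) / length(terms) else numeric(K)
    e <- config$neighbor_share * base + (1 - config$neighbor_share) * sparse_vec()
    e[match(g, genes)] <- e[match(g, genes)] + config$self_effect
    e
  }
  singles <- lapply(targets, single_effect)
  names(singles) <- targets

  # Unordered pairs of single targets. Redundancy pairs take the pairs whose
  # singles are already near-duplicates (genes sharing pathways inherit
  # correlated effects, so interchangeable singles arise naturally and the
  # pathway-consistency contract of every single stays intact); the other
  # planted subtypes take dissimilar singles, since with near-identical
  # singles several subtypes become indistinguishable.
  all_pairs <- t(utils::combn(targets, 2))
  if (nrow(all_pairs) < config$n_double)
    stop("not enough single targets to form the requested two-gene conditions")
  ord <- sample(nrow(all_pairs))
  pair_cor <- vapply(ord, function(i)
    stats::cor(singles[[all_pairs[i, 1]]], singles[[all_pairs[i, 2]]]),
    numeric(1))
  n_red <- if ("redundancy" %in% names(config$planted))
    config$planted[["redundancy"]] else 0L
  red_pos <- order(-pair_cor)[seq_len(n_red)]
  if (n_red > 0 && min(pair_cor[red_pos]) < 0.8)
    stop("not enough naturally near-duplicate gene pairs for the requested ",
         "redundancy plantings; raise neighbor_share or n_single")
  other_labels <- rep(names(config$planted), config$planted)
  other_labels <- other_labels[other_labels != "redundancy"]
  pool_planted <- setdiff(which(abs(pair_cor) < 0.3), red_pos)
  if (length(pool_planted) < length(other_labels))
    stop("could not assemble the requested planted pairs; ",
         "lower the planted counts or raise n_single")
  planted_pos <- pool_planted[seq_along(other_labels)]
  pool_add <- setdiff(seq_along(ord), c(red_pos, planted_pos))
  n_add <- config$n_double - n_red - length(other_labels)
  if (length(pool_add) < n_add)
    stop("not enough remaining pairs for the additive two-gene conditions")
  chosen <- ord[c(red_pos, planted_pos, pool_add[seq_len(n_add)])]
  subtype_of <- c(rep("redundancy", n_red), other_labels, rep("additive", n_add))
  pairs <- data.frame(gene_a = all_pairs[chosen, 1],
                      gene_b = all_pairs[chosen, 2],
                      subtype = subtype_of, stringsAsFactors = FALSE)
  pairs$condition <- canonical_condition(paste(pairs$gene_a, pairs$gene_b,
                                               sep = "+"))

  orthogonalize <- function(v, basis) {
    for (b in basis) {
      nb <- sum(b^2)
      if (nb > 0) v <- v - sum(v * b) / nb * b
    }
    v
  }
  doubles <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    da <- singles[[a]]; db <- singles[[b]]
    doubles[[i]] <- switch(pairs$subtype[i],
      additive = da + db,
      synergy = config$synergy_factor * (da + db),
      suppression = config$suppression_factor * (da + db),
      neomorphism = {
        v <- orthogonalize(sparse_vec(), list(da, db))
        v / max(sqrt(sum(v^2)), 1e-12) * sqrt(sum((da + db)^2))
      },
      epistasis = da,
      redundancy = da)                 # sub-additive: combo equals one single
  }
  names(doubles) <- pairs$condition

  effects <- c(singles, doubles)
  # per-gene baseline shifted so all condition means stay positive unclipped
  min_eff <- Reduce(pmin, effects, accumulate = FALSE)
  baseline <- stats::runif(K, 1, 3) - pmin(0, min_eff)

  conds <- c("ctrl", paste0(targets, "+ctrl"), pairs$condition)
  n_cells <- c(config$n_control,
               rep(config$cells_per_condition, length(targets) + nrow(pairs)))
  means <- c(list(baseline),
             lapply(effects, function(e) baseline + e))
  expr <- do.call(rbind, lapply(seq_along(conds), function(i) {
    n <- n_cells[i]
    mu <- means[[i]]
    m <- matrix(stats::rnorm(n * K, 0, config$noise_sd), n, K, byrow = FALSE)
    pmax(m + rep(mu, each = n), 0)
  }))
  colnames(expr) <- genes
  cond_vec <- rep(conds, n_cells)
  ds <- perturb_dataset(expr, cond_vec, normalize = "none")

  truth <- list(effects = effects, pairs = pairs, singles = targets,
                baseline = baseline, factors = factors, config = config)
  out <- list(dataset = ds, membership = membership, truth = truth)
  if (isTRUE(config$nb_counts)) {
    mu_counts <- expm1(expr)
    size <- 10
    counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                    size = size), nrow(expr), K)
    colnames(counts) <- genes
    out$counts <- counts
  }
  out
}

#' Write a simulation to disk (MTX triplet + pathway TSV + truth JSON)
#'
#' Output is deterministic for a given simulation: identical inputs give
#' byte-identical files.
#'
#' @param sim result of [simulate_perturb_data()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset_mtx(sim$dataset, dir)
  write_pathways(sim$membership, file.path(dir, "pathways.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(pairs = truth$pairs, singles = truth$singles,
         baseline = truth$baseline,
         effects = lapply(truth$effects, unname),
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recovery report: predicted vs true perturbation effects
#'
#' Pearson correlation between each condition's predicted delta and its true
#' planted effect vector (zero-variance predictions score 0), plus per-
#' subtype ranking checks when a GI score table is supplied.
#'
#' @param truth the \code{truth} element of [simulate_perturb_data()].
#' @param predictions named list (condition -> predicted delta vector) or a
#'   matrix with condition rownames.
#' @return data.frame with condition, subtype (for pairs), pearson.
#' @export
truth_metrics <- function(truth, predictions) {
  if (is.matrix(predictions))
    predictions <- stats::setNames(
      lapply(seq_len(nrow(predictions)), function(i) predictions[i, ]),
      rownames(predictions))
  keys <- intersect(names(predictions), names(truth$effects))
  if (length(keys) == 0L) stop("no predicted conditions match the truth")
  data.frame(
    condition = keys,
    subtype = truth$pairs$subtype[match(keys, truth$pairs$condition)],
    pearson = vapply(keys, function(k) {
      p <- predictions[[k]]; e <- truth$effects[[k]]
      if (stats::sd(p) == 0 || stats::sd(e) == 0) 0 else stats::cor(p, e)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
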