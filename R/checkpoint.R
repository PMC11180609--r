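# Model checkpointing: one JSON file carrying every parameter tensor plus a
# sidecar header with the embedding dimension, gene lists, graph hashes and
# training config. Loading verifies that the gene list matches the saved
# hash, so a checkpoint cannot silently be applied to a different gene
# universe.

# small stable string hash (djb2-style polynomial over the UTF-8 bytes,
# kept in double-exact integer range)
hash_strings <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

graph_hash <- function(graph) {
  hash_strings(c(graph$kind, graph$nodes,
                 sprintf("%s>%s:%.6g", graph$edges$source, graph$edges$target,
                         graph$edges$weight)))
}

#' Save a fitted model to a single JSON checkpoint
#'
#' @param model a [gears()] object.
#' @param path output path (conventionally .json).
#' @export
save_gears <- function(model, path) {
  obj <- list(
    format = "perturbgraph-checkpoint-1",
    d = model$config$d,
    genes = model$genes,
    pert_genes = model$pert_genes,
    gene_hash = hash_strings(model$genes),
    graph_hash_gene = graph_hash(model$g_gene),
    graph_hash_pert = graph_hash(model$g_pert),
    config = model$config,
    ctrl_mean = unname(model$ctrl_mean),
    g_gene = list(nodes = model$g_gene$nodes, edges = model$g_gene$edges,
                  kind = model$g_gene$kind),
    g_pert = list(nodes = model$g_pert$nodes, edges = model$g_pert$edges,
                  kind = model$g_pert$kind),
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), x = as.vector(p)) else
        list(dim = length(p), x = as.vector(p)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_gears()].
#' @param genes optional expected gene list; loading fails if its hash does
#'   not match the checkpoint's.
#' @return a \code{gears} object (without training history).
#' @export
load_gears <- function(path, genes = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "perturbgraph-checkpoint-1"))
    stop("not a perturbgraph checkpoint: ", path)
  if (!identical(hash_strings(obj$genes), obj$gene_hash))
    stop("checkpoint gene list does not match its stored hash (corrupt file?)")
  if (!is.null(genes) && !identical(hash_strings(genes), obj$gene_hash))
    stop("checkpoint was trained on a different gene list")
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$x, p$dim[1], p$dim[2]) else as.numeric(p$x)
  })
  g_gene <- gene_graph(obj$g_gene$nodes, as.data.frame(obj$g_gene$edges),
                       kind = obj$g_gene$kind)
  g_pert <- gene_graph(obj$g_pert$nodes, as.data.frame(obj$g_pert$edges),
                       kind = obj$g_pert$kind)
  config <- obj$config
  structure(list(
    params = params, genes = obj$genes, pert_genes = obj$pert_genes,
    g_gene = g_gene, g_pert = g_pert,
    Ag = aggregation_matrix(g_gene, obj$genes, config$use_edge_weights),
    Ap = aggregation_matrix(g_pert, obj$pert_genes, config$use_edge_weights),
    ctrl_mean = stats::setNames(obj$ctrl_mean, obj$genes),
    config = config, history = NULL, split = NULL
  ), class = "gears")
}
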