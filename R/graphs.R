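#' Gene graph constructor
#'
#' A weighted directed graph over genes (or perturbations). An edge
#' \code{source -> target} records that \code{target} is one of
#' \code{source}'s top-H most similar genes; message passing aggregates each
#' node's selected neighbors (\code{target}s) into the node itself.
#'
#' @param nodes character vector of node identifiers.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{weight}.
#' @param kind "coexpression" or "perturbation_similarity".
#' @return an object of class \code{gene_graph}.
#' @export
gene_graph <- function(nodes, edges, kind = c("coexpression", "perturbation_similarity")) {
  kind <- match.arg(kind)
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (any(!is.finite(edges$weight))) stop("edge weights must be finite")
  if (!all(edges$source %in% nodes) || !all(edges$target %in% nodes))
    stop("edge endpoints must be graph nodes")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, kind = kind), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph (%s): %d nodes, %d directed edges\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  deg <- table(factor(x$edges$source, levels = x$nodes))
  cat(sprintf("  out-degree: median %d, max %d; %d isolated source nodes\n",
              as.integer(stats::median(deg)), max(as.integer(deg)), sum(deg == 0)))
  invisible(x)
}

# per-row top-H selection above a strict threshold; stable tie-break by
# (-similarity, column index). Returns an edge data.frame.
top_h_edges <- function(sim, nodes, H, threshold = -Inf) {
  K <- nrow(sim)
  diag(sim) <- -Inf
  out <- vector("list", K)
  for (u in seq_len(K)) {
    s <- sim[u, ]
    keep <- which(s > threshold & is.finite(s))
    if (length(keep) == 0L) next
    ord <- keep[order(-s[keep], keep)]
    ord <- ord[seq_len(min(H, length(ord)))]
    out[[u]] <- data.frame(source = nodes[u], target = nodes[ord],
                           weight = unname(s[ord]), stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  edges
}

#' Build the gene coexpression graph
#'
#' For each gene u, connects u to the top \code{h_gene} genes v with the
#' highest Pearson correlation rho_uv over the training cells, subject to
#' rho_uv > delta. Edge weight is rho_uv. Correlations involving a
#' zero-variance gene are defined as 0 (never NaN). Only the supplied training
#' cells are used, so the graph cannot leak information from held-out
#' conditions.
#'
#' @param ds a perturb_dataset.
#' @param h_gene cap on the out-degree of each gene (top-H selection).
#' @param delta correlation threshold in [0,1]; only rho > delta edges kept.
#' @param cells integer indices of the cells to use (default: all; pass the
#'   training partition's cells).
#' @return a [gene_graph()] of kind "coexpression".
#' @export
build_coexpression_graph <- function(ds, h_gene = 20, delta = 0.1, cells = NULL) {
  if (h_gene < 1) stop("h_gene must be >= 1")
  x <- if (is.null(cells)) ds$expr else ds$expr[cells, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 cells to compute correlations")
  rho <- suppressWarnings(stats::cor(x))
  rho[!is.finite(rho)] <- 0
  gene_graph(ds$genes, top_h_edges(rho, ds$genes, h_gene, delta),
             kind = "coexpression")
}

#' Pathway membership
#'
#' Bipartite gene-to-pathway relation, stored as a named list mapping each
#' gene to its (possibly empty) set of pathway term identifiers.
#'
#' @param x named list of character vectors (gene -> terms).
#' @return object of class \code{pathway_membership}.
#' @export
pathway_membership <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(v) sort(unique(as.character(v))))
  structure(x, class = "pathway_membership")
}

#' Read a two-column gene/term TSV into a pathway membership
#'
#' @param path TSV with columns \code{gene} and \code{term} (header optional).
#' @param genes optional gene universe; genes with no annotation get empty sets.
#' @return a [pathway_membership()].
#' @export
read_pathways <- function(path, genes = NULL) {
  tab <- utils::read.delim(path, header = looks_like_pathway_header(path),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("pathway TSV must have two columns: gene, term")
  names(tab)[1:2] <- c("gene", "term")
  memb <- split(tab$term, tab$gene)
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(memb))
    memb <- c(memb, stats::setNames(rep(list(character(0)), length(missing)), missing))
    memb <- memb[genes]
  }
  pathway_membership(memb)
}

looks_like_pathway_header <- function(f) {
  first <- tolower(strsplit(readLines(f, n = 1L), "\t")[[1]])
  any(first %in% c("gene", "term", "pathway", "go_id"))
}

#' Write a pathway membership as a two-column TSV
#' @param membership a pathway_membership.
#' @param path output file.
#' @export
write_pathways <- function(membership, path) {
  genes <- rep(names(membership), lengths(membership))
  terms <- unlist(membership, use.names = FALSE)
  utils::write.table(data.frame(gene = genes, term = terms),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jaccard similarity of two genes' pathway sets
#'
#' \eqn{J_{u,v} = |N_u \cap N_v| / |N_u \cup N_v|}; defined as 0 when both
#' sets are empty.
#'
#' @param membership a pathway_membership.
#' @param u,v gene identifiers present in the membership.
#' @return numeric in [0,1].
#' @export
jaccard_similarity <- function(membership, u, v) {
  if (!u %in% names(membership)) stop("gene not in membership: ", u)
  if (!v %in% names(membership)) stop("gene not in membership: ", v)
  nu <- membership[[u]]; nv <- membership[[v]]
  un <- length(union(nu, nv))
  if (un == 0L) return(0)
  length(intersect(nu, nv)) / un
}

# all-pairs Jaccard via the binary incidence matrix
jaccard_matrix <- function(membership, genes) {
  terms <- sort(unique(unlist(membership[genes], use.names = FALSE)))
  K <- length(genes)
  if (length(terms) == 0L) return(matrix(0, K, K, dimnames = list(genes, genes)))
  B <- matrix(0, K, length(terms), dimnames = list(genes, terms))
  for (g in genes) B[g, membership[[g]]] <- 1
  inter <- B %*% t(B)
  sizes <- rowSums(B)
  un <- outer(sizes, sizes, "+") - inter
  J <- ifelse(un > 0, inter / un, 0)
  dimnames(J) <- list(genes, genes)
  J
}

#' Build the perturbation similarity graph from pathway membership
#'
#' For each gene u, connects u to its top \code{h_pert} genes v by Jaccard
#' similarity of pathway sets (excluding u itself); zero-weight edges are
#' dropped, so genes with no shared pathways are isolated.
#'
#' @param membership a [pathway_membership()].
#' @param genes gene identifiers to build the graph over (graph nodes).
#' @param h_pert cap on the out-degree of each gene.
#' @return a [gene_graph()] of kind "perturbation_similarity".
#' @export
build_perturbation_graph <- function(membership, genes, h_pert = 20) {
  if (h_pert < 1) stop("h_pert must be >= 1")
  missing <- setdiff(genes, names(membership))
  if (length(missing)) {
    membership <- c(membership,
                    stats::setNames(rep(list(character(0)), length(missing)), missing))
  }
  J <- jaccard_matrix(membership, genes)
  gene_graph(genes, top_h_edges(J, genes, h_pert, threshold = 0),
             kind = "perturbation_similarity")
}

#' Write / read a gene graph as an edge-list TSV
#' @param graph a gene_graph.
#' @param path TSV with columns source, target, weight.
#' @export
write_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @param nodes node universe (defaults to the endpoints present in the file).
#' @param kind graph kind.
#' @export
read_edges <- function(path, nodes = NULL,
                       kind = c("coexpression", "perturbation_similarity")) {
  kind <- match.arg(kind)
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  gene_graph(nodes, edges, kind = kind)
}

# K x K sparse aggregation matrix A with A[u, v] = normalized weight of
# v's contribution to u (rows = edge sources). use_weights=FALSE gives 1/deg.
aggregation_matrix <- function(graph, nodes = graph$nodes, use_weights = TRUE) {
  K <- length(nodes)
  e <- graph$edges
  e <- e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE]
  if (nrow(e) == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                 x = numeric(0), dims = c(K, K)))
  i <- match(e$source, nodes); j <- match(e$target, nodes)
  w <- if (use_weights) abs(e$weight) else rep(1, nrow(e))
  tot <- tapply(w, i, sum)
  w <- w / as.numeric(tot[as.character(i)])
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(K, K))
}
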