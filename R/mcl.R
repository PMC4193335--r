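#' Markov clustering of a similarity graph
#'
#' Runs MCL on the weighted adjacency matrix: self-loops are added with
#' weight equal to the node's maximum incident edge weight (1 for isolated
#' nodes), columns are normalized to stochastic form, and the process
#' alternates expansion (matrix squaring) with inflation (entrywise power
#' followed by column renormalization) until the maximum entrywise change
#' between successive iterations falls below `tol` or `max_iter` iterations
#' have run.  Entries below `prune` are zeroed each iteration for stability.
#' Clusters are the connected components of the attractor graph: rows with a
#' positive diagonal attract the members of their positive columns.  Isolated
#' nodes become singleton clusters.
#'
#' @param graph An undirected `igraph` graph with optional `weight` edge
#'   attribute, or a symmetric non-negative numeric matrix with dimnames.
#' @param inflation Inflation exponent, must be > 1 (default 1.5).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence threshold on the maximum entrywise change.
#' @param prune Numerical floor below which entries are zeroed.
#' @return Data frame with columns `cluster_id` and `gene_id` (plus
#'   `genome_id` when the graph carries a `genome` vertex attribute).
#'   Cluster ids are assigned in decreasing size order (ties by first
#'   member).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 200L,
                        tol = 1e-8, prune = 1e-12) {
  if (inflation <= 1) stop("inflation must be > 1")
  genome <- NULL
  if (inherits(graph, "igraph")) {
    A <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
      igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
    A <- unname(as.matrix(A))
    dimnames(A) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
    if ("genome" %in% igraph::vertex_attr_names(graph)) {
      genome <- setNames(igraph::V(graph)$genome, igraph::V(graph)$name)
    }
  } else {
    A <- as.matrix(graph)
  }
  if (nrow(A) == 0L) {
    return(data.frame(cluster_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(rownames(A))) {
    dimnames(A) <- list(as.character(seq_len(nrow(A))),
                        as.character(seq_len(nrow(A))))
  }
  if (!isSymmetric(unname(A), tol = 1e-9)) stop("input matrix must be symmetric")
  if (any(A < 0)) stop("edge weights must be non-negative")
  nodes <- rownames(A)
  diag(A) <- 0
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # attractor interpretation
  thr <- 1e-6
  att <- which(diag(M) > thr)
  memb <- seq_along(nodes)  # union-find over node indices
  find <- function(x) { while (memb[x] != x) { memb[x] <<- memb[memb[x]]; x <- memb[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) memb[max(ra, rb)] <<- min(ra, rb) }
  for (r in att) {
    members <- which(M[r, ] > thr)
    for (c in members) unite(r, c)
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  comp <- split(nodes, root)
  sizes <- lengths(comp)
  first <- vapply(comp, function(x) sort(x)[1L], character(1))
  ordc <- order(-sizes, first)
  comp <- comp[ordc]
  out <- data.frame(
    cluster_id = rep(sprintf("C%04d", seq_along(comp)), lengths(comp)),
    gene_id = unlist(lapply(comp, sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(genome)) out$genome_id <- unname(genome[out$gene_id])
  rownames(out) <- NULL
  out
}
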