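#' Poisson-corrected distance matrix
#'
#' For each pair of rows of a gap-free alignment, the proportion of differing
#' columns `p` is transformed to `d = -ln(1 - p)`, the expected number of
#' amino-acid substitutions per site under a Poisson substitution process.
#' Run [complete_deletion()] first; a pair with `p >= 1` has no defined
#' distance and is an error naming the pair.
#'
#' @param msa Gap-free alignment (named character vector or `AAStringSet`).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
poisson_distance <- function(msa) {
  m <- msa_matrix(msa)
  if (any(m == "-" | m == "X")) {
    stop("alignment contains gaps or missing data; run complete_deletion() first")
  }
  n <- nrow(m); L <- ncol(m)
  taxa <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- sum(m[i, ] != m[j, ]) / L
      if (p >= 1) {
        stop("p-distance >= 1 between ", taxa[i], " and ", taxa[j],
             "; Poisson distance undefined")
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must have taxon names")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(!is.finite(D))) stop("distances must be finite")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' from the standard NJ formulas.  Negative branch lengths are clamped to
#' zero with the deficit moved to the sister branch (the behavior of common
#' desktop phylogeny software).  The result is unrooted (trifurcating root
#' node).
#'
#' @param D Symmetric distance matrix with taxon dimnames, at least 3 taxa.
#' @return An [ape] `phylo` object.
#' @export
nj_tree <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa for a neighbor-joining tree")
  labs <- rownames(D)
  nodes <- labs                       # newick fragment per active node
  D <- unname(D)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which.min(Q)                 # deterministic: first minimum, column-major
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; lj <- D[i, j] }
    if (lj < 0) { lj <- 0; li <- D[i, j] }
    newdist <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    newdist[newdist < 0] <- 0
    merged <- paste0("(", nodes[i], ":", fmt(li), ",", nodes[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist),
               c(newdist, 0))
    nodes <- c(nodes[keep], merged)
    n <- n - 1L
  }
  # closing trifurcation: three-point formulas
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", nodes[1], ":", fmt(x), ",", nodes[2], ":", fmt(y),
                ",", nodes[3], ":", fmt(z), ");")
  ape::read.tree(text = nwk)
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# for each internal edge, the tip set on the side NOT containing the
# reference taxon (the alphabetically smallest), sorted and joined by "|"
tree_bipartitions <- function(tree, by_node = FALSE) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  ord <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) tipsets[[t]] <- tree$tip.label[t]
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; c <- ord$edge[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[c]])
  }
  internal_children <- ord$edge[ord$edge[, 2L] > nt, 2L]
  keys <- vapply(internal_children, function(nd) {
    side <- tipsets[[nd]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  if (by_node) setNames(keys, internal_children) else keys
}

# contract the internal edges above the given child nodes, producing
# polytomies; branch lengths of contracted edges are dropped
collapse_tree_edges <- function(tree, child_nodes) {
  if (length(child_nodes) == 0L) return(tree)
  edge_rows <- match(child_nodes, tree$edge[, 2L])
  tree$edge.length[edge_rows] <- -1
  out <- ape::di2multi(tree, tol = -0.5)
  out
}

#' Bootstrap consensus tree with branch supports
#'
#' Resamples alignment columns with replacement to the original length, and
#' for each replicate recomputes [poisson_distance()] and [nj_tree()].  The
#' support of each internal bipartition of the full-data NJ tree is the
#' percentage of replicates containing it; branches supported by fewer than
#' 50% of replicates (or the given `collapse` threshold) are collapsed into
#' polytomies, with branch lengths taken from the full-data tree.
#' Replicates in which the Poisson distance is undefined are discarded; more
#' than 10% discarded is an error.  Deterministic for a fixed seed.
#'
#' @param msa Gap-free alignment.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param collapse Support threshold in percent below which branches are
#'   collapsed (default 50; use 0 to keep all branches).
#' @return An unrooted `phylo` tree; `node.label` holds the integer percent
#'   support of each retained internal branch.
#' @export
bootstrap_consensus <- function(msa, replicates = 1000L, seed = 1L,
                                collapse = 50) {
  if (replicates < 1L) stop("replicates must be >= 1")
  rows <- as_msa_chars(msa)
  m <- msa_matrix(rows)
  L <- ncol(m)
  ref <- nj_tree(poisson_distance(rows))
  ref_keys <- tree_bipartitions(ref, by_node = TRUE)
  counts <- setNames(rep(0L, length(ref_keys)), unname(ref_keys))
  # canonicalized resampling: row order of the alignment does not enter
  set.seed(seed)
  discarded <- 0L
  kept <- 0L
  taxa <- rownames(m)
  for (b in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- m[, idx, drop = FALSE]
    rows_b <- setNames(apply(sub, 1L, paste, collapse = ""), taxa)
    tr <- tryCatch(nj_tree(poisson_distance(rows_b)), error = function(e) NULL)
    if (is.null(tr)) { discarded <- discarded + 1L; next }
    kept <- kept + 1L
    keys_b <- tree_bipartitions(tr)
    hit <- names(counts) %in% keys_b
    counts[hit] <- counts[hit] + 1L
  }
  if (discarded > 0.1 * replicates) {
    stop(discarded, " of ", replicates, " replicates discarded (undefined distances)")
  }
  support <- 100 * counts / kept
  weak_nodes <- as.integer(names(ref_keys)[support[unname(ref_keys)] < collapse])
  out <- collapse_tree_edges(ref, weak_nodes)
  # reattach supports by bipartition key on the collapsed tree
  out_keys <- tree_bipartitions(out, by_node = TRUE)
  nt <- length(out$tip.label)
  labels <- rep("", out$Nnode)
  for (i in seq_along(out_keys)) {
    nd <- as.integer(names(out_keys)[i])
    labels[nd - nt] <- as.character(round(support[out_keys[i]]))
  }
  out$node.label <- labels
  attr(out, "replicates_kept") <- kept
  attr(out, "replicates_discarded") <- discarded
  out
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path.
#'
#' @param tree A `phylo` tree with positive total branch length.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    stop("midpoint rooting needs positive branch lengths")
  }
  if (length(tree$tip.label) == 2L) {
    tot <- sum(tree$edge.length)
    tree$edge.length <- rep(tot / 2, length(tree$edge.length))
    return(tree)
  }
  phangorn::midpoint(tree, node.labels = "support")
}

#' Robinson-Foulds distance between two trees
#'
#' Count of bipartitions present in exactly one of the two unrooted trees.
#'
#' @param a,b `phylo` trees over the same taxon set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(a, b) {
  ka <- tree_bipartitions(a)
  kb <- tree_bipartitions(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
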