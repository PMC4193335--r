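# Small fixture builders shared across test files.  Everything is generated
# in code at test time; no binary fixtures.

AA20_h <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20_h, len, replace = TRUE), collapse = "")
}

rand_protein_set <- function(n, len, seed = 1) {
  set.seed(seed)
  Biostrings::AAStringSet(setNames(
    vapply(seq_len(n), function(i) rand_protein(len), character(1)),
    sprintf("p%02d", seq_len(n))))
}

# random tree with strictly positive branch lengths plus its (additive)
# patristic distance matrix
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# weighted adjacency matrix of a union of disjoint cliques with random
# positive weights; returns the matrix and the planted component labels
random_clique_union <- function(seed, max_nodes = 30L) {
  set.seed(seed)
  sizes <- integer(0)
  while (sum(sizes) < 6L) {
    n_cliques <- sample(2:5, 1)
    sizes <- sample(2:6, n_cliques, replace = TRUE)
  }
  sizes <- sizes[cumsum(sizes) <= max_nodes]
  n <- sum(sizes)
  labels <- sprintf("n%02d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  memb <- rep(seq_along(sizes), sizes)
  for (k in seq_along(sizes)) {
    idx <- which(memb == k)
    for (i in idx) for (j in idx) if (i < j) {
      A[i, j] <- A[j, i] <- runif(1, 0.5, 2)
    }
  }
  list(A = A, membership = setNames(memb, labels))
}

# 3-clique helper for barbell-style graphs
barbell_graph <- function(w_in = 1, w_across = 0.1) {
  A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- w_in
  }
  A[3, 4] <- A[4, 3] <- w_across
  A
}

cluster_sets <- function(clusters) {
  unname(lapply(split(clusters$gene_id, clusters$cluster_id), sort))
}

# planted family membership as comparable set-of-sets
family_sets <- function(families) {
  unname(lapply(split(families$gene_id, families$family_id), sort))
}

same_partition <- function(a, b) {
  setequal(vapply(a, paste, "", collapse = ","),
           vapply(b, paste, "", collapse = ","))
}
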