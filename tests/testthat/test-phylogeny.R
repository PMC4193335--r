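test_that("progressive alignment handles identical, gapped and simulated inputs", {
  # identical sequences: gapless, all columns identical
  s <- rand_protein(30, seed = 1)
  al <- progressive_align(c(a = s, b = s))
  expect_identical(unname(al), c(s, s))

  # one-residue deletion: a single gap column, aligned length 3
  al2 <- progressive_align(c(x = "MKV", y = "MV"))
  expect_equal(unique(nchar(al2)), 3L)
  expect_identical(unname(al2["y"]), "M-V")

  expect_error(progressive_align(c(a = "MKV")), "at least 2")

  # low-divergence simulated family: planted columns recovered
  sim <- simulate_genomes(n_genomes = 5, n_core = 1, divergence = 0.1,
                          seed = 19, gene_len_nt = c(150, 180),
                          orphans_per_genome = 0)
  tr <- translate_calls(sim$genomes,
                        sim$truth$coords[, c("genome_id", "gene_id", "start",
                                             "end", "strand", "source")])
  seqs <- setNames(as.character(tr$proteins), unname(tr$genome_of))
  al3 <- progressive_align(seqs)
  # generator plants no indels, so homologous columns align gaplessly
  expect_false(any(grepl("-", al3, fixed = TRUE)))
  expect_equal(unique(nchar(al3)), unique(nchar(seqs)))
})

test_that("concatenation stitches per-cluster alignments with partitions", {
  a1 <- c(g1 = "MKVLA", g2 = "MKVIA")
  a2 <- c(g2 = "DDEE", g1 = "DDEE")
  cc <- concatenate_core(list(c1 = a1, c2 = a2))
  expect_equal(unique(nchar(cc)), 9L)
  expect_identical(unname(cc["g1"]), "MKVLADDEE")
  p <- attr(cc, "partitions")
  expect_equal(p$start, c(1L, 6L))
  expect_equal(p$end, c(5L, 9L))
  # single cluster: identity
  cc1 <- concatenate_core(list(c1 = a1))
  expect_identical(unname(cc1[names(a1)]), unname(a1))
  expect_error(concatenate_core(list(c1 = a1, c2 = a2[1])), "missing")
})

test_that("complete deletion removes exactly the gapped/missing columns", {
  msa <- c(a = "MKVLA", b = "MK-LA", c = "MKVLA")
  cd <- complete_deletion(msa)
  expect_equal(unique(nchar(cd)), 4L)
  expect_identical(unname(cd["b"]), "MKLA")
  expect_equal(attr(cd, "column_map"), c(1L, 2L, 4L, 5L))
  # gapless input unchanged
  msa2 <- c(a = "MKVLA", b = "MKVIA")
  expect_equal(complete_deletion(msa2), msa2, ignore_attr = TRUE)
  # X counts as missing data
  msa3 <- c(a = "MXVLA", b = "MKVLA")
  expect_equal(unique(nchar(complete_deletion(msa3))), 4L)
  expect_error(complete_deletion(c(a = "-K", b = "M-")), "no ungapped columns")
})

test_that("Poisson correction matches its closed form", {
  # identical rows: distance 0
  expect_equal(unname(poisson_distance(c(a = "AAAA", b = "AAAA"))["a", "b"]), 0)
  # p = 0.5 -> 0.6931; p = 0.1 -> 0.10536
  d5 <- poisson_distance(c(a = "AAAAAAAAAA", b = "AAAAACCCCC"))["a", "b"]
  expect_equal(d5, -log(0.5), tolerance = 1e-12)
  expect_equal(round(d5, 4), 0.6931)
  d1 <- poisson_distance(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))["a", "b"]
  expect_equal(d1, -log(0.9), tolerance = 1e-12)
  expect_equal(round(d1, 5), 0.10536)
  expect_error(poisson_distance(c(a = "AC", b = "CA")), "a and b")
  expect_error(poisson_distance(c(a = "A-", b = "AA")), "complete_deletion")
  # Poisson distance always >= p-distance
  set.seed(2)
  for (i in 1:10) {
    x <- rand_protein(60); y <- rand_protein(60)
    p <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (p < 1) {
      expect_gte(poisson_distance(c(a = x, b = y))["a", "b"], p)
    }
  }
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(pd), unname(D), tolerance = 1e-12)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- -1
  expect_error(nj_tree(Dn), "non-negative")
})

test_that("neighbor joining recovers the quartet topology from the additive matrix", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_true(paste(sort(c("C", "D")), collapse = "|") %in%
                n4core:::tree_bipartitions(tr) ||
              paste(sort(c("A", "B")), collapse = "|") %in%
                n4core:::tree_bipartitions(tr))
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(pd), unname(D), tolerance = 1e-12)
})

test_that("neighbor joining is exact on additive matrices and agrees with ape", {
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    case <- random_additive_case(n, seed)
    tr <- nj_tree(case$D)
    # topology identical to the generating tree (both oracles)
    expect_equal(rf_distance(tr, case$tree), 0)
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr),
                                              ape::unroot(case$tree))), 0)
    # path lengths reproduced (additivity)
    pd <- ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)]
    expect_equal(unname(pd), unname(case$D), tolerance = 1e-9)
    # independent implementation agrees on topology
    ref <- ape::nj(as.dist(case$D))
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr),
                                              ape::unroot(ref))), 0)
  }
})

test_that("midpoint rooting balances the two deepest subtrees", {
  # 2-leaf tree with branch lengths 1 and 3: root at distance 2 from each
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(t2)
  expect_equal(sort(r2$edge.length), c(2, 2))
  # symmetric quartet: root on the central branch
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r4 <- midpoint_root(t4)
  d <- ape::node.depth.edgelength(r4)[seq_along(r4$tip.label)]
  expect_equal(max(d), 2)
  expect_error(midpoint_root(ape::read.tree(text = "((A:0,B:0):0,C:0);")),
               "positive branch lengths")
  # property: the deepest root-to-leaf paths on the two sides of the root
  # have equal length
  for (seed in 1:20) {
    set.seed(seed)
    tr <- ape::rtree(sample(4:12, 1), br = function(k) runif(k, 0.1, 2))
    rt <- midpoint_root(ape::unroot(tr))
    nt <- length(rt$tip.label)
    depths <- ape::node.depth.edgelength(rt)[seq_len(nt)]
    root_kids <- rt$edge[rt$edge[, 1] == nt + 1L, 2]
    side_max <- vapply(root_kids, function(k) {
      tips <- unlist(phangorn::Descendants(rt, k, "tips"))
      max(depths[tips])
    }, numeric(1))
    side_max <- sort(side_max, decreasing = TRUE)
    expect_equal(side_max[1], side_max[2], tolerance = 1e-8)
  }
})

test_that("bootstrap consensus reports supports and collapses weak branches", {
  # replicates = 1: the consensus is that replicate's tree, all supports 100
  sim <- simulate_genomes(n_genomes = 5, n_core = 2, divergence = 0.2,
                          seed = 61, gene_len_nt = c(150, 240),
                          orphans_per_genome = 0)
  tr <- translate_calls(sim$genomes,
                        sim$truth$coords[, c("genome_id", "gene_id", "start",
                                             "end", "strand", "source")])
  alns <- lapply(split(sim$truth$families$gene_id, sim$truth$families$family_id),
                 function(genes) {
    seqs <- setNames(as.character(tr$proteins[genes]),
                     unname(tr$genome_of[genes]))
    progressive_align(seqs)
  })
  msa <- complete_deletion(concatenate_core(alns))
  one <- bootstrap_consensus(msa, replicates = 1, seed = 5)
  expect_true(all(one$node.label[one$node.label != ""] == "100"))

  # strongly resolved data keep the generating topology at high support
  bt <- bootstrap_consensus(msa, replicates = 100, seed = 7)
  expect_equal(rf_distance(bt, sim$truth$tree), 0)
  sup <- as.numeric(bt$node.label[bt$node.label != ""])
  expect_true(all(sup >= 50))
})

test_that("clade support tracks the diagnostic-column resampling expectation", {
  # 6 identical sequences except one column diagnostic for {D,E,F}; the
  # chance a bootstrap replicate retains the clade is 1 - (1 - 1/L)^L
  L <- 20L
  base <- strrep("A", L - 1L)
  msa <- c(A = paste0(base, "A"), B = paste0(base, "A"), C = paste0(base, "A"),
           D = paste0(base, "K"), E = paste0(base, "K"), F = paste0(base, "K"))
  R <- 100L
  bt <- bootstrap_consensus(msa, replicates = R, seed = 13, collapse = 0)
  keys <- n4core:::tree_bipartitions(bt, by_node = TRUE)
  nt <- length(bt$tip.label)
  clade_key <- paste(sort(c("D", "E", "F")), collapse = "|")
  # the clade may be keyed by either side; find its node label
  node <- names(keys)[keys == clade_key |
                        keys == paste(sort(c("A", "B", "C")), collapse = "|")]
  expect_length(node, 1L)
  sup <- as.numeric(bt$node.label[as.integer(node) - nt])
  q <- 1 - (1 - 1 / L)^L
  expect_lt(abs(sup / 100 - q), 3 * sqrt(q * (1 - q) / R))
})

test_that("bootstrap supports are invariant to taxon input order", {
  sim <- simulate_genomes(n_genomes = 6, n_core = 2, divergence = 0.25,
                          seed = 71, gene_len_nt = c(150, 240),
                          orphans_per_genome = 0)
  tr <- translate_calls(sim$genomes,
                        sim$truth$coords[, c("genome_id", "gene_id", "start",
                                             "end", "strand", "source")])
  alns <- lapply(split(sim$truth$families$gene_id, sim$truth$families$family_id),
                 function(genes) {
    seqs <- setNames(as.character(tr$proteins[genes]),
                     unname(tr$genome_of[genes]))
    progressive_align(seqs)
  })
  msa <- complete_deletion(concatenate_core(alns))
  b1 <- bootstrap_consensus(msa, replicates = 50, seed = 3)
  b2 <- bootstrap_consensus(msa[rev(names(msa))], replicates = 50, seed = 3)
  k1 <- n4core:::tree_bipartitions(b1, by_node = TRUE)
  k2 <- n4core:::tree_bipartitions(b2, by_node = TRUE)
  nt <- length(b1$tip.label)
  s1 <- setNames(b1$node.label[as.integer(names(k1)) - nt], unname(k1))
  s2 <- setNames(b2$node.label[as.integer(names(k2)) - nt], unname(k2))
  expect_setequal(names(s1), names(s2))
  expect_identical(s1[sort(names(s1))], s2[sort(names(s1))])
})
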