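# a CDS encoding a fixed, non-repetitive protein for exact-substring tests
make_gene <- function(len_aa = 120, seed = 33) {
  set.seed(seed)
  aa <- c("M", sample(AA20_h, len_aa - 1, TRUE))
  codons <- vapply(aa, function(a) {
    opts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    sample(opts, 1)
  }, "")
  codons[1] <- "ATG"
  paste(c(codons, "TAA"), collapse = "")
}

mk_sample <- function(reads, id = "S1", n = length(reads), env = NA_character_) {
  list(sample_id = id,
       reads = Biostrings::DNAStringSet(reads),
       n_sequences = n, environment = env)
}

test_that("an exact substring read is recruited at full identity in one frame", {
  nt <- make_gene()
  genes <- Biostrings::DNAStringSet(c(geneA = nt))
  read <- substr(nt, 31, 120)  # 90-nt in-frame substring
  h <- translated_search(genes, mk_sample(c(r1 = read)))
  expect_gt(nrow(h), 0)
  best <- h[which.min(h$evalue), ]
  expect_equal(best$pct_identity, 100)
  expect_equal(best$read_frame, 1L)
  expect_equal(best$gene_frame, 1L)
  expect_lte(best$evalue, 1e-4)
})

test_that("a reverse-complemented substring is found via a negative frame", {
  nt <- make_gene()
  genes <- Biostrings::DNAStringSet(c(geneA = nt))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(nt, 31, 120))))
  h <- translated_search(genes, mk_sample(c(r1 = rc)))
  expect_gt(nrow(h), 0)
  best <- h[which.min(h$evalue), ]
  expect_equal(best$pct_identity, 100)
  expect_lt(best$read_frame, 0L)
})

test_that("an out-of-frame substring is still recruited (six frames searched)", {
  nt <- make_gene()
  genes <- Biostrings::DNAStringSet(c(geneA = nt))
  read <- substr(nt, 32, 121)  # +2 offset relative to codon structure
  h <- translated_search(genes, mk_sample(c(r1 = read)))
  expect_gt(nrow(h), 0)
  expect_lte(min(h$evalue), 1e-4)
})

test_that("random reads almost never hit an unrelated gene", {
  nt <- make_gene(seed = 99)
  genes <- Biostrings::DNAStringSet(c(geneA = nt))
  set.seed(123)
  reads <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""), "")
  names(reads) <- paste0("r", 1:1000)
  h <- translated_search(genes, mk_sample(reads))
  expect_lte(length(unique(h$read_id)), 10L)  # >= 99% of reads hit nothing
  expect_error(translated_search(Biostrings::DNAStringSet(), mk_sample(reads)),
               "empty gene list")
})

test_that("reciprocal filter ranks panel proteins and applies the top-k rule", {
  target <- rand_protein(80, seed = 7)
  mutate <- function(s, n, seed) {
    set.seed(seed); x <- strsplit(s, "")[[1]]
    i <- sample(seq_along(x), n)
    x[i] <- vapply(x[i], function(a) sample(setdiff(AA20_h, a), 1), "")
    paste(x, collapse = "")
  }
  # focal protein is an exact match; four relatives at increasing divergence
  prots <- Biostrings::AAStringSet(c(
    focal_p = target,
    rel1_p = mutate(target, 5, 1), rel2_p = mutate(target, 10, 2),
    rel3_p = mutate(target, 15, 3), rel4_p = mutate(target, 20, 4)))
  panel <- viral_panel(prots, c(focal_p = "FOCAL", rel1_p = "REL1",
                                rel2_p = "REL2", rel3_p = "REL3",
                                rel4_p = "REL4"))
  expect_true(reciprocal_filter(target, panel, "FOCAL", k = 1))
  # focal at rank 5 when four relatives match the segment better
  seg2 <- mutate(target, 40, 9)         # distant from everything
  far_panel <- viral_panel(Biostrings::AAStringSet(c(
    a_p = seg2, b_p = mutate(seg2, 2, 11), c_p = mutate(seg2, 3, 12),
    d_p = mutate(seg2, 4, 13), focal_p = target)),
    c(a_p = "A", b_p = "B", c_p = "C", d_p = "D", focal_p = "FOCAL"))
  expect_false(reciprocal_filter(seg2, far_panel, "FOCAL", k = 4))
  # k = panel size always admits any focal hit
  expect_true(reciprocal_filter(seg2, far_panel, "FOCAL", k = 5))
  expect_error(reciprocal_filter(seg2, far_panel, "FOCAL", k = 0), "k must be")
  expect_error(reciprocal_filter("", far_panel, "FOCAL"), "empty read segment")
})

test_that("reciprocal filter keeps reads of the focal phage among close relatives", {
  # clade of 5 related phages carrying a shared diverged family; a read from
  # the focal member must keep the focal phage in its top 4
  sim <- simulate_genomes(n_genomes = 5, n_core = 1, divergence = 0.15,
                          seed = 43, gene_len_nt = c(240, 300),
                          orphans_per_genome = 0)
  tr <- translate_calls(sim$genomes,
                        sim$truth$coords[, c("genome_id", "gene_id", "start",
                                             "end", "strand", "source")])
  panel <- viral_panel(tr$proteins, setNames(unname(tr$genome_of),
                                             names(tr$genome_of)))
  focal_gene <- names(tr$genome_of)[tr$genome_of == "G01"][1]
  seg <- substr(as.character(tr$proteins[[focal_gene]]), 10, 45)
  expect_true(reciprocal_filter(seg, panel, "G01", k = 4))
  h <- data.frame(gene_id = "g", read_id = "r", read_segment = seg,
                  stringsAsFactors = FALSE)
  expect_equal(nrow(filter_hits(h, panel, "G01", k = 4)), 1L)
})

test_that("abundance normalization follows the stated formula", {
  counts <- matrix(c(10L, 0L), 1, 2,
                   dimnames = list("g1", c("S1", "S2")))
  # raw value 10/1000/100 = 1e-4; grand mean (1e-4 + 0)/2 = 5e-5; scaled 2.0
  ab <- abundance(counts, c(S1 = 1000, S2 = 1000), c(g1 = 100))
  expect_equal(ab$scaling_mean, 5e-5)
  expect_equal(unname(ab$normalized["g1", ]), c(2, 0))

  # all counts equal with equal sizes and lengths: everything scales to 1
  eq <- abundance(matrix(5L, 2, 2, dimnames = list(c("a", "b"), c("S1", "S2"))),
                  c(S1 = 100, S2 = 100), c(a = 50, b = 50))
  expect_true(all(eq$normalized == 1))

  # doubling one sample's counts doubles its scaled values in a fixed context
  m1 <- matrix(c(4L, 6L, 8L, 12L), 2, 2,
               dimnames = list(c("a", "b"), c("S1", "S2")))
  ab1 <- abundance(m1, c(S1 = 100, S2 = 100), c(a = 50, b = 50))
  expect_equal(unname(ab1$normalized[, "S2"] / ab1$normalized[, "S1"]), c(2, 2))

  z <- matrix(0L, 1, 1, dimnames = list("g", "S"))
  expect_error(abundance(z, c(S = 10), c(g = 10)), "scaling mean undefined")
  zz <- abundance(z, c(S = 10), c(g = 10), allow_zero = TRUE)
  expect_true(all(zz$normalized == 0))
  expect_error(abundance(m1, c(S1 = 0, S2 = 100), c(a = 50, b = 50)), "positive")
})

test_that("environment grouping averages normalized abundances per label", {
  m <- matrix(c(1, 3, 5), 1, 3, dimnames = list("g", c("S1", "S2", "S3")))
  ab <- abundance(m, c(S1 = 1, S2 = 1, S3 = 1), c(g = 1))
  lab <- c(S1 = "coastal", S2 = "coastal", S3 = "open ocean")
  gr <- group_by_environment(ab, lab)
  expect_equal(unname(gr["g", "coastal"]),
               mean(ab$normalized["g", c("S1", "S2")]))
  # one-sample group: identity
  expect_equal(unname(gr["g", "open ocean"]), ab$normalized["g", "S3"][[1]])
  expect_error(group_by_environment(ab, lab[1:2]), "unlabeled sample")
})

test_that("per-read counting collapses multiple frame-level hits", {
  h <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                  read_id = c("r1", "r1", "r2", "r1"),
                  stringsAsFactors = FALSE)
  counts <- count_hits(list(S1 = h), c("g1", "g2"))
  expect_equal(unname(counts[, "S1"]), c(2L, 1L))
})
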