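# Synthetic phage-genome generator with planted ground truth.
#
# The generator emulates the architecture of a phage genus: a syntenic core
# shared by all genomes, clade-specific and partially-shared accessory genes
# inserted at fixed hotspot positions between core blocks, orphan genes
# unique to single genomes, and intergenic spacers of configurable GC
# content.  Protein evolution follows a Poisson substitution process with
# uniform exchangeabilities along a known tree, which makes the
# Poisson-corrected distance of the phylogeny stage a consistent estimator
# by construction.  Codons are inherited along the tree and redrawn
# (uniformly among synonymous codons) only at substituted sites, so at zero
# divergence all genomes carry byte-identical core genes.

GENETIC_CODE_REV <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_protein <- function(len) {
  c("M", sample(AA20, len - 1L, replace = TRUE))
}

codons_for <- function(aa_vec) {
  vapply(aa_vec, function(a) {
    opts <- GENETIC_CODE_REV[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
}

# evolve protein + codons along the tree; returns per-tip codon vectors
evolve_family <- function(tree, anc_aa, anc_cod) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  tips <- vector("list", nt)
  recurse <- function(node, aa, cod) {
    kids <- which(tree$edge[, 1L] == node)
    if (length(kids) == 0L) {
      tips[[node]] <<- cod
      return(invisible())
    }
    for (e in kids) {
      child <- tree$edge[e, 2L]
      b <- tree$edge.length[e]
      aa2 <- aa; cod2 <- cod
      if (b > 0 && length(aa) > 1L) {
        p_sub <- 1 - exp(-b)
        hit <- which(runif(length(aa) - 1L) < p_sub) + 1L  # site 1 (M) fixed
        for (s in hit) {
          aa2[s] <- sample(setdiff(AA20, aa2[s]), 1L)
          cod2[s] <- codons_for(aa2[s])
        }
      }
      recurse(child, aa2, cod2)
    }
  }
  recurse(root, anc_aa, anc_cod)
  setNames(tips[seq_len(nt)], tree$tip.label)
}

random_spacer <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a set of related phage genomes with planted gene families
#'
#' Generates a random rooted binary tree over `n_genomes` genomes (branch
#' lengths scaled so that the mean root-to-tip depth equals `divergence`
#' expected amino-acid substitutions per site), plants `n_core` core gene
#' families evolved along the tree, optional clade-exclusive and
#' clade-shared accessory families, and per-genome orphan genes, assembles
#' genomes with intergenic spacers, and records full ground truth.
#'
#' @param n_genomes Number of genomes (>= 3).
#' @param n_core Number of core families present in every genome.
#' @param clade Optional clade definition: a list with `members` (genome
#'   ids), `n_exclusive` (families present in all members and nowhere else)
#'   and `n_shared` (families present in all members plus a random proper
#'   subset of outsiders).
#' @param divergence Expected amino-acid substitutions per site from root to
#'   tip, in (0, 1].  Zero is allowed and yields identical core genes.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param gene_len_nt Range of gene lengths in nucleotides (start and stop
#'   codon included; rounded to multiples of 3).
#' @param orphans_per_genome Orphan (genome-unique) genes per genome.
#' @param spacer_len Range of intergenic spacer lengths.
#' @param spacer_gc GC content of intergenic spacers (default 0.49, the GC
#'   content of the roseophage genomes this generator emulates).
#' @param start_freq Sampling weights of the `ATG`, `GTG`, `TTG` initiators.
#' @return List with `genomes` (named `DNAStringSet`) and `truth`, a list
#'   holding `tree` (the generating `phylo`), `families` (data frame:
#'   `family_id`, `class`, `genome_id`, `gene_id`), `coords` (planted CDS
#'   calls with the coding-orientation nucleotide sequence in `seq_nt`),
#'   and `seed`.
#' @export
simulate_genomes <- function(n_genomes = 10L, n_core = 8L, clade = NULL,
                             divergence = 0.2, seed = 1L,
                             gene_len_nt = c(150L, 900L),
                             orphans_per_genome = 2L,
                             spacer_len = c(60L, 120L), spacer_gc = 0.49,
                             start_freq = c(ATG = 0.9, GTG = 0.05, TTG = 0.05)) {
  if (n_genomes < 3L) stop("n_genomes must be >= 3")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(n_genomes))
  if (!is.null(clade)) {
    if (!all(clade$members %in% ids)) stop("clade members must be a subset of the genomes")
    if (length(clade$members) >= n_genomes) stop("clade must be a proper subset")
  }
  # generating tree: random topology, branch lengths uniform in [0.1, 1]
  # before scaling (bounded away from zero so every internal edge carries
  # signal), scaled to the requested mean root-to-tip depth
  tree <- ape::rtree(n_genomes, tip.label = ids,
                     br = function(n) runif(n, 0.1, 1))
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_genomes)]
  tree$edge.length <- tree$edge.length * divergence / mean(depths)

  fam <- list()
  add_family <- function(class, members) {
    fam[[length(fam) + 1L]] <<- list(class = class, members = members)
  }
  for (i in seq_len(n_core)) add_family("core", ids)
  n_excl <- 0L; n_shared <- 0L
  if (!is.null(clade)) {
    n_excl <- clade$n_exclusive %||% 0L
    n_shared <- clade$n_shared %||% 0L
    outsiders <- setdiff(ids, clade$members)
    for (i in seq_len(n_excl)) add_family("clade_exclusive", clade$members)
    for (i in seq_len(n_shared)) {
      n_extra <- sample.int(max(length(outsiders) - 1L, 1L), 1L)
      add_family("clade_shared",
                 c(clade$members, sample(outsiders, n_extra)))
    }
  }
  for (g in ids) {
    for (i in seq_len(orphans_per_genome)) add_family("orphan", g)
  }
  fam_ids <- sprintf("F%03d", seq_along(fam))

  # ancestral proteins and codons; evolve non-orphan families along the tree
  aa_range <- pmax(round(gene_len_nt / 3) - 1L, 10L)  # residues incl. start M
  tip_codons <- vector("list", length(fam))
  for (k in seq_along(fam)) {
    len_aa <- sample(aa_range[1L]:aa_range[2L], 1L)
    anc_aa <- random_protein(len_aa)
    anc_cod <- codons_for(anc_aa)
    if (fam[[k]]$class == "orphan") {
      tip_codons[[k]] <- setNames(list(anc_cod), fam[[k]]$members)
    } else {
      tip_codons[[k]] <- evolve_family(tree, anc_aa, anc_cod)
    }
  }

  # gene order: core families in index order; accessory families at fixed
  # hotspots (after a core block drawn once per family); orphans at random
  # hotspots per genome
  hotspot <- integer(length(fam))
  for (k in seq_along(fam)) {
    hotspot[k] <- if (fam[[k]]$class == "core") match(k, which(
      vapply(fam, function(f) f$class == "core", logical(1))))
    else sample.int(n_core + 1L, 1L) - 1L  # insert after this many core genes
  }

  genomes <- character(n_genomes)
  coords <- list()
  families <- list()
  for (gi in seq_along(ids)) {
    g <- ids[gi]
    members_k <- which(vapply(fam, function(f) g %in% f$members, logical(1)))
    core_k <- members_k[vapply(members_k, function(k) fam[[k]]$class == "core", logical(1))]
    acc_k <- setdiff(members_k, core_k)
    slot <- hotspot[acc_k]
    # genome gene order: accessory genes interleaved after their hotspot core
    order_k <- integer(0)
    for (pos in 0:n_core) {
      order_k <- c(order_k, acc_k[slot == pos][order(acc_k[slot == pos])])
      if (pos < n_core) order_k <- c(order_k, core_k[pos + 1L])
    }
    seq_parts <- character(0)
    cursor <- 0L
    gene_n <- 0L
    for (k in order_k) {
      sp <- random_spacer(sample(spacer_len[1L]:spacer_len[2L], 1L), spacer_gc)
      cod <- tip_codons[[k]][[g]]
      start_codon <- sample(names(start_freq), 1L, prob = start_freq)
      stop_codon <- sample(STOP_CODONS, 1L)
      nt <- paste(c(start_codon, cod[-1L], stop_codon), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "+") nt else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
      gene_n <- gene_n + 1L
      gstart <- cursor + nchar(sp) + 1L
      gend <- gstart + nchar(nt) - 1L
      seq_parts <- c(seq_parts, sp, placed)
      cursor <- gend
      gene_id <- sprintf("%s_g%03d", g, gene_n)
      coords[[length(coords) + 1L]] <- data.frame(
        genome_id = g, gene_id = gene_id, start = gstart, end = gend,
        strand = strand, source = "planted", family_id = fam_ids[k],
        seq_nt = nt, stringsAsFactors = FALSE)
      families[[length(families) + 1L]] <- data.frame(
        family_id = fam_ids[k], class = fam[[k]]$class, genome_id = g,
        gene_id = gene_id, stringsAsFactors = FALSE)
    }
    tail_sp <- random_spacer(sample(spacer_len[1L]:spacer_len[2L], 1L), spacer_gc)
    genomes[gi] <- paste(c(seq_parts, tail_sp), collapse = "")
  }
  genomes <- Biostrings::DNAStringSet(setNames(genomes, ids))
  coords <- do.call(rbind, coords)
  families <- do.call(rbind, families)
  list(genomes = genomes,
       truth = list(tree = tree, families = families, coords = coords,
                    clade = clade, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a pair of imperfect gene-predictor outputs
#'
#' Derives two CDS call sets from the planted truth.  Each predictor
#' independently drops a call with probability `miss_rate` and, with
#' probability `start_error_rate`, truncates a call's start downstream to
#' the next in-frame alternative initiator (`ATG`/`GTG`/`TTG`) within the
#' gene (calls without such an initiator are left intact).
#'
#' @param truth Truth list from [simulate_genomes()].
#' @param start_error_rate,miss_rate Error rates in `[0, 1)`; a scalar
#'   applies to both predictors, a length-2 vector gives per-predictor
#'   rates.
#' @param seed Integer seed.
#' @return List of two CDS call data frames (`source` `"predA"`/`"predB"`).
#' @export
simulate_predictor_pair <- function(truth, start_error_rate = 0.1,
                                    miss_rate = 0, seed = 1L) {
  ser <- rep_len(start_error_rate, 2L)
  mr <- rep_len(miss_rate, 2L)
  if (any(ser < 0 | ser >= 1) || any(mr < 0 | mr >= 1)) {
    stop("rates must be in [0, 1)")
  }
  set.seed(seed)
  coords <- truth$coords
  out <- vector("list", 2L)
  for (p in 1:2) {
    label <- c("predA", "predB")[p]
    keep <- runif(nrow(coords)) >= mr[p]
    calls <- coords[keep, , drop = FALSE]
    err <- runif(nrow(calls)) < ser[p]
    for (i in which(err)) {
      nt <- calls$seq_nt[i]
      ncod <- nchar(nt) %/% 3L
      pos <- 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(nt, pos, pos + 2L)
      alt <- which(codons[2:(ncod - 1L)] %in% ALT_STARTS)
      if (length(alt) == 0L) next
      shift <- 3L * alt[1L]              # bases removed from the 5' end
      if (calls$strand[i] == "+") {
        calls$start[i] <- calls$start[i] + shift
      } else {
        calls$end[i] <- calls$end[i] - shift
      }
    }
    calls$gene_id <- paste0(label, "_", calls$gene_id)
    calls$source <- label
    out[[p]] <- calls[, c("genome_id", "gene_id", "start", "end",
                          "strand", "source")]
    rownames(out[[p]]) <- NULL
  }
  names(out) <- c("predA", "predB")
  out
}

#' Simulate a metagenome read sample
#'
#' Reads are exact substrings of the source genomes: the genome is chosen
#' proportionally to its abundance weight times its length (weights are
#' genome copy numbers, and a shotgun read samples bases, so a genome's
#' read share scales with copies x size), the position uniformly, and the
#' strand uniformly.  A `background_frac` fraction of reads are i.i.d.
#' random nucleotides at the mean GC content of the genomes.
#'
#' @param genomes Named `DNAStringSet`.
#' @param abundances Named non-negative per-copy abundance weights per
#'   genome.
#' @param n_reads Number of reads (also recorded as the database size).
#' @param read_len Read length (>= 60).
#' @param background_frac Fraction of background reads in `[0, 1]`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param environment Optional environment label (e.g. `"coastal"`).
#' @return Metagenome sample: list with `sample_id`, `reads` (named
#'   `DNAStringSet`), `n_sequences`, `environment`, and `read_origin` (data
#'   frame of per-read source genome, position and strand; background reads
#'   have genome `"background"`).
#' @export
simulate_metagenome <- function(genomes, abundances, n_reads = 1000L,
                                read_len = 100L, background_frac = 0,
                                seed = 1L, sample_id = "S1",
                                environment = NA_character_) {
  if (read_len < 60L) stop("read_len must be >= 60")
  abundances <- abundances[names(genomes)]
  if (anyNA(abundances) || any(abundances < 0)) {
    stop("abundances must be non-negative weights named by genome")
  }
  if (sum(abundances) == 0 && background_frac < 1) {
    stop("all-zero abundance weights with background_frac < 1")
  }
  set.seed(seed)
  n_bg <- round(n_reads * background_frac)
  n_gen <- n_reads - n_bg
  gseq <- as.character(genomes)
  glen <- nchar(gseq)
  gc <- mean(gc_content(genomes))
  origin <- character(n_reads); pos <- integer(n_reads); strand <- character(n_reads)
  reads <- character(n_reads)
  if (n_gen > 0L) {
    prob <- abundances * glen[names(genomes)]
    pick <- sample(names(genomes), n_gen, replace = TRUE,
                   prob = prob / sum(prob))
    for (i in seq_len(n_gen)) {
      g <- pick[i]
      p <- sample.int(glen[[g]] - read_len + 1L, 1L)
      r <- substr(gseq[[g]], p, p + read_len - 1L)
      s <- sample(c("+", "-"), 1L)
      if (s == "-") {
        r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      }
      origin[i] <- g; pos[i] <- p; strand[i] <- s; reads[i] <- r
    }
  }
  if (n_bg > 0L) {
    for (i in seq_len(n_bg)) {
      reads[n_gen + i] <- random_spacer(read_len, gc)
      origin[n_gen + i] <- "background"; pos[n_gen + i] <- NA_integer_
      strand[n_gen + i] <- NA_character_
    }
  }
  ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  list(sample_id = sample_id,
       reads = Biostrings::DNAStringSet(setNames(reads, ids)),
       n_sequences = n_reads,
       environment = environment,
       read_origin = data.frame(read_id = ids, genome = origin, pos = pos,
                                strand = strand, stringsAsFactors = FALSE))
}

#' The paper-shaped simulation scenario
#'
#' Returns the argument list of the default study-sized scenario: 25 genomes
#' with 14 core families and a 5-genome clade carrying 9 exclusive and 10
#' partially-shared accessory families (so the clade conserves 33 families
#' in total), 2 orphan genes per genome, amino-acid divergence 0.2, and
#' compact gene lengths (150-300 nt) so that the all-vs-all stage stays
#' desk-sized.
#'
#' @param seed Integer seed.
#' @return Named list of [simulate_genomes()] arguments.
#' @export
paper_shaped_scenario <- function(seed = 42L) {
  list(n_genomes = 25L, n_core = 14L,
       clade = list(members = sprintf("G%02d", 1:5),
                    n_exclusive = 9L, n_shared = 10L),
       divergence = 0.2, seed = seed,
       gene_len_nt = c(150L, 300L), orphans_per_genome = 2L)
}
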