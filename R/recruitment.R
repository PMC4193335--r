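#' Six-frame translation of nucleotide sequences
#'
#' Frames `+1,+2,+3` translate the sequence offset by 0-2 bases; frames
#' `-1,-2,-3` do the same on the reverse complement.  Partial codons are
#' trimmed; stop codons appear as `*`.
#'
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @return A list with `aa` (an `AAStringSet` named `<id>|<frame>`),
#'   `seq_id` and `frame` (parallel vectors).
#' @export
six_frame_translate <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  rc <- Biostrings::reverseComplement(seqs)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out_aa <- vector("list", 6L)
  for (k in seq_along(frames)) {
    f <- frames[k]
    src <- if (f > 0L) seqs else rc
    off <- abs(f)
    w <- Biostrings::width(src)
    start <- pmin.int(off, w + 1L)
    len <- pmax.int(w - off + 1L, 0L)
    len <- len - (len %% 3L)
    x <- Biostrings::subseq(src, start = start, width = len)
    out_aa[[k]] <- Biostrings::translate(x, no.init.codon = TRUE,
                                         if.fuzzy.codon = "X")
  }
  aa <- do.call(c, out_aa)
  seq_id <- rep(names(seqs), 6L)
  frame <- rep(frames, each = length(seqs))
  names(aa) <- paste0(seq_id, "|", frame)
  keep <- Biostrings::width(aa) > 0L
  list(aa = aa[keep], seq_id = seq_id[keep], frame = frame[keep])
}

# word index: for each sequence, its set of length-`w` amino-acid words
word_sets <- function(aa, w) {
  chr <- as.character(aa)
  n <- nchar(chr) - w + 1L
  lapply(seq_along(chr), function(i) {
    if (n[i] < 1L) return(character(0))
    unique(substring(chr[i], seq_len(n[i]), seq_len(n[i]) + w - 1L))
  })
}

#' Translated search of metagenome reads against query genes
#'
#' Emulates a translated (protein-space) search of a nucleotide read
#' database with nucleotide gene queries: all six reading frames of each
#' gene are aligned against all six frames of each read by Smith-Waterman
#' under BLOSUM62 (gap open 11 / extend 1), and every hit with expectation
#' value at most `evalue_max` is reported, with no cap on hit counts.  The
#' search space for a hit is (gene-frame length) x (total translated
#' database residues).  Candidate pairs are pre-screened by exact shared
#' amino-acid words (`word_size`, `min_words`); at the default expectation
#' cutoff and database sizes of interest any passing alignment is guaranteed
#' to share at least `min_words` exact words, so the screen does not lose
#' hits (set `word_size = NULL` to disable).
#'
#' @param genes Named `DNAStringSet` of CDS nucleotide sequences.
#' @param sample Metagenome sample: a list with elements `sample_id`,
#'   `reads` (named `DNAStringSet`), `n_sequences`, optionally
#'   `environment` (see [simulate_metagenome()]).
#' @param evalue_max Expectation cutoff (default `1e-4`).
#' @param word_size,min_words Word screen parameters (defaults 4 and 2).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Hit table: data frame with columns `gene_id`, `read_id`,
#'   `gene_frame`, `read_frame`, `raw_score`, `bitscore`, `evalue`,
#'   `pct_identity`, `read_segment` (the aligned, ungapped amino-acid
#'   segment of the read).
#' @export
translated_search <- function(genes, sample, evalue_max = 1e-4,
                              word_size = 4L, min_words = 2L,
                              lambda = 0.267, K = 0.041) {
  if (is.character(genes)) genes <- Biostrings::DNAStringSet(genes)
  if (length(genes) == 0L) stop("empty gene list")
  if (is.null(names(genes)) || anyDuplicated(names(genes))) {
    stop("genes must have unique names")
  }
  reads <- sample$reads
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  empty <- data.frame(gene_id = character(), read_id = character(),
                      gene_frame = integer(), read_frame = integer(),
                      raw_score = numeric(), bitscore = numeric(),
                      evalue = numeric(), pct_identity = numeric(),
                      read_segment = character(), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  gf <- six_frame_translate(genes)
  rf <- six_frame_translate(reads)
  n_db <- sum(Biostrings::width(rf$aa))
  submat <- get_submat("BLOSUM62")

  # candidate (gene frame, read frame) pairs by shared words
  if (!is.null(word_size)) {
    read_words <- word_sets(rf$aa, word_size)
    wvec <- unlist(read_words, use.names = FALSE)
    widx <- rep(seq_along(read_words), lengths(read_words))
    gene_words <- word_sets(gf$aa, word_size)
  }
  rows <- list()
  for (q in seq_along(gf$aa)) {
    m_q <- Biostrings::width(gf$aa)[q]
    if (m_q < 1L) next
    if (!is.null(word_size)) {
      in_gene <- wvec %in% gene_words[[q]]
      cnt <- tabulate(widx[in_gene], nbins = length(rf$aa))
      cand <- which(cnt >= min_words)
    } else {
      cand <- seq_along(rf$aa)
    }
    if (length(cand) == 0L) next
    s <- Biostrings::pairwiseAlignment(
      rf$aa[cand], gf$aa[[q]], type = "local", substitutionMatrix = submat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    ev <- ka_evalue(s, m_q, n_db, lambda, K)
    hit <- which(ev <= evalue_max)
    if (length(hit) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      rf$aa[cand[hit]], gf$aa[[q]], type = "local",
      substitutionMatrix = submat, gapOpening = 11, gapExtension = 1)
    seg <- substr(as.character(rf$aa[cand[hit]]),
                  Biostrings::start(Biostrings::pattern(aln)),
                  Biostrings::end(Biostrings::pattern(aln)))
    pid <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = rep(sub("\\|[^|]+$", "", names(gf$aa)[q]), length(hit)),
      read_id = rf$seq_id[cand[hit]],
      gene_frame = rep(gf$frame[q], length(hit)),
      read_frame = rf$frame[cand[hit]],
      raw_score = s[hit],
      bitscore = ka_bitscore(s[hit], lambda, K),
      evalue = ev[hit],
      pct_identity = unname(pid),
      read_segment = unname(seg),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$read_id, out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a viral protein reference panel
#'
#' @param proteins Named `AAStringSet`.
#' @param phage_of Named character vector mapping protein id to phage name.
#' @return Panel list used by [reciprocal_filter()].
#' @export
viral_panel <- function(proteins, phage_of) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  if (!all(names(proteins) %in% names(phage_of))) {
    stop("every panel protein must be mapped to a phage")
  }
  list(proteins = proteins, phage_of = phage_of[names(proteins)])
}

#' Reciprocal top-k filter against a viral panel
#'
#' The translated read segment of a hit is searched against the panel;
#' panel proteins are ranked by bit score (ties broken by lower expectation
#' value, then lexicographic phage name).  The hit is retained iff any
#' protein of the focal phage occurs at rank `<= k`.
#'
#' @param segment Amino-acid string (the aligned read segment).
#' @param panel Panel from [viral_panel()].
#' @param focal_phage Phage name that must appear in the top `k`.
#' @param k Rank cutoff (default 4).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Logical scalar.
#' @export
reciprocal_filter <- function(segment, panel, focal_phage, k = 4L,
                              lambda = 0.267, K = 0.041) {
  if (k < 1L) stop("k must be >= 1")
  if (length(panel$proteins) == 0L) stop("empty panel")
  if (is.null(segment) || is.na(segment) || nchar(segment) == 0L) {
    stop("empty read segment")
  }
  submat <- get_submat("BLOSUM62")
  s <- Biostrings::pairwiseAlignment(
    panel$proteins, Biostrings::AAString(segment), type = "local",
    substitutionMatrix = submat, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  n_db <- sum(Biostrings::width(panel$proteins))
  ev <- ka_evalue(s, nchar(segment), n_db, lambda, K)
  ord <- order(-s, ev, panel$phage_of, names(panel$proteins))
  top <- panel$phage_of[ord][seq_len(min(k, length(ord)))]
  focal_phage %in% top
}

#' Apply the reciprocal filter to a hit table
#'
#' @param hits Hit table from [translated_search()].
#' @inheritParams reciprocal_filter
#' @return Filtered hit table (rows whose read segment passes).
#' @export
filter_hits <- function(hits, panel, focal_phage, k = 4L) {
  if (nrow(hits) == 0L) return(hits)
  segs <- unique(hits$read_segment)
  pass <- vapply(segs, reciprocal_filter, logical(1),
                 panel = panel, focal_phage = focal_phage, k = k)
  hits[pass[hits$read_segment], , drop = FALSE]
}

#' Count recruited reads per gene and sample
#'
#' A read contributes at most one count per gene per sample, regardless of
#' how many frame-level alignments it produces.
#'
#' @param hit_tables Named list of hit tables, one per sample (names =
#'   sample ids).
#' @param gene_ids Gene ids defining the row order.
#' @return Integer matrix genes x samples.
#' @export
count_hits <- function(hit_tables, gene_ids) {
  samples <- names(hit_tables)
  m <- matrix(0L, length(gene_ids), length(samples),
              dimnames = list(gene_ids, samples))
  for (s in samples) {
    h <- hit_tables[[s]]
    if (nrow(h) == 0L) next
    u <- unique(h[, c("gene_id", "read_id")])
    tab <- table(u$gene_id)
    m[names(tab), s] <- as.integer(tab)
  }
  m
}

#' Normalized relative abundance
#'
#' Each count is divided by the number of sequences in the sample's database
#' and by the gene-product length, then the whole matrix is scaled by the
#' grand mean of these raw values (computed over all gene x sample cells,
#' zeros included), giving dimensionless relative abundances with mean 1.
#'
#' @param counts Integer matrix genes x samples (from [count_hits()]).
#' @param sample_sizes Named numeric: total sequences in each sample's
#'   database (may exceed the number of reads actually searched).
#' @param gene_lengths Named numeric: gene-product length in residues.
#' @param allow_zero If `TRUE`, an all-zero count matrix yields a matrix of
#'   zeros instead of an error.
#' @return List of class `"abundance_matrix"` with elements `raw_counts`,
#'   `normalized`, `scaling_mean`, `sample_sizes`, `gene_lengths`.
#' @export
abundance <- function(counts, sample_sizes, gene_lengths, allow_zero = FALSE) {
  counts <- as.matrix(counts)
  sample_sizes <- sample_sizes[colnames(counts)]
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(sample_sizes) || any(sample_sizes <= 0)) {
    stop("sample_sizes must be positive for every sample")
  }
  if (anyNA(gene_lengths) || any(gene_lengths <= 0)) {
    stop("gene_lengths must be positive for every gene")
  }
  v <- sweep(counts, 2L, sample_sizes, "/")
  v <- sweep(v, 1L, gene_lengths, "/")
  m <- mean(v)
  if (m == 0) {
    if (!allow_zero) stop("all counts zero: scaling mean undefined")
    norm <- v
  } else {
    norm <- v / m
  }
  structure(list(raw_counts = counts, normalized = norm, scaling_mean = m,
                 sample_sizes = sample_sizes, gene_lengths = gene_lengths),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$normalized), "genes x",
      ncol(x$normalized), "samples; scaling mean", format(x$scaling_mean), "\n")
  print(round(x$normalized, 3), ...)
  invisible(x)
}

#' Group normalized abundances by environment
#'
#' Per-gene mean of the normalized abundances over the samples of each
#' environment.
#'
#' @param ab `abundance_matrix` from [abundance()].
#' @param labels Named character vector mapping sample id to environment.
#' @param env_order Optional environment column order.
#' @return Numeric matrix genes x environments.
#' @export
group_by_environment <- function(ab, labels, env_order = NULL) {
  samples <- colnames(ab$normalized)
  lab <- labels[samples]
  if (anyNA(lab)) {
    stop("unlabeled sample: ", samples[which(is.na(lab))[1L]])
  }
  envs <- if (is.null(env_order)) unique(unname(lab)) else env_order
  out <- vapply(envs, function(e) {
    rowMeans(ab$normalized[, lab == e, drop = FALSE])
  }, numeric(nrow(ab$normalized)))
  out <- matrix(out, nrow = nrow(ab$normalized),
                dimnames = list(rownames(ab$normalized), envs))
  out
}

#' Abundance heatmap
#'
#' Draws a genes x samples heatmap of normalized relative abundance.
#' Requires the `pheatmap` package.
#'
#' @param ab `abundance_matrix`.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_abundance_heatmap <- function(ab, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_abundance_heatmap() needs the pheatmap package")
  }
  invisible(pheatmap::pheatmap(ab$normalized, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}
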