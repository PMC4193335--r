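#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for a gapped local alignment score `S`
#' with query length `m` and database size `n` residues.  Defaults are the
#' published gapped BLOSUM62-11/1 constants (`lambda` = 0.267, `K` = 0.041).
#'
#' @param score Raw Smith-Waterman score(s).
#' @param m Query length (residues).
#' @param n Database size (total residues searched).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expectation value(s).
#' @export
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Bit score from a raw alignment score
#'
#' @inheritParams ka_evalue
#' @return Normalized bit score(s).
#' @export
ka_bitscore <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

#' All-vs-all protein similarity search
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()]) of
#' every ordered protein pair, scored with BLOSUM62 and affine gaps
#' (open 11, extend 1), with Karlin-Altschul expectation values computed over
#' a search space of query length times total database residues.  Hits with
#' `E <= evalue_max` are returned; self-hits are discarded.  Scores are
#' computed once per unordered pair (the matrix is symmetric) and reported in
#' both directions with direction-specific expectation values.
#'
#' @param proteins Named `AAStringSet` (or named character vector).
#' @param evalue_max Expectation-value cutoff (default `1e-6`).
#' @param matrix Substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_ext Affine gap penalties (default 11, 1).
#' @param lambda,K Karlin-Altschul parameters for `matrix`/gap settings.
#' @return Hit table: a data frame with the 12 standard tabular columns
#'   (`query`, `subject`, `pct_identity`, `aln_len`, `mismatches`,
#'   `gapopens`, `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`)
#'   plus `raw_score`.
#' @export
all_vs_all <- function(proteins, evalue_max = 1e-6, matrix = "BLOSUM62",
                       gap_open = 11, gap_ext = 1,
                       lambda = 0.267, K = 0.041) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  n_prot <- length(proteins)
  if (n_prot < 2L) stop("need at least 2 proteins")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteins must have unique names")
  w <- Biostrings::width(proteins)
  if (any(w == 0L)) stop("protein ", ids[which(w == 0L)[1L]], " has zero length")
  submat <- get_submat(matrix)
  n_db <- sum(w)

  # pass 1: score-only over unordered pairs
  pair_i <- integer(0); pair_j <- integer(0); pair_s <- numeric(0)
  for (i in seq_len(n_prot - 1L)) {
    jj <- (i + 1L):n_prot
    s <- Biostrings::pairwiseAlignment(
      proteins[jj], proteins[[i]], type = "local",
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_ext, scoreOnly = TRUE)
    e_best <- ka_evalue(s, pmax(w[i], w[jj]), n_db, lambda, K)
    keep <- e_best <= evalue_max
    pair_i <- c(pair_i, rep.int(i, sum(keep)))
    pair_j <- c(pair_j, jj[keep])
    pair_s <- c(pair_s, s[keep])
  }
  empty <- data.frame(query = character(), subject = character(),
                      pct_identity = numeric(), aln_len = integer(),
                      mismatches = integer(), gapopens = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      raw_score = numeric(), stringsAsFactors = FALSE)
  if (length(pair_i) == 0L) return(empty)

  # pass 2: full alignments for passing pairs, grouped by subject
  rows <- vector("list", length(unique(pair_i)))
  ri <- 0L
  for (i in unique(pair_i)) {
    sel <- which(pair_i == i)
    jj <- pair_j[sel]
    aln <- Biostrings::pairwiseAlignment(
      proteins[jj], proteins[[i]], type = "local",
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_ext)
    score <- Biostrings::score(aln)
    aln_len <- Biostrings::nchar(aln)
    matches <- Biostrings::nmatch(aln)
    mism <- Biostrings::nmismatch(aln)
    ni <- Biostrings::nindel(aln)
    gapopens <- Biostrings::insertion(ni)[, "Length"] +
      Biostrings::deletion(ni)[, "Length"]
    # pattern = protein j, subject = protein i
    jstart <- Biostrings::start(Biostrings::pattern(aln))
    jend <- Biostrings::end(Biostrings::pattern(aln))
    istart <- Biostrings::start(Biostrings::subject(aln))
    iend <- Biostrings::end(Biostrings::subject(aln))
    pid <- 100 * matches / aln_len
    bits <- ka_bitscore(score, lambda, K)
    e_j <- ka_evalue(score, w[jj], n_db, lambda, K)  # j as query
    e_i <- ka_evalue(score, w[i], n_db, lambda, K)   # i as query
    ri <- ri + 1L
    rows[[ri]] <- rbind(
      data.frame(query = ids[jj], subject = ids[i], pct_identity = pid,
                 aln_len = aln_len, mismatches = mism, gapopens = gapopens,
                 qstart = jstart, qend = jend, sstart = istart, send = iend,
                 evalue = e_j, bitscore = bits, raw_score = score,
                 stringsAsFactors = FALSE)[e_j <= evalue_max, ],
      data.frame(query = ids[i], subject = ids[jj], pct_identity = pid,
                 aln_len = aln_len, mismatches = mism, gapopens = gapopens,
                 qstart = istart, qend = iend, sstart = jstart, send = jend,
                 evalue = e_i, bitscore = bits, raw_score = score,
                 stringsAsFactors = FALSE)[e_i <= evalue_max, ])
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(out$query, out$evalue, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Hit table from [all_vs_all()] or [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
            "gapopens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' Accepts the standard tab-separated hit format (as written by common
#' external search tools), so that full-scale searches can be imported in
#' place of the built-in Smith-Waterman backend.
#'
#' @param path Tab-separated hit file, 12 columns, no header.
#' @return Hit table data frame.
#' @export
read_hits <- function(path) {
  out <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("query", "subject", "pct_identity",
                                  "aln_len", "mismatches", "gapopens",
                                  "qstart", "qend", "sstart", "send",
                                  "evalue", "bitscore"),
                    stringsAsFactors = FALSE)
  out
}

#' Bidirectional-best-hit graph
#'
#' For each ordered genome pair and each gene, the best hit is the subject
#' with maximal bit score (ties broken by lower expectation value, longer
#' alignment, then lexicographic subject id).  An undirected edge joins two
#' genes iff each is the other's best hit in the other genome; the edge
#' weight is `-log10(max(evalue, 1e-180))` averaged over the two directions.
#' Within-genome hits never produce edges (strict between-genome BBH).
#'
#' @param hits Hit table pre-filtered at the expectation-value cutoff.
#' @param genome_of Named character vector mapping gene id to genome id;
#'   defines the node set (genes without edges become isolated nodes).
#' @return An undirected `igraph` graph with vertex attribute `genome` and
#'   edge attribute `weight`.
#' @export
bbh_graph <- function(hits, genome_of) {
  genes <- names(genome_of)
  if (nrow(hits) > 0L) {
    unknown <- setdiff(unique(c(hits$query, hits$subject)), genes)
    if (length(unknown) > 0L) {
      stop("gene in hits but not in genome_of: ", unknown[[1L]])
    }
  }
  h <- hits[genome_of[hits$query] != genome_of[hits$subject], , drop = FALSE]
  edges <- NULL
  if (nrow(h) > 0L) {
    tgt <- genome_of[h$subject]
    ord <- order(h$query, tgt, -h$bitscore, h$evalue, -h$aln_len, h$subject)
    h <- h[ord, , drop = FALSE]
    best <- h[!duplicated(paste(h$query, genome_of[h$subject])), , drop = FALSE]
    fwd_key <- paste(best$query, best$subject)
    rev_key <- paste(best$subject, best$query)
    mutual <- fwd_key %in% rev_key
    b <- best[mutual, , drop = FALSE]
    if (nrow(b) > 0L) {
      lo <- pmin(b$query, b$subject)
      hi <- pmax(b$query, b$subject)
      wlog <- -log10(pmax(b$evalue, 1e-180))
      agg <- tapply(wlog, paste(lo, hi, sep = "\r"), mean)
      pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
      edges <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                          weight = as.numeric(agg), stringsAsFactors = FALSE)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes,
                            genome = unname(genome_of))
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                           weight = edges$weight)
  }
  g
}
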