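#' Naive ORF caller
#'
#' Reports, for every (stop codon, strand) on both strands, the longest open
#' reading frame starting at `ATG`, `GTG` or `TTG`, ending at `TAA`, `TAG` or
#' `TGA`, and encoding at least `min_aa` residues (start included, stop
#' excluded).  This is a deliberately simple stand-in for heuristic gene
#' callers, sufficient for synthetic genomes where genes were planted with
#' these start/stop conventions.
#'
#' @param genome A single-element named `DNAStringSet`, a `DNAString`, or a
#'   character scalar.  If unnamed, the genome id defaults to `"genome"`.
#' @param min_aa Minimum protein length in residues (default 30).
#' @param genome_id Genome id recorded in the calls; defaults to the sequence
#'   name.
#' @param predictor Label recorded in the `source` column.
#' @return CDS call data frame ordered by `start`; may have zero rows.
#' @export
find_orfs <- function(genome, min_aa = 30L, genome_id = NULL,
                      predictor = "orfcall") {
  if (min_aa < 1L) stop("min_aa must be >= 1")
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(genome_id)) genome_id <- names(genome)[1L]
    genome <- as.character(genome)[[1L]]
  } else if (inherits(genome, "DNAString")) {
    genome <- as.character(genome)
  }
  if (is.null(genome_id)) genome_id <- "genome"
  genome <- toupper(genome)
  L <- nchar(genome)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))

  scan_strand <- function(seqchr) {
    # returns data.frame of (s, e) 1-based inclusive coords on seqchr,
    # s = first base of start codon, e = last base of stop codon
    out <- list()
    for (off in 0:2) {
      n_cod <- (nchar(seqchr) - off) %/% 3L
      if (n_cod < 2L) next
      pos <- off + 1L + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(seqchr, pos, pos + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_start <- codons %in% ALT_STARTS
      stops <- which(is_stop)
      prev <- 0L
      for (st in stops) {
        cand <- which(is_start[(prev + 1L):(st - 1L)])
        if (length(cand) > 0L) {
          first_start <- prev + cand[1L]
          aa_len <- st - first_start  # codons before the stop
          if (aa_len >= min_aa) {
            out[[length(out) + 1L]] <- c(pos[first_start], pos[st] + 2L)
          }
        }
        prev <- st
      }
    }
    if (length(out) == 0L) return(NULL)
    m <- do.call(rbind, out)
    data.frame(s = m[, 1L], e = m[, 2L])
  }

  fwd <- scan_strand(genome)
  rev <- scan_strand(rc)
  calls <- list()
  if (!is.null(fwd)) {
    calls[[1L]] <- data.frame(start = fwd$s, end = fwd$e, strand = "+")
  }
  if (!is.null(rev)) {
    # map coordinates on the reverse complement back to the forward strand
    calls[[length(calls) + 1L]] <-
      data.frame(start = L - rev$e + 1L, end = L - rev$s + 1L, strand = "-")
  }
  if (length(calls) == 0L) {
    return(data.frame(genome_id = character(), gene_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, calls)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  data.frame(genome_id = genome_id,
             gene_id = sprintf("%s_orf%03d", genome_id, seq_len(nrow(df))),
             start = df$start, end = df$end, strand = df$strand,
             source = predictor, stringsAsFactors = FALSE)
}

# shared stop-coordinate key: the stop codon ends at `end` on "+" and begins
# at `start` on "-", so (key, strand) identifies a gene across predictors
stop_key <- function(calls) {
  ifelse(calls$strand == "+", calls$end, calls$start)
}

#' Amalgamate two gene-prediction call sets
#'
#' Predictions are matched by (stop coordinate, strand): two predictions of
#' the same gene always share a stop and can differ only in their start.  For
#' such discordant start codons the longer of the two predictions is kept;
#' calls unique to either predictor are retained unchanged.  The output
#' `source` is `"merged"`.
#'
#' @param a,b CDS call data frames for the same genome.
#' @return Merged CDS call data frame, ordered by `start`.
#' @export
merge_predictions <- function(a, b) {
  validate_cds(a); validate_cds(b)
  ga <- unique(a$genome_id); gb <- unique(b$genome_id)
  if (length(ga) > 1L || length(gb) > 1L) {
    stop("each prediction set must reference a single genome")
  }
  if (length(ga) == 1L && length(gb) == 1L && ga != gb) {
    stop("prediction sets reference different genomes: ", ga, " vs ", gb)
  }
  both <- rbind(a[, c("genome_id", "gene_id", "start", "end", "strand")],
                b[, c("genome_id", "gene_id", "start", "end", "strand")])
  key <- paste(stop_key(both), both$strand)
  len <- both$end - both$start + 1L
  # keep the longest call per key; ties (identical calls) keep the first
  ord <- order(key, -len, both$gene_id)
  both <- both[ord, , drop = FALSE]
  keep <- !duplicated(paste(stop_key(both), both$strand))
  out <- both[keep, , drop = FALSE]
  out$source <- "merged"
  # predictors sharing a naming scheme can collide on ids for different genes
  out$gene_id <- make.unique(out$gene_id, sep = "_")
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
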