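#' Read a genome FASTA file
#'
#' Reads nucleotide FASTA into a named [Biostrings::DNAStringSet].  Sequences
#' are uppercased and restricted to the alphabet `{A,C,G,T,N}`; any other
#' IUPAC ambiguity code is rejected so that malformed records fail fast.
#' Record order is preserved and ids (the first whitespace-delimited token of
#' each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by sequence id, with the full headers kept
#'   in the `description` metadata column.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id ", dup[[1L]])
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  extra <- Biostrings::width(x) - rowSums(
    Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T", "N")))
  if (any(extra > 0L)) {
    stop("sequence ", ids[which(extra > 0L)[1L]],
         " contains characters outside {A,C,G,T,N}")
  }
  if (any(Biostrings::width(x) == 0L)) {
    stop("sequence ", ids[which(Biostrings::width(x) == 0L)[1L]], " is empty")
  }
  names(x) <- ids
  attr(x, "description") <- desc
  x
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param x A named `XStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("all sequences must be named")
  }
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T).  `N` characters are excluded from both
#' numerator and denominator.
#'
#' @param seq A character string, `DNAString`, or `DNAStringSet` (vectorized
#'   over its elements).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(toupper(seq))
  if (inherits(seq, "DNAString")) seq <- Biostrings::DNAStringSet(list(seq))
  f <- Biostrings::letterFrequency(seq, letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  if (any(tot == 0L)) stop("no unambiguous bases")
  unname((f[, "G"] + f[, "C"]) / tot)
}

#' AT content of a nucleotide sequence
#'
#' Complement of [gc_content()] over unambiguous bases.
#' @inheritParams gc_content
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
at_content <- function(seq) 1 - gc_content(seq)

ALT_STARTS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate a table of CDS calls
#'
#' CDS calls are plain data frames with columns `genome_id`, `gene_id`,
#' `start`, `end`, `strand` (`"+"` or `"-"`), `source` and optionally
#' `product`.  Coordinates are 1-based and inclusive, following GFF3.
#'
#' @param calls CDS call data frame.
#' @param genomes Optional named `DNAStringSet`; when given, calls are checked
#'   against genome bounds.
#' @return `calls`, invisibly, or an error.
#' @export
validate_cds <- function(calls, genomes = NULL) {
  need <- c("genome_id", "gene_id", "start", "end", "strand", "source")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0L) stop("missing CDS columns: ", paste(miss, collapse = ", "))
  if (any(calls$start < 1L) || any(calls$start > calls$end)) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  if (!all(calls$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  key <- paste(calls$genome_id, calls$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate gene_id within genome: ", key[which(duplicated(key))[1L]])
  }
  if (!is.null(genomes)) {
    unknown <- setdiff(unique(calls$genome_id), names(genomes))
    if (length(unknown) > 0L) stop("unknown genome_id: ", unknown[[1L]])
    glen <- Biostrings::width(genomes)[match(calls$genome_id, names(genomes))]
    if (any(calls$end > glen)) {
      bad <- which(calls$end > glen)[1L]
      stop("CDS ", calls$gene_id[bad], " extends past the end of ",
           calls$genome_id[bad])
    }
  }
  invisible(calls)
}

#' Extract a CDS and translate it to protein
#'
#' The CDS is cut from the genome (reverse-complemented for strand `-`), its
#' initial codon is translated as `M` when it is one of the alternative
#' initiators `ATG`, `GTG`, `TTG`, the trailing stop codon (if present) is
#' stripped, and an internal stop codon is an error reporting the codon
#' position.
#'
#' @param genome A `DNAString` or single character string.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Protein sequence as a character scalar (no `*`).
#' @export
extract_and_translate <- function(genome, start, end, strand = "+") {
  if (inherits(genome, "DNAString") || inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)[[1L]]
  }
  glen <- nchar(genome)
  if (start < 1L || end > glen || start > end) {
    stop("CDS coordinates ", start, "..", end, " out of bounds for genome of length ", glen)
  }
  len <- end - start + 1L
  if (len %% 3L != 0L) stop("CDS length ", len, " not divisible by 3")
  nt <- substr(genome, start, end)
  if (strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  } else if (strand != "+") {
    stop("strand must be '+' or '-'")
  }
  translate_cds(nt)
}

#' Translate an in-frame CDS nucleotide sequence
#'
#' @param nt CDS nucleotide string, already in coding orientation.
#' @return Protein character scalar; trailing stop removed, alternative start
#'   codons read as `M`.
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L) stop("CDS length ", nchar(nt), " not divisible by 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt), no.init.codon = TRUE, if.fuzzy.codon = "X"))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
    n <- n - 1L
  }
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) stop("internal stop codon at codon ", star)
  if (substr(nt, 1L, 3L) %in% ALT_STARTS) aa <- paste0("M", substr(aa, 2L, n))
  if (nchar(aa) == 0L) stop("empty protein after stop trimming")
  aa
}

#' Translate a full CDS call set to proteins
#'
#' @param genomes Named `DNAStringSet`.
#' @param calls CDS call data frame (see [validate_cds()]).
#' @return A list with `proteins` (an `AAStringSet` named by gene id) and
#'   `genome_of` (named character vector mapping gene id to genome id).
#' @export
translate_calls <- function(genomes, calls) {
  validate_cds(calls, genomes)
  aa <- vapply(seq_len(nrow(calls)), function(i) {
    extract_and_translate(genomes[[calls$genome_id[i]]],
                          calls$start[i], calls$end[i], calls$strand[i])
  }, character(1))
  proteins <- Biostrings::AAStringSet(setNames(aa, calls$gene_id))
  list(proteins = proteins,
       genome_of = setNames(calls$genome_id, calls$gene_id))
}

#' Write CDS calls as GFF3
#'
#' One `CDS` feature per call, `ID` attribute set to the gene id.
#'
#' @param calls CDS call data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(calls, path) {
  validate_cds(calls)
  prod <- if ("product" %in% names(calls)) calls$product
          else rep(NA_character_, nrow(calls))
  attr9 <- ifelse(is.na(prod) | prod == "",
                  paste0("ID=", calls$gene_id),
                  paste0("ID=", calls$gene_id, ";product=", prod))
  lines <- paste(calls$genome_id, calls$source, "CDS", calls$start, calls$end,
                 ".", calls$strand, "0", attr9, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read CDS calls from GFF3
#'
#' Only `CDS` features are kept; the `ID` attribute becomes the gene id.
#'
#' @param path GFF3 file path.
#' @return CDS call data frame.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(raw, "\t", fixed = TRUE)
  ok <- vapply(f, length, integer(1)) == 9L
  f <- f[ok]
  m <- do.call(rbind, f)
  keep <- m[, 3L] == "CDS"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no CDS features in ", path)
  id <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9L])
  prod <- ifelse(grepl("product=", m[, 9L]),
                 sub("^.*product=([^;]+).*$", "\\1", m[, 9L]), NA_character_)
  out <- data.frame(genome_id = m[, 1L], gene_id = id,
                    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
                    strand = m[, 7L], source = m[, 2L], product = prod,
                    stringsAsFactors = FALSE)
  validate_cds(out)
  out
}
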