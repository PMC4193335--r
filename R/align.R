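# Multiple alignments are represented as named character vectors of
# equal-length strings (gap character "-"); helpers convert to a character
# matrix (rows = sequences).

as_msa_chars <- function(msa) {
  if (inherits(msa, "AAStringSet") || inherits(msa, "XStringSet")) {
    msa <- setNames(as.character(msa), names(msa))
  }
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    stop("alignment rows must have unique names")
  }
  if (length(unique(nchar(msa))) > 1L) stop("alignment rows differ in length")
  msa
}

msa_matrix <- function(msa) {
  msa <- as_msa_chars(msa)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# column frequency profile over the 20 amino acids; gaps/X contribute zero
profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  P <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (a in AA20) P[a, ] <- colSums(m == a)
  P / nrow(m)
}

# global (Needleman-Wunsch) profile-profile alignment with affine gaps;
# returns the merged rows.  The DP is vectorized row-wise: the horizontal
# gap state is computed with a cummax transformation, so only the outer loop
# over profile-A columns is an R loop.
profile_align <- function(rows_a, rows_b, submat, gap_open, gap_ext) {
  Pa <- profile_of(rows_a); Pb <- profile_of(rows_b)
  La <- ncol(Pa); Lb <- ncol(Pb)
  B <- submat[AA20, AA20]
  S <- t(Pa) %*% B %*% Pb                       # La x Lb column-pair scores
  NEG <- -1e18
  M <- matrix(NEG, La + 1L, Lb + 1L)
  X <- matrix(NEG, La + 1L, Lb + 1L)            # gap in B (consumes A)
  Y <- matrix(NEG, La + 1L, Lb + 1L)            # gap in A (consumes B)
  M[1L, 1L] <- 0
  if (La > 0L) X[2L:(La + 1L), 1L] <- -(gap_open + (seq_len(La) - 1L) * gap_ext)
  if (Lb > 0L) Y[1L, 2L:(Lb + 1L)] <- -(gap_open + (seq_len(Lb) - 1L) * gap_ext)
  jj <- seq_len(Lb)
  for (i in seq_len(La)) {
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    diag_best <- pmax(prevM[jj], prevX[jj], prevY[jj])
    Mi <- c(NEG, diag_best + S[i, ])
    Xi <- c(X[i + 1L, 1L], pmax(prevM[jj + 1L] - gap_open, prevX[jj + 1L] - gap_ext))
    # Y[i,j] = max(M[i,j-1] - open, Y[i,j-1] - ext), via cummax
    V <- c(NEG, Mi[jj] + jj * gap_ext - gap_open)
    U <- cummax(V)
    Yi <- U - (0:Lb) * gap_ext
    Yi[1L] <- NEG
    M[i + 1L, ] <- Mi; X[i + 1L, ] <- Xi; Y[i + 1L, ] <- Yi
  }
  # traceback
  i <- La; j <- Lb
  fin <- c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
  state <- which.max(fin)
  steps <- character(0)
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L) {                       # match column
      steps <- c("M", steps)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {                # consume A, gap in B
      steps <- c("X", steps)
      if (i > 1L && abs(X[i + 1L, j + 1L] - (X[i, j + 1L] - gap_ext)) < eps) {
        state <- 2L
      } else state <- 1L
      i <- i - 1L
      if (i == 0L && j == 0L) break
      if (i == 0L) state <- 3L               # remaining B prefix
    } else {                                 # consume B, gap in A
      steps <- c("Y", steps)
      if (j > 1L && abs(Y[i + 1L, j + 1L] - (Y[i + 1L, j] - gap_ext)) < eps) {
        state <- 3L
      } else state <- 1L
      j <- j - 1L
      if (i == 0L && j == 0L) break
      if (j == 0L) state <- 2L               # remaining A prefix
    }
    if (i == 0L && j == 0L) break
    if (i == 0L && state != 3L) state <- 3L
    if (j == 0L && state != 2L) state <- 2L
  }
  a_idx <- cumsum(steps != "Y")
  b_idx <- cumsum(steps != "X")
  expand <- function(rows, take, idx) {
    chars <- strsplit(rows, "", fixed = TRUE)
    vapply(chars, function(x) {
      out <- rep("-", length(steps))
      out[take] <- x[idx[take]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(rows_a, steps != "Y", a_idx),
    expand(rows_b, steps != "X", b_idx))
}

kmer_counts <- function(s, k = 3L) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(table(character(0)))
  table(substring(s, seq_len(n), seq_len(n) + k - 1L))
}

#' k-mer count distance between unaligned sequences
#'
#' `1 - shared / (min(length) - k + 1)` where `shared` is the summed minimum
#' count of each k-mer in the two sequences.  Used to build the progressive
#' alignment guide tree.
#'
#' @param seqs Named character vector or `AAStringSet`.
#' @param k Word size (default 3).
#' @return Symmetric distance matrix.
#' @export
kmer_distance <- function(seqs, k = 3L) {
  if (inherits(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  n <- length(seqs)
  counts <- lapply(seqs, kmer_counts, k = k)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- intersect(names(counts[[i]]), names(counts[[j]]))
      shared <- sum(pmin(counts[[i]][common], counts[[j]][common]))
      denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L
      D[i, j] <- D[j, i] <- 1 - shared / max(denom, 1L)
    }
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from k-mer (k = 3) count distances by neighbor
#' joining (midpoint-rooted), then merges sub-alignments bottom-up with
#' global profile-profile alignment under BLOSUM62 and affine gap penalties
#' (open 10, extend 0.5).  Deterministic for a fixed input order.
#'
#' @param seqs Named character vector or `AAStringSet`, at least 2 sequences.
#' @param gap_open,gap_ext Affine gap penalties.
#' @param matrix Substitution matrix name or matrix.
#' @return Named character vector of aligned rows (input order), class
#'   unchanged; all rows equal length with gap character `-`.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 0.5,
                              matrix = "BLOSUM62") {
  if (inherits(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  submat <- get_submat(matrix)
  if (length(seqs) == 2L) {
    out <- profile_align(seqs[1L], seqs[2L], submat, gap_open, gap_ext)
    return(setNames(out, names(seqs)))
  }
  D <- kmer_distance(seqs)
  merged <- if (max(D) == 0) NULL else tryCatch({
    guide <- midpoint_root(nj_tree(D))
    align_node <- function(node) {
      kids <- guide$edge[guide$edge[, 1L] == node, 2L]
      if (length(kids) == 0L) {
        return(setNames(seqs[guide$tip.label[node]], guide$tip.label[node]))
      }
      parts <- lapply(kids, align_node)
      out <- parts[[1L]]
      for (p in parts[-1L]) out <- profile_align(out, p, submat, gap_open, gap_ext)
      out
    }
    align_node(length(guide$tip.label) + 1L)
  }, error = function(e) NULL)
  if (is.null(merged)) {
    # identical (or degenerate) sequences: sequential merge in input order
    merged <- seqs[1L]
    for (i in 2L:length(seqs)) {
      merged <- profile_align(merged, seqs[i], submat, gap_open, gap_ext)
    }
  }
  merged[names(seqs)]
}

#' Concatenate per-cluster core alignments
#'
#' Every alignment must contain exactly one row per genome (rows named by
#' genome id).  Rows are concatenated in the given cluster order; partition
#' boundaries are recorded in the `"partitions"` attribute.
#'
#' @param alignments Named list of alignments (named character vectors or
#'   `AAStringSet`s keyed by genome id).
#' @return Named character vector: one concatenated row per genome.
#' @export
concatenate_core <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  alignments <- lapply(alignments, as_msa_chars)
  genomes <- sort(names(alignments[[1L]]))
  for (nm in names(alignments)) {
    missing <- setdiff(genomes, names(alignments[[nm]]))
    extra <- setdiff(names(alignments[[nm]]), genomes)
    if (length(missing) > 0L || length(extra) > 0L) {
      stop("genome ", c(missing, extra)[1L],
           " missing from (or extra in) core alignment ", nm)
    }
  }
  widths <- vapply(alignments, function(a) nchar(a[[1L]]), numeric(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  rows <- vapply(genomes, function(g) {
    paste(vapply(alignments, function(a) a[[g]], character(1)), collapse = "")
  }, character(1))
  attr(rows, "partitions") <- data.frame(
    cluster = if (is.null(names(alignments)))
      as.character(seq_along(alignments)) else names(alignments),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE)
  rows
}

#' Remove alignment columns with gaps or missing data
#'
#' Complete deletion: every column containing `-` or `X` in any row is
#' removed.  The indices of the retained columns (in the original alignment)
#' are kept in the `"column_map"` attribute.
#'
#' @param msa Alignment (named character vector or `AAStringSet`).
#' @return Filtered alignment as a named character vector.
#' @export
complete_deletion <- function(msa) {
  m <- msa_matrix(msa)
  keep <- colSums(m == "-" | m == "X") == 0L
  if (!any(keep)) stop("no ungapped columns remain")
  kept <- m[, keep, drop = FALSE]
  out <- setNames(apply(kept, 1L, paste, collapse = ""), rownames(m))
  attr(out, "column_map") <- which(keep)
  out
}
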