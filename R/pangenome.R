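#' Cluster-by-genome presence matrix
#'
#' @param clusters Cluster membership data frame with columns `cluster_id`,
#'   `gene_id`, `genome_id` (as returned by [mcl_cluster()] on a graph with
#'   genome labels).
#' @param genomes Optional character vector of genome ids to force as
#'   columns (genomes with no clustered genes get all-zero columns).
#' @return Integer matrix, rows = cluster ids, columns = genome ids, cell =
#'   number of members of the cluster in the genome.
#' @export
presence_matrix <- function(clusters, genomes = NULL) {
  if (!all(c("cluster_id", "gene_id", "genome_id") %in% names(clusters))) {
    stop("clusters must have cluster_id, gene_id and genome_id columns")
  }
  tab <- table(clusters$cluster_id, clusters$genome_id)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  if (!is.null(genomes)) {
    missing <- setdiff(genomes, colnames(m))
    if (length(missing) > 0L) {
      m <- cbind(m, matrix(0L, nrow(m), length(missing),
                           dimnames = list(NULL, missing)))
    }
    m <- m[, genomes, drop = FALSE]
  }
  m
}

check_genomes <- function(matrix, genomes) {
  unknown <- setdiff(genomes, colnames(matrix))
  if (length(unknown) > 0L) stop("unknown genome id: ", unknown[[1L]])
}

#' Core gene families
#'
#' Clusters with at least one member in every listed genome.  Presence means
#' one or more members; paralog multiplicity does not affect core status.
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param genomes Genome set over which "core" is defined (default: all
#'   columns).
#' @return Character vector of cluster ids.
#' @export
core_clusters <- function(matrix, genomes = colnames(matrix)) {
  check_genomes(matrix, genomes)
  if (length(genomes) == 0L) stop("empty genome set")
  sub <- matrix[, genomes, drop = FALSE]
  rownames(sub)[rowSums(sub >= 1L) == length(genomes)]
}

#' Clade-conserved gene families
#'
#' Clusters present in every clade genome; presence outside the clade is
#' permitted.  With `clade` equal to all genomes this reduces to
#' [core_clusters()].
#'
#' @inheritParams core_clusters
#' @param clade Genome ids forming the clade.
#' @return Character vector of cluster ids.
#' @export
conserved_clusters <- function(matrix, clade) {
  core_clusters(matrix, clade)
}

#' Clade-exclusive gene families
#'
#' Clusters present in every clade genome and absent from every genome
#' outside the clade.
#'
#' @inheritParams conserved_clusters
#' @return Character vector of cluster ids.
#' @export
exclusive_clusters <- function(matrix, clade) {
  check_genomes(matrix, clade)
  if (length(clade) == 0L) stop("empty clade")
  outsiders <- setdiff(colnames(matrix), clade)
  if (length(outsiders) == 0L) {
    stop("clade equals the full genome set; use core_clusters()")
  }
  inside <- matrix[, clade, drop = FALSE]
  outside <- matrix[, outsiders, drop = FALSE]
  rownames(matrix)[rowSums(inside >= 1L) == length(clade) &
                     rowSums(outside) == 0L]
}

#' Genome-unique genes
#'
#' Genes of one genome that fall in singleton clusters, i.e. have no homolog
#' in any other genome of the comparison set.
#'
#' @param clusters Cluster membership data frame (`cluster_id`, `gene_id`,
#'   `genome_id`).
#' @param genome Genome id.
#' @return Character vector of gene ids (sorted).
#' @export
unique_genes <- function(clusters, genome) {
  if (!genome %in% clusters$genome_id) stop("unknown genome id: ", genome)
  size <- table(clusters$cluster_id)
  singleton <- names(size)[size == 1L]
  sel <- clusters$cluster_id %in% singleton & clusters$genome_id == genome
  sort(clusters$gene_id[sel])
}

#' Write a presence matrix as TSV
#'
#' @param matrix Presence matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(cluster_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster membership, one line per cluster
#'
#' Format: `cluster_id<TAB>genome:gene genome:gene ...`
#'
#' @param clusters Cluster membership data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  sp <- split(paste0(clusters$genome_id, ":", clusters$gene_id),
              clusters$cluster_id)
  lines <- paste0(names(sp), "\t", vapply(sp, paste, "", collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
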