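#' Workflow configuration
#'
#' Bundles the tunable thresholds of the two canned workflows.  The defaults
#' are the parameters of the study this pipeline re-implements: ortholog
#' expectation cutoff 1e-6 with Markov-clustering inflation 1.5, recruitment
#' expectation cutoff 1e-4 with reciprocal top-4 panel filter, and 1000
#' bootstrap replicates.
#'
#' @param evalue_ortho Expectation cutoff for the all-vs-all search.
#' @param inflation Markov clustering inflation.
#' @param evalue_recruit Expectation cutoff for the translated search.
#' @param reciprocal_k Rank cutoff of the reciprocal panel filter.
#' @param bootstrap_replicates Bootstrap replicates for the consensus tree.
#' @param seed Master seed; per-stage seeds are derived from it by hashing
#'   the stage name, so stages are independently reproducible.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(evalue_ortho = 1e-6, inflation = 1.5,
                       evalue_recruit = 1e-4, reciprocal_k = 4L,
                       bootstrap_replicates = 1000L, seed = 1L) {
  stopifnot(evalue_ortho > 0, inflation > 1, evalue_recruit > 0,
            reciprocal_k >= 1, bootstrap_replicates >= 1)
  structure(list(evalue_ortho = evalue_ortho, inflation = inflation,
                 evalue_recruit = evalue_recruit,
                 reciprocal_k = as.integer(reciprocal_k),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Derive a per-stage seed from the master seed
#'
#' Stage names are hashed (polynomial rolling hash of the character codes)
#' and folded into the master seed modulo `2^31 - 1`, so each stage draws
#' from an independent, reproducible stream.
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# representative member of a cluster for one genome: the member with the
# highest summed bit score against the cluster's members in other genomes;
# ties broken by longer protein, then lexicographic id
select_representative <- function(members, genome_members, hits, widths) {
  if (length(genome_members) == 1L) return(genome_members)
  others <- setdiff(members, genome_members)
  sums <- vapply(genome_members, function(g) {
    sel <- hits$query == g & hits$subject %in% others
    sum(hits$bitscore[sel])
  }, numeric(1))
  ord <- order(-sums, -widths[genome_members], genome_members)
  genome_members[ord[1L]]
}

stage_msg <- function(log, stage, ...) {
  if (log) message(sprintf("[%s] %s", stage, paste0(...)))
}

write_provenance <- function(path, config, extra = list()) {
  rec <- c(list(package = "n4core",
                version = as.character(utils::packageVersion("n4core")),
                r_version = R.version.string,
                parameters = unclass(config)),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Core-genome workflow: merge, orthology, pan-genome, phylogeny
#'
#' Runs the full comparative stage: optional amalgamation of two prediction
#' sets, translation, all-vs-all similarity search, bidirectional-best-hit
#' graph, Markov clustering, presence matrix and core-cluster extraction,
#' per-core-cluster progressive alignment (one representative per genome),
#' concatenation, complete deletion, Poisson distances, neighbor joining,
#' bootstrap consensus and midpoint rooting.  Any stage failure aborts with
#' the stage name; intermediates computed so far are written to `out_dir`
#' if given.
#'
#' @param genomes Named `DNAStringSet`.
#' @param calls CDS call data frame, or a list of two prediction sets to be
#'   merged per genome with [merge_predictions()].
#' @param config [run_config()].
#' @param clade Optional genome ids of a focal clade; adds conserved and
#'   exclusive cluster sets to the output.
#' @param out_dir Optional directory for intermediates and provenance.
#' @param log Emit per-stage progress messages.
#' @return List: `calls`, `hits`, `clusters`, `presence`, `core`,
#'   `conserved`, `exclusive`, `core_alignment` (concatenated, after
#'   complete deletion), `tree_nj` (full-data NJ tree), `tree` (midpoint-
#'   rooted bootstrap consensus), `genome_of`.
#' @export
run_core_workflow <- function(genomes, calls, config = run_config(),
                              clade = NULL, out_dir = NULL, log = FALSE) {
  stage <- "merge"
  res <- list()
  save_part <- function() {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (!is.null(res$calls)) write_gff3(res$calls, file.path(out_dir, "merged.gff3"))
      if (!is.null(res$hits)) write_hits(res$hits, file.path(out_dir, "hits.tsv"))
      if (!is.null(res$clusters)) write_clusters(res$clusters, file.path(out_dir, "clusters.tsv"))
      if (!is.null(res$presence)) write_presence_matrix(res$presence, file.path(out_dir, "presence.tsv"))
      if (!is.null(res$tree)) ape::write.tree(res$tree, file.path(out_dir, "core_tree.nwk"))
      write_provenance(file.path(out_dir, "provenance.json"), config,
                       list(n_genomes = length(genomes)))
    }
  }
  run_stage <- function(name, expr) {
    stage_msg(log, name, "running")
    tryCatch(expr, error = function(e) {
      save_part()
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  res$calls <- run_stage("merge", {
    if (is.data.frame(calls)) calls else {
      by_genome <- lapply(split(seq_len(nrow(calls[[1L]])), calls[[1L]]$genome_id),
                          function(i) calls[[1L]][i, , drop = FALSE])
      merged <- lapply(names(by_genome), function(g) {
        b <- calls[[2L]][calls[[2L]]$genome_id == g, , drop = FALSE]
        merge_predictions(by_genome[[g]], b)
      })
      do.call(rbind, merged)
    }
  })
  tr <- run_stage("translate", translate_calls(genomes, res$calls))
  res$genome_of <- tr$genome_of
  res$hits <- run_stage("all_vs_all",
                        all_vs_all(tr$proteins, evalue_max = config$evalue_ortho))
  graph <- run_stage("bbh", bbh_graph(res$hits, tr$genome_of))
  res$clusters <- run_stage("mcl", mcl_cluster(graph, inflation = config$inflation))
  res$presence <- run_stage("pangenome",
                            presence_matrix(res$clusters, names(genomes)))
  res$core <- run_stage("pangenome", core_clusters(res$presence))
  if (!is.null(clade)) {
    res$conserved <- run_stage("pangenome", conserved_clusters(res$presence, clade))
    res$exclusive <- run_stage("pangenome", exclusive_clusters(res$presence, clade))
  }
  res$tree_nj <- NULL
  phylo_res <- run_stage("phylogeny", {
    if (length(genomes) < 3L) {
      stop("need at least 3 genomes for the core-gene phylogeny")
    }
    if (length(res$core) < 1L) stop("no core clusters found")
    widths <- setNames(Biostrings::width(tr$proteins), names(tr$proteins))
    alns <- lapply(res$core, function(cid) {
      mem <- res$clusters[res$clusters$cluster_id == cid, , drop = FALSE]
      reps <- vapply(names(genomes), function(g) {
        select_representative(mem$gene_id, mem$gene_id[mem$genome_id == g],
                              res$hits, widths)
      }, character(1))
      seqs <- setNames(as.character(tr$proteins[unname(reps)]), names(reps))
      progressive_align(seqs)
    })
    names(alns) <- res$core
    concat <- concatenate_core(alns)
    clean <- complete_deletion(concat)
    tree_nj <- nj_tree(poisson_distance(clean))
    cons <- bootstrap_consensus(clean, replicates = config$bootstrap_replicates,
                                seed = derive_seed(config$seed, "bootstrap"))
    list(alignment = clean, tree_nj = tree_nj,
         tree = midpoint_root(cons))
  })
  res$core_alignment <- phylo_res$alignment
  res$tree_nj <- phylo_res$tree_nj
  res$tree <- phylo_res$tree
  save_part()
  res
}

#' Recruitment workflow: translated search, reciprocal filter, abundance
#'
#' For each metagenome sample, runs the six-frame translated search of the
#' query genes, optionally applies the reciprocal top-k panel filter, counts
#' at most one hit per read per gene, and converts counts to normalized
#' relative abundance.  When every sample carries an environment label, the
#' per-environment grouped means are included.
#'
#' @param genes Named `DNAStringSet` of query CDS nucleotide sequences.
#' @param samples List of metagenome samples (see [simulate_metagenome()]).
#' @param config [run_config()].
#' @param panel Optional [viral_panel()] for the reciprocal filter.
#' @param focal_phage Focal phage name (required with `panel`).
#' @param out_dir Optional directory for intermediates and provenance.
#' @param log Emit per-stage progress messages.
#' @return List: `hits` (per-sample hit tables), `counts`, `abundance`
#'   (class `abundance_matrix`), `by_environment` (or `NULL`).
#' @export
run_recruit_workflow <- function(genes, samples, config = run_config(),
                                 panel = NULL, focal_phage = NULL,
                                 out_dir = NULL, log = FALSE) {
  if (length(samples) == 0L) stop("empty sample manifest")
  if (is.character(genes)) genes <- Biostrings::DNAStringSet(genes)
  if (length(genes) == 0L) stop("empty gene list")
  if (!is.null(panel) && is.null(focal_phage)) {
    stop("focal_phage is required when a panel is given")
  }
  sample_ids <- vapply(samples, `[[`, "", "sample_id")
  names(samples) <- sample_ids
  hits <- lapply(samples, function(s) {
    stage_msg(log, "search", s$sample_id)
    h <- translated_search(genes, s, evalue_max = config$evalue_recruit)
    if (!is.null(panel)) {
      h <- filter_hits(h, panel, focal_phage, k = config$reciprocal_k)
    }
    h
  })
  counts <- count_hits(hits, names(genes))
  sizes <- vapply(samples, `[[`, numeric(1), "n_sequences")
  gene_aa <- floor(Biostrings::width(genes) / 3) - 1L  # product length, residues
  names(gene_aa) <- names(genes)
  ab <- abundance(counts, sizes, gene_aa, allow_zero = TRUE)
  envs <- vapply(samples, function(s) s$environment %||% NA_character_, "")
  by_env <- NULL
  if (!anyNA(envs)) {
    by_env <- group_by_environment(ab, setNames(envs, sample_ids))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(gene_id = rownames(ab$normalized),
                           round(ab$normalized, 6), check.names = FALSE),
                file.path(out_dir, "abundance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_provenance(file.path(out_dir, "provenance.json"), config,
                     list(n_samples = length(samples), n_genes = length(genes)))
  }
  list(hits = hits, counts = counts, abundance = ab, by_environment = by_env)
}
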