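## End-to-end orchestration: search -> call/classify -> topology/sequons ->
## clusters/summary -> motifs -> groups/expansion, with per-stage outputs.

#' Pipeline configuration
#'
#' @param genome,queries,decoys,references FASTA paths or in-memory named
#'   character vectors. `references` must carry `|group=<label>` headers
#'   (optional; group assignment is skipped without it).
#' @param max_evalue E-value cutoff for the translated search.
#' @param min_aa functional length threshold (aa).
#' @param cluster_gap cluster chaining gap (bp, strict `<`).
#' @param flank,max_chain_gap gene-model construction parameters (bp).
#' @param n_motifs,width_grid motif discovery settings.
#' @param require_7tm drop genes with TM count outside [6, 8].
#' @param tree_classify use tree-clade group assignment instead of
#'   nearest-reference.
#' @param seed integer seed for motif discovery.
#' @return a list of class `or_config`.
#' @export
or_config <- function(genome, queries, decoys = NULL, references = NULL,
                      max_evalue = 1e-10, min_aa = 250L, cluster_gap = 1e6,
                      flank = 1500L, max_chain_gap = 5000L,
                      n_motifs = 5L,
                      width_grid = c(8L, 10L, 12L, 15L, 20L, 30L, 50L),
                      require_7tm = FALSE, tree_classify = FALSE, seed = 1L) {
  stopifnot(max_evalue > 0, min_aa > 0, cluster_gap > 0)
  structure(as.list(environment()), class = "or_config")
}

#' Read a config from YAML
#' @param path YAML file whose keys mirror [or_config()] arguments.
#' @return an `or_config`.
#' @export
read_config <- function(path) {
  do.call(or_config, yaml::read_yaml(path))
}

.as_seqs <- function(x, molecule) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && file.exists(x)) parse_fasta(x, molecule) else x
}

#' Run the full OR annotation pipeline
#'
#' Executes every stage and writes the standard outputs into `out_dir`:
#' `genes.gff3`, `genes.tsv`, `rep.table1.tsv`, `rep.table2.tsv`,
#' `clusters.tsv`, `motifs/motif_<k>.tsv`, `tree.nwk`, `groups.tsv`,
#' `expansion.tsv`, and `run.log` echoing every threshold applied. Motif
#' discovery runs on functional peptides only, matching the convention
#' that conserved-motif and glycosylation analyses address the functional
#' repertoire.
#'
#' @param config an [or_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the gene table, clusters, summary,
#'   motifs, group assignment and expansion table.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "or_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("orscan %s | R %s", as.character(utils::packageVersion("orscan")),
           paste(R.version$major, R.version$minor, sep = "."))
  for (nm in c("max_evalue", "min_aa", "cluster_gap", "flank",
               "max_chain_gap", "n_motifs", "require_7tm", "tree_classify",
               "seed"))
    log_line("config %s = %s", nm, paste(config[[nm]], collapse = ","))

  stage <- "load"
  result <- list()
  tryCatch({
    genome <- .as_seqs(config$genome, "nucleotide")
    queries <- .as_seqs(config$queries, "protein")
    decoys <- .as_seqs(config$decoys, "protein")
    refs <- .as_seqs(config$references, "protein")

    stage <- "search"
    hsps <- scan_genome(queries, genome, max_evalue = config$max_evalue)
    log_line("search: %d HSPs at E <= %g", nrow(hsps), config$max_evalue)
    write.table(hsps, file.path(out_dir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "call"
    genes <- call_genes(hsps, genome, queries,
                        decoys = if (is.null(decoys)) character(0) else decoys,
                        flank = config$flank,
                        max_chain_gap = config$max_chain_gap,
                        min_aa = config$min_aa)
    log_line("call: %d gene models", nrow(genes))

    stage <- "topology"
    genes <- annotate_topology(genes, require_7tm = config$require_7tm)

    stage <- "classify_groups"
    if (!is.null(refs) && nrow(genes) > 0) {
      ga <- assign_groups(setNames(gsub("[*]", "", genes$peptide), genes$id),
                          refs,
                          method = if (config$tree_classify) "tree" else "nearest")
      genes$group <- ga$group[match(genes$id, ga$gene_id)]
      write.table(ga, file.path(out_dir, "groups.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (length(genes$id) >= 3L) {
        peps <- setNames(gsub("[*]", "", genes$peptide), genes$id)
        ok <- nchar(peps) >= 30L
        if (sum(ok) + length(refs) >= 3L) {
          tr <- nj_tree(distance_matrix(c(peps[ok], refs)))
          writeLines(tree_newick(tr), file.path(out_dir, "tree.nwk"))
        }
      }
      result$groups <- ga
    }

    stage <- "clusters"
    clusters <- assign_clusters(genes, max_gap = config$cluster_gap)
    write.table(clusters, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line("clusters: %d (%d tandem-consistent)", nrow(clusters),
             sum(clusters$tandem_flag))

    stage <- "summary"
    sizes <- setNames(nchar(genome), names(genome))
    summ <- summarize_repertoire(genes, chrom_sizes = sizes)
    write_repertoire_tables(summ, file.path(out_dir, "rep"))

    stage <- "motifs"
    func_pep <- gsub("[*]", "", genes$peptide[genes$status == "functional"])
    names(func_pep) <- genes$id[genes$status == "functional"]
    motifs <- list()
    if (length(func_pep) >= 2L) {
      motifs <- discover_top_motifs(func_pep, n_motifs = config$n_motifs,
                                    width_grid = config$width_grid,
                                    seed = config$seed)
      dir.create(file.path(out_dir, "motifs"), showWarnings = FALSE)
      for (k in seq_along(motifs)) {
        m <- motifs[[k]]
        tab <- as.data.frame(t(m$pwm))
        tab <- cbind(position = seq_len(m$width), tab, ic = m$ic_profile)
        write.table(tab, file.path(out_dir, "motifs",
                                   sprintf("motif_%d.tsv", k)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        log_line("motif %d: width %d consensus %s LLR %.2f sites %d",
                 k, m$width, m$consensus, m$log_likelihood_ratio,
                 nrow(m$sites))
      }
    }

    stage <- "expansion"
    if (!is.null(genes$group)) {
      ref_groups <- .group_from_header(names(refs))
      ref_counts <- lapply(split(ref_groups, ref_groups), length)
      exp_tab <- detect_expansion(genes[!is.na(genes$group), , drop = FALSE],
                                  ref_counts)
      write.table(exp_tab, file.path(out_dir, "expansion.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      result$expansion <- exp_tab
    }

    stage <- "write"
    gene_out <- genes[, setdiff(names(genes), "verify_score")]
    write.table(gene_out, file.path(out_dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(genes) > 0) {
      ann <- annotation_table(genes$chrom, genes$start, genes$end,
                              genes$strand, "gene", id = genes$id,
                              status = genes$status,
                              defects = genes$defects,
                              tm_count = genes$tm_count,
                              group = if (is.null(genes$group)) NA
                                      else genes$group)
      write_annotations(ann, file.path(out_dir, "genes.gff3"), "GFF3")
    }
    log_line("done: %d genes (%d functional, %d partial, %d pseudogene)",
             nrow(genes), sum(genes$status == "functional"),
             sum(genes$status == "partial"),
             sum(genes$status == "pseudogene"))
    result$genes <- genes
    result$clusters <- clusters
    result$summary <- summ
    result$motifs <- motifs
  }, error = function(e) {
    log_line("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
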