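## Chromosomal cluster detection, orientation analysis, and repertoire
## summary tables.

#' Group OR genes into chromosomal clusters
#'
#' A cluster is a maximal single-linkage chain of genes on one chromosome
#' in which consecutive genes (sorted by start) are separated by a
#' nearest-edge gap strictly below `max_gap` (default < 1 Mb). Singletons
#' are clusters of size one. A cluster is flagged as a candidate tandem
#' array (`tandem_flag`) when it has at least two members and all share
#' one transcriptional orientation.
#'
#' @param genes gene table with `id`, `chrom`, `start`, `end`, `strand`
#'   (and optionally `group`).
#' @param max_gap maximum edge-to-edge gap in bp (strict inequality).
#' @return data.frame with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_genes`, `members` (comma-separated ids),
#'   `orientation_fraction`, `tandem_flag`, `family_composition`.
#' @export
assign_clusters <- function(genes, max_gap = 1e6) {
  if (nrow(genes) == 0L) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_genes = integer(0), members = character(0),
                      orientation_fraction = numeric(0),
                      tandem_flag = logical(0),
                      family_composition = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (chrom in sort(unique(genes$chrom))) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    brk <- if (nrow(g) > 1L)
      as.integer(g$start[-1L] - cummax(g$end)[-nrow(g)] >= max_gap)
    else integer(0)
    cl <- cumsum(c(1L, brk))
    for (ci in split(seq_len(nrow(g)), cl)) {
      mem <- g[ci, , drop = FALSE]
      oc <- orientation_consistency(mem$strand)
      comp <- if (!is.null(mem$group)) {
        tb <- table(mem$group)
        paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ";")
      } else ""
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(mem$start), end = max(mem$end),
        n_genes = nrow(mem), members = paste(mem$id, collapse = ","),
        orientation_fraction = oc$orientation_fraction,
        tandem_flag = oc$tandem_flag, family_composition = comp,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Orientation consistency of a gene cluster
#'
#' @param strands character vector of `+`/`-` for the cluster members.
#' @return list with `orientation_fraction` (share of members on the
#'   majority strand, in [0.5, 1]) and `tandem_flag` (TRUE when >= 2
#'   members all share one strand).
#' @export
orientation_consistency <- function(strands) {
  stopifnot(length(strands) >= 1L, all(strands %in% c("+", "-")))
  frac <- max(mean(strands == "+"), mean(strands == "-"))
  list(orientation_fraction = frac,
       tandem_flag = length(strands) >= 2L && frac == 1)
}

## round half away from zero, as printed summary tables conventionally do
.round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize an OR repertoire at species and chromosome level
#'
#' Produces the two standard summary tables: a one-row species summary with
#' per-category counts and percentages (2-decimal, half-up rounding), and a
#' per-chromosome composition table. Category counts always sum to the
#' total at both granularities.
#'
#' @param genes gene table with `chrom` and
#'   `status` in functional/partial/pseudogene; alternatively pass `counts`
#'   as a named vector `c(functional=, partial=, pseudogene=)` to summarize
#'   pre-tabulated counts.
#' @param chrom_sizes optional named vector of chromosome lengths in bp.
#' @param counts optional pre-tabulated species counts (overrides `genes`).
#' @return list with `species` (one-row data.frame: counts, percentages,
#'   total) and `per_chromosome` (data.frame, one row per chromosome plus
#'   totals consistency by construction).
#' @export
summarize_repertoire <- function(genes = NULL, chrom_sizes = NULL, counts = NULL) {
  statuses <- c("functional", "partial", "pseudogene")
  if (is.null(counts)) {
    stopifnot(!is.null(genes))
    if (nrow(genes) > 0 && !all(genes$status %in% statuses))
      stop("gene with unknown status: ",
           paste(setdiff(unique(genes$status), statuses), collapse = ","))
    counts <- vapply(statuses, function(s) sum(genes$status == s), numeric(1))
  } else {
    counts <- counts[statuses]
    stopifnot(!anyNA(counts))
  }
  total <- sum(counts)
  pct <- if (total > 0) .round_half_up(100 * counts / total) else {
    warning("empty repertoire: percentages reported as 0")
    setNames(rep(0, 3), statuses)
  }
  species <- data.frame(
    functional = counts[["functional"]], functional_pct = pct[["functional"]],
    partial = counts[["partial"]], partial_pct = pct[["partial"]],
    pseudogene = counts[["pseudogene"]], pseudogene_pct = pct[["pseudogene"]],
    total = total)

  per_chrom <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes) else sort(unique(genes$chrom))
    per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      data.frame(chrom = ch,
                 size_mb = if (!is.null(chrom_sizes))
                   .round_half_up(chrom_sizes[[ch]] / 1e6) else NA_real_,
                 functional = sum(g$status == "functional"),
                 partial = sum(g$status == "partial"),
                 pseudogene = sum(g$status == "pseudogene"),
                 total = nrow(g), stringsAsFactors = FALSE)
    }))
    rownames(per_chrom) <- NULL
  }
  list(species = species, per_chromosome = per_chrom)
}

#' Write repertoire summary tables to TSV
#'
#' @param summary output of [summarize_repertoire()].
#' @param out_prefix path prefix; writes `<prefix>.table1.tsv` (species
#'   summary) and, when present, `<prefix>.table2.tsv` (per chromosome).
#' @return the paths written, invisibly.
#' @export
write_repertoire_tables <- function(summary, out_prefix) {
  p1 <- paste0(out_prefix, ".table1.tsv")
  sp <- summary$species
  t1 <- data.frame(
    functional = sprintf("%d (%.2f)", sp$functional, sp$functional_pct),
    partial = sprintf("%d (%.2f)", sp$partial, sp$partial_pct),
    pseudogene = sprintf("%d (%.2f)", sp$pseudogene, sp$pseudogene_pct),
    total = sp$total)
  write.table(t1, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(summary$per_chromosome)) {
    p2 <- paste0(out_prefix, ".table2.tsv")
    write.table(summary$per_chromosome, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
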