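## Synthetic genomes with planted OR gene truth. The generator emulates the
## repertoire structure seen in fish genomes: oriented tandem clusters of
## intronless OR-like genes embedded in random background, with a stated
## fraction pseudogenized or truncated.

.codon_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$tab)) {
      gc <- Biostrings::GENETIC_CODE
      env$tab <- split(names(gc), unname(gc))
    }
    env$tab
  }
})

## distinct hydrophilic loop pools keep group templates >= ~25% diverged
.group_pools <- list(
  beta = c("D", "E", "N", "S"), gamma = c("K", "R", "Q", "T"),
  delta = c("E", "Q", "H", "G"), epsilon = c("D", "K", "T", "S"),
  zeta = c("R", "N", "G", "Y"), eta = c("E", "R", "S", "H"),
  kappa = c("D", "Q", "K", "G"))

OR_CONSERVED_MOTIF <- "MAYDRYVAIC"

#' Generate a synthetic OR template peptide and CDS
#'
#' Builds a ~310-aa peptide with the rhodopsin-like GPCR architecture:
#' seven 21-aa hydrophobic stretches separated by hydrophilic loops, the
#' conserved "MAYDRYVAIC" block after the third helix, and an N-terminal
#' N-X-S/T sequon. Loop composition is group-specific so that templates of
#' different groups are separable by alignment distance. The CDS is a
#' uniform-synonymous-codon back-translation with ATG start and a single
#' terminal stop. Deterministic per (group_label, seed).
#'
#' @param group_label one of beta, gamma, delta, epsilon, zeta, eta, kappa.
#' @param seed integer seed.
#' @return list with `peptide` (310 aa) and `cds` (933 nt incl. stop).
#' @export
make_or_template <- function(group_label = "delta", seed = 1L) {
  pool <- .group_pools[[group_label]]
  if (is.null(pool)) stop("unknown group label: ", group_label)
  tm_pool <- c("I", "L", "V")
  mild <- c("S", "T", "G")
  .with_seed(seed + 7L * match(group_label, names(.group_pools)), {
    pick <- function(set, n) paste(sample(set, n, replace = TRUE), collapse = "")
    ## strongly hydrophobic Ile/Val edges keep every helix above the
    ## detection threshold for a full 15-residue run
    tm <- function() paste0(pick(c("I", "V"), 4L), pick(tm_pool, 13L),
                            pick(c("I", "V"), 4L))
    ## mildly polar loop edges stop deep hydrophilic residues from eroding
    ## the windowed hydropathy at the helix boundaries
    loop <- function(n) paste0(pick(mild, 3L), pick(pool, n - 6L),
                               pick(mild, 3L))
    nterm <- paste0(pick(pool, 10L), "NGT", pick(pool, 8L), pick(mild, 3L))
    loops <- vapply(1:6, function(i) {
      if (i == 3L) paste0(pick(mild, 3L), OR_CONSERVED_MOTIF,
                          pick(pool, 3L), pick(mild, 3L))
      else loop(19L)
    }, character(1))
    tail <- paste0(pick(mild, 3L), pick(pool, 21L))
    pep <- paste0("M", nterm, paste(vapply(1:7, function(i) {
      paste0(tm(), if (i < 7L) loops[i] else "")
    }, character(1)), collapse = ""), tail)
    list(peptide = pep, cds = .back_translate(pep))
  })
}

## uniform synonymous codon choice; uses the current RNG stream
.back_translate <- function(peptide, stop_codon = NULL) {
  tab <- .codon_table()
  aa <- strsplit(peptide, "")[[1]]
  codons <- vapply(aa, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) stop("cannot back-translate residue: ", a)
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
  if (is.null(stop_codon)) stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste0(paste(codons, collapse = ""), stop_codon)
}

#' Simulation specification for [generate_genome()]
#'
#' Defaults describe the benchmark layout used throughout the package:
#' two 1-Mb chromosomes, three same-orientation tandem clusters of ten
#' gene copies, 5% amino-acid divergence per copy, and category
#' proportions matching a large fish OR repertoire (about 6% pseudogenes,
#' 3% partial genes).
#'
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param gc background GC fraction.
#' @param n_clusters number of planted clusters; each uses one template.
#' @param copies_per_cluster gene copies per cluster.
#' @param intergene_gap_range bp gap range between copies in a cluster.
#' @param p_pseudo,p_partial per-copy probability of a pseudogenizing
#'   lesion (premature stop or 1-nt frameshift) or of truncation.
#' @param aa_divergence per-copy amino-acid substitution rate.
#' @param orientation_mode `"same"` (tandem layout) or `"mixed"`.
#' @param groups group labels to cycle templates over.
#' @param seed integer seed.
#' @return a list of class `or_sim_spec`.
#' @export
or_sim_spec <- function(n_chromosomes = 2L, chrom_length = 1e6, gc = 0.41,
                        n_clusters = 3L, copies_per_cluster = 10L,
                        intergene_gap_range = c(5e3, 5e4),
                        p_pseudo = 19 / 318, p_partial = 10 / 318,
                        aa_divergence = 0.05,
                        orientation_mode = c("same", "mixed"),
                        groups = c("delta", "zeta", "gamma"),
                        seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(p_pseudo >= 0, p_partial >= 0, p_pseudo + p_partial <= 1,
            gc > 0, gc < 1, aa_divergence >= 0, aa_divergence <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length, gc = gc,
                 n_clusters = as.integer(n_clusters),
                 copies_per_cluster = as.integer(copies_per_cluster),
                 intergene_gap_range = intergene_gap_range,
                 p_pseudo = p_pseudo, p_partial = p_partial,
                 aa_divergence = aa_divergence,
                 orientation_mode = orientation_mode,
                 groups = groups, seed = as.integer(seed)),
            class = "or_sim_spec")
}

#' Mutate a peptide at a fixed amino-acid substitution rate
#'
#' Each position after the initiator Met is substituted with probability
#' `rate` by a uniformly drawn different residue. Uses the caller's RNG
#' stream.
#'
#' @param pep amino-acid string.
#' @param rate per-residue substitution probability.
#' @return the mutated peptide.
#' @export
mutate_peptide <- function(pep, rate) {
  aa <- strsplit(pep, "")[[1]]
  ## keep the initiator Met so lesions are planted only where intended
  idx <- which(runif(length(aa)) < rate & seq_along(aa) > 1L)
  for (i in idx) aa[i] <- sample(setdiff(AA_ALPHABET20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' Generate a synthetic genome with planted OR gene truth
#'
#' Background sequence is iid at the requested GC; clusters are placed at
#' non-overlapping anchors; within a cluster, copies of one group template
#' are mutated at the amino-acid level, back-translated, spaced by random
#' intergenic gaps, and oriented per `orientation_mode`. Each copy is
#' independently pseudogenized (premature stop or 1-nt frameshift, chosen
#' uniformly, placed in the middle 60% of the CDS) with probability
#' `p_pseudo`, or truncated (start or stop region removed) with
#' probability `p_partial`. Identical seeds give byte-identical output.
#'
#' @param spec an [or_sim_spec()].
#' @return list with `genome` (named chromosome strings), `truth`
#'   (data.frame: gene_id, chrom, start, end, strand, true_status,
#'   template_id, group_label, cluster_id), `templates` (named peptides,
#'   `<group>|group=<group>`), and `spec`.
#' @export
generate_genome <- function(spec = or_sim_spec()) {
  stopifnot(inherits(spec, "or_sim_spec"))
  groups <- rep(spec$groups, length.out = spec$n_clusters)
  tmpl <- lapply(unique(groups), make_or_template, seed = spec$seed)
  names(tmpl) <- unique(groups)

  .with_seed(spec$seed, {
    nucs <- c("A", "C", "G", "T")
    p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    genome <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      genome[[sprintf("chr%d", ci)]] <-
        sample(nucs, spec$chrom_length, replace = TRUE, prob = p)
    }

    truth <- list()
    cluster_chrom <- rep(seq_len(spec$n_chromosomes),
                         length.out = spec$n_clusters)
    next_free <- rep(1L, spec$n_chromosomes)  # naive left-to-right packing
    ## tandem arrays on one chromosome share orientation, so clusters that
    ## fall within 1 Mb of each other merge into a consistent tandem block
    chrom_strand <- sample(c("+", "-"), spec$n_chromosomes, replace = TRUE)
    gid <- 0L
    for (ki in seq_len(spec$n_clusters)) {
      grp <- groups[ki]
      template <- tmpl[[grp]]
      ch <- cluster_chrom[ki]
      strand_cluster <- chrom_strand[ch]
      pos <- next_free[ch] + sample.int(2e4, 1L)
      for (copy in seq_len(spec$copies_per_cluster)) {
        pep <- mutate_peptide(template$peptide, spec$aa_divergence)
        cds <- .back_translate(pep)
        u <- runif(1L)
        status <- if (u < spec$p_pseudo) "pseudogene"
          else if (u < spec$p_pseudo + spec$p_partial) "partial"
          else "functional"
        n_cod <- nchar(cds) / 3L
        mid <- seq.int(floor(n_cod * 0.2), floor(n_cod * 0.8))
        if (status == "pseudogene") {
          cp <- sample(mid, 1L)
          if (runif(1L) < 0.5) {  # premature stop
            substr(cds, 3L * cp + 1L, 3L * cp + 3L) <- "TGA"
          } else {                # 1-nt frameshift (deletion)
            at <- 3L * cp + 1L
            cds <- paste0(substr(cds, 1L, at - 1L),
                          substr(cds, at + 1L, nchar(cds)))
          }
        } else if (status == "partial") {
          cut <- 3L * floor(n_cod * 0.35)
          cds <- if (runif(1L) < 0.5)
            substr(cds, cut + 1L, nchar(cds))        # start region removed
          else substr(cds, 1L, nchar(cds) - cut)     # stop region removed
        }
        glen <- nchar(cds)
        if (pos + glen > spec$chrom_length - 1000L)
          stop("planted genes exceed chromosome capacity")
        gseq <- if (strand_cluster == "+") cds else revcomp(cds)
        v <- genome[[ch]]
        v[(pos + 1L):(pos + glen)] <- strsplit(gseq, "")[[1]]
        genome[[ch]] <- v
        gid <- gid + 1L
        truth[[gid]] <- data.frame(
          gene_id = sprintf("true_%03d", gid),
          chrom = sprintf("chr%d", ch), start = pos, end = pos + glen,
          strand = if (spec$orientation_mode == "same") strand_cluster
                   else sample(c("+", "-"), 1L),
          true_status = status, template_id = grp, group_label = grp,
          array_id = sprintf("array_%02d", ki),
          stringsAsFactors = FALSE)
        if (spec$orientation_mode == "mixed") {
          s <- truth[[gid]]$strand
          gseq <- if (s == "+") cds else revcomp(cds)
          v <- genome[[ch]]
          v[(pos + 1L):(pos + glen)] <- strsplit(gseq, "")[[1]]
          genome[[ch]] <- v
        }
        gap <- round(runif(1L, spec$intergene_gap_range[1L],
                           spec$intergene_gap_range[2L]))
        pos <- pos + glen + gap
      }
      next_free[ch] <- pos
    }
    truth <- do.call(rbind, truth)
    ## truth cluster ids follow the < 1 Mb single-linkage rule applied to
    ## the planted coordinates, so cluster recovery is well-defined even
    ## when two arrays land within 1 Mb of each other
    cl <- assign_clusters(data.frame(id = truth$gene_id, chrom = truth$chrom,
                                     start = truth$start, end = truth$end,
                                     strand = truth$strand,
                                     stringsAsFactors = FALSE))
    truth$cluster_id <- NA_character_
    for (i in seq_len(nrow(cl))) {
      mem <- strsplit(cl$members[i], ",")[[1]]
      truth$cluster_id[truth$gene_id %in% mem] <- cl$cluster_id[i]
    }
    genome <- vapply(genome, paste, character(1), collapse = "")
    templates <- vapply(tmpl, `[[`, character(1), "peptide")
    names(templates) <- sprintf("%s|group=%s", names(tmpl), names(tmpl))
    list(genome = genome, truth = truth, templates = templates, spec = spec)
  })
}

#' Random decoy (non-OR) proteins
#'
#' Hydrophilic random proteins with no transmembrane architecture, used as
#' the negative set for [verify_candidate()].
#'
#' @param n number of decoys.
#' @param length_aa decoy length.
#' @param seed integer seed.
#' @return named character vector.
#' @export
make_decoys <- function(n = 5L, length_aa = 300L, seed = 99L) {
  .with_seed(seed, {
    pool <- c("A", "D", "E", "G", "K", "N", "P", "Q", "R", "S", "T", "H")
    setNames(vapply(seq_len(n), function(i)
      paste(c("M", sample(pool, length_aa - 1L, replace = TRUE)),
            collapse = ""), character(1)),
      sprintf("decoy_%02d", seq_len(n)))
  })
}
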