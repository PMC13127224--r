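## Gene-model construction and three-way functional classification.
## OR genes are intronless, so a model is a single ORF on one strand.

## strand-oriented subsequence of a chromosome, 0-based half-open genomic
## coordinates; on '-' the reverse complement is returned so downstream code
## always reads 5'->3' in coding orientation
.oriented_region <- function(chrom_seq, start, end, strand) {
  s <- substr(chrom_seq, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

## codon starts (0-based, region-local) of in-frame stop codons
.stop_positions <- function(region, offset) {
  n <- nchar(region)
  starts <- seq.int(offset, n - 3L, by = 3L)
  if (length(starts) == 0L) return(integer(0))
  cod <- substring(region, starts + 1L, starts + 3L)
  starts[cod %in% c("TAA", "TAG", "TGA")]
}

.codon_starts_matching <- function(region, offset, codon) {
  n <- nchar(region)
  starts <- seq.int(offset, n - 3L, by = 3L)
  if (length(starts) == 0L) return(integer(0))
  starts[substring(region, starts + 1L, starts + 3L) == codon]
}

#' Build a draft OR gene model from a candidate locus
#'
#' The locus envelope is extended by `flank` bp on each side, and the
#' maximal in-frame ORF overlapping the best HSP is located on the locus
#' strand: from the closest upstream ATG after the previous in-frame stop
#' (or from the region edge if no ATG exists there) to the first in-frame
#' stop. `missing_start` / `missing_stop` are recorded when the ORF is not
#' properly bounded within the extended region.
#'
#' @param locus a candidate locus from [chain_and_select()].
#' @param genome named character vector holding at least `locus$chrom`.
#' @param flank extension in bp (default 1500, enough to span a full
#'   ~310-codon OR ORF beyond any HSP).
#' @return a draft gene model: list with `id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end` (0-based half-open, genomic), `peptide`,
#'   `length_aa`, `defects` (character vector), and the originating locus.
#' @export
build_gene_model <- function(locus, genome, flank = 1500L) {
  chrom_seq <- genome[[locus$chrom]]
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stop("locus chromosome not in genome: ", locus$chrom)
  L <- nchar(chrom_seq)
  if (locus$g_start >= L || locus$g_end > L) stop("locus outside genome record")
  r_start <- max(0L, locus$g_start - flank)
  r_end <- min(L, locus$g_end + flank)
  region <- .oriented_region(chrom_seq, r_start, r_end, locus$strand)
  nreg <- nchar(region)

  ## best HSP anchors the reading frame; map its genomic span into
  ## region-local coding-orientation coordinates
  best <- locus$hsps[order(locus$hsps$evalue,
                           -(locus$hsps$q_end - locus$hsps$q_start)), ][1L, ]
  if (locus$strand == "+") {
    a_start <- best$g_start - r_start
    a_end <- best$g_end - r_start
  } else {
    a_start <- r_end - best$g_end
    a_end <- r_end - best$g_start
  }
  offset <- a_start %% 3L

  stops <- .stop_positions(region, offset)
  ## in-frame segment containing the aligned span start
  prev_stops <- stops[stops < a_start]
  seg_start <- if (length(prev_stops)) max(prev_stops) + 3L else offset
  next_stops <- stops[stops >= a_start]
  seg_stop <- if (length(next_stops)) min(next_stops) else NA_integer_

  atgs <- .codon_starts_matching(region, offset, "ATG")
  atgs <- atgs[atgs >= seg_start & atgs <= a_start]
  defects <- character(0)
  if (length(atgs)) {
    ## anchor the start at the ATG nearest the aligned region so intact
    ## planted genes recover their exact coordinates
    cds_from <- max(atgs)
  } else {
    cds_from <- seg_start
    defects <- c(defects, "missing_start")
  }
  if (is.na(seg_stop)) {
    cds_to <- cds_from + ((nreg - cds_from) %/% 3L) * 3L
    defects <- c(defects, "missing_stop")
  } else {
    cds_to <- seg_stop + 3L   # include the stop codon in the CDS span
  }
  cds_nt <- substr(region, cds_from + 1L, cds_to)
  pep_nt <- if (is.na(seg_stop)) cds_nt else substr(cds_nt, 1L, nchar(cds_nt) - 3L)
  peptide <- if (nchar(pep_nt) >= 3L) {
    as.character(Biostrings::translate(Biostrings::DNAString(pep_nt),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  } else ""

  if (locus$strand == "+") {
    cds_start <- r_start + cds_from; cds_end <- r_start + cds_to
  } else {
    cds_start <- r_end - cds_to; cds_end <- r_end - cds_from
  }
  list(id = sprintf("%s_%d_%s", locus$chrom, cds_start, locus$strand),
       chrom = locus$chrom, strand = locus$strand,
       cds_start = cds_start, cds_end = cds_end,
       peptide = peptide, length_aa = nchar(peptide),
       defects = defects, locus = locus,
       aligned_span = c(best$g_start, best$g_end),
       frame_stop = seg_stop, region_bounds = c(r_start, r_end))
}

#' Detect coding defects in a draft gene model
#'
#' Adds to the defects recorded at construction: `premature_stop` when an
#' in-frame stop interrupts the aligned coding span before the aligned
#' query end; `frameshift` when chained HSPs of the same query advance
#' along the query while switching reading frame on the same strand;
#' `too_short` when the peptide is <= `min_aa` residues and nothing else
#' explains it.
#'
#' @param locus the candidate locus the model was built from.
#' @param model a draft model from [build_gene_model()].
#' @param min_aa functional length threshold (aa); default 250 means
#'   functional genes must exceed 250 residues.
#' @return character vector of defects.
#' @export
detect_defects <- function(locus, model, min_aa = 250L, min_identity = 0.5) {
  defects <- model$defects

  ## defect evidence comes from confident HSPs only: OR helices resemble
  ## each other enough to seed low-identity off-diagonal self-hits that
  ## would otherwise mimic frame switches and stretch the aligned span
  h <- locus$hsps[locus$hsps$identity >= min_identity, , drop = FALSE]
  if (nrow(h) == 0L) h <- locus$hsps
  for (q in unique(h$query_id)) {
    hq <- h[h$query_id == q, , drop = FALSE]
    if (nrow(hq) < 2L) next
    hq <- hq[order(hq$q_start), ]
    adv <- diff(hq$q_start) > 0
    jump <- diff(hq$frame) != 0
    if (any(adv & jump)) { defects <- c(defects, "frameshift"); break }
  }

  ## premature stop: the ORF's terminating stop falls inside the aligned
  ## span, short of the projected end of the aligned query region
  if (!is.na(model$frame_stop)) {
    r <- model$region_bounds
    if (model$strand == "+") {
      stop_g <- r[1L] + model$frame_stop
    } else {
      stop_g <- r[2L] - model$frame_stop - 3L
    }
    hb <- h[h$query_id == locus$best_query, , drop = FALSE]
    if (nrow(hb) == 0L) hb <- h
    a <- c(min(hb$g_start), max(hb$g_end))
    if (stop_g >= a[1L] && stop_g + 3L < a[2L])
      defects <- c(defects, "premature_stop")
  }

  if (model$length_aa <= min_aa && length(defects) == 0L)
    defects <- c(defects, "too_short")
  unique(defects)
}

#' Classify a gene model as functional, partial, or pseudogene
#'
#' Pseudogene if a premature stop or frameshift disrupts the ORF; else
#' partial if the start or stop is missing or the peptide is too short;
#' else functional (which therefore requires an intact ORF longer than
#' 250 aa). Disruptive defects take precedence when categories co-occur.
#'
#' @param defects character vector of defects.
#' @param length_aa peptide length.
#' @param min_aa functional length threshold.
#' @return one of `"functional"`, `"partial"`, `"pseudogene"`.
#' @export
classify_gene <- function(defects, length_aa, min_aa = 250L) {
  if (any(defects %in% c("premature_stop", "frameshift"))) return("pseudogene")
  if (any(defects %in% c("missing_start", "missing_stop", "too_short")))
    return("partial")
  if (length_aa <= min_aa) return("partial")
  "functional"
}

#' Verify a candidate against the OR query set
#'
#' Reciprocal-style check replacing an external-database lookup: the
#' candidate peptide must score better against the OR query set than
#' against a decoy (non-OR) protein set under local alignment.
#'
#' @param model gene model with a `peptide`.
#' @param queries named character vector of OR query proteins.
#' @param decoys named character vector of non-OR decoy proteins
#'   (may be empty, in which case any positive OR score verifies).
#' @return `TRUE` if the model looks OR-like.
#' @export
verify_candidate <- function(model, queries, decoys = character(0)) {
  if (length(queries) == 0L) stop("no queries")
  pep <- gsub("[*X]", "", model$peptide)
  if (!nzchar(pep)) return(FALSE)
  best_q <- max(vapply(queries, function(q)
    local_align(pep, q)$score, numeric(1)))
  if (length(decoys) == 0L) return(best_q > 0)
  best_d <- max(vapply(decoys, function(d)
    local_align(pep, d)$score, numeric(1)))
  best_q > best_d
}

#' Call and classify OR gene models from HSPs
#'
#' Runs the full calling stage: chain HSPs into loci, build a model per
#' locus, detect defects, verify against queries (and decoys if given),
#' deduplicate overlapping same-strand models (keeping the higher verify
#' score, then the longer peptide), and classify each survivor.
#'
#' @param hsps HSP table from [scan_genome()].
#' @param genome named character vector of chromosomes.
#' @param queries,decoys protein sets for [verify_candidate()].
#' @param flank,max_chain_gap,min_aa tuning parameters (see the
#'   per-operation functions).
#' @return data.frame with one row per called gene: coordinates, strand,
#'   peptide, defects (comma-separated), status, best query.
#' @export
call_genes <- function(hsps, genome, queries, decoys = character(0),
                       flank = 1500L, max_chain_gap = 5000L, min_aa = 250L) {
  loci <- chain_and_select(hsps, max_chain_gap = max_chain_gap)
  models <- list()
  for (locus in loci) {
    model <- build_gene_model(locus, genome, flank = flank)
    model$defects <- detect_defects(locus, model, min_aa = min_aa)
    model$status <- classify_gene(model$defects, model$length_aa, min_aa = min_aa)
    if (!verify_candidate(model, queries, decoys)) next
    pep <- gsub("[*X]", "", model$peptide)
    model$verify_score <- if (nzchar(pep))
      max(vapply(queries, function(q) local_align(pep, q)$score, numeric(1)))
    else 0
    models[[length(models) + 1L]] <- model
  }
  if (length(models) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_aa = integer(0),
                      defects = character(0), status = character(0),
                      best_query = character(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    id = vapply(models, `[[`, character(1), "id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, `[[`, numeric(1), "cds_start"),
    end = vapply(models, `[[`, numeric(1), "cds_end"),
    strand = vapply(models, `[[`, character(1), "strand"),
    length_aa = vapply(models, `[[`, numeric(1), "length_aa"),
    defects = vapply(models, function(m)
      paste(m$defects, collapse = ","), character(1)),
    status = vapply(models, `[[`, character(1), "status"),
    best_query = vapply(models, function(m) m$locus$best_query, character(1)),
    verify_score = vapply(models, `[[`, numeric(1), "verify_score"),
    peptide = vapply(models, `[[`, character(1), "peptide"),
    stringsAsFactors = FALSE)

  ## deduplicate overlapping same-strand models
  df <- df[order(df$chrom, df$strand, -df$verify_score, -df$length_aa), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(df)) > i &
                 df$chrom == df$chrom[i] & df$strand == df$strand[i] &
                 df$start < df$end[i] & df$end > df$start[i])
    keep[j] <- FALSE
  }
  df <- df[keep, ]
  df <- df[order(df$chrom, df$start), ]
  df$id <- sprintf("or_%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}
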