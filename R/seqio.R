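#' @import Biostrings
#' @importFrom GenomicRanges GRanges mcols strand start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a FASTA file into a list of sequence records
#'
#' Wraps \pkg{Biostrings} FASTA parsing and enforces the invariants the
#' pipeline relies on: unique non-empty ids, non-empty sequences, and an
#' alphabet consistent with the declared molecule type. Sequences are
#' upper-cased; multi-line records are concatenated.
#'
#' @param path path to a FASTA file.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each header, the full header is kept in
#'   the `"desc"` attribute.
#' @export
parse_fasta <- function(path, molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  desc <- names(set)
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("empty sequence id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1L])
  legal <- if (molecule == "nucleotide") "ACGTN" else
    paste0(paste(AA_ALPHABET20, collapse = ""), "X*")
  bad <- regexpr(sprintf("[^%s]", legal), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                 molecule, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  structure(setNames(seqs, ids), desc = setNames(desc, ids))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1/+2/+3 translate the forward strand starting at offsets 0/1/2;
#' frames -1/-2/-3 translate the reverse complement at the same offsets.
#' Stop codons are rendered `*`; codons containing `N` are rendered `X`
#' (so an ambiguous codon never counts as a stop). Trailing 1-2 nt that do
#' not complete a codon are dropped.
#'
#' @param seq nucleotide string, length >= 3.
#' @return named character vector with elements `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  out <- character(6)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      n <- length(s) - (f - 1L)
      n <- n - n %% 3L
      key <- paste0(strand, f)
      if (n < 3L) { out[key] <- ""; next }
      cod <- Biostrings::subseq(s, start = f, width = n)
      out[key] <- as.character(Biostrings::translate(
        cod, if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
  }
  out
}

#' Construct an annotation table
#'
#' Internal annotation records use 0-based half-open coordinates. Extra
#' columns (e.g. `status`, `defects`, `tm_count`, `group`) are carried as
#' attributes on output.
#'
#' @param seq_id,start,end,strand,feature_type vectors of equal length;
#'   `start`/`end` 0-based half-open.
#' @param ... further attribute columns (recycled).
#' @return a `data.frame` with one row per record.
#' @export
annotation_table <- function(seq_id, start, end, strand, feature_type = "gene", ...) {
  stopifnot(all(start >= 0), all(start < end), all(strand %in% c("+", "-")))
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   feature_type = as.character(feature_type),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

.ann_to_granges <- function(records) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$seq_id,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  extras <- setdiff(names(records), c("seq_id", "start", "end", "strand", "feature_type"))
  GenomicRanges::mcols(gr)$type <- records$feature_type
  for (nm in extras) GenomicRanges::mcols(gr)[[nm]] <- records[[nm]]
  gr
}

#' Write annotation records to GFF3, BED, or TSV
#'
#' GFF3 is emitted 1-based inclusive with extra columns as attributes;
#' BED is 0-based half-open; TSV mirrors the internal table exactly.
#'
#' @param records an annotation `data.frame` (see [annotation_table()]).
#' @param path output file path.
#' @param format one of `"GFF3"`, `"BED"`, `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, format = c("GFF3", "BED", "TSV")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown annotation format: ", format[1]))
  if (format == "TSV") {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gr <- .ann_to_granges(records)
  if (format == "GFF3") {
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    if (is.null(GenomicRanges::mcols(gr)$name) && !is.null(records$id))
      GenomicRanges::mcols(gr)$name <- records$id
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Read annotation records written by [write_annotations()]
#'
#' @param path input file.
#' @param format one of `"GFF3"`, `"BED"`, `"TSV"`.
#' @return annotation `data.frame` in internal (0-based half-open) coordinates.
#' @export
read_annotations <- function(path, format = c("GFF3", "BED", "TSV")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown annotation format: ", format[1]))
  if (format == "TSV") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    df$seq_id <- as.character(df$seq_id)
    return(df)
  }
  gr <- rtracklayer::import(path, format = if (format == "GFF3") "GFF3" else "BED")
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  if (format == "GFF3") {
    df$feature_type <- as.character(mc$type)
    for (nm in setdiff(names(mc), c("type", "source", "phase", "score")))
      df[[nm]] <- mc[[nm]]
  } else {
    df$feature_type <- "gene"
    if (!is.null(mc$name)) df$id <- mc$name
  }
  df
}
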