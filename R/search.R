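#' @importFrom utils data packageVersion
#' @importFrom stats as.dist
NULL

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' BLOSUM62 with gap open 11 / extend 1 by default, i.e. a gap of length L
#' costs `gap_open + L * gap_extend`. Returns the optimal score with one
#' traceback; spans are 1-based inclusive residue ranges, empty when the
#' optimal score is 0.
#'
#' @param query,subject amino-acid strings.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalty magnitudes.
#' @return list with `score`, `q_span`, `s_span` (integer length-2 vectors),
#'   `identity` (fraction of identical aligned columns).
#' @export
local_align <- function(query, subject, matrix = NULL,
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  if (is.null(matrix)) matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = FALSE)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, q_span = integer(0), s_span = integer(0), identity = NA_real_))
  }
  pq <- Biostrings::pattern(pa)
  ps <- Biostrings::subject(pa)
  qa <- strsplit(as.character(pq), "")[[1]]
  sa <- strsplit(as.character(ps), "")[[1]]
  list(score = sc,
       q_span = c(Biostrings::start(pq), Biostrings::end(pq)),
       s_span = c(Biostrings::start(ps), Biostrings::end(ps)),
       identity = mean(qa == sa))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a search space of `m * n` residues.
#' Defaults are the standard gapped BLOSUM62 (open 11 / extend 1) constants.
#'
#' @param score raw alignment score (>= 0).
#' @param m query length (aa).
#' @param n search-space length (aa).
#' @param lambda,K Karlin-Altschul statistics.
#' @return the expectation value.
#' @export
estimate_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(lambda <= 0) || any(K <= 0)) stop("lambda and K must be positive")
  stopifnot(all(score >= 0), all(m >= 1), all(n >= 1))
  K * m * n * exp(-lambda * score)
}

## integer-encode an aa string; residues outside the 20-letter alphabet
## (stops, X) map to NA so seeds and scores never cross them
.aa_encode <- function(s) {
  code <- match(utf8ToInt(s), utf8ToInt(paste(AA_ALPHABET20, collapse = "")))
  code
}

## substitution scores along a diagonal for encoded residues (NA -> -4,
## matching the BLOSUM62 minimum so defects terminate segments)
.diag_scores <- function(m20, qv, sv) {
  sc <- rep(-4, length(qv))
  ok <- !is.na(qv) & !is.na(sv)
  sc[ok] <- m20[cbind(qv[ok], sv[ok])]
  sc
}

## best-scoring contiguous segment (Kadane via cumulative sums); returns
## c(score, start, end) 1-based in the local vector, or NULL if all <= 0
.best_segment <- function(sc) {
  cs <- cumsum(sc)
  prev <- c(0, head(cs, -1L))
  run_min <- cummin(prev)
  gain <- cs - run_min
  best <- which.max(gain)
  if (gain[best] <= 0) return(NULL)
  start <- max(which(prev[seq_len(best)] == run_min[best]))
  c(gain[best], start, best)
}

## map an aa interval [p1,p2) (0-based, frame-local) to genomic 0-based
## half-open coordinates; L = chromosome length, frame in +-1..3
.frame_to_genomic <- function(frame, p1, p2, L) {
  f <- abs(frame)
  if (frame > 0) c((f - 1L) + 3L * p1, (f - 1L) + 3L * p2)
  else c(L - ((f - 1L) + 3L * p2), L - ((f - 1L) + 3L * p1))
}

#' Translated six-frame homology scan of a genome
#'
#' A TBLASTN-style heuristic: every chromosome is translated in six frames,
#' exact amino-acid k-mer seeds (k = 4) against the query set are grouped by
#' diagonal, and each seeded diagonal is scored by its best ungapped BLOSUM62
#' segment. Segment scores are converted to Karlin-Altschul E-values over a
#' search space of the total translated genome length (both strands) times
#' the query length, and hits above `max_evalue` are discarded.
#'
#' Reported scores are ungapped segment scores, so they never exceed the
#' exact Smith-Waterman optimum for the same sequence pair.
#'
#' @param queries named character vector of protein queries.
#' @param genome named character vector of chromosome sequences.
#' @param max_evalue E-value cutoff (default 1e-10).
#' @param lambda,K Karlin-Altschul statistics.
#' @param k seed word size (aa).
#' @return data.frame of HSPs: `query_id, chrom, q_start, q_end` (aa,
#'   0-based half-open), `g_start, g_end` (bp, 0-based half-open), `strand`,
#'   `frame`, `score`, `evalue`, `identity`, sorted by (chrom, g_start,
#'   query_id).
#' @export
scan_genome <- function(queries, genome, max_evalue = 1e-10,
                        lambda = 0.267, K = 0.041, k = 4L) {
  if (length(queries) == 0L) stop("no queries")
  if (length(genome) == 0L) stop("no genome records")
  m20 <- .blosum62()[AA_ALPHABET20, AA_ALPHABET20]
  qenc <- lapply(queries, .aa_encode)
  qlen <- vapply(qenc, length, integer(1))
  n_space <- sum(2 * floor(nchar(genome) / 3))

  ## query k-mer index: numeric code -> (query index, 0-based offset)
  base <- 20L
  qk_code <- integer(0); qk_qi <- integer(0); qk_off <- integer(0)
  for (qi in seq_along(qenc)) {
    v <- qenc[[qi]] - 1L
    n <- length(v)
    if (n < k) next
    idx <- seq_len(n - k + 1L)
    code <- v[idx]
    for (j in 1L:(k - 1L)) code <- code * base + v[idx + j]
    keep <- !is.na(code)
    qk_code <- c(qk_code, code[keep])
    qk_qi <- c(qk_qi, rep.int(qi, sum(keep)))
    qk_off <- c(qk_off, idx[keep] - 1L)
  }
  qk_order <- order(qk_code)
  qk_code <- qk_code[qk_order]; qk_qi <- qk_qi[qk_order]; qk_off <- qk_off[qk_order]
  uniq_codes <- unique(qk_code)
  code_first <- match(uniq_codes, qk_code)
  code_last <- c(code_first[-1L] - 1L, length(qk_code))

  hsps <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    frames <- six_frame_translate(genome[[chrom]])
    for (fr_name in names(frames)) {
      aa <- frames[[fr_name]]
      n <- nchar(aa)
      if (n < k) next
      frame <- as.integer(fr_name)
      senc <- .aa_encode(aa)
      v <- senc - 1L
      idx <- seq_len(n - k + 1L)
      code <- v[idx]
      for (j in 1L:(k - 1L)) code <- code * base + v[idx + j]
      hit_pos <- which(!is.na(code) & (code %in% uniq_codes))
      if (length(hit_pos) == 0L) next
      ci <- match(code[hit_pos], uniq_codes)
      ## expand to (query, qoff, soff) seed triples
      reps <- code_last[ci] - code_first[ci] + 1L
      soff <- rep.int(hit_pos - 1L, reps)
      take <- sequence(reps, from = code_first[ci])
      qi <- qk_qi[take]; qoff <- qk_off[take]
      diag <- soff - qoff
      key <- paste(qi, diag)
      for (grp in split(seq_along(key), key)) {
        qi0 <- qi[grp[1L]]; d <- diag[grp[1L]]
        qv <- qenc[[qi0]]
        ## diagonal window: whole query projected on the subject
        s1 <- max(0L, d)               # 0-based subject start of overlap
        s2 <- min(n, d + qlen[qi0])    # 0-based exclusive end
        if (s2 - s1 < k) next
        qv_loc <- qv[(s1 - d + 1L):(s2 - d)]
        sv_loc <- senc[(s1 + 1L):s2]
        seg <- .best_segment(.diag_scores(m20, qv_loc, sv_loc))
        if (is.null(seg)) next
        score <- seg[1L]
        ev <- estimate_evalue(score, qlen[qi0], n_space, lambda, K)
        if (ev > max_evalue) next
        p1 <- s1 + seg[2L] - 1L        # 0-based frame-local aa start
        p2 <- s1 + seg[3L]             # exclusive
        g <- .frame_to_genomic(frame, p1, p2, L)
        qspan <- c(p1 - d, p2 - d)
        ident <- mean(qv[(qspan[1L] + 1L):qspan[2L]] ==
                        senc[(p1 + 1L):p2], na.rm = TRUE)
        hsps[[length(hsps) + 1L]] <- data.frame(
          query_id = names(queries)[qi0], chrom = chrom,
          q_start = qspan[1L], q_end = qspan[2L],
          g_start = g[1L], g_end = g[2L],
          strand = if (frame > 0) "+" else "-", frame = frame,
          score = score, evalue = ev, identity = ident,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hsps) == 0L) {
    return(data.frame(query_id = character(0), chrom = character(0),
                      q_start = integer(0), q_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      strand = character(0), frame = integer(0),
                      score = numeric(0), evalue = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hsps)
  ## identical diagonal segments can be seeded by several k-mers
  out <- out[!duplicated(out[c("query_id", "chrom", "frame", "g_start", "g_end")]), ]
  out <- out[order(out$chrom, out$g_start, out$query_id), ]
  rownames(out) <- NULL
  out
}

#' Chain HSPs into candidate loci and pick the best query per locus
#'
#' HSPs on the same chromosome and strand whose genomic gap is below
#' `max_chain_gap` are single-linkage chained into one locus; loci from
#' different queries that end up overlapping are merged. The representative
#' query follows the best-hit rule: lowest E-value, then longest aligned
#' length, then lexicographic query id.
#'
#' @param hsps HSP data.frame from [scan_genome()].
#' @param max_chain_gap maximum genomic gap (bp) bridged within a locus.
#' @return list of candidate loci; each has `chrom`, `strand`, `g_start`,
#'   `g_end`, `best_query`, `frames_used`, and the member `hsps`.
#' @export
chain_and_select <- function(hsps, max_chain_gap = 5000L) {
  if (is.null(hsps) || nrow(hsps) == 0L) return(list())
  loci <- list()
  for (key in unique(paste(hsps$chrom, hsps$strand))) {
    sub <- hsps[paste(hsps$chrom, hsps$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$g_start, sub$g_end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      sub$g_start[-1L] - cummax(sub$g_end)[-nrow(sub)] >= max_chain_gap)))
    for (g in split(seq_len(nrow(sub)), grp)) {
      mem <- sub[g, , drop = FALSE]
      alen <- mem$q_end - mem$q_start
      ord <- order(mem$evalue, -alen, mem$query_id)
      loci[[length(loci) + 1L]] <- list(
        chrom = mem$chrom[1L], strand = mem$strand[1L],
        g_start = min(mem$g_start), g_end = max(mem$g_end),
        best_query = mem$query_id[ord[1L]],
        frames_used = sort(unique(mem$frame)),
        hsps = mem)
    }
  }
  ord <- order(vapply(loci, `[[`, character(1), "chrom"),
               vapply(loci, `[[`, numeric(1), "g_start"))
  loci[ord]
}
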