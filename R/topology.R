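## Kyte-Doolittle hydropathy and N-glycosylation sequon annotation.

KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Predict transmembrane segments from windowed hydropathy
#'
#' Kyte-Doolittle hydropathy is averaged over a sliding window (centred;
#' truncated at the peptide ends). Maximal runs of residues whose averaged
#' hydropathy exceeds `threshold` become candidate segments; segments
#' separated by fewer than `min_sep` residues are merged, and segments
#' shorter than `min_len` residues are dropped. Seven such segments is the
#' canonical GPCR architecture; `topology_ok` flags counts in [6, 8].
#'
#' @param peptide amino-acid string, at least `window` residues.
#' @param window averaging window (odd; default 19).
#' @param threshold hydropathy cutoff (default 1.6).
#' @param min_sep merge segments closer than this many residues.
#' @param min_len minimum retained segment length (aa).
#' @return list with `profile` (per-residue averaged hydropathy),
#'   `segments` (matrix of 1-based start/end), `tm_count`, `topology_ok`.
#' @export
predict_tm <- function(peptide, window = 19L, threshold = 1.6,
                       min_sep = 3L, min_len = 15L) {
  n <- nchar(peptide)
  if (n < window) stop("peptide shorter than hydropathy window")
  aa <- strsplit(peptide, "")[[1]]
  h <- unname(KYTE_DOOLITTLE[aa])
  h[is.na(h)] <- 0  # X/* and unknowns treated as neutral
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(h))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  profile <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  above <- profile > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 1L) {
    merged <- seg[1L, , drop = FALSE]
    for (i in 2L:nrow(seg)) {
      if (seg[i, 1L] - merged[nrow(merged), 2L] - 1L < min_sep) {
        merged[nrow(merged), 2L] <- seg[i, 2L]
      } else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  if (nrow(seg)) seg <- seg[seg[, 2L] - seg[, 1L] + 1L >= min_len, , drop = FALSE]
  colnames(seg) <- c("start", "end")
  list(profile = profile, segments = seg, tm_count = nrow(seg),
       topology_ok = nrow(seg) >= 6L && nrow(seg) <= 8L)
}

#' Find N-glycosylation sequons (N-X-S/T, X != P)
#'
#' @param peptide amino-acid string.
#' @return integer vector of 0-based positions of the asparagine of every
#'   (possibly overlapping) sequon, strictly increasing.
#' @export
find_sequons <- function(peptide) {
  if (!nzchar(peptide)) stop("empty peptide")
  m <- gregexpr("N(?=[^P][ST])", peptide, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Annotate a called gene table with TM counts and sequons
#'
#' Appends `tm_count`, `topology_ok`, and `sequons` (comma-separated
#' 0-based positions) columns. Peptides shorter than the hydropathy window
#' get `tm_count = NA`. With `require_7tm = TRUE`, genes whose TM count
#' falls outside [6, 8] are dropped (annotation is otherwise non-filtering).
#'
#' @param genes gene table from [call_genes()].
#' @param window,threshold see [predict_tm()].
#' @param require_7tm strict mode switch.
#' @return the annotated (possibly filtered) gene table.
#' @export
annotate_topology <- function(genes, window = 19L, threshold = 1.6,
                              require_7tm = FALSE) {
  if (nrow(genes) == 0L) {
    genes$tm_count <- integer(0); genes$topology_ok <- logical(0)
    genes$sequons <- character(0)
    return(genes)
  }
  tm <- lapply(genes$peptide, function(p) {
    p <- gsub("[*]", "", p)
    if (nchar(p) < window) return(list(tm_count = NA_integer_, topology_ok = FALSE))
    predict_tm(p, window = window, threshold = threshold)
  })
  genes$tm_count <- vapply(tm, function(x) as.integer(x$tm_count), integer(1))
  genes$topology_ok <- vapply(tm, function(x) isTRUE(x$topology_ok), logical(1))
  genes$sequons <- vapply(genes$peptide, function(p) {
    p <- gsub("[*]", "", p)
    if (!nzchar(p)) return("")
    paste(find_sequons(p), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  if (require_7tm) genes <- genes[genes$topology_ok %in% TRUE, ]
  genes
}
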