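## ZOOPS (zero-or-one occurrence per sequence) EM motif discovery on
## protein sequences, MEME-style: widths 5-50, top-k motifs by masking.

## run expr with a private RNG stream so motif discovery is deterministic
## under its seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## encode peptides to integer vectors; 1..20 residues, 21 = masked/other
.pep_encode <- function(s) {
  v <- match(strsplit(s, "")[[1]], AA_ALPHABET20)
  v[is.na(v)] <- 21L
  v
}

## window log-odds scores for one encoded sequence under a 21 x w log-odds
## matrix (row 21 is zero: masked positions score as background)
.window_scores <- function(a, lo, w) {
  m <- length(a) - w + 1L
  if (m < 1L) return(numeric(0))
  s <- numeric(m)
  for (k in seq_len(w)) s <- s + lo[a[k:(k + m - 1L)], k]
  s
}

## offsets whose window contains a masked position are invalid site starts
.valid_offsets <- function(a, w) {
  m <- length(a) - w + 1L
  if (m < 1L) return(logical(0))
  bad <- a == 21L
  cs <- c(0L, cumsum(bad))
  (cs[(1:m) + w] - cs[1:m]) == 0L
}

.em_single <- function(enc, w, pwm0, gamma0, bg, max_iter, tol, pseudocount) {
  pwm <- pwm0
  gamma <- gamma0
  lbg <- log(bg)
  n <- length(enc)
  valid <- lapply(enc, .valid_offsets, w = w)
  ## residue-at-offset index per sequence: key (k-1)*21 + residue for a
  ## single weighted rowsum in the M-step
  keys <- lapply(enc, function(a) {
    m <- length(a) - w + 1L
    if (m < 1L) return(integer(0))
    idx <- outer(seq_len(m), 0:(w - 1L), "+")
    as.integer(a[idx]) + 21L * rep(0:(w - 1L), each = m)
  })
  ll_trace <- numeric(0)
  z_list <- NULL
  for (it in seq_len(max_iter)) {
    lo <- rbind(log(pwm) - lbg, rep(0, w))
    ll <- 0
    gamma_num <- 0
    z_list <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- .window_scores(enc[[i]], lo, w)
      sc[!valid[[i]]] <- -Inf
      m_i <- sum(valid[[i]])
      if (m_i == 0L) {
        ll <- ll + log(1 - gamma)
        z_list[[i]] <- numeric(length(sc))
        next
      }
      mx <- max(sc)
      if (mx < -500) {  # motif nowhere near: site posteriors vanish
        z_list[[i]] <- numeric(length(sc))
        ll <- ll + log(1 - gamma)
        next
      }
      wgt <- exp(sc - mx)
      wgt[!is.finite(wgt)] <- 0
      z <- (gamma / m_i) * wgt
      tot <- (1 - gamma) * exp(-mx) + sum(z)
      z <- z / tot
      z_list[[i]] <- z
      ll <- ll + mx + log((1 - gamma) * exp(-mx) + (gamma / m_i) * sum(wgt))
      gamma_num <- gamma_num + sum(z)
    }
    ll_trace <- c(ll_trace, ll)
    ## M-step: one weighted rowsum over all (sequence, offset, column) cells
    zv <- unlist(lapply(seq_len(n), function(i)
      rep.int(z_list[[i]], w)), use.names = FALSE)
    kv <- unlist(keys, use.names = FALSE)
    counts <- matrix(0, nrow = 21L, ncol = w)
    if (length(zv)) {
      gs <- rowsum(zv, kv)
      key <- as.integer(rownames(gs))
      counts[cbind((key - 1L) %% 21L + 1L, (key - 1L) %/% 21L + 1L)] <- gs[, 1L]
    }
    counts <- counts[1:20, , drop = FALSE] + pseudocount * bg
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    gamma <- min(max(gamma_num / n, 1e-4), 1 - 1e-4)
    if (it > 1L && ll_trace[it] - ll_trace[it - 1L] < tol) break
  }
  list(pwm = pwm, gamma = gamma, ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, z = z_list, valid = valid)
}

.pwm_from_seed_word <- function(word_enc, bg, conc = 0.7) {
  w <- length(word_enc)
  pwm <- matrix(rep(bg * (1 - conc), w), nrow = 20L)
  for (k in seq_len(w)) {
    a <- word_enc[k]
    if (a <= 20L) pwm[a, k] <- pwm[a, k] + conc
    else pwm[, k] <- bg
  }
  sweep(pwm, 2L, colSums(pwm), "/")
}

#' Fit a ZOOPS motif model of fixed width by expectation-maximization
#'
#' The ZOOPS model assumes each sequence carries zero or one motif
#' occurrence over a 0-order background. Starting points are chosen
#' MEME-style from the data: the most frequently repeated words of the
#' requested width plus randomly drawn words; each start is run to
#' convergence and the best fit by log-likelihood ratio is returned.
#' Fully deterministic for a given `seed`.
#'
#' @param sequences character vector of peptides (named or not). Sequences
#'   shorter than `width` are skipped with a warning.
#' @param width motif width, in `[5, 50]`.
#' @param seed integer seed for the restart draws.
#' @param max_iter,tol EM stopping rule (log-likelihood improvement).
#' @param n_starts number of EM starting points.
#' @param pseudocount Dirichlet-style pseudocount weight on the PWM.
#' @param background optional 20-vector of residue frequencies; default
#'   empirical frequencies of the input.
#' @return a motif model: list with `width`, `pwm` (20 x width, columns sum
#'   to 1), `background`, `sites` (data.frame seq, offset 0-based),
#'   `log_likelihood_ratio`, `ll_trace`, `consensus`, `ic_profile`.
#' @export
em_zoops <- function(sequences, width, seed = 1L, max_iter = 100L,
                     tol = 1e-6, n_starts = 5L, pseudocount = 0.01,
                     background = NULL) {
  if (width < 5L || width > 50L) stop("width must be in [5, 50]")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  short <- nchar(sequences) < width
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than width skipped")
    sequences <- sequences[!short]
  }
  if (length(sequences) < 2L) stop("need at least 2 sequences of length >= width")
  enc <- lapply(sequences, .pep_encode)
  all_res <- unlist(enc)
  all_res <- all_res[all_res <= 20L]
  bg <- if (is.null(background)) {
    tb <- tabulate(all_res, nbins = 20L) + 1
    tb / sum(tb)
  } else background / sum(background)

  ## candidate seed words: most repeated exact words, then random draws
  words <- unlist(lapply(enc, function(a) {
    ok <- .valid_offsets(a, width)
    if (!any(ok)) return(character(0))
    off <- which(ok)
    vapply(off, function(j) paste(a[j:(j + width - 1L)], collapse = "."),
           character(1))
  }), use.names = FALSE)
  if (length(words) == 0L) stop("no windows available at this width")
  tb <- sort(table(words), decreasing = TRUE)
  n_top <- min(max(1L, n_starts - 2L), length(tb))
  seed_words <- names(tb)[seq_len(n_top)]
  fits <- .with_seed(seed, {
    extra <- n_starts - n_top
    if (extra > 0L)
      seed_words <- c(seed_words, sample(words, extra, replace = TRUE))
    lapply(seed_words, function(wd) {
      we <- as.integer(strsplit(wd, ".", fixed = TRUE)[[1]])
      .em_single(enc, width, .pwm_from_seed_word(we, bg), 0.5, bg,
                 max_iter, tol, pseudocount)
    })
  })
  lls <- vapply(fits, `[[`, numeric(1), "ll")
  best <- fits[[which.max(lls)]]

  sites <- do.call(rbind, lapply(seq_along(enc), function(i) {
    z <- best$z[[i]]
    if (length(z) == 0L) return(NULL)
    j <- which.max(z)
    if (z[j] >= 0.5)
      data.frame(seq_id = names(sequences)[i], offset = j - 1L,
                 posterior = z[j], stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(sites))
    sites <- data.frame(seq_id = character(0), offset = integer(0),
                        posterior = numeric(0), stringsAsFactors = FALSE)
  pwm <- best$pwm
  rownames(pwm) <- AA_ALPHABET20
  ic <- apply(pwm, 2L, function(p) {
    p <- p[p > 0]
    max(0, min(log2(20) + sum(p * log2(p)), log2(20)))
  })
  structure(list(width = width, pwm = pwm, background = bg, sites = sites,
                 gamma = best$gamma,
                 log_likelihood_ratio = best$ll,
                 ll_trace = best$ll_trace,
                 consensus = paste(AA_ALPHABET20[apply(pwm, 2L, which.max)],
                                   collapse = ""),
                 ic_profile = as.numeric(ic)),
            class = "or_motif")
}

#' @export
print.or_motif <- function(x, ...) {
  cat(sprintf("ZOOPS motif  width %d  consensus %s\n  LLR %.2f  sites %d  mean IC %.2f bits\n",
              x$width, x$consensus, x$log_likelihood_ratio,
              nrow(x$sites), mean(x$ic_profile)))
  invisible(x)
}

#' Discover the top conserved motifs by iterative masking
#'
#' For each motif rank, [em_zoops()] is run over a width grid and the best
#' model is kept by a length-penalized log-likelihood ratio
#' (`LLR - 0.5 * 19 * width * log(n)`); its sites are then masked with a
#' neutral symbol (scored as background) and the next motif is sought.
#' Mirrors the conventional protein-motif scan on OR repertoires: widths
#' within 5-50 and the five best-supported motifs retained.
#'
#' @param sequences character vector of peptides.
#' @param n_motifs number of motifs to report (default 5).
#' @param width_grid widths to scan (subset of 5..50).
#' @param seed integer seed.
#' @param ... passed to [em_zoops()].
#' @return list of motif models ordered by decreasing penalized score.
#' @export
discover_top_motifs <- function(sequences, n_motifs = 5L,
                                width_grid = c(8L, 10L, 12L, 15L, 20L, 30L, 50L),
                                seed = 1L, ...) {
  if (n_motifs < 1L) stop("n_motifs must be >= 1")
  stopifnot(all(width_grid >= 5L), all(width_grid <= 50L))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  work <- sequences
  out <- list()
  for (rank in seq_len(n_motifs)) {
    usable <- sum(nchar(work) >= min(width_grid))
    if (usable < 2L) break
    cand <- list(); score <- numeric(0)
    for (w in width_grid) {
      if (sum(nchar(work) >= w) < 2L) next
      fit <- suppressWarnings(
        em_zoops(work, width = w, seed = seed + 1000L * rank + w, ...))
      cand[[length(cand) + 1L]] <- fit
      score <- c(score, fit$log_likelihood_ratio -
                   0.5 * 19 * w * log(length(work)))
    }
    if (length(cand) == 0L) break
    best <- cand[[which.max(score)]]
    best$penalized_llr <- max(score)
    if (nrow(best$sites) == 0L) break
    out[[rank]] <- best
    ## mask the claimed sites so later motifs cannot reuse them
    for (r in seq_len(nrow(best$sites))) {
      id <- best$sites$seq_id[r]; off <- best$sites$offset[r]
      substr(work[[id]], off + 1L, off + best$width) <-
        paste(rep("x", best$width), collapse = "")
    }
  }
  ## ranks follow the width-penalized score used for selection, so long
  ## widths cannot outrank sharper short motifs on raw likelihood alone
  out[order(-vapply(out, `[[`, numeric(1), "penalized_llr"))]
}
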