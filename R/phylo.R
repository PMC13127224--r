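## Distance-based OR group classification: pairwise alignment distances,
## neighbor-joining trees, nearest-reference / tree-clade group assignment,
## and group expansion detection.

OR_GROUPS <- c("beta", "gamma", "delta", "epsilon", "zeta", "eta", "kappa")
OR_TYPE <- c(beta = "I", gamma = "I", delta = "I", epsilon = "I",
             zeta = "I", eta = "II", kappa = "II",
             theta = "non-OR", lambda = "non-OR")

#' Pairwise alignment distance matrix for peptides
#'
#' For every pair, a global affine-gap alignment (BLOSUM62, open 11 /
#' extend 1) is computed and the distance is `1 - identities / aligned
#' columns` (pairwise alignments have no gap-gap columns). Symmetric with
#' a zero diagonal by construction.
#'
#' @param peptides named character vector (>= 2 sequences).
#' @param gap_open,gap_extend gap penalty magnitudes.
#' @return a symmetric numeric matrix with `labels` as dimnames.
#' @export
distance_matrix <- function(peptides, gap_open = 11, gap_extend = 1) {
  n <- length(peptides)
  if (n < 2L) stop("need at least 2 peptides")
  if (is.null(names(peptides)))
    names(peptides) <- sprintf("pep%03d", seq_len(n))
  mat <- .blosum62()
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  set <- Biostrings::AAStringSet(gsub("[*]", "", peptides))
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(
      set[rep(i, n - i)], set[(i + 1L):n],
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    pid <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - pid
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion agglomeration, Saitou-Nei branch
#' lengths) with negative branch lengths clamped to zero. Exact on
#' additive distance matrices.
#'
#' @param dm symmetric distance matrix with labels (>= 3 taxa).
#' @return an [ape::phylo] tree; serialize with [tree_newick()].
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  stopifnot(isSymmetric(unname(dm)), all(is.finite(dm)))
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Newick serialization of a tree
#' @param tree an `ape::phylo` object.
#' @return single newick string with branch lengths.
#' @export
tree_newick <- function(tree) {
  ape::write.tree(tree)
}

.group_from_header <- function(ids) {
  ## reference headers carry `|group=<label>`
  g <- sub(".*\\|group=([A-Za-z]+).*", "\\1", ids)
  g[!grepl("\\|group=", ids)] <- NA_character_
  tolower(g)
}

#' Assign OR genes to phylogenetic groups
#'
#' Default rule: each gene takes the group of its nearest labelled
#' reference under [distance_matrix()]. In `method = "tree"` a
#' neighbor-joining tree of genes plus references is built and each gene
#' takes the majority group of the smallest clade containing it and at
#' least one reference (ties fall back to the nearest reference). Groups
#' map to type I (beta, gamma, delta, epsilon, zeta) or type II (eta,
#' kappa); theta and lambda labels are accepted but reported as non-OR.
#'
#' @param genes named character vector of gene peptides.
#' @param references named character vector of reference peptides; group
#'   labels either in a `groups` vector or embedded in names as
#'   `id|group=<label>`.
#' @param groups optional character vector of labels parallel to
#'   `references`.
#' @param method `"nearest"` or `"tree"`.
#' @return data.frame: `gene_id`, `group`, `type`, `support` (distance to
#'   the nearest reference of the assigned group).
#' @export
assign_groups <- function(genes, references, groups = NULL,
                          method = c("nearest", "tree")) {
  method <- match.arg(method)
  if (length(references) == 0L) stop("no references")
  if (is.null(groups)) groups <- .group_from_header(names(references))
  if (anyNA(groups)) stop("reference without group label")
  bad <- setdiff(groups, names(OR_TYPE))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ","))
  ref_ids <- sprintf("ref_%04d", seq_along(references))
  gene_ids <- names(genes)
  all_pep <- c(setNames(genes, gene_ids), setNames(references, ref_ids))
  d <- distance_matrix(all_pep)
  dref <- d[gene_ids, ref_ids, drop = FALSE]

  nearest_group <- function(i) {
    dv <- dref[i, ]
    cand <- which(dv == min(dv))
    gs <- sort(unique(groups[cand]))
    gs[1L]  # full-precision tie -> alphabetical group
  }

  assigned <- character(length(gene_ids))
  if (method == "nearest") {
    assigned <- vapply(seq_along(gene_ids), nearest_group, character(1))
  } else {
    tr <- nj_tree(d)
    ntip <- length(tr$tip.label)
    is_ref <- tr$tip.label %in% ref_ids
    parent <- integer(ntip + tr$Nnode)
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    kids <- split(tr$edge[, 2L], tr$edge[, 1L])
    tips_under <- function(node) {
      if (node <= ntip) return(node)
      unlist(lapply(kids[[as.character(node)]], tips_under))
    }
    for (i in seq_along(gene_ids)) {
      tip <- match(gene_ids[i], tr$tip.label)
      node <- tip
      grp <- NA_character_
      repeat {
        node <- parent[node]
        if (node == 0L) break
        tips <- tips_under(node)
        refs_here <- tr$tip.label[tips[tips <= ntip & is_ref[tips]]]
        if (length(refs_here)) {
          gtab <- table(groups[match(refs_here, ref_ids)])
          top <- names(gtab)[gtab == max(gtab)]
          grp <- if (length(top) == 1L) top else nearest_group(i)
          break
        }
      }
      assigned[i] <- if (is.na(grp)) nearest_group(i) else grp
    }
  }
  support <- vapply(seq_along(gene_ids), function(i)
    min(dref[i, groups == assigned[i]]), numeric(1))
  data.frame(gene_id = gene_ids, group = assigned,
             type = unname(OR_TYPE[assigned]), support = support,
             stringsAsFactors = FALSE)
}

#' Detect group-specific repertoire expansion
#'
#' Fold change of the focal species' group counts over the mean count in
#' reference species (with a pseudo-count of 1); a group is flagged
#' expanded at `fold >= min_fold`.
#'
#' @param assignment output of [assign_groups()] (or any data.frame with a
#'   `group` column).
#' @param reference_counts named list / data.frame: per group, a vector of
#'   counts in reference species.
#' @param min_fold expansion threshold (default 2).
#' @return data.frame: `group`, `count`, `reference_mean`, `fold`,
#'   `expanded`.
#' @export
detect_expansion <- function(assignment, reference_counts, min_fold = 2) {
  stopifnot(nrow(assignment) > 0)
  groups <- sort(unique(c(assignment$group, names(reference_counts))))
  out <- do.call(rbind, lapply(groups, function(g) {
    cnt <- sum(assignment$group == g)
    refs <- reference_counts[[g]]
    rmean <- if (is.null(refs) || length(refs) == 0L) 0 else mean(refs)
    ## pseudo-count keeps the ratio finite for groups absent from the
    ## reference species
    fold <- cnt / max(rmean, 1)
    data.frame(group = g, count = cnt, reference_mean = rmean, fold = fold,
               expanded = fold >= min_fold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
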