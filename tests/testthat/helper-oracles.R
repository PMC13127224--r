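# Independent brute-force oracles used to cross-check the package's
# implementations. These share no code with the package internals.

# full O(mn) affine-gap Smith-Waterman, score only (Gotoh three-matrix DP);
# a gap of length L costs gap_open + L * gap_extend
sw_score_oracle <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa); n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)  # gap in query (horizontal)
  F <- matrix(-Inf, m + 1, n + 1)  # gap in subject (vertical)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# transitive closure of the pairwise "< max_gap apart on one chromosome"
# relation, as a partition label vector
closure_cluster_oracle <- function(chrom, start, end, max_gap = 1e6) {
  n <- length(start)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || chrom[i] != chrom[j]) next
      gap <- max(start[i], start[j]) - min(end[i], end[j])
      if (gap < max_gap && lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# position-by-position sequon scan, deliberately naive
sequon_oracle <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  n <- length(aa)
  out <- integer(0)
  if (n >= 3) for (i in 1:(n - 2)) {
    if (aa[i] == "N" && aa[i + 1] != "P" && aa[i + 2] %in% c("S", "T"))
      out <- c(out, i - 1L)
  }
  out
}

# leaf-to-leaf path distances of an ape::phylo computed from the edge
# matrix by accumulating distances to the root (no ape distance functions)
tree_path_dist_oracle <- function(tr) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  parent <- integer(nn); plen <- numeric(nn)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  plen[tr$edge[, 2]] <- tr$edge.length
  path_to_root <- function(v) {
    nodes <- v; d <- 0
    while (parent[v] != 0) {
      d <- c(d, d[length(d)] + plen[v])
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    list(nodes = nodes, d = d)
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tr$tip.label, tr$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    pi <- paths[[i]]; pj <- paths[[j]]
    anc <- intersect(pi$nodes, pj$nodes)[1]
    D[i, j] <- D[j, i] <- pi$d[match(anc, pi$nodes)] + pj$d[match(anc, pj$nodes)]
  }
  D
}

# random binary tree topology with positive branch lengths, plus its
# additive leaf distance matrix built by direct path summation
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.2, 2))
  D <- tree_path_dist_oracle(tr)
  list(tree = tr, D = D)
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a tiny genome with one planted CDS at a known position
plant_cds <- function(cds, chrom_len = 20000L, at = 7000L, strand = "+",
                      seed = 1L) {
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  ins <- if (strand == "+") cds else revcomp(cds)
  bg[(at + 1L):(at + nchar(ins))] <- strsplit(ins, "")[[1]]
  c(chr_t = paste(bg, collapse = ""))
}

blosum62_mat <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
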