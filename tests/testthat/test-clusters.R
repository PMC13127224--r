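mk_genes <- function(start, end = start + 1000, chrom = "chr1",
                     strand = "+", group = NULL) {
  df <- data.frame(id = sprintf("g%03d", seq_along(start)), chrom = chrom,
                   start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  df
}

test_that("genes within < 1 Mb chain into one cluster, strict at the boundary", {
  g <- mk_genes(c(0.10e6, 0.90e6, 2.50e6), end = c(0.10e6, 0.90e6, 2.50e6) + 1)
  cl <- assign_clusters(g)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_genes, c(2L, 1L))

  # an exactly 1,000,000 bp edge gap does NOT join
  g2 <- mk_genes(c(0, 2e6), end = c(1e6, 2e6 + 1000))
  expect_equal(nrow(assign_clusters(g2)), 2)
  g3 <- mk_genes(c(0, 2e6 - 1), end = c(1e6, 2e6 + 1000))
  expect_equal(nrow(assign_clusters(g3)), 1)
})

test_that("clustering equals the transitive-closure oracle and is shuffle-invariant", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(4:15, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- sample.int(6e6, n)
    g <- mk_genes(start, start + sample(500:1500, n), chrom = chrom)
    cl <- assign_clusters(g)
    oracle <- closure_cluster_oracle(g$chrom, g$start, g$end)
    expect_equal(nrow(cl), length(unique(oracle)))
    member_of <- setNames(rep(seq_len(nrow(cl)),
                              lengths(strsplit(cl$members, ","))),
                          unlist(strsplit(cl$members, ",")))
    # same partition: oracle classes and cluster ids are in bijection
    expect_equal(length(unique(paste(oracle, member_of[g$id]))),
                 length(unique(oracle)))

    shuf <- g[sample.int(n), ]
    cl2 <- assign_clusters(shuf)
    expect_equal(cl2$members, cl$members)
  }
})

test_that("orientation consistency and the tandem flag follow the majority strand", {
  expect_equal(orientation_consistency(c("+", "+", "+", "+")),
               list(orientation_fraction = 1, tandem_flag = TRUE))
  expect_equal(orientation_consistency(c("+", "+", "-", "-")),
               list(orientation_fraction = 0.5, tandem_flag = FALSE))
  expect_equal(orientation_consistency("+"),
               list(orientation_fraction = 1, tandem_flag = FALSE))
})

test_that("a planted tandem array is recovered as one tandem cluster", {
  starts <- seq(1e5, by = 2e4, length.out = 10)
  g <- mk_genes(starts, starts + 930, strand = "+",
                group = rep("delta", 10))
  cl <- assign_clusters(g)
  expect_equal(nrow(cl), 1)
  expect_true(cl$tandem_flag)
  expect_equal(cl$orientation_fraction, 1)
  expect_equal(cl$family_composition, "delta:10")
})

test_that("repertoire summary reproduces printed-style percentages", {
  g <- rbind(mk_genes(seq(1, by = 2000, length.out = 289)),
             mk_genes(seq(1, by = 2000, length.out = 10), chrom = "chr2"),
             mk_genes(seq(1, by = 2000, length.out = 19), chrom = "chr3"))
  g$status <- rep(c("functional", "partial", "pseudogene"), c(289, 10, 19))
  s <- summarize_repertoire(g)
  expect_equal(s$species$total, 318)
  expect_equal(s$species$functional_pct, 90.88)
  expect_equal(s$species$partial_pct, 3.14)
  expect_equal(s$species$pseudogene_pct, 5.97)
  expect_equal(sum(s$per_chromosome$total), s$species$total)
  expect_equal(s$per_chromosome$functional + s$per_chromosome$partial +
                 s$per_chromosome$pseudogene, s$per_chromosome$total)

  g$status[1] <- "mystery"
  expect_error(summarize_repertoire(g), "unknown status")

  expect_warning(s0 <- summarize_repertoire(mk_genes(1)[0, ]), "empty")
  expect_equal(s0$species$total, 0)
  expect_equal(s0$species$functional_pct, 0)
})

test_that("pre-tabulated counts summarize identically to gene tables", {
  s <- summarize_repertoire(counts = c(functional = 289, partial = 10,
                                       pseudogene = 19))
  expect_equal(unlist(s$species[c("functional_pct", "partial_pct",
                                  "pseudogene_pct", "total")],
                      use.names = FALSE), c(90.88, 3.14, 5.97, 318))
})
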