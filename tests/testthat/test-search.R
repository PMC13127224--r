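test_that("local alignment reproduces hand-computed BLOSUM62 scores", {
  r <- local_align("MAYDRYVAIC", "MAYDRYVAIC")
  # sum of diagonal entries M5 A4 Y7 D6 R5 Y7 V4 A4 I4 C9
  expect_equal(r$score, 55)
  expect_equal(r$q_span, c(1L, 10L))
  expect_equal(r$identity, 1)

  # tryptophan against a poly-A run has no positive-scoring pair
  r0 <- local_align("WWWW", "AAAAAA")
  expect_equal(r0$score, 0)
  expect_length(r0$q_span, 0)

  expect_error(local_align("", "MK"), "empty")
})

test_that("local alignment matches the exhaustive DP oracle on random pairs", {
  set.seed(101)
  mat <- blosum62_mat()
  for (i in 1:40) {
    q <- random_peptide(sample(5:12, 1))
    s <- random_peptide(sample(5:12, 1))
    expect_equal(local_align(q, s)$score, sw_score_oracle(q, s, mat),
                 info = paste(q, s))
  }
})

test_that("Karlin-Altschul expectation follows E = K m n exp(-lambda S)", {
  # 0.041 * 300 * 10000 * exp(-0.267 * 40) = 2.829
  expect_equal(estimate_evalue(40, 300, 10000), 2.829, tolerance = 1e-3)
  expect_equal(estimate_evalue(0, 300, 10000), 0.041 * 300 * 10000)
  expect_lt(estimate_evalue(50, 300, 1e4), estimate_evalue(40, 300, 1e4))
  expect_error(estimate_evalue(10, 300, 1e4, lambda = -1), "positive")
})

test_that("the scan recovers a planted CDS on either strand with true coordinates", {
  t <- make_or_template("delta", seed = 3)
  for (strand in c("+", "-")) {
    genome <- plant_cds(t$cds, at = 6000L, strand = strand, seed = 5)
    h <- scan_genome(c(q = t$peptide), genome)
    expect_gt(nrow(h), 0)
    top <- h[which.min(h$evalue), ]
    expect_equal(top$strand, strand)
    expect_lt(top$g_start, 6000 + nchar(t$cds))
    expect_gt(top$g_end, 6000)
    expect_true(all(h$evalue <= 1e-10))
    expect_true(all((h$g_end - h$g_start) %% 3 == 0))
  }
})

test_that("HSP frame, strand and coordinates are mutually consistent", {
  t <- make_or_template("zeta", seed = 9)
  genome <- plant_cds(t$cds, at = 3000L, strand = "-", seed = 8)
  h <- scan_genome(c(q = t$peptide), genome)
  frames <- six_frame_translate(genome[[1]])
  L <- nchar(genome[[1]])
  for (i in seq_len(nrow(h))) {
    f <- h$frame[i]
    # recover the frame-local aa span from genomic coordinates
    p1 <- if (f > 0) (h$g_start[i] - (f - 1)) / 3 else
      (L - h$g_end[i] - (abs(f) - 1)) / 3
    aa_len <- (h$g_end[i] - h$g_start[i]) / 3
    sub <- substr(frames[[sprintf("%+d", f)]], p1 + 1, p1 + aa_len)
    qsub <- substr(t$peptide, h$q_start[i] + 1, h$q_end[i])
    expect_equal(nchar(sub), nchar(qsub))
    expect_equal(mean(strsplit(sub, "")[[1]] == strsplit(qsub, "")[[1]]),
                 h$identity[i], tolerance = 1e-9)
  }
})

test_that("random background yields no hits at the stringent threshold", {
  set.seed(77)
  bg <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
              collapse = "")
  t <- make_or_template("eta", seed = 2)
  h <- scan_genome(c(q = t$peptide), c(chrB = bg))
  expect_equal(nrow(h), 0)
})

test_that("scanned scores never exceed the exact local optimum on planted genes", {
  t <- make_or_template("gamma", seed = 13)
  genome <- plant_cds(t$cds, at = 5000L, seed = 21)
  h <- scan_genome(c(q = t$peptide), genome)
  top <- h[which.min(h$evalue), ]
  frames <- six_frame_translate(genome[[1]])
  subj <- substr(frames[[sprintf("%+d", top$frame)]],
                 (top$g_start - (top$frame - 1)) / 3 + 1,
                 (top$g_start - (top$frame - 1)) / 3 + (top$g_end - top$g_start) / 3)
  exact <- local_align(t$peptide, subj)$score
  expect_lte(top$score, exact)
  expect_equal(top$score, exact)  # substitution-free plant: the two agree
})

test_that("chaining groups nearby HSPs and picks the best query", {
  h <- data.frame(query_id = c("qa", "qa"), chrom = "chr1",
                  q_start = c(0L, 120L), q_end = c(100L, 250L),
                  g_start = c(1000L, 4300L), g_end = c(1300L, 4690L),
                  strand = "+", frame = 1L, score = c(200, 210),
                  evalue = c(1e-30, 1e-32), identity = 0.9)
  loci <- chain_and_select(h, max_chain_gap = 5000L)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$g_start, 1000L)
  expect_equal(loci[[1]]$g_end, 4690L)

  loci2 <- chain_and_select(h, max_chain_gap = 2000L)
  expect_length(loci2, 2)

  # equal E-value: the longer aligned query wins
  h2 <- data.frame(query_id = c("q_short", "q_long"), chrom = "chr1",
                   q_start = 0L, q_end = c(250L, 300L),
                   g_start = 100L, g_end = c(850L, 1000L),
                   strand = "+", frame = 1L, score = 500,
                   evalue = 1e-50, identity = 0.9)
  expect_equal(chain_and_select(h2)[[1]]$best_query, "q_long")
  expect_length(chain_and_select(h2[0, ]), 0)
})

test_that("chaining equals the transitive closure of the gap relation", {
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    gs <- sort(sample.int(50000L, n))
    h <- data.frame(query_id = sample(c("q1", "q2"), n, replace = TRUE),
                    chrom = "chr1", q_start = 0L, q_end = 100L,
                    g_start = gs, g_end = gs + sample(300:900, n),
                    strand = "+", frame = 1L, score = 300,
                    evalue = 1e-20, identity = 0.8)
    gap <- 3000L
    loci <- chain_and_select(h, max_chain_gap = gap)
    oracle <- closure_cluster_oracle(h$chrom, h$g_start, h$g_end, gap)
    expect_equal(length(loci), length(unique(oracle)))
    # each locus envelope covers exactly one oracle class
    env <- vapply(loci, function(l) {
      cls <- unique(oracle[h$g_start >= l$g_start & h$g_end <= l$g_end])
      length(cls) == 1L
    }, logical(1))
    expect_true(all(env))
  }
})
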