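# helper: scan a one-gene genome and return (locus, model, defects, status)
call_one <- function(cds, queries, at = 6000L, strand = "+", seed = 5,
                     chrom_len = 20000L, min_aa = 250L) {
  genome <- plant_cds(cds, chrom_len = chrom_len, at = at, strand = strand,
                      seed = seed)
  h <- scan_genome(queries, genome)
  loci <- chain_and_select(h)
  expect_gte(length(loci), 1)
  locus <- loci[[1]]
  model <- build_gene_model(locus, genome)
  model$defects <- detect_defects(locus, model)
  model$status <- classify_gene(model$defects, model$length_aa,
                                min_aa = min_aa)
  model
}

test_that("an intact planted gene is recovered with exact CDS coordinates", {
  t <- make_or_template("delta", seed = 4)
  q <- c(delta = t$peptide)
  m <- call_one(t$cds, q, at = 6000L)
  expect_equal(m$cds_start, 6000)
  expect_equal(m$cds_end, 6000 + nchar(t$cds))
  expect_equal(m$peptide, t$peptide)
  expect_length(m$defects, 0)
  expect_equal(m$status, "functional")

  m2 <- call_one(t$cds, q, at = 6000L, strand = "-")
  expect_equal(m2$cds_start, 6000)
  expect_equal(m2$cds_end, 6000 + nchar(t$cds))
  expect_equal(m2$strand, "-")
  expect_equal(m2$peptide, t$peptide)
})

test_that("a mutated start codon is reported as missing_start", {
  t <- make_or_template("delta", seed = 4)
  cds <- t$cds
  substr(cds, 1, 3) <- "CTG"
  m <- call_one(cds, c(delta = t$peptide), seed = 6)
  expect_true("missing_start" %in% m$defects ||
                m$status == "partial")  # an upstream in-frame ATG may rescue
})

test_that("a gene truncated by the contig edge lacks its stop", {
  t <- make_or_template("zeta", seed = 8)
  half <- substr(t$cds, 1, 3 * 280)  # no stop codon within the contig
  genome <- plant_cds(half, chrom_len = 7000L + 3 * 280, at = 7000L, seed = 9)
  genome[[1]] <- substr(genome[[1]], 1, 7000 + 3 * 280)
  h <- scan_genome(c(zeta = t$peptide), genome)
  locus <- chain_and_select(h)[[1]]
  m <- build_gene_model(locus, genome)
  expect_true("missing_stop" %in% m$defects)
  expect_equal(classify_gene(detect_defects(locus, m), m$length_aa), "partial")
})

test_that("a premature stop codon makes a pseudogene", {
  t <- make_or_template("delta", seed = 4)
  cds <- t$cds
  substr(cds, 3 * 100 + 1, 3 * 100 + 3) <- "TGA"  # codon 100 of ~310
  m <- call_one(cds, c(delta = t$peptide), seed = 7)
  expect_true("premature_stop" %in% m$defects)
  expect_equal(m$status, "pseudogene")
})

test_that("a single-nucleotide insertion makes a frameshift pseudogene", {
  t <- make_or_template("delta", seed = 4)
  cds <- paste0(substr(t$cds, 1, 450), "G", substr(t$cds, 451, nchar(t$cds)))
  m <- call_one(cds, c(delta = t$peptide), seed = 8)
  expect_true(any(c("frameshift", "premature_stop") %in% m$defects))
  expect_equal(m$status, "pseudogene")
})

test_that("an intact but short ORF is too_short and partial", {
  t <- make_or_template("delta", seed = 4)
  short_pep <- substr(t$peptide, 1, 200)
  short_cds <- paste0(substr(t$cds, 1, 600), "TAA")
  m <- call_one(short_cds, c(delta = short_pep), seed = 9)
  expect_true("too_short" %in% m$defects)
  expect_equal(m$status, "partial")
})

test_that("classification is total, deterministic, and defect-driven", {
  expect_equal(classify_gene(character(0), 310), "functional")
  expect_equal(classify_gene(c("premature_stop", "missing_start"), 120),
               "pseudogene")  # disruptive defect takes precedence
  expect_equal(classify_gene("missing_start", 280), "partial")
  expect_equal(classify_gene("frameshift", 300), "pseudogene")
  expect_equal(classify_gene(character(0), 250), "partial")  # strict > 250
  expect_equal(classify_gene(character(0), 251), "functional")

  all_defects <- c("premature_stop", "frameshift", "missing_start",
                   "missing_stop", "too_short")
  set.seed(11)
  for (i in 1:50) {
    d <- sample(all_defects, sample(0:5, 1))
    s <- classify_gene(d, sample(50:400, 1))
    expect_true(s %in% c("functional", "partial", "pseudogene"))
    if (any(d %in% c("premature_stop", "frameshift")))
      expect_equal(s, "pseudogene")
    else if (length(d)) expect_equal(s, "partial")
  }
})

test_that("verification separates OR-like peptides from decoys", {
  t <- make_or_template("gamma", seed = 5)
  queries <- c(gamma = t$peptide)
  decoys <- make_decoys(3, seed = 50)

  model <- list(peptide = t$peptide)
  expect_true(verify_candidate(model, queries, decoys))

  set.seed(12)
  mut <- mutate_peptide(t$peptide, 0.1)
  expect_true(verify_candidate(list(peptide = mut), queries, decoys))

  expect_false(verify_candidate(list(peptide = decoys[[1]]), queries, decoys))
  expect_error(verify_candidate(model, character(0)), "no queries")
})
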