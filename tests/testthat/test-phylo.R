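test_that("alignment distances behave on hand cases", {
  d <- distance_matrix(c(a = "MAYDRYVAIC", b = "MAYDRYVAIC"))
  expect_equal(d["a", "b"], 0)
  d2 <- distance_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(d2["a", "b"], 0.25)  # 3/4 identical columns, no gaps opened
  expect_error(distance_matrix(c(a = "MK")), "at least 2")
})

test_that("distance matrices are symmetric with a zero diagonal", {
  set.seed(31)
  peps <- setNames(replicate(5, random_peptide(sample(25:40, 1))),
                   paste0("p", 1:5))
  d <- distance_matrix(peps)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("neighbor joining recovers a known quartet exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  got <- tree_path_dist_oracle(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, D, tolerance = 1e-9)
  # AB|CD split: the path A-B never passes through C or D's edges
  expect_equal(got["A", "B"], 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(61)
  for (rep in 1:15) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(case$D)
    got <- tree_path_dist_oracle(tr)
    got <- got[rownames(case$D), colnames(case$D)]
    expect_equal(got, case$D, tolerance = 1e-8)
  }
})

test_that("three taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  got <- tree_path_dist_oracle(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(got, D, tolerance = 1e-9)
})

test_that("genes take the group and type of their nearest reference", {
  refs <- setNames(
    vapply(c("delta", "eta"), function(g)
      make_or_template(g, seed = 21)$peptide, character(1)),
    c("d1|group=delta", "e1|group=eta"))
  set.seed(14)
  gene_d <- mutate_peptide(refs[[1]], 0.05)
  ga <- assign_groups(c(gd = gene_d, ge = refs[[2]]), refs)
  expect_equal(ga$group, c("delta", "eta"))
  expect_equal(ga$type, c("I", "II"))
  expect_equal(ga$support[2], 0)
  expect_error(assign_groups(c(g = gene_d), character(0)), "no references")
})

test_that("the group-to-type mapping follows the two-clade OR classification", {
  expect_equal(unname(orscan:::OR_TYPE[c("beta", "gamma", "delta", "epsilon",
                                         "zeta")]), rep("I", 5))
  expect_equal(unname(orscan:::OR_TYPE[c("eta", "kappa")]), rep("II", 2))
  expect_equal(unname(orscan:::OR_TYPE[c("theta", "lambda")]),
               rep("non-OR", 2))
})

test_that("assignment is reference-order invariant and accurate at 10% divergence", {
  groups <- c("beta", "gamma", "delta", "epsilon", "zeta", "eta", "kappa")
  refs <- setNames(
    vapply(groups, function(g) make_or_template(g, seed = 33)$peptide,
           character(1)),
    sprintf("r_%s|group=%s", groups, groups))
  set.seed(91)
  genes <- unlist(lapply(groups, function(g) {
    setNames(vapply(1:3, function(i)
      mutate_peptide(refs[[sprintf("r_%s|group=%s", g, g)]], 0.10),
      character(1)), sprintf("%s_copy%d", g, 1:3))
  }))
  truth <- rep(groups, each = 3)
  ga <- assign_groups(genes, refs)
  expect_gte(mean(ga$group == truth), 0.95)

  perm <- sample(seq_along(refs))
  ga2 <- assign_groups(genes, refs[perm])
  expect_equal(ga2$group, ga$group)

  ga3 <- assign_groups(genes, refs, method = "tree")
  expect_gte(mean(ga3$group == truth), 0.95)
})

test_that("expansion detection flags only the amplified group", {
  a <- data.frame(group = rep(c("delta", "gamma"), c(50, 3)))
  ref <- list(delta = c(10, 10, 10), gamma = c(3, 3, 3))
  ex <- detect_expansion(a, ref)
  expect_equal(ex$fold[ex$group == "delta"], 5)
  expect_true(ex$expanded[ex$group == "delta"])
  expect_equal(ex$fold[ex$group == "gamma"], 1)
  expect_false(ex$expanded[ex$group == "gamma"])
})
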