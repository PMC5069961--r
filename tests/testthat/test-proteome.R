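test_that("peptide group means average observed values and propagate missingness", {
  tab <- pep_tbl(
    "p1", "g1", "s1", 10,
    "p1", "g1", "s2", NA,
    "p1", "g1", "s3", 14,
    "p2", "g1", "s1", NA,
    "p2", "g1", "s2", NA,
    "p3", "g1", "s1", 7
  )
  expect_equal(peptide_group_mean(tab, "p1", c("s1", "s2", "s3")), 12)
  expect_true(is.na(peptide_group_mean(tab, "p2", c("s1", "s2"))))
  expect_equal(peptide_group_mean(tab, "p3", "s1"), 7)
  expect_error(peptide_group_mean(tab, "p1", character()), "nonempty")
})

test_that("peptide folds carry detection sentinels", {
  expect_equal(peptide_fold(20, 10), list(fold = 2, sentinel = "finite"))
  expect_equal(peptide_fold(20, NA)$sentinel, "POS_INF")
  expect_equal(peptide_fold(NA, 10)$sentinel, "INV_INF")
  expect_equal(peptide_fold(NA, NA)$sentinel, "none")
  expect_equal(render_fold(NA, "INV_INF"), "1/Inf")
  expect_equal(render_fold(NA, "ND"), "ND")
})

test_that("protein folds average peptide folds and resolve sentinels", {
  expect_equal(protein_fold(c(2, 4))$fold, 3)
  expect_equal(protein_fold(c(1, 1, 1))$fold, 1)
  expect_equal(protein_fold(numeric(), c("POS_INF", "POS_INF"))$sentinel, "POS_INF")
  expect_warning(out <- protein_fold(numeric(), c("POS_INF", "INV_INF")),
                 "contradictory")
  expect_equal(out$sentinel, "undefined")
  expect_error(protein_fold(numeric(), character()), "at least one")
})

test_that("exactly one of finite fold / sentinel states holds per record", {
  study <- simulate_study(seed = 5)
  g <- condition_groups(study$samples)
  q <- protein_quant(study$peptides, g$LS, g$CS, loci = study$mrna$locus)
  expect_equal(nrow(q), nrow(study$mrna))
  expect_true(all(q$sentinel %in% c("finite", "POS_INF", "INV_INF", "ND", "undefined")))
  expect_true(all(is.finite(q$fold[q$sentinel == "finite"])))
  expect_true(all(is.na(q$fold[q$sentinel != "finite"])))
  expect_true(all(q$n_peptides_used[q$sentinel == "finite"] >= 1))
})

test_that("protein-level p follows the one-sample conventions", {
  tab <- pep_tbl(
    "p1", "g1", "b1", 10, "p1", "g1", "a1", 10,
    "p2", "g1", "b1", 4,  "p2", "g1", "a1", 4
  )
  expect_equal(protein_test_p(tab, "g1", "b1", "a1"), 1) # all log2 folds exactly 0

  up <- pep_tbl(
    "p1", "g1", "b1", 19, "p1", "g1", "a1", 10,
    "p2", "g1", "b1", 20, "p2", "g1", "a1", 10,
    "p3", "g1", "b1", 21, "p3", "g1", "a1", 10
  )
  p <- protein_test_p(up, "g1", "b1", "a1") # folds 1.9, 2.0, 2.1
  expect_lt(p, 0.01)
  expect_equal(p, stats::t.test(log2(c(1.9, 2, 2.1)), mu = 0)$p.value)

  single <- pep_tbl("p1", "g1", "b1", 19, "p1", "g1", "a1", 10)
  expect_true(is.na(protein_test_p(single, "g1", "b1", "a1")))
})

test_that("rollup is permutation-invariant and matches the plain ratio for one peptide", {
  tab <- pep_tbl(
    "p1", "g1", "b1", 30, "p1", "g1", "b2", 34,
    "p1", "g1", "a1", 16, "p1", "g1", "a2", 16,
    "q1", "g2", "b1", 5,  "q1", "g2", "a1", 10,
    "q2", "g2", "b1", 7,  "q2", "g2", "a1", 10
  )
  q <- protein_quant(tab, c("b1", "b2"), c("a1", "a2"))
  expect_equal(q$fold[q$locus == "g1"], 2) # mean(30,34)/mean(16,16), one peptide
  expect_equal(q$fold[q$locus == "g2"], mean(c(0.5, 0.7)))

  shuffled <- tab[c(5, 2, 8, 1, 6, 3, 7, 4), ]
  q2 <- protein_quant(shuffled, c("b1", "b2"), c("a1", "a2"))
  expect_equal(q2[order(q2$locus), ], q[order(q$locus), ])
})

test_that("zero-noise planted protein effects are recovered exactly", {
  study <- simulate_study(noise = zero_noise(), seed = 9)
  g <- condition_groups(study$samples)
  q <- protein_quant(study$peptides, g$LS, g$CE, loci = study$mrna$locus)
  fx <- study$effects
  fin <- q[q$sentinel == "finite", ]
  planted <- fx$p_LS[match(fin$locus, fx$locus)]
  expect_equal(fin$fold, planted, tolerance = 1e-12)
})

test_that("the never-detected census matches the planted detection flags", {
  study <- simulate_study(seed = 3)
  cens <- nd_census(study$peptides, study$effects$locus)
  nd <- sort(cens$locus[!cens$detected])
  expect_equal(nd, sort(study$effects$locus[study$effects$detect == "never"]))
  expect_true(all(c("SAR11_0287", "SAR11_1163", "SAR11_1164") %in% nd))
  one_hit <- pep_tbl("p1", "gX", "s1", 3)
  expect_true(nd_census(one_hit, "gX")$detected)
})
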