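test_that("mean fold change is the ratio of arithmetic group means", {
  m <- expr_tbl("g1", c(20, 22, 18, 10, 9, 11, 10),
                samples = c("b1", "b2", "b3", "a1", "a2", "a3", "a4"))
  fc <- mean_fold_change(m, c("b1", "b2", "b3"), c("a1", "a2", "a3", "a4"))
  expect_equal(fc$fold, 2)
  # groups with identical abundance profiles give a fold of exactly 1
  same <- expr_tbl("g1", c(5, 7, 5, 7), samples = c("x1", "x2", "y1", "y2"))
  expect_equal(mean_fold_change(same, c("x1", "x2"), c("y1", "y2"))$fold, 1)
})

test_that("fold changes are reciprocal and scale-invariant", {
  withr::with_seed(31, {
    m <- expr_tbl(paste0("g", 1:5), rlnorm(5 * 6, 4, 0.5))
  })
  a <- paste0("s", 1:3)
  b <- paste0("s", 4:6)
  ab <- mean_fold_change(m, b, a)$fold
  ba <- mean_fold_change(m, a, b)$fold
  expect_equal(ab * ba, rep(1, 5))

  m2 <- m
  m2[-1] <- m2[-1] * 1000
  expect_equal(mean_fold_change(m2, b, a)$fold, ab)
  p1 <- apply(as.matrix(m[-1]), 1, function(v) group_test_p(v[1:3], v[4:6]))
  p2 <- apply(as.matrix(m2[-1]), 1, function(v) group_test_p(v[1:3], v[4:6]))
  expect_equal(p1, p2)
})

test_that("group mean-fold errors on empty, overlapping groups and unknown loci", {
  m <- expr_tbl("g1", c(1, 2, 3, 4))
  expect_error(mean_fold_change(m, character(), "s1"), "nonempty")
  expect_error(mean_fold_change(m, c("s1", "s2"), c("s2", "s3")), "disjoint")
  expect_error(mean_fold_change(m, "s1", "s2", loci = "nope"), "nope")
})

test_that("the Welch test follows its degenerate-input conventions", {
  expect_equal(group_test_p(c(4, 4, 4), c(4, 4, 4)), 1)
  expect_equal(group_test_p(2^c(1, 2, 3), 2^c(1, 2, 3)), 1) # equal log2 means
  expect_equal(group_test_p(c(2, 2), c(8, 8)), 0)
  expect_true(is.na(group_test_p(5, c(1, 2))))
})

test_that("a clearly separated pair is significant and agrees with a permutation oracle", {
  a <- 2^c(0, 0.1, -0.1)
  b <- 2^c(3, 3.1, 2.9)
  p <- group_test_p(a, b)
  expect_lt(p, 0.001)
  # the permutation oracle's resolution at n=3+3 is 1/choose(6,3); both
  # should land at their respective floors for perfectly separated groups
  expect_lt(permutation_p(log2(a), log2(b)), 0.11)

  # moderate case: parametric p and permutation p agree in magnitude
  withr::with_seed(8, {
    x <- rnorm(5, 0, 1)
    y <- rnorm(5, 1.2, 1)
  })
  p_par <- group_test_p(2^x, 2^y)
  p_perm <- permutation_p(x, y)
  expect_lt(abs(log10(p_par) - log10(p_perm)), 0.7)
})

test_that("Benjamini-Hochberg flags match the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.04, 0.9)
  expect_equal(adjust_multiple(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04 / 0.75, 0.9))
  expect_true(adjust_multiple(0.01, 0.05))
  expect_equal(adjust_multiple(rep(1, 10), 0.05), rep(FALSE, 10))

  for (seed in 1:10) {
    withr::with_seed(seed, p <- runif(30)^2)
    expect_equal(adjust_multiple(p, 0.05), bh_flags_by_hand(p, 0.05))
    # corrected flags are a subset of raw flags
    expect_true(all(!adjust_multiple(p, 0.05) | p <= 0.05))
  }
})

test_that("a single planted eightfold locus is the only any-condition hit", {
  withr::with_seed(13, {
    base <- matrix(rep(100, 5 * 16), nrow = 5) * rlnorm(80, 0, 0.01)
  })
  base[3, 1:3] <- base[3, 1:3] * 8 # eightfold in the LE samples
  m <- expr_tbl(paste0("g", 1:5), base,
                samples = c(paste0("le", 1:3), paste0("ls", 1:5),
                            paste0("ce", 1:4), paste0("cs", 1:4)))
  s <- tibble::tibble(
    sample_id = names(m)[-1],
    culture_id = names(m)[-1],
    treatment = rep(c("limited", "control"), c(8, 8)),
    harvest_day = 1,
    density = 1e6,
    nominal_phase = rep(c("exponential", "stationary", "exponential", "stationary"),
                        c(3, 5, 4, 4))
  )
  de <- diff_expression(m, state = NA, samples = s)
  expect_equal(table1_filter(de), "g3")
  expect_equal(table2_filter(de, threshold = Inf), character())
})

test_that("the exponential-phase scatter flags the fivefold box correctly", {
  rec <- tibble::tibble(
    locus = c("flat", "up6"),
    layer = "mRNA", comparison = "LE",
    fold = c(1, 6), sentinel = "finite",
    p_value = c(0.01, 0.01),
    significant_raw = TRUE, significant_corrected = TRUE
  )
  sc <- fig2_scatter(rec)
  expect_equal(sc$outside_box[sc$locus == "flat"], FALSE)
  expect_equal(sc$outside_box[sc$locus == "up6"], TRUE)
})

test_that("condition groups follow assigned phases and exclude transitioning samples", {
  study <- simulate_study(seed = 2, peptides = FALSE)
  gs <- growth_state(study)
  g <- condition_groups(study$samples, gs)
  expect_equal(lengths(g[c("LE", "LS", "CE", "CS")]),
               c(LE = 3L, LS = 5L, CE = 4L, CS = 4L))
  expect_false(any(c("L4_exp", "L5_exp") %in% g$LE))
  expect_equal(sum(lengths(g)), 16) # 13 transitioning samples left out
})

test_that("the vectorized matrix Welch path equals the scalar test per locus", {
  withr::with_seed(42, {
    m <- matrix(rlnorm(20 * 9, 4, 0.4), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  })
  m[3, ] <- 7 # constant row exercises the degenerate convention
  b <- paste0("s", 1:4)
  a <- paste0("s", 5:9)
  pv <- sulfurlim:::mrna_group_p(m, b, a)
  ps <- apply(m, 1, function(v) group_test_p(v[a], v[b]))
  expect_equal(pv, unname(ps))
})
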