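test_that("marker normalization is min-max on the log2 scale", {
  m <- expr_tbl("mk1", c(4, 8, 16))
  expect_equal(unname(normalize_markers(m, "mk1")[1, ]), c(0, 0.5, 1))
  m2 <- expr_tbl("mk1", c(1, 2))
  expect_equal(unname(normalize_markers(m2, "mk1")[1, ]), c(0, 1))
  withr::with_seed(4, {
    m3 <- expr_tbl(c("a", "b"), rlnorm(8, 3, 2))
  })
  n3 <- normalize_markers(m3, c("a", "b"))
  expect_true(all(n3 >= 0 & n3 <= 1))
  expect_true(all(apply(n3, 1, min) == 0) && all(apply(n3, 1, max) == 1))
})

test_that("constant markers are rejected by name", {
  m <- expr_tbl(c("ok", "flat"), c(1, 5, 2, 5, 3, 5))
  expect_error(normalize_markers(m, c("ok", "flat")), "flat")
})

test_that("the growth-state score is the mean of normalized markers", {
  norm <- matrix(c(0, 1, 1, 0, 0.5, 1), nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_equal(unname(growth_state_score(norm)), c(0.5, 0.5, 0.75))
  # a sample at every marker's maximum scores exactly 1; at every minimum, 0
  m <- expr_tbl(c("a", "b"), c(2, 3, 8, 12, 32, 48))
  sc <- growth_state_score(normalize_markers(m, c("a", "b")))
  expect_equal(unname(sc), c(0, 0.5, 1))
})

test_that("three-phase classification matches the hand partition and flags reclassification", {
  sc <- c(a = 0.85, b = 0.82, c = 0.50, d = 0.45, e = 0.20, f = 0.10)
  out <- classify_phases(sc)
  expect_equal(out$phase, c("exponential", "exponential", "transitioning",
                            "transitioning", "stationary", "stationary"))

  # the published cluster ranges separate cleanly
  pub <- c(0.91, 0.80, 0.58, 0.39, 0.29, 0.08)
  out2 <- classify_phases(pub)
  expect_equal(out2$phase, rep(c("exponential", "transitioning", "stationary"), each = 2))

  out3 <- classify_phases(c(0.9, 0.88, 0.15, 0.5, 0.85),
                          nominal_phase = rep("exponential", 5))
  expect_equal(sum(out3$reclassified), 2) # the 0.15 and 0.5 samples
  expect_equal(nrow(out3), 5)             # relabelled, never dropped

  expect_error(classify_phases(c(1, 1, 1)), "distinct")
})

test_that("clustering equals the brute-force optimal 3-partition for small n", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(4:9, 1)
      x <- round(runif(n), 3)
    })
    if (length(unique(x)) < 3) next
    grp <- classify_phases(x)$phase
    expect_equal(cluster_sse(x, grp), brute_force_3cluster_sse(x),
                 tolerance = 1e-10, label = sprintf("seed %d", seed))
  }
})

test_that("scores are invariant under per-marker power-law rescaling and sample permutation", {
  withr::with_seed(9, {
    m <- expr_tbl(c("a", "b", "c"), rlnorm(15, 4, 1))
  })
  sc <- growth_state_score(normalize_markers(m, c("a", "b", "c")))
  m2 <- m
  m2[m2$locus == "a", -1] <- 3.7 * m2[m2$locus == "a", -1]^2.5 # x -> c * x^a
  m2[m2$locus == "c", -1] <- 0.01 * m2[m2$locus == "c", -1]^0.3
  sc2 <- growth_state_score(normalize_markers(m2, c("a", "b", "c")))
  expect_equal(sc, sc2, tolerance = 1e-12)

  perm <- c(3, 1, 5, 2, 4)
  m3 <- m[, c(1, 1 + perm)]
  sc3 <- growth_state_score(normalize_markers(m3, c("a", "b", "c")))
  expect_equal(unname(sc3), unname(sc[perm]))
})

test_that("on synthetic studies the classifier recovers true phases and the two late harvests", {
  study <- simulate_study(seed = 21, peptides = FALSE)
  fit <- growth_state(study)
  a <- tidy(fit)
  truth <- study$samples$true_phase[match(a$sample_id, study$samples$sample_id)]
  expect_gte(mean(a$phase == truth), 0.9)
  expect_equal(sort(a$sample_id[a$reclassified]), c("L4_exp", "L5_exp"))
  g <- glance(fit)
  expect_equal(g$n_reclassified, 2)
  expect_equal(g$n_samples, 29)
})
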