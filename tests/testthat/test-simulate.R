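test_that("carrying capacity follows the sulfur quota arithmetic", {
  # 100e-9 mol/L / 6.67e-18 mol/cell = 1.50e10 cells/L = 1.50e7 cells/ml
  p <- growth_params(dmsp_initial = 100, sulfur_quota = 6.67, k_other = 1e12)
  expect_equal(p$capacity, 100e-9 / 6.67e-18 / 1000)
  expect_equal(p$capacity, 1.4993e7, tolerance = 1e-4)
})

test_that("growth curves plateau at the effective capacity and stay below it", {
  # carbon-limited regime: high dose, plateau set by k_other at 3.5e7
  p <- growth_params(dmsp_initial = 1000, k_other = 3.5e7)
  g <- simulate_growth(p, 30)
  expect_lt(max(g$density), p$capacity * (1 + 1e-9))
  expect_equal(g$density[31], 3.5e7, tolerance = 1e-3)
  expect_true(all(diff(g$density) >= 0))

  flat <- simulate_growth(growth_params(growth_rate = 1e-9), 10)
  expect_equal(flat$density, rep(4e5, 11), tolerance = 1e-6)
})

test_that("plateau density never decreases with the DMSP dose", {
  doses <- c(20, 50, 100, 200, 500, 1000)
  plateaus <- vapply(doses, function(d) {
    max(simulate_growth(growth_params(dmsp_initial = d), 40)$density)
  }, numeric(1))
  expect_true(all(diff(plateaus) >= 0))
})

test_that("nonpositive growth parameters are rejected", {
  expect_error(growth_params(initial_density = 0), "positive")
  expect_error(growth_params(dmsp_initial = -5), "positive")
})

test_that("default effect configuration plants the published fold changes", {
  fx <- default_effect_config()
  expect_equal(nrow(fx), 1354)
  look <- function(locus, col) fx[[col]][fx$locus == locus]
  expect_equal(look("SAR11_1172", "m_LE"), 50.04)
  expect_equal(look("SAR11_1173", "m_LE"), 33.77)
  expect_equal(look("SAR11_1030", "m_LE"), 7.14)
  expect_equal(look("SAR11_1171", "m_LE"), 17.28)
  # stationary-contrast ratio for ccmC comes out of its two planted effects
  expect_equal(look("SAR11_0287", "m_LS") / look("SAR11_0287", "m_CS"),
               4.74, tolerance = 2e-3)
  # unlisted loci are null in every condition and layer
  null_row <- fx[fx$locus == "NULL_S0001", ]
  expect_equal(unlist(null_row[c("m_LE", "m_LS", "m_CS", "p_LE", "p_LS", "p_CS")]),
               rep(1, 6), ignore_attr = TRUE)
  expect_equal(sort(fx$locus[fx$marker])[1:2], c("SAR11_1102", "SAR11_1104"))
  expect_equal(sum(fx$marker), 21)
})

test_that("noiseless transcriptomes reproduce baselines and planted ratios exactly", {
  fx <- default_effect_config(n_loci = 60)
  fx$m_LE <- 1
  fx$m_LS <- 1
  fx$m_CS <- 1
  s <- simulate_design()$samples
  m <- simulate_transcriptome(fx, s, zero_noise(), seed = 3)
  vals <- as.matrix(m[-1])
  expect_true(all(vals == fx$baseline)) # no effects: every column is baseline

  fx2 <- fx
  fx2$m_LE[1] <- 2
  m2 <- simulate_transcriptome(fx2, s, zero_noise(), seed = 3)
  le <- s$sample_id[s$treatment == "limited" & s$true_phase == "exponential"]
  ce <- s$sample_id[s$treatment == "control" & s$true_phase == "exponential"]
  expect_equal(unlist(m2[1, le]) / unlist(m2[1, ce][[1]]), rep(2, 3),
               ignore_attr = TRUE)
})

test_that("the generator is reproducible by seed", {
  fx <- default_effect_config(n_loci = 80)
  s <- simulate_design()$samples
  a <- simulate_transcriptome(fx, s, noise_model(), seed = 5)
  b <- simulate_transcriptome(fx, s, noise_model(), seed = 5)
  c <- simulate_transcriptome(fx, s, noise_model(), seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))

  pa <- simulate_peptides(fx, s, noise_model(), seed = 5)
  pb <- simulate_peptides(fx, s, noise_model(), seed = 5)
  expect_identical(pa, pb)
})

test_that("across seeds, estimated group-mean ratios recover a planted effect", {
  fx <- default_effect_config(n_loci = 60)
  s <- simulate_design()$samples
  le <- s$sample_id[s$treatment == "limited" & s$true_phase == "exponential"]
  ce <- s$sample_id[s$treatment == "control" & s$true_phase == "exponential"]
  folds <- vapply(1:50, function(seed) {
    m <- simulate_transcriptome(fx, s, noise_model(), seed = seed)
    mean_fold_change(m, le, ce, "SAR11_1172")$fold
  }, numeric(1))
  expect_equal(mean(folds), 50.04, tolerance = 0.1)
})

test_that("peptide simulation honours dropout, multiplicity and detection flags", {
  fx <- default_effect_config(n_loci = 60)
  s <- simulate_design()$samples

  all_out <- simulate_peptides(fx, s, noise_model(dropout_rate = 1), seed = 2)
  expect_true(all(is.na(all_out$abundance)))

  nm <- noise_model(cv_protein = 0, peptide_efficiency_sd = 0, dropout_rate = 0,
                    peptides_per_protein = c(2L, 2L))
  pp <- simulate_peptides(fx, s, nm, seed = 2)
  # two peptides with unit efficiency and no noise equal the protein abundance
  one <- pp[pp$locus == "NULL_S0001", ]
  expect_equal(length(unique(one$peptide_id)), 2)
  per_sample <- tapply(one$abundance, one$sample_id, unique)
  expect_true(all(vapply(per_sample, length, integer(1)) == 1))

  expect_equal(nrow(pp[pp$locus == "SAR11_0287", ]), 0) # never detected
  not_cs <- pp[pp$locus == "SAR11_0173", ]
  cs <- s$sample_id[s$treatment == "control" & s$true_phase == "stationary"]
  expect_true(all(is.na(not_cs$abundance[not_cs$sample_id %in% cs])))
  expect_true(all(!is.na(not_cs$abundance[!not_cs$sample_id %in% cs])))
})

test_that("the standard design has the study's group structure", {
  d <- simulate_design()
  s <- d$samples
  expect_equal(nrow(s), 29)
  expect_equal(length(unique(s$culture_id)), 9)
  tab <- table(s$treatment, s$true_phase)
  expect_equal(tab["limited", "exponential"], 3, ignore_attr = TRUE)
  expect_equal(tab["limited", "stationary"], 5, ignore_attr = TRUE)
  expect_equal(tab["control", "exponential"], 4, ignore_attr = TRUE)
  expect_equal(tab["control", "stationary"], 4, ignore_attr = TRUE)
  # the two late-harvested limited cultures are nominally exponential
  late <- s[s$nominal_phase == "exponential" & s$true_phase == "transitioning", ]
  expect_equal(sort(late$sample_id), c("L4_exp", "L5_exp"))
})
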