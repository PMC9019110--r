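test_that("isoform_tpm splits total TPM by splicing ratio", {
  expect_equal(isoform_tpm(100, 15, "exclusion_productive"), 85)
  expect_equal(isoform_tpm(10, 96, "inclusion_coding"), 9.6)
  expect_equal(isoform_tpm(42, 0, "exclusion_productive"), 42)
  expect_true(is.na(isoform_tpm(10, NA, "inclusion_coding")))
  expect_error(isoform_tpm(10, 120, "inclusion_coding"),
    class = "spliceamp_invariant_error")
  expect_error(isoform_tpm(-1, 50, "inclusion_coding"),
    class = "spliceamp_invariant_error")
})

test_that("degradation factor aggregates fold changes", {
  # Geometric mean of the two published knockout fold changes gives the
  # reported one-decimal factor; the arithmetic mean does not.
  lam <- estimate_degradation_factor(c(8.7, 6.8))
  expect_equal(round(lam$lambda, 1), 7.7)
  expect_equal(lam$method, "geometric")
  expect_equal(lam$inputs, c(8.7, 6.8))

  expect_equal(estimate_degradation_factor(3.2)$lambda, 3.2)
  expect_equal(estimate_degradation_factor(c(4, 9))$lambda, 6)
  expect_equal(
    estimate_degradation_factor(c(4, 9), "arithmetic")$lambda, 6.5
  )
  expect_error(estimate_degradation_factor(numeric(0)),
    class = "spliceamp_invariant_error")
  expect_error(estimate_degradation_factor(c(2, -1)),
    class = "spliceamp_invariant_error")
})

test_that("corrected output reconstructs transcription from steady state", {
  expect_equal(corrected_output(68.5, 35.6, 7.7), 288.93)
  expect_equal(corrected_output(8.0, 0.9, 7.7), 55.57)
  expect_equal(corrected_output(42, 10, 1), 42) # no NMD, no correction
  expect_error(corrected_output(10, 12, 7.7),
    class = "spliceamp_invariant_error")
  expect_error(corrected_output(10, 5, 0.5),
    class = "spliceamp_invariant_error")
})

test_that("corrected output is linear: group means commute", {
  withr::with_seed(31, {
    total <- stats::runif(10, 5, 100)
    productive <- total * stats::runif(10, 0, 1)
    lam <- 7.7
    expect_equal(
      corrected_output(mean(total), mean(productive), lam),
      mean(corrected_output(total, productive, lam)),
      tolerance = 1e-12
    )
  })
})

test_that("isoform decomposition conserves total TPM", {
  sim <- simulate_tissue_panel(sim_config(), seed = 3)
  psi <- psi_table(sim$junctions)
  iso <- isoform_output(sim$expression, psi, 7.7)
  expect_equal(iso$productive_tpm + iso$nmd_tpm, iso$total_tpm,
    tolerance = 1e-12)
  expect_true(all(iso$productive_tpm >= 0 & iso$nmd_tpm >= 0, na.rm = TRUE))
  expect_true(all(iso$corrected_output >= iso$total_tpm, na.rm = TRUE))
})

test_that("group fold change carries raw and reporting precision", {
  fc <- group_fold_change(66, 1.5, "coding_long_tpm")
  expect_equal(fc$fold, 44)
  expect_equal(fc$fold_nearest, 44)

  fc <- group_fold_change(35.6, 0.9, "productive_tpm")
  expect_equal(round(fc$fold, 1), 39.6)
  expect_equal(fc$fold_nearest_ten, 40)

  expect_equal(group_fold_change(c(2, 4), c(2, 4))$fold, 1)
  expect_error(group_fold_change(1, 0), class = "spliceamp_invariant_error")
  expect_error(group_fold_change(numeric(0), 1),
    class = "spliceamp_invariant_error")
})

test_that("splicing amplifies the neural/non-neural contrast", {
  # Under the panel's generative regime (NMD exon low / coding exon high
  # in neural tissue and the reverse in non-neural tissue) the isoform
  # fold changes must exceed the steady-state fold change.
  sim <- simulate_tissue_panel(sim_config(), seed = 17)
  psi <- psi_table(sim$junctions)
  iso <- isoform_output(sim$expression, psi, 7.7) %>%
    dplyr::inner_join(sim$samples, by = "sample_id") %>%
    dplyr::group_by(tissue, tissue_group) %>%
    dplyr::summarise(
      dplyr::across(c(total_tpm, productive_tpm, coding_long_tpm),
        ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  a <- iso[iso$tissue_group == "neural", ]
  b <- iso[iso$tissue_group == "non_neural", ]
  fold_total <- group_fold_change(a$total_tpm, b$total_tpm)$fold
  fold_prod <- group_fold_change(a$productive_tpm, b$productive_tpm)$fold
  fold_coding <- group_fold_change(a$coding_long_tpm, b$coding_long_tpm)$fold
  expect_gt(fold_prod, fold_total)
  expect_gt(fold_coding, fold_total)
})
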