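test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config()
  a <- simulate_tissue_panel(cfg, seed = 42)
  b <- simulate_tissue_panel(cfg, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$junctions, simulate_tissue_panel(cfg, seed = 43)$junctions
  ))

  dir_a <- tempfile()
  dir_b <- tempfile()
  write_simulation(a, dir_a)
  write_simulation(b, dir_b)
  for (f in c("samples.tsv", "junctions.tsv", "expression.tsv",
    "truth.json")) {
    expect_identical(
      unname(tools::md5sum(file.path(dir_a, f))),
      unname(tools::md5sum(file.path(dir_b, f)))
    )
  }
})

test_that("simulated tables pass the package readers", {
  sim <- simulate_tissue_panel(sim_config(), seed = 8)
  dir <- tempfile()
  write_simulation(sim, dir)
  samples <- read_samples(file.path(dir, "samples.tsv"))
  junc <- read_junctions(file.path(dir, "junctions.tsv"), samples)
  expr <- read_expression(file.path(dir, "expression.tsv"), samples)
  expect_equal(nrow(samples), 24)
  expect_equal(junc$excl, sim$junctions$excl)
  expect_equal(expr$tpm, sim$expression$tpm, tolerance = 1e-12)
})

test_that("without NMD the steady state equals transcription", {
  cfg <- sim_config(noise = FALSE, lambda_true = 1,
    psi8_mean = c(neural = 50, non_neural = 50))
  sim <- simulate_tissue_panel(cfg, seed = 1)
  expect_equal(sim$expression$tpm[1],
    sim$truth$tissues$transcription[1], tolerance = 1e-12)
  psi <- psi_table(sim$junctions)
  expect_equal(psi$psi[psi$event_id == "E8"], rep(50, 24),
    tolerance = 1e-12)
})

test_that("post-decay inclusion matches the two-state steady-state oracle", {
  cfg <- sim_config(noise = FALSE,
    psi8_mean = c(neural = 50, non_neural = 50), lambda_true = 7.7)
  sim <- simulate_tissue_panel(cfg, seed = 1)
  # Independent closed form: surviving inclusion = (p/lambda) of
  # transcription vs (1 - p) productive, p = 0.5.
  oracle <- 100 * (0.5 / 7.7) / (0.5 / 7.7 + 0.5)
  expect_equal(unique(sim$truth$tissues$psi8_steady), oracle,
    tolerance = 1e-12)
  psi <- psi_table(sim$junctions)
  expect_equal(psi$psi[psi$event_id == "E8"], rep(oracle, 24),
    tolerance = 1e-12)
  expect_equal(oracle, 11.49425287, tolerance = 1e-8)
})

test_that("junction reads are even in the molecule model", {
  sim <- simulate_tissue_panel(sim_config(), seed = 5)
  incl <- sim$junctions$incl_up + sim$junctions$incl_down
  expect_true(all(incl %% 2 == 0))
})

test_that("noiseless knockout contrast recovers lambda exactly", {
  cfg <- sim_config(noise = FALSE, lambda_true = 7.7)
  sim <- simulate_nmd_ko_contrast(cfg, seed = 1)
  lam <- lambda_from_contrast(sim)
  expect_equal(lam$lambda, 7.7, tolerance = 1e-9)
  expect_error(
    simulate_nmd_ko_contrast(sim_config(lambda_true = 1), seed = 1),
    class = "spliceamp_invariant_error"
  )
})

test_that("development course encodes independent exons", {
  cfg <- sim_config(noise = FALSE)
  sim <- simulate_development_course(cfg, seed = 2)
  ci <- conditional_inclusion(
    sim$isoforms$n_pp, sim$isoforms$n_pm,
    sim$isoforms$n_mp, sim$isoforms$n_mm
  )
  # Independence: exon 10 inclusion is the same within E8+ and E8-
  # transcripts at every stage.
  expect_equal(ci$e10_given_e8plus, ci$e10_given_e8minus,
    tolerance = 1e-12)
  # Recovered PSI trajectories are monotone in the noiseless limit.
  psi <- psi_table(sim$junctions) %>%
    dplyr::inner_join(sim$samples, by = "sample_id") %>%
    dplyr::group_by(stage, event_id) %>%
    dplyr::summarise(psi = mean(psi), .groups = "drop")
  p10 <- psi$psi[psi$event_id == "E10"][order(match(
    psi$stage[psi$event_id == "E10"], cfg$stages
  ))]
  expect_true(all(diff(p10) > 0))

  expect_warning(
    simulate_development_course(
      sim_config(stage_psi8 = c(10, 50, 40, 25, 12)), seed = 1
    ),
    "monoton"
  )
})

test_that("deleting the NMD exon raises steady-state mRNA early", {
  cfg <- sim_config(noise = FALSE)
  sim <- simulate_development_course(cfg, seed = 3, include_e8_ko = TRUE)
  expr <- dplyr::inner_join(sim$expression, sim$samples, by = "sample_id") %>%
    dplyr::group_by(stage, condition) %>%
    dplyr::summarise(tpm = mean(tpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = condition, values_from = tpm)
  # NMD removal inflates total mRNA wherever the NMD exon is included;
  # the effect is largest at the earliest (high-inclusion) stage.
  expect_true(all(expr$E8_KO > expr$WT))
  ratio <- expr$E8_KO / expr$WT
  early <- which(expr$stage == "EB_D8")
  expect_equal(max(ratio), ratio[early])
})

test_that("decay course simulation honors its noise model", {
  exact <- simulate_decay_course(4.3, sigma = 0)
  expect_equal(exact$fraction, 0.5^(exact$time_h / 4.3))
  expect_equal(exact$fraction[1], 1)

  # Frozen closed forms at t = 12 h for the two published half-lives:
  # far below the reported 31%/6% remaining, so observed chases are not
  # pure exponentials of those half-lives.
  expect_equal(0.5^(12 / 1.9), 0.0125533, tolerance = 1e-5)
  expect_equal(0.5^(12 / 4.3), 0.1445161, tolerance = 1e-5)

  noisy <- simulate_decay_course(4.3, sigma = 0.1, seed = 9)
  expect_identical(noisy, simulate_decay_course(4.3, sigma = 0.1, seed = 9))
  expect_equal(noisy$fraction[1], 1)

  expect_error(simulate_decay_course(-1), class = "spliceamp_invariant_error")
  expect_error(simulate_decay_course(2, sigma = -0.1),
    class = "spliceamp_invariant_error")
  expect_error(simulate_decay_course(2, timepoints = c(1, 2, 3)),
    class = "spliceamp_invariant_error")
})
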