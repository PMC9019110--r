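# Seeded generative simulator for every input the pipeline consumes:
# multi-tissue adult panel, NMD-knockout contrasts, developmental time
# course, and protein decay assays, with ground truth recorded.

#' Simulation configuration
#'
#' Returns the generative parameters for all simulation scenarios. The
#' defaults encode the study conditions the pipeline is meant to emulate:
#' a 12-tissue adult panel (3 neural + 9 non-neural, 2 biological
#' replicates each) in which the noiseless steady state reproduces the
#' published group means (total TPM 68.5 neural vs 8.0 non-neural;
#' productive exon 8- isoform 35.6 vs 0.9; coding exon 10+ isoform 66 vs
#' 1.5) under a degradation factor of 7.7. Group-level transcription and
#' transcription-level PSIs were obtained by inverting the steady-state
#' model: observed inclusion fraction `s = (p/lambda)/(p/lambda + 1 - p)`
#' and observed total `T * ((1 - p) + p/lambda)`.
#'
#' Junction reads are sampled at post-decay (steady-state) isoform
#' proportions, because RNA-seq measures steady-state RNA: each inclusion
#' molecule emits two inclusive junction reads, each skipping molecule one
#' exclusive read. `junction_mode = "exact"` emits the expected
#' (real-valued) counts instead of Poisson/binomial draws.
#'
#' @param noise If `FALSE`, all dispersions are zeroed and
#'   `junction_mode` is set to `"exact"`, giving the deterministic
#'   noiseless limit of the generative model.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(noise = TRUE, ...) {
  cfg <- list(
    gene_id = "Trim46",
    tissues = tibble(
      tissue = c(
        "cortex", "cerebellum", "hypothalamus",
        "liver", "heart", "kidney", "lung", "spleen", "thymus",
        "muscle", "testis", "intestine"
      ),
      tissue_group = c(rep("neural", 3), rep("non_neural", 9))
    ),
    n_replicates = 2L,
    # Transcription output (TPM scale) and transcription-level PSIs.
    transcription_mean = c(neural = 288.9, non_neural = 55.7),
    transcription_sdlog = 0.5,
    replicate_sdlog = 0.2,
    psi8_mean = c(neural = 87.7, non_neural = 98.4),
    psi10_mean = c(neural = 96, non_neural = 27),
    psi_concentration = 80,
    lambda_true = 7.7,
    junction_depth = 500,
    junction_mode = "poisson",
    # 5-stage differentiation course: NMD exon declining, coding exon rising.
    stages = c("EB_D8", "DIV1", "DIV3", "DIV5", "DIV7"),
    stage_psi8 = c(85, 60, 40, 25, 12),
    stage_psi10 = c(8, 30, 50, 65, 75),
    stage_transcription = c(40, 80, 150, 220, 290),
    # NMD-knockout contrast (embryonic and early postnatal neocortex).
    ko_stages = c("E14.5", "P1"),
    ko_psi8 = c(60, 40),
    ko_transcription = c(120, 200),
    # Protein decay assay.
    half_lives = c(short = 1.9, long = 4.3),
    synthesis_ratio = 1,
    decay_sigma = 0.1,
    decay_timepoints = c(0, 1, 3, 6, 12, 24)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field: ", unknown[1]),
      class = "spliceamp_schema_error")
  }
  cfg[names(overrides)] <- overrides
  if (!noise) {
    cfg$transcription_sdlog <- 0
    cfg$replicate_sdlog <- 0
    cfg$psi_concentration <- Inf
    cfg$junction_mode <- "exact"
    cfg$decay_sigma <- 0
  }
  stopifnot(
    all(cfg$psi8_mean >= 0 & cfg$psi8_mean <= 100),
    all(cfg$psi10_mean >= 0 & cfg$psi10_mean <= 100),
    cfg$lambda_true >= 1,
    cfg$junction_depth >= 1
  )
  structure(cfg, class = "sim_config")
}

# Beta draw of PSI percentages around a group mean; Inf concentration is
# the deterministic limit.
draw_psi <- function(mean_pct, concentration, n) {
  if (!is.finite(concentration) || mean_pct %in% c(0, 100)) {
    return(rep(mean_pct, n))
  }
  m <- mean_pct / 100
  100 * rbeta(n, shape1 = m * concentration, shape2 = (1 - m) * concentration)
}

# Lognormal draw with the group value as geometric centre; sdlog 0 is the
# deterministic limit.
draw_lognorm <- function(centre, sdlog, n) {
  if (sdlog == 0) rep_len(centre, n) else rlnorm(n, log(centre), sdlog)
}

# Two-state steady state under NMD: inclusion isoform degraded lambda-fold.
steady_state <- function(transcription, p_incl, lambda) {
  productive <- transcription * (1 - p_incl)
  nmd <- transcription * p_incl / lambda
  total <- productive + nmd
  list(
    productive = productive, nmd = nmd, total = total,
    incl_frac = ifelse(total > 0, nmd / total, 0)
  )
}

# Junction-read pair for one sample/event at steady-state inclusion
# fraction s. Poisson total of informative molecules, binomial split;
# exact mode emits expected counts (real-valued).
draw_junctions <- function(s, depth, mode) {
  s <- unname(s)
  if (mode == "exact") {
    m <- depth * s
    return(c(incl = 2 * m, excl = depth - m))
  }
  n <- rpois(1, depth)
  m <- rbinom(1, n, s)
  c(incl = 2 * m, excl = n - m)
}

#' Simulate the multi-tissue adult panel
#'
#' Per tissue, draws a transcription level (lognormal around the group
#' mean) and transcription-level PSIs for the NMD exon (E8) and the coding
#' exon (E10) (beta around the group means), pushes them through the NMD
#' steady state, and emits per-replicate expression (with multiplicative
#' replicate noise) and junction counts sampled at the post-decay isoform
#' proportions. The coding exon is unaffected by NMD because, with the two
#' exons spliced independently, degradation of inclusion-isoform
#' transcripts removes E10+ and E10- molecules in equal proportion.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives identical
#'   output.
#' @return A list with `samples`, `junctions`, `expression` (tibbles in
#'   the reader schemas) and `truth` (realized per-tissue parameters plus
#'   `lambda_true` and `seed`).
#' @export
simulate_tissue_panel <- function(config = sim_config(), seed = 1) {
  withr::with_seed(seed, {
    ts <- config$tissues
    n_t <- nrow(ts)
    transcription <- draw_lognorm(
      unname(config$transcription_mean[ts$tissue_group]),
      config$transcription_sdlog, n_t
    )
    psi8 <- draw_psi_by_group(ts$tissue_group, config$psi8_mean,
      config$psi_concentration)
    psi10 <- draw_psi_by_group(ts$tissue_group, config$psi10_mean,
      config$psi_concentration)
    ss <- steady_state(transcription, psi8 / 100, config$lambda_true)

    truth <- tibble(
      tissue = ts$tissue, tissue_group = ts$tissue_group,
      transcription = transcription,
      psi8_transcription = psi8, psi10 = psi10,
      total_steady = ss$total, productive_steady = ss$productive,
      nmd_steady = ss$nmd, psi8_steady = 100 * ss$incl_frac
    )

    samples <- tidyr::crossing(ts, replicate = seq_len(config$n_replicates)) %>%
      mutate(
        sample_id = paste0(tissue, "_rep", replicate),
        condition = "WT", stage = "adult"
      ) %>%
      select(sample_id, tissue, tissue_group, condition, stage, replicate)

    expr_rows <- junc_rows <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      ti <- match(samples$tissue[i], ts$tissue)
      tpm <- ss$total[ti] * draw_lognorm(1, config$replicate_sdlog, 1)
      expr_rows[[i]] <- tibble(
        sample_id = samples$sample_id[i], gene_id = config$gene_id, tpm = tpm
      )
      j8 <- draw_junctions(ss$incl_frac[ti], config$junction_depth,
        config$junction_mode)
      j10 <- draw_junctions(psi10[ti] / 100, config$junction_depth,
        config$junction_mode)
      # Each inclusion molecule spans both flanking junctions, so the
      # inclusive total splits evenly into upstream and downstream reads.
      junc_rows[[i]] <- tibble(
        sample_id = samples$sample_id[i],
        event_id = c("E8", "E10"),
        incl_up = c(j8[["incl"]], j10[["incl"]]) / 2,
        incl_down = c(j8[["incl"]], j10[["incl"]]) / 2,
        excl = c(j8[["excl"]], j10[["excl"]]),
        combined = FALSE
      )
    }

    list(
      samples = samples,
      junctions = bind_rows(junc_rows),
      expression = bind_rows(expr_rows),
      truth = list(
        tissues = truth, lambda_true = config$lambda_true, seed = seed
      )
    )
  })
}

draw_psi_by_group <- function(groups, means, concentration) {
  unname(vapply(
    groups,
    function(g) draw_psi(unname(means[g]), concentration, 1),
    numeric(1)
  ))
}

#' Simulate a paired NMD-knockout contrast
#'
#' Wild-type samples are generated under the configured degradation
#' factor; NMD-knockout samples under lambda = 1 with the same
#' transcription level and transcription-level PSIs. In the noiseless
#' limit the NMD-isoform fold change (knockout over control) equals
#' `lambda_true` exactly.
#'
#' @inheritParams simulate_tissue_panel
#' @return A list with `samples`, `junctions`, `expression`, `truth`.
#' @export
simulate_nmd_ko_contrast <- function(config = sim_config(), seed = 1) {
  if (config$lambda_true <= 1) {
    abort("lambda_true must exceed 1 for an informative contrast",
      class = "spliceamp_invariant_error")
  }
  withr::with_seed(seed, {
    rows_s <- rows_j <- rows_e <- list()
    for (k in seq_along(config$ko_stages)) {
      stage <- config$ko_stages[k]
      p8 <- config$ko_psi8[k] / 100
      tr <- config$ko_transcription[k]
      for (cond in c("WT", "NMD_KO")) {
        lam <- if (cond == "WT") config$lambda_true else 1
        ss <- steady_state(tr, p8, lam)
        for (r in seq_len(config$n_replicates)) {
          sid <- paste(stage, cond, r, sep = "_")
          rows_s[[sid]] <- tibble(
            sample_id = sid, tissue = "neocortex", tissue_group = "neural",
            condition = cond, stage = stage, replicate = r
          )
          tpm <- ss$total * draw_lognorm(1, config$replicate_sdlog, 1)
          rows_e[[sid]] <- tibble(
            sample_id = sid, gene_id = config$gene_id, tpm = tpm
          )
          j8 <- draw_junctions(ss$incl_frac, config$junction_depth,
            config$junction_mode)
          rows_j[[sid]] <- tibble(
            sample_id = sid, event_id = "E8",
            incl_up = j8[["incl"]] / 2, incl_down = j8[["incl"]] / 2,
            excl = j8[["excl"]], combined = FALSE
          )
        }
      }
    }
    list(
      samples = bind_rows(rows_s),
      junctions = bind_rows(rows_j),
      expression = bind_rows(rows_e),
      truth = list(
        lambda_true = config$lambda_true,
        stages = config$ko_stages, psi8 = config$ko_psi8,
        transcription = config$ko_transcription, seed = seed
      )
    )
  })
}

#' Estimate the degradation factor from a knockout contrast
#'
#' Computes per-sample PSI for the NMD exon, converts it to the
#' NMD-isoform ratio `psi / (100 - psi)`, aggregates replicates by
#' geometric mean, forms the knockout-over-control fold change per stage,
#' and aggregates stages with [estimate_degradation_factor()]. Non-finite
#' replicate ratios (PSI of exactly 0 or 100) are dropped with a warning.
#'
#' @param sim Output of [simulate_nmd_ko_contrast()] or any list with
#'   `junctions` and `samples` in the same schema.
#' @param min_informative Coverage threshold passed to [psi_table()].
#' @param method Aggregation across stages, `"geometric"` or
#'   `"arithmetic"`.
#' @return A `degradation_factor` object.
#' @export
lambda_from_contrast <- function(sim, min_informative = 10,
                                 method = "geometric") {
  psi <- psi_table(sim$junctions, min_informative = min_informative) %>%
    filter(event_id == "E8") %>%
    inner_join(sim$samples, by = "sample_id") %>%
    mutate(ratio = psi / (100 - psi))
  if (any(!is.finite(psi$ratio))) {
    warn("dropping replicate(s) with PSI at the 0/100 boundary")
    psi <- filter(psi, is.finite(ratio))
  }
  per_stage <- psi %>%
    group_by(stage, condition) %>%
    summarise(ratio = exp(mean(log(ratio))), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = condition, values_from = ratio)
  folds <- nmd_fold_change(per_stage$NMD_KO, per_stage$WT)
  estimate_degradation_factor(folds, method = method)
}

#' Simulate the differentiation time course
#'
#' Emits per-stage, per-replicate junction counts for both exons,
#' expression, and steady-state four-isoform abundances generated under
#' independence of the two exons. Optionally adds a paired NMD-exon
#' knockout condition (inclusion forced to zero), in which total
#' steady-state mRNA exceeds wild type wherever the NMD exon is included.
#'
#' @inheritParams simulate_tissue_panel
#' @param include_e8_ko Also generate `E8_KO` samples with the NMD exon
#'   deleted.
#' @return A list with `samples`, `junctions`, `expression`, `isoforms`
#'   (columns `sample_id`, `n_pp`, `n_pm`, `n_mp`, `n_mm` for E8+E10+,
#'   E8+E10-, E8-E10+, E8-E10-) and `truth`.
#' @export
simulate_development_course <- function(config = sim_config(), seed = 1,
                                        include_e8_ko = FALSE) {
  if (any(diff(config$stage_psi8) > 0)) {
    warn("stage_psi8 trajectory is not monotonically decreasing")
  }
  if (any(diff(config$stage_psi10) < 0)) {
    warn("stage_psi10 trajectory is not monotonically increasing")
  }
  withr::with_seed(seed, {
    conditions <- c("WT", if (include_e8_ko) "E8_KO")
    rows_s <- rows_j <- rows_e <- rows_i <- list()
    for (k in seq_along(config$stages)) {
      stage <- config$stages[k]
      p10 <- config$stage_psi10[k] / 100
      tr <- config$stage_transcription[k]
      for (cond in conditions) {
        p8 <- if (cond == "E8_KO") 0 else config$stage_psi8[k] / 100
        ss <- steady_state(tr, p8, config$lambda_true)
        for (r in seq_len(config$n_replicates)) {
          sid <- paste(stage, cond, r, sep = "_")
          rows_s[[sid]] <- tibble(
            sample_id = sid, tissue = "culture", tissue_group = "neural",
            condition = cond, stage = stage, replicate = r
          )
          noise <- draw_lognorm(1, config$replicate_sdlog, 1)
          rows_e[[sid]] <- tibble(
            sample_id = sid, gene_id = config$gene_id, tpm = ss$total * noise
          )
          j8 <- draw_junctions(ss$incl_frac, config$junction_depth,
            config$junction_mode)
          j10 <- draw_junctions(p10, config$junction_depth,
            config$junction_mode)
          rows_j[[sid]] <- tibble(
            sample_id = sid, event_id = c("E8", "E10"),
            incl_up = c(j8[["incl"]], j10[["incl"]]) / 2,
            incl_down = c(j8[["incl"]], j10[["incl"]]) / 2,
            excl = c(j8[["excl"]], j10[["excl"]]),
            combined = FALSE
          )
          # Steady-state joint abundances: the two exons are independent at
          # the transcription level; NMD then scales the E8+ classes only.
          rows_i[[sid]] <- tibble(
            sample_id = sid,
            n_pp = ss$nmd * p10, n_pm = ss$nmd * (1 - p10),
            n_mp = ss$productive * p10, n_mm = ss$productive * (1 - p10)
          ) %>% mutate(across(c(n_pp, n_pm, n_mp, n_mm), ~ .x * noise))
        }
      }
    }
    list(
      samples = bind_rows(rows_s),
      junctions = bind_rows(rows_j),
      expression = bind_rows(rows_e),
      isoforms = bind_rows(rows_i),
      truth = list(
        stages = config$stages, psi8 = config$stage_psi8,
        psi10 = config$stage_psi10,
        transcription = config$stage_transcription,
        lambda_true = config$lambda_true, seed = seed
      )
    )
  })
}

#' Simulate a cycloheximide-chase decay course
#'
#' `fraction(t) = 0.5^(t / half_life)` with multiplicative lognormal
#' measurement noise of standard deviation `sigma` on the log scale; the
#' t = 0 fraction is forced to 1 (normalization anchor).
#'
#' @param half_life True half-life in hours, > 0.
#' @param timepoints Hours, strictly increasing, first = 0.
#' @param sigma Lognormal noise sd (>= 0); 0 gives the exact exponential.
#' @param seed Optional integer seed.
#' @return A tibble with `time_h` and `fraction`.
#' @export
simulate_decay_course <- function(half_life,
                                  timepoints = c(0, 1, 3, 6, 12, 24),
                                  sigma = 0.1, seed = NULL) {
  if (half_life <= 0) {
    abort("half_life must be positive", class = "spliceamp_invariant_error")
  }
  if (sigma < 0) {
    abort("sigma must be non-negative", class = "spliceamp_invariant_error")
  }
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0)) {
    abort("timepoints must start at 0 and be strictly increasing",
      class = "spliceamp_invariant_error")
  }
  gen <- function() {
    f <- 0.5^(timepoints / half_life)
    if (sigma > 0) {
      f <- f * exp(rnorm(length(timepoints), 0, sigma))
    }
    f[1] <- 1
    tibble(time_h = timepoints, fraction = f)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a simulated dataset to disk
#'
#' Emits `samples.tsv`, `junctions.tsv`, `expression.tsv` (and
#' `isoforms.tsv` when present) in the reader schemas, plus `truth.json`.
#' Output is deterministic: identical input produces byte-identical files.
#'
#' @param sim A simulation result list.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"),
    progress = FALSE)
  readr::write_tsv(sim$junctions, file.path(dir, "junctions.tsv"),
    progress = FALSE)
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"),
    progress = FALSE)
  if (!is.null(sim$isoforms)) {
    readr::write_tsv(sim$isoforms, file.path(dir, "isoforms.tsv"),
      progress = FALSE)
  }
  truth <- sim$truth
  if (is.data.frame(truth$tissues)) {
    truth$tissues <- as.data.frame(truth$tissues)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE
  )
  invisible(dir)
}
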