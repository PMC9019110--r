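# PSI estimation from splice-junction reads, the four-isoform joint
# analysis, and the NMD-isoform normalization statistic.

#' Percent spliced-in from junction reads
#'
#' Each inclusion molecule contributes two inclusive junction reads (one per
#' flanking junction) while each skipping molecule contributes a single
#' exclusive read, so inclusive reads are down-weighted by 0.5:
#' \deqn{PSI = 100 \cdot \frac{0.5 I}{0.5 I + E}}
#' where `I` is the total inclusive junction-read count and `E` the
#' exclusive count. For a molecule population (m_incl, m_excl) emitting
#' I = 2 m_incl and E = m_excl this recovers the true inclusion fraction
#' exactly. The informative-read depth is `0.5 I + E`; estimates below
#' `min_informative` are flagged `low_coverage`, and PSI is undefined
#' (`NA`) when the depth is zero.
#'
#' @param inclusive Non-negative inclusive junction-read counts (vector).
#' @param exclusive Non-negative exclusive junction-read counts (vector).
#' @param min_informative Minimum informative reads (`0.5 I + E`) for an
#'   estimate to be considered well covered. Default 10.
#' @return A tibble with columns `psi`, `exclusion` (`100 - psi`),
#'   `informative_reads`, and `flag` (`"ok"` or `"low_coverage"`).
#' @examples
#' compute_psi(30, 15) # 15 inclusion + 15 skipping molecules -> PSI 50
#' @export
compute_psi <- function(inclusive, exclusive, min_informative = 10) {
  if (any(inclusive < 0, na.rm = TRUE) || any(exclusive < 0, na.rm = TRUE)) {
    abort("junction counts must be non-negative",
      class = "spliceamp_invariant_error")
  }
  n <- max(length(inclusive), length(exclusive))
  inclusive <- rep_len(inclusive, n)
  exclusive <- rep_len(exclusive, n)
  informative <- 0.5 * inclusive + exclusive
  psi <- ifelse(informative > 0, 100 * (0.5 * inclusive) / informative,
    NA_real_)
  tibble(
    psi = psi,
    exclusion = 100 - psi,
    informative_reads = informative,
    flag = ifelse(informative < min_informative, "low_coverage", "ok")
  )
}

#' Per-sample, per-event PSI table
#'
#' Applies [compute_psi()] to a junction-count table (split or combined
#' dialect; the inclusive total is `incl_up + incl_down`).
#'
#' @param junctions Junction tibble as returned by [read_junctions()] or
#'   the simulator.
#' @param min_informative Passed to [compute_psi()].
#' @return A tibble with `sample_id`, `event_id`, `psi`, `exclusion`,
#'   `informative_reads`, `flag`.
#' @export
psi_table <- function(junctions, min_informative = 10) {
  est <- compute_psi(
    junctions$incl_up + junctions$incl_down, junctions$excl,
    min_informative = min_informative
  )
  bind_cols(junctions[c("sample_id", "event_id")], est)
}

#' Replicate-averaged PSI per tissue
#'
#' PSI is computed per replicate and then arithmetically averaged within
#' each tissue (never by pooling reads across replicates). Undefined PSIs
#' are excluded from the mean, not zero-filled.
#'
#' @param psi PSI table from [psi_table()].
#' @param samples Sample metadata tibble.
#' @return A tibble with `tissue`, `tissue_group`, `event_id`, `psi_mean`,
#'   `n_replicates`.
#' @export
psi_by_tissue <- function(psi, samples) {
  psi %>%
    inner_join(samples, by = "sample_id") %>%
    group_by(tissue, tissue_group, event_id) %>%
    summarise(
      psi_mean = mean(psi, na.rm = TRUE),
      n_replicates = sum(!is.na(psi)),
      .groups = "drop"
    )
}

#' Conditional exon-10 inclusion given exon-8 status
#'
#' From the four joint isoform abundances (E8+E10+, E8+E10-, E8-E10+,
#' E8-E10-) computes the percentage of exon 10 inclusion within
#' exon-8-containing transcripts, within exon-8-skipping transcripts, and
#' the two marginals. Abundances may be real-valued (densitometry-style
#' inputs). A conditional with a zero denominator is `NA`.
#'
#' @param n_pp,n_pm,n_mp,n_mm Non-negative abundances of E8+E10+, E8+E10-,
#'   E8-E10+, E8-E10-.
#' @return A tibble with `e10_given_e8plus`, `e10_given_e8minus`,
#'   `marginal_e8`, `marginal_e10` (all percentages).
#' @export
conditional_inclusion <- function(n_pp, n_pm, n_mp, n_mm) {
  if (any(c(n_pp, n_pm, n_mp, n_mm) < 0)) {
    abort("isoform abundances must be non-negative",
      class = "spliceamp_invariant_error")
  }
  total <- n_pp + n_pm + n_mp + n_mm
  if (any(total <= 0)) {
    abort("at least one isoform abundance must be positive",
      class = "spliceamp_invariant_error")
  }
  safe_pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  tibble(
    e10_given_e8plus = safe_pct(n_pp, n_pp + n_pm),
    e10_given_e8minus = safe_pct(n_mp, n_mp + n_mm),
    marginal_e8 = 100 * (n_pp + n_pm) / total,
    marginal_e10 = 100 * (n_pp + n_mp) / total
  )
}

#' NMD-isoform normalization ratio
#'
#' Ratio of the NMD-sensitive isoform level to the non-NMD isoform level
#' within a sample; the standard normalization for NMD-inhibition assays.
#'
#' @param nmd_level Abundance of the NMD-sensitive (inclusion) isoform.
#' @param non_nmd_level Abundance of the productive isoform; must be > 0.
#' @return The ratio (vectorized).
#' @export
nmd_ratio <- function(nmd_level, non_nmd_level) {
  if (any(non_nmd_level <= 0)) {
    abort("non-NMD isoform level must be positive",
      class = "spliceamp_invariant_error")
  }
  if (any(nmd_level < 0)) {
    abort("NMD isoform level must be non-negative",
      class = "spliceamp_invariant_error")
  }
  nmd_level / non_nmd_level
}

#' Fold change of the NMD ratio between two conditions
#'
#' The ratio-of-ratios statistic used to quantify NMD-isoform stabilization
#' when NMD is compromised (e.g. NMD-factor knockout vs control): the
#' normalized NMD-isoform ratio in the case divided by the same ratio in
#' the control.
#'
#' @param ratio_case NMD ratio in the NMD-deficient condition.
#' @param ratio_control NMD ratio in the control condition; must be > 0.
#' @return The fold change (vectorized).
#' @export
nmd_fold_change <- function(ratio_case, ratio_control) {
  if (any(ratio_control <= 0)) {
    abort("control NMD ratio must be positive",
      class = "spliceamp_invariant_error")
  }
  ratio_case / ratio_control
}
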