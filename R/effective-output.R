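# Isoform-level decomposition of steady-state TPM, the NMD degradation
# factor, NMD-corrected transcriptional output, and group fold changes.

#' Isoform-level expression from total TPM and PSI
#'
#' Splits steady-state gene TPM by splicing ratio. In
#' `exclusion_productive` mode the result is the productive (NMD-escaping,
#' exon-skipping) isoform level, `TPM * (100 - psi) / 100`; in
#' `inclusion_coding` mode it is the inclusion (long, protein-coding)
#' isoform level, `TPM * psi / 100`. Undefined PSIs yield `NA`.
#'
#' @param total_tpm Steady-state gene-level TPM (vector).
#' @param psi PSI percentage in `[0, 100]` for the relevant event.
#' @param mode `"exclusion_productive"` or `"inclusion_coding"`.
#' @return Isoform-level TPM (vector).
#' @examples
#' isoform_tpm(100, 15, "exclusion_productive") # 85
#' isoform_tpm(10, 96, "inclusion_coding") # 9.6
#' @export
isoform_tpm <- function(total_tpm,
                        psi,
                        mode = c("exclusion_productive", "inclusion_coding")) {
  mode <- match.arg(mode)
  if (any(total_tpm < 0, na.rm = TRUE)) {
    abort("total_tpm must be non-negative", class = "spliceamp_invariant_error")
  }
  if (any(psi < 0 | psi > 100, na.rm = TRUE)) {
    abort("psi must be within [0, 100]", class = "spliceamp_invariant_error")
  }
  if (mode == "exclusion_productive") {
    total_tpm * (100 - psi) / 100
  } else {
    total_tpm * psi / 100
  }
}

#' Estimate the NMD degradation factor
#'
#' The degradation factor (lambda) is the fold by which the NMD-sensitive
#' isoform is degraded relative to the productive isoform at steady state.
#' It is estimated by aggregating NMD-isoform fold changes observed in
#' NMD-deficient vs control contrasts (see [nmd_fold_change()]); the
#' default aggregation is the geometric mean, which treats the fold
#' changes on their natural ratio scale.
#'
#' @param fold_changes Positive fold changes, one per contrast.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return A list of class `degradation_factor` with elements `lambda`,
#'   `method`, and `inputs`.
#' @examples
#' estimate_degradation_factor(c(8.7, 6.8)) # lambda ~ 7.7
#' @export
estimate_degradation_factor <- function(fold_changes,
                                        method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(fold_changes) == 0) {
    abort("fold_changes must be non-empty", class = "spliceamp_invariant_error")
  }
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    abort("fold_changes must all be positive and finite",
      class = "spliceamp_invariant_error")
  }
  lambda <- if (method == "geometric") {
    exp(mean(log(fold_changes)))
  } else {
    mean(fold_changes)
  }
  structure(
    list(lambda = lambda, method = method, inputs = fold_changes),
    class = "degradation_factor"
  )
}

#' @export
print.degradation_factor <- function(x, ...) {
  cat(
    "NMD degradation factor lambda =", format(x$lambda, digits = 4),
    "(", x$method, "mean of", length(x$inputs), "fold change(s) )\n"
  )
  invisible(x)
}

as_lambda <- function(lambda) {
  if (inherits(lambda, "degradation_factor")) lambda$lambda else lambda
}

#' NMD-corrected transcriptional output
#'
#' Reconstructs the transcription level implied by steady-state
#' measurements if the NMD isoform had not been degraded lambda-fold:
#' \deqn{output = productive + \lambda (total - productive)}
#' The correction is linear, so it commutes with group averaging: the
#' corrected output of group means equals the group mean of per-sample
#' corrected outputs.
#'
#' @param total_tpm Steady-state total TPM (vector).
#' @param productive_tpm Productive-isoform TPM, `<= total_tpm`.
#' @param lambda Degradation factor (`>= 1`), a number or a
#'   `degradation_factor` object.
#' @return Corrected transcriptional output in TPM units.
#' @examples
#' corrected_output(68.5, 35.6, 7.7) # ~ 288.9
#' @export
corrected_output <- function(total_tpm, productive_tpm, lambda) {
  lambda <- as_lambda(lambda)
  if (lambda < 1) {
    abort("lambda must be >= 1", class = "spliceamp_invariant_error")
  }
  if (any(productive_tpm > total_tpm, na.rm = TRUE)) {
    abort("productive_tpm cannot exceed total_tpm",
      class = "spliceamp_invariant_error")
  }
  if (any(productive_tpm < 0, na.rm = TRUE)) {
    abort("productive_tpm must be non-negative",
      class = "spliceamp_invariant_error")
  }
  productive_tpm + lambda * (total_tpm - productive_tpm)
}

#' Group fold change of a metric
#'
#' Ratio of arithmetic group means (each value typically a
#' replicate-averaged per-tissue metric). Reported at full precision plus
#' the usual reporting precisions: nearest fold and nearest ten-fold.
#'
#' @param values_a,values_b Non-empty numeric vectors; `mean(values_b)`
#'   must be positive.
#' @param metric Optional metric label carried into the result.
#' @return A one-row tibble with `metric`, `mean_a`, `mean_b`, `fold`,
#'   `fold_nearest`, `fold_nearest_ten`.
#' @export
group_fold_change <- function(values_a, values_b, metric = "") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must be non-empty", class = "spliceamp_invariant_error")
  }
  mean_a <- mean(values_a)
  mean_b <- mean(values_b)
  if (mean_b <= 0) {
    abort("denominator group mean must be positive",
      class = "spliceamp_invariant_error")
  }
  fold <- mean_a / mean_b
  tibble(
    metric = metric,
    mean_a = mean_a,
    mean_b = mean_b,
    fold = fold,
    fold_nearest = round(fold),
    fold_nearest_ten = 10 * round(fold / 10)
  )
}

#' Per-sample isoform-output decomposition
#'
#' Joins expression and PSI tables and decomposes each sample's
#' steady-state TPM into the productive (NMD-exon-skipping) isoform, the
#' NMD isoform, and the long protein-coding (coding-exon-including)
#' isoform, then adds the NMD-corrected transcriptional output.
#'
#' @param expression Expression tibble (`sample_id`, `gene_id`, `tpm`).
#' @param psi PSI table from [psi_table()] holding both events.
#' @param lambda Degradation factor (number or `degradation_factor`).
#' @param nmd_event,coding_event Event identifiers of the NMD-on-inclusion
#'   event and the frameshift-on-skipping coding event.
#' @return A tibble with per-sample `total_tpm`, `productive_tpm`,
#'   `nmd_tpm`, `coding_long_tpm`, `corrected_output`.
#' @export
isoform_output <- function(expression, psi, lambda,
                           nmd_event = "E8", coding_event = "E10") {
  lambda <- as_lambda(lambda)
  wide <- psi %>%
    filter(event_id %in% c(nmd_event, coding_event)) %>%
    select(sample_id, event_id, psi) %>%
    tidyr::pivot_wider(names_from = event_id, values_from = psi)
  for (ev in c(nmd_event, coding_event)) {
    if (!ev %in% names(wide)) {
      abort(paste0("PSI table has no event '", ev, "'"),
        class = "spliceamp_invariant_error")
    }
  }
  expression %>%
    inner_join(wide, by = "sample_id") %>%
    mutate(
      total_tpm = tpm,
      productive_tpm = isoform_tpm(tpm, .data[[nmd_event]],
        "exclusion_productive"),
      nmd_tpm = total_tpm - productive_tpm,
      coding_long_tpm = isoform_tpm(tpm, .data[[coding_event]],
        "inclusion_coding"),
      corrected_output = corrected_output(total_tpm, productive_tpm, lambda)
    ) %>%
    select(
      sample_id, gene_id, total_tpm, productive_tpm, nmd_tpm,
      coding_long_tpm, corrected_output
    )
}
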