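# Published reference values for the mouse Trim46 tissue-panel analysis
# and the reconstruction of its effective-output arithmetic.

#' Published Trim46 reference values
#'
#' Group-level summaries reported for the mouse Trim46 analysis of the
#' ENCODE adult-tissue RNA-seq panel and the associated NMD-knockout and
#' protein-stability experiments:
#' steady-state total TPM (brain 68.5, non-neural 8.0), productive exon 8-
#' isoform TPM (35.6 vs 0.9), coding exon 10+ isoform TPM (66 vs 1.5),
#' exon 10 PSI (96 vs 27), NMD-isoform fold changes in Upf2 knockout
#' neocortex (8.7 at E14.5, 6.8 at P1), the reported degradation factor
#' 7.7, the reported corrected transcriptional outputs (288 brain, 56
#' non-neural), and the protein half-lives (TRIM46S 1.9 h, TRIM46L
#' 4.3 h).
#'
#' @return A named list of reference constants.
#' @export
trim46_reference <- function() {
  list(
    group_means = tibble(
      metric = c("total_tpm", "productive_tpm", "coding_long_tpm"),
      brain = c(68.5, 35.6, 66),
      non_neural = c(8.0, 0.9, 1.5)
    ),
    psi10_mean = c(brain = 96, non_neural = 27),
    nmd_ko_folds = c(E14.5 = 8.7, P1 = 6.8),
    lambda_reported = 7.7,
    corrected_reported = c(brain = 288, non_neural = 56),
    half_lives = c(TRIM46S = 1.9, TRIM46L = 4.3)
  )
}

#' Reconstruct the reference effective-output arithmetic
#'
#' Runs the package's effective-output operations on the published group
#' means: estimates the degradation factor from the two NMD-knockout fold
#' changes, reconstructs the NMD-corrected transcriptional output for
#' brain and non-neural tissues, and forms the group fold changes for the
#' total, productive, coding-long, and corrected metrics. Full-precision
#' values are reported alongside the conventional reporting precisions.
#'
#' @param lambda_method Aggregation for the degradation factor.
#' @return A list with `lambda` (a `degradation_factor`), `corrected`
#'   (named vector, TPM), and `folds` (tibble from
#'   [group_fold_change()]).
#' @examples
#' reference_output_analysis()$corrected # ~ 288.9 and 55.6
#' @export
reference_output_analysis <- function(lambda_method = "geometric") {
  ref <- trim46_reference()
  lambda <- estimate_degradation_factor(ref$nmd_ko_folds,
    method = lambda_method)
  # The corrected outputs are reconstructed with the reported one-decimal
  # degradation factor, matching how the published estimates were formed;
  # the full-precision estimate is returned alongside in `lambda`.
  lambda_use <- round(lambda$lambda, 1)
  gm <- ref$group_means
  total <- unlist(gm[gm$metric == "total_tpm", c("brain", "non_neural")])
  productive <- unlist(
    gm[gm$metric == "productive_tpm", c("brain", "non_neural")]
  )
  coding <- unlist(
    gm[gm$metric == "coding_long_tpm", c("brain", "non_neural")]
  )
  corrected <- corrected_output(total, productive, lambda_use)
  folds <- bind_rows(
    group_fold_change(total[["brain"]], total[["non_neural"]],
      "total_tpm"),
    group_fold_change(productive[["brain"]], productive[["non_neural"]],
      "productive_tpm"),
    group_fold_change(coding[["brain"]], coding[["non_neural"]],
      "coding_long_tpm"),
    group_fold_change(corrected[["brain"]], corrected[["non_neural"]],
      "corrected_output")
  )
  list(lambda = lambda, corrected = corrected, folds = folds)
}
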