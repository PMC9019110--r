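# Tissue-specificity index tau over a log2 tissue panel with
# neural-tissue collapsing.

#' Build a log2 tissue panel with brain collapsing
#'
#' Transforms per-tissue linear values to `log2(value + pseudocount)` and
#' replaces the named brain tissues by a single `brain` entry holding the
#' arithmetic mean of their log-transformed values (mean of logs, not log
#' of mean). Non-brain tissues are kept unchanged apart from the log
#' transform.
#'
#' @param values Named numeric vector: tissue -> linear (e.g. TPM) value.
#' @param brain_tissues Character vector of tissue names to collapse; may
#'   be empty. Every name must be present in `values`.
#' @param pseudocount Added inside the log; default 1.
#' @return A tibble with columns `tissue` and `x` (log2 scale).
#' @export
collapse_brain <- function(values, brain_tissues = character(),
                           pseudocount = 1) {
  if (is.null(names(values)) || any(names(values) == "")) {
    abort("values must be a named vector (tissue -> value)",
      class = "spliceamp_schema_error")
  }
  missing <- setdiff(brain_tissues, names(values))
  if (length(missing) > 0) {
    abort(paste0("brain tissue absent from panel: ", missing[1]),
      class = "spliceamp_invariant_error")
  }
  x <- log2(values + pseudocount)
  if (length(brain_tissues) > 0) {
    brain_x <- mean(x[brain_tissues])
    x <- x[!names(x) %in% brain_tissues]
    x <- c(setNames(brain_x, "brain"), x)
  }
  tibble(tissue = names(x), x = unname(x))
}

#' Tissue-specificity index tau
#'
#' \deqn{\tau = \frac{\sum_i (1 - \hat x_i)}{n - 1}, \qquad
#'   \hat x_i = \frac{x_i}{\max_i x_i}}
#' over `n >= 2` tissues, with `x_i` the (log-scale, non-negative)
#' expression in tissue i. `tau = 1` means expression confined to a single
#' tissue; `tau = 0` means uniform expression. A gene silent in every
#' tissue (`max(x) = 0`) is assigned `tau = 0` with `silent = TRUE`.
#'
#' @param panel A tibble from [collapse_brain()] (columns `tissue`, `x`)
#'   or a plain numeric vector of panel values.
#' @return A list with `tau`, `n`, and `silent`.
#' @examples
#' tau(c(4, 2, 2))$tau # 0.5
#' @export
tau <- function(panel) {
  x <- if (is.data.frame(panel)) panel$x else panel
  n <- length(x)
  if (n < 2) {
    abort("tau requires at least two tissues",
      class = "spliceamp_invariant_error")
  }
  if (any(x < 0)) {
    abort("panel values must be non-negative (log2 of value + pseudocount)",
      class = "spliceamp_invariant_error")
  }
  mx <- max(x)
  if (mx == 0) {
    return(list(tau = 0, n = n, silent = TRUE))
  }
  list(tau = sum(1 - x / mx) / (n - 1), n = n, silent = FALSE)
}

#' Specificity report across metrics
#'
#' Computes tau for several metrics measured over the same tissue panel
#' (after identical brain collapsing), plus all pairwise tau differences.
#'
#' @param metrics Named list of named numeric vectors (metric -> per-tissue
#'   linear values). All vectors must cover the same tissue set.
#' @param brain_tissues,pseudocount Passed to [collapse_brain()].
#' @return A list with `tau` (tibble: `metric`, `tau`, `n_tissues`,
#'   `silent`, `pseudocount`, `collapsed_brain`) and `differences`
#'   (tibble of pairwise `tau_a - tau_b`).
#' @export
specificity_report <- function(metrics, brain_tissues = character(),
                               pseudocount = 1) {
  if (length(metrics) == 0 || is.null(names(metrics))) {
    abort("metrics must be a non-empty named list",
      class = "spliceamp_schema_error")
  }
  tissue_sets <- lapply(metrics, function(v) sort(names(v)))
  if (!all(vapply(tissue_sets, identical, logical(1), y = tissue_sets[[1]]))) {
    abort("all metrics must share the same tissue set",
      class = "spliceamp_invariant_error")
  }
  taus <- lapply(names(metrics), function(m) {
    res <- tau(collapse_brain(metrics[[m]], brain_tissues, pseudocount))
    tibble(
      metric = m, tau = res$tau, n_tissues = res$n, silent = res$silent,
      pseudocount = pseudocount,
      collapsed_brain = length(brain_tissues) > 0
    )
  })
  tau_tbl <- bind_rows(taus)
  pairs <- utils::combn(tau_tbl$metric, 2, simplify = FALSE)
  diff_tbl <- bind_rows(lapply(pairs, function(p) {
    tibble(
      metric_a = p[1], metric_b = p[2],
      tau_diff = tau_tbl$tau[tau_tbl$metric == p[1]] -
        tau_tbl$tau[tau_tbl$metric == p[2]]
    )
  }))
  list(tau = tau_tbl, differences = diff_tbl)
}
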