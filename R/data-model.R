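# Table readers, validation, and report writers shared by all pipeline stages.
#
# All on-disk tables are UTF-8 TSV with a mandatory header; missing values are
# the literal "NA". Event coordinates are 0-based half-open (BED convention).

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "spliceamp_io_error")
  }
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(
        "table ", path, " is missing required column(s): ",
        paste(missing, collapse = ", ")
      ),
      class = "spliceamp_schema_error"
    )
  }
}

# Row-addressed invariant check on a numeric column.
check_nonneg <- function(df, col, path, integer = FALSE) {
  v <- df[[col]]
  if (!is.numeric(v)) {
    abort(paste0("column '", col, "' in ", path, " is not numeric"),
      class = "spliceamp_schema_error"
    )
  }
  bad <- which(is.na(v) | v < 0 | (integer & v != floor(v)))
  if (length(bad) > 0) {
    abort(
      paste0(
        "invalid value in column '", col, "' of ", path, " at row ",
        bad[1], ": must be a non-negative ",
        if (integer) "integer" else "number"
      ),
      class = "spliceamp_invariant_error"
    )
  }
  invisible(df)
}

#' Read cassette-exon event definitions
#'
#' Events are stored BED-like: `chrom`, `start`, `end`, `event_id`,
#' `gene_id`, `strand`, plus two boolean flags. `nmd_on_inclusion` marks
#' events whose inclusion introduces a premature termination codon (the
#' exon-8-like NMD exon); `frameshift_on_skipping` marks events whose
#' skipping changes the C-terminal reading frame (the exon-10-like coding
#' exon). Coordinates are 0-based half-open. Strand is stored but not used
#' in any computation: junction counts arrive pre-oriented.
#'
#' @param path Path to a tab-separated event table with a header row.
#' @return A tibble with one row per event.
#' @export
read_events <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c(
    "chrom", "start", "end", "event_id", "gene_id", "strand",
    "nmd_on_inclusion", "frameshift_on_skipping"
  ), path)
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    abort(paste0("event table ", path, " row ", bad[1],
      ": start must be < end"), class = "spliceamp_invariant_error")
  }
  if (anyDuplicated(df[c("gene_id", "event_id")]) > 0) {
    abort(paste0("duplicate (gene_id, event_id) in ", path),
      class = "spliceamp_invariant_error"
    )
  }
  df$nmd_on_inclusion <- as.logical(df$nmd_on_inclusion)
  df$frameshift_on_skipping <- as.logical(df$frameshift_on_skipping)
  as_tibble(df)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `tissue`, `tissue_group` (one of `neural`,
#' `non_neural`), `condition`, `stage`, `replicate`. Sample identifiers
#' must be unique and every tissue must map to exactly one tissue group.
#'
#' @param path Path to a tab-separated sample table.
#' @return A tibble with one row per sample.
#' @export
read_samples <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c(
    "sample_id", "tissue", "tissue_group", "condition", "stage", "replicate"
  ), path)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id in ", path, ": ", dup[1]),
      class = "spliceamp_invariant_error"
    )
  }
  grp <- unique(df[c("tissue", "tissue_group")])
  multi <- grp$tissue[duplicated(grp$tissue)]
  if (length(multi) > 0) {
    abort(
      paste0("tissue '", multi[1], "' in ", path,
        " maps to more than one tissue_group"),
      class = "spliceamp_invariant_error"
    )
  }
  check_nonneg(df, "replicate", path, integer = TRUE)
  as_tibble(df)
}

#' Read per-sample junction counts
#'
#' Two dialects are accepted. The split dialect has columns `incl_up`,
#' `incl_down`, `excl` (reads spanning the upstream-exon to cassette
#' junction, cassette to downstream junction, and the skipping junction).
#' The combined dialect has a single `inclusive` column holding the total
#' inclusive junction reads; it is stored as `incl_up` with `incl_down = 0`
#' and `combined = TRUE`.
#'
#' @param path Path to a tab-separated junction-count table.
#' @param samples Optional sample-metadata tibble; when supplied, every
#'   `sample_id` in the junction table must exist in it.
#' @return A tibble with columns `sample_id`, `event_id`, `incl_up`,
#'   `incl_down`, `excl`, `combined`.
#' @export
read_junctions <- function(path, samples = NULL) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample_id", "event_id"), path)
  if (all(c("incl_up", "incl_down") %in% names(df))) {
    require_columns(df, c("incl_up", "incl_down", "excl"), path)
    check_nonneg(df, "incl_up", path, integer = TRUE)
    check_nonneg(df, "incl_down", path, integer = TRUE)
    df$combined <- FALSE
  } else if ("inclusive" %in% names(df)) {
    require_columns(df, c("inclusive", "excl"), path)
    check_nonneg(df, "inclusive", path, integer = TRUE)
    df$incl_up <- df$inclusive
    df$incl_down <- 0
    df$inclusive <- NULL
    df$combined <- TRUE
  } else {
    abort(
      paste0(
        "junction table ", path,
        " must have either (incl_up, incl_down, excl) or (inclusive, excl)"
      ),
      class = "spliceamp_schema_error"
    )
  }
  check_nonneg(df, "excl", path, integer = TRUE)
  check_sample_refs(df, samples, path)
  as_tibble(df)[c(
    "sample_id", "event_id", "incl_up", "incl_down", "excl", "combined"
  )]
}

#' Read gene-level expression
#'
#' Expects columns `sample_id`, `gene_id`, `tpm` (transcripts per million,
#' non-negative).
#'
#' @inheritParams read_junctions
#' @return A tibble with one row per (sample, gene).
#' @export
read_expression <- function(path, samples = NULL) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample_id", "gene_id", "tpm"), path)
  check_nonneg(df, "tpm", path)
  check_sample_refs(df, samples, path)
  as_tibble(df)
}

check_sample_refs <- function(df, samples, path) {
  if (is.null(samples)) {
    return(invisible(df))
  }
  unknown <- setdiff(unique(df$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(
      paste0("table ", path, " references sample_id '", unknown[1],
        "' absent from sample metadata"),
      class = "spliceamp_invariant_error"
    )
  }
  invisible(df)
}

#' Read a run configuration
#'
#' Reads a YAML key-value file and merges it over the package defaults:
#' `min_informative_reads` (10), `lambda_method` ("geometric"),
#' `log_pseudocount` (1), `brain_tissues` (required for specificity
#' analyses of real panels, hence no default set), `seed`, `output_dir`.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    min_informative_reads = 10,
    lambda_method = "geometric",
    log_pseudocount = 1,
    brain_tissues = character(),
    seed = 1L,
    output_dir = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  if (cfg$min_informative_reads < 1) {
    abort("min_informative_reads must be >= 1",
      class = "spliceamp_invariant_error")
  }
  if (cfg$log_pseudocount <= 0) {
    abort("log_pseudocount must be > 0", class = "spliceamp_invariant_error")
  }
  if (!cfg$lambda_method %in% c("geometric", "arithmetic")) {
    abort("lambda_method must be 'geometric' or 'arithmetic'",
      class = "spliceamp_invariant_error")
  }
  cfg
}

#' Write a stage result to disk
#'
#' Data frames are written as CSV; lists as JSON. Numeric fields keep full
#' double precision so that a write/read round trip reproduces values to at
#' least 12 significant digits. Writing an empty result is an error, not an
#' empty file.
#'
#' @param results A non-empty data frame or list.
#' @param path Output path; the extension (.csv or .json) selects the format.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.data.frame(results)) {
    if (nrow(results) == 0) {
      abort("refusing to write an empty result table",
        class = "spliceamp_invariant_error")
    }
    # Doubles are serialized at 12 significant digits: enough to round
    # trip values, and stable so that write -> read -> write is
    # byte-identical.
    out <- results
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        v <- out[[col]]
        out[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.12g", v))
      }
    }
    readr::write_csv(out, path, progress = FALSE)
  } else if (is.list(results)) {
    if (length(results) == 0) {
      abort("refusing to write an empty result list",
        class = "spliceamp_invariant_error")
    }
    jsonlite::write_json(results, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  } else {
    abort("results must be a data frame or a list",
      class = "spliceamp_schema_error")
  }
  invisible(path)
}

#' Read back a CSV report
#'
#' @param path Path written by [write_report()].
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}
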