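# In-code fixtures: small well-formed tables written to tempfiles.

write_fixture <- function(text, name) {
  path <- file.path(tempfile(), name)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(text, path)
  path
}

fixture_samples <- function() {
  write_fixture(c(
    "sample_id\ttissue\ttissue_group\tcondition\tstage\treplicate",
    "ctx_1\tcortex\tneural\tWT\tadult\t1",
    "ctx_2\tcortex\tneural\tWT\tadult\t2",
    "liv_1\tliver\tnon_neural\tWT\tadult\t1"
  ), "samples.tsv")
}

fixture_junctions_split <- function() {
  write_fixture(c(
    "sample_id\tevent_id\tincl_up\tincl_down\texcl",
    "ctx_1\tE8\t10\t12\t30",
    "ctx_2\tE8\t8\t9\t25",
    "liv_1\tE8\t40\t38\t2"
  ), "junctions.tsv")
}

fixture_junctions_combined <- function() {
  write_fixture(c(
    "sample_id\tevent_id\tinclusive\texcl",
    "ctx_1\tE8\t22\t30",
    "liv_1\tE8\t78\t2"
  ), "junctions_combined.tsv")
}

fixture_expression <- function() {
  write_fixture(c(
    "sample_id\tgene_id\ttpm",
    "ctx_1\tTrim46\t70.25",
    "ctx_2\tTrim46\t66.75",
    "liv_1\tTrim46\t8.5"
  ), "expression.tsv")
}

fixture_events <- function() {
  write_fixture(c(
    paste("chrom", "start", "end", "event_id", "gene_id", "strand",
      "nmd_on_inclusion", "frameshift_on_skipping", sep = "\t"),
    "chr3\t89000100\t89000250\tE8\tTrim46\t+\tTRUE\tFALSE",
    "chr3\t89002000\t89002120\tE10\tTrim46\t+\tFALSE\tTRUE"
  ), "events.tsv")
}
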