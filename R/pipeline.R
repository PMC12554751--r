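#' Run the full enrichment-analysis pipeline
#'
#' Orchestrates tally -> clone table -> matrices -> selection on a manifest
#' of merged-read files, writing every intermediate artifact plus a
#' machine-readable run manifest. Matrices and frequencies are built from
#' the permissive replicate-common table ("common in all replicates of at
#' least one round"); clone scoring is restricted to the stricter candidate
#' set ("common in all replicates of every round except the terminal one",
#' presence in the terminal round optional) — clones may legitimately be
#' unobserved in the terminal round and still be scored.
#'
#' The log reports the campaign's milestone counts: reads kept per sample,
#' clones in the permissive set, clones in the candidate set, top-K overlap
#' size and final selection size after the cysteine filter.
#'
#' @param manifest Path to a sample manifest (see [read_manifest()]) or the
#'   tibble it returns.
#' @param output_dir Directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @param pserm_pairs,k,background,exclude_wt Passed to [select_clones()].
#' @param required_rounds Rounds in which candidates must appear in all
#'   replicates (default: all but the terminal round).
#' @param wt_string Wild-type mutation string; defaults to the manifest's
#'   `wt_string`, else the most frequent clone in the terminal round (with a
#'   message).
#' @param verbose Log progress and milestone counts.
#' @return The `selection_report`, with attributes `clone_table`
#'   (permissive), `candidates` (strict table) and `paths` (written files).
#' @export
run_pipeline <- function(manifest, output_dir = NULL, pserm_pairs = NULL,
                         k = 40L, background = 0.05,
                         required_rounds = NULL, exclude_wt = TRUE,
                         wt_string = NULL, verbose = TRUE) {
  if (is.character(manifest)) {
    manifest_path <- manifest
    manifest <- read_manifest(manifest)
  } else manifest_path <- NULL
  rounds <- attr(manifest, "rounds")
  tallies <- tally_manifest(manifest, verbose = verbose)

  wt_string <- wt_string %||% attr(manifest, "wt_string")
  table_all <- clone_table(tallies, rounds = rounds, wt_string = wt_string,
                           filter = "common_any_round")
  if (is.null(wt_string)) {
    wt_string <- table_all$clones$mutation_string[[1L]]
    table_all$wt_string <- wt_string
    if (verbose) inform(sprintf(
      "no wild type declared; using the most frequent terminal-round clone %s",
      wt_string))
  }
  table_cand <- clone_table(tallies, rounds = rounds, wt_string = wt_string,
                            filter = "common_required_rounds",
                            required_rounds = required_rounds)
  if (verbose) {
    inform(sprintf(
      "replicate-common clones: %d; candidates common to required rounds: %d",
      nrow(table_all$clones), nrow(table_cand$clones)))
  }

  report <- select_clones(table_all, pserm_pairs = pserm_pairs,
                          candidates = table_cand, k = k,
                          background = background, exclude_wt = exclude_wt)
  if (verbose) {
    inform(sprintf(
      "top-%d overlap: %d clones; removed for unpaired cysteine: %d; selected: %d",
      report$k, length(report$overlap), length(report$removed_cysteine),
      length(report$final)))
  }

  paths <- character(0L)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(output_dir, ...)
    write_clone_table(table_all, p("clone_table.tsv"))
    write_clone_table(table_cand, p("clone_table_candidates.tsv"))
    for (m in report$pserms) {
      write_position_matrix(m, p(paste0(matrix_label(m), ".tsv")))
    }
    for (r in unique(unlist(pserm_pairs %||%
                            lapply(report$pserms, function(m)
                              c(attr(m, "late"), attr(m, "early")))))) {
      write_position_matrix(round_pssm(table_all, r, background),
                            p(sprintf("pssm_%s.tsv", r)))
    }
    write_selection_report(report, p("selection_report.tsv"),
                           p("selection_summary.json"))
    run_meta <- list(
      package = as.character(utils::packageVersion("pserm")),
      manifest = manifest_path,
      input_md5 = as.list(tools::md5sum(manifest$file)),
      config = list(k = k, background = background,
                    exclude_wt = exclude_wt, rounds = rounds,
                    required_rounds = required_rounds %||%
                      head(rounds, -1L),
                    wt_string = wt_string)
    )
    jsonlite::write_json(run_meta, p("run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- list.files(output_dir, full.names = TRUE)
  }
  attr(report, "clone_table") <- table_all
  attr(report, "candidates") <- table_cand
  attr(report, "qc") <- attr(tallies, "qc")
  attr(report, "paths") <- paths
  report
}
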