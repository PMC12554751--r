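#' Merge replicate tallies into a clone table
#'
#' The clone table is the central ledger of a sorting campaign: one row per
#' clone (mutation string), with per-(round, replicate) read counts and
#' per-round replicate-averaged frequencies. A clone's frequency in a
#' replicate is its count divided by the replicate's total QC-passing reads;
#' the per-round frequency `f_<round>` is the mean of the replicate
#' frequencies, with an unobserved (round, replicate) contributing zero.
#'
#' Two replicate-consistency filters are available:
#' \describe{
#'   \item{`"common_any_round"`}{keep clones observed in *all* replicates of
#'     at least one round — the permissive set used to build scoring
#'     matrices.}
#'   \item{`"common_required_rounds"`}{keep clones observed in all replicates
#'     of *every* round in `required_rounds` (presence in other rounds is not
#'     required) — the stricter candidate set used for clone scoring, which
#'     typically requires presence in every round but the terminal one.}
#' }
#' Totals are always computed from the unfiltered tallies, so frequencies do
#' not change when the filter drops clones.
#'
#' @param tallies Tibble of per-sample counts (`mutation_string`, `round`,
#'   `replicate`, `count`), e.g. from [tally_manifest()].
#' @param rounds Ordered character vector of round labels. Defaults to the
#'   `rounds` attribute of `tallies`, else the sorted unique labels.
#' @param wt_string The wild-type (parental) mutation string, or `NULL`.
#' @param filter Replicate-consistency filter (see above).
#' @param required_rounds Round labels that must contain the clone in all
#'   replicates under `"common_required_rounds"`. Defaults to all rounds but
#'   the last.
#' @return A `clone_table` object: a list with `clones` (wide tibble:
#'   `mutation_string`, `n_<round>_<rep>` counts, `f_<round>` frequencies,
#'   rows ordered by descending terminal-round frequency then
#'   lexicographically), `totals` (per-(round, replicate) read totals),
#'   `rounds`, `replicates`, `wt_string`, `filter`.
#' @export
clone_table <- function(tallies, rounds = NULL, wt_string = NULL,
                        filter = c("common_any_round", "common_required_rounds"),
                        required_rounds = NULL) {
  filter <- match.arg(filter)
  rounds <- rounds %||% attr(tallies, "rounds") %||% sort(unique(tallies$round))
  wt_string <- wt_string %||% attr(tallies, "wt_string")
  if (!all(tallies$round %in% rounds)) {
    abort("`tallies` contains round labels not in `rounds`")
  }
  tallies <- dplyr::filter(tallies, .data$count > 0L)
  replicates <- sort(unique(tallies$replicate))
  if (length(replicates) < 2L) {
    abort("at least 2 replicates per round are required to merge")
  }

  totals <- tallies |>
    dplyr::group_by(.data$round, .data$replicate) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    tidyr::complete(round = rounds, replicate = replicates,
                    fill = list(total = 0L)) |>
    dplyr::mutate(round = factor(.data$round, levels = rounds)) |>
    dplyr::arrange(.data$round, .data$replicate) |>
    dplyr::mutate(round = as.character(.data$round))

  # replicate-consistency filter
  presence <- tallies |>
    dplyr::distinct(.data$mutation_string, .data$round, .data$replicate) |>
    dplyr::group_by(.data$mutation_string, .data$round) |>
    dplyr::summarise(n_rep = dplyr::n(), .groups = "drop")
  n_rep_total <- length(replicates)
  keep <- switch(filter,
    common_any_round = presence |>
      dplyr::filter(.data$n_rep == n_rep_total) |>
      dplyr::distinct(.data$mutation_string),
    common_required_rounds = {
      required_rounds <- required_rounds %||% head(rounds, -1L)
      if (!all(required_rounds %in% rounds)) {
        abort("`required_rounds` must be a subset of `rounds`")
      }
      presence |>
        dplyr::filter(.data$round %in% required_rounds,
                      .data$n_rep == n_rep_total) |>
        dplyr::count(.data$mutation_string) |>
        dplyr::filter(.data$n == length(required_rounds)) |>
        dplyr::distinct(.data$mutation_string)
    }
  )

  kept <- dplyr::semi_join(tallies, keep, by = "mutation_string")
  check_mutation_strings(keep$mutation_string)

  counts_wide <- kept |>
    dplyr::mutate(col = paste0("n_", .data$round, "_", .data$replicate)) |>
    tidyr::pivot_wider(id_cols = "mutation_string", names_from = "col",
                       values_from = "count", values_fill = 0L)
  # ensure every (round, replicate) column exists, in round-major order
  all_cols <- paste0("n_", rep(rounds, each = n_rep_total), "_", replicates)
  for (cn in setdiff(all_cols, names(counts_wide))) counts_wide[[cn]] <- 0L
  counts_wide <- counts_wide[, c("mutation_string", all_cols)]

  tot <- setNames(totals$total, paste0(totals$round, "_", totals$replicate))
  for (r in rounds) {
    fr <- 0
    for (k in replicates) {
      tk <- tot[[paste0(r, "_", k)]]
      nk <- counts_wide[[paste0("n_", r, "_", k)]]
      fr <- fr + (if (tk > 0) nk / tk else 0)
    }
    counts_wide[[paste0("f_", r)]] <- fr / n_rep_total
  }

  terminal <- rounds[length(rounds)]
  counts_wide <- counts_wide |>
    dplyr::arrange(dplyr::desc(.data[[paste0("f_", terminal)]]),
                   .data$mutation_string)

  structure(
    list(clones = counts_wide, totals = totals, rounds = rounds,
         replicates = replicates, wt_string = wt_string, filter = filter),
    class = "clone_table"
  )
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("<clone_table> %d clones, rounds %s, %d replicates, filter '%s'\n",
              nrow(x$clones), paste(x$rounds, collapse = ","),
              length(x$replicates), x$filter))
  if (!is.null(x$wt_string)) cat(sprintf("  wild type: %s\n", x$wt_string))
  print(x$clones, n = 5)
  invisible(x)
}

#' @method as_tibble clone_table
#' @export
as_tibble.clone_table <- function(x, ...) x$clones

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clone table into long format
#'
#' @param x A `clone_table`.
#' @param ... Unused.
#' @return A long tibble: `mutation_string`, `round`, `replicate`, `count`,
#'   `freq` (the per-round replicate-averaged frequency, repeated across
#'   replicates).
#' @method tidy clone_table
#' @export
tidy.clone_table <- function(x, ...) {
  counts_long <- x$clones |>
    dplyr::select("mutation_string", dplyr::starts_with("n_")) |>
    tidyr::pivot_longer(dplyr::starts_with("n_"),
                        names_to = c("round", "replicate"),
                        names_pattern = "^n_(.+)_([0-9]+)$",
                        values_to = "count") |>
    dplyr::mutate(replicate = as.integer(.data$replicate))
  freqs_long <- x$clones |>
    dplyr::select("mutation_string", dplyr::starts_with("f_")) |>
    tidyr::pivot_longer(dplyr::starts_with("f_"), names_to = "round",
                        names_pattern = "^f_(.+)$", values_to = "freq")
  dplyr::left_join(counts_long, freqs_long,
                   by = c("mutation_string", "round"))
}

#' @describeIn clone_table Per-round summed (across replicates) counts for
#'   the clones of the table, as a named integer vector.
#' @param x A `clone_table`.
#' @param round A round label of `x`.
#' @export
round_counts <- function(x, round) {
  stopifnot(inherits(x, "clone_table"))
  if (!round %in% x$rounds) abort(sprintf("unknown round '%s'", round))
  cols <- paste0("n_", round, "_", x$replicates)
  setNames(as.integer(rowSums(x$clones[, cols, drop = FALSE])),
           x$clones$mutation_string)
}

#' @describeIn clone_table Per-round replicate-averaged frequencies, as a
#'   named numeric vector.
#' @export
round_freqs <- function(x, round) {
  stopifnot(inherits(x, "clone_table"))
  if (!round %in% x$rounds) abort(sprintf("unknown round '%s'", round))
  setNames(x$clones[[paste0("f_", round)]], x$clones$mutation_string)
}

#' Write / read a clone table as TSV
#'
#' The TSV holds the wide clone tibble; table-level metadata (round order,
#' replicate ids, per-sample read totals, wild type, filter) is stored in
#' `#key=value` comment lines before the header so the round trip is exact:
#' counts are integers and frequencies are written at full double precision.
#'
#' @param x A `clone_table`.
#' @param path Output path.
#' @return `write_clone_table()` returns `path` invisibly;
#'   `read_clone_table()` returns a `clone_table`.
#' @export
write_clone_table <- function(x, path) {
  stopifnot(inherits(x, "clone_table"))
  meta <- c(
    sprintf("#rounds=%s", paste(x$rounds, collapse = ",")),
    sprintf("#replicates=%s", paste(x$replicates, collapse = ",")),
    sprintf("#filter=%s", x$filter),
    if (!is.null(x$wt_string)) sprintf("#wt_string=%s", x$wt_string),
    sprintf("#total_%s_%s=%d", x$totals$round, x$totals$replicate,
            x$totals$total)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(x$clones), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x$clones, function(col) {
    if (is.double(col)) format(col, digits = 17, scientific = TRUE, trim = TRUE)
    else as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  lines <- readLines(path, n = 200L)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- stringr::str_match(meta_lines, "^#([^=]+)=(.*)$")
  vals <- setNames(as.list(meta[, 3L]), meta[, 2L])
  rounds <- strsplit(vals$rounds, ",", fixed = TRUE)[[1L]]
  replicates <- as.integer(strsplit(vals$replicates, ",", fixed = TRUE)[[1L]])
  tot_keys <- grep("^total_", names(vals), value = TRUE)
  tot_parts <- stringr::str_match(tot_keys, "^total_(.+)_([0-9]+)$")
  totals <- tibble(round = tot_parts[, 2L],
                   replicate = as.integer(tot_parts[, 3L]),
                   total = as.integer(unlist(vals[tot_keys])))
  clones <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  clones <- dplyr::mutate(clones, dplyr::across(dplyr::starts_with("n_"),
                                                as.integer))
  structure(
    list(clones = clones, totals = totals, rounds = rounds,
         replicates = replicates, wt_string = vals$wt_string %||% NULL,
         filter = vals$filter, path = path),
    class = "clone_table"
  )
}
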