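#' Score clones under a position matrix
#'
#' A clone's score under a PSSM or PSERM is the sum of the matrix entries at
#' its residues, one lookup per mutagenized position. Under a PSERM the
#' score is the summed per-site enrichment of the clone's residues between
#' the two rounds, in bits.
#'
#' @param strings Character vector of mutation strings (length = matrix
#'   columns).
#' @param m A `pssm` or `pserm` (any `position_matrix` works).
#' @return Named numeric vector of scores.
#' @export
score_clones <- function(strings, m) {
  check_mutation_strings(strings, L = ncol(m))
  if (length(strings) == 0L) return(setNames(numeric(), character()))
  chars <- string_matrix(strings, L = ncol(m))
  idx <- matrix(aa_index(as.vector(chars)), nrow = nrow(chars))
  if (any(idx == 0L)) abort("mutation string contains a residue not in the matrix")
  sc <- numeric(length(strings))
  for (j in seq_len(ncol(m))) sc <- sc + unclass(m)[cbind(idx[, j], j)]
  setNames(sc, strings)
}

#' Conventional frequency and enrichment-ratio metrics
#'
#' For each clone of the table: the replicate-averaged frequency in the
#' terminal round, the global enrichment ratio
#' `log2(f_terminal / f_early)` and the local enrichment ratio
#' `log2(f_terminal / f_prior)`. A ratio is undefined (`NA`) when either
#' frequency is zero; such clones are excluded from that metric's ranking
#' rather than imputed.
#'
#' @param x A [clone_table()].
#' @param terminal,early,prior Round labels; defaults are the last, first
#'   and second-to-last rounds of the table.
#' @return Tibble: `mutation_string`, `freq_terminal`, `global_er`,
#'   `local_er`.
#' @export
enrichment_metrics <- function(x, terminal = NULL, early = NULL,
                               prior = NULL) {
  stopifnot(inherits(x, "clone_table"))
  terminal <- terminal %||% x$rounds[length(x$rounds)]
  early <- early %||% x$rounds[1L]
  prior <- prior %||% x$rounds[length(x$rounds) - 1L]
  f_t <- round_freqs(x, terminal)
  f_e <- round_freqs(x, early)
  f_p <- round_freqs(x, prior)
  ratio <- function(num, den) ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
  tibble(
    mutation_string = x$clones$mutation_string,
    freq_terminal = unname(f_t),
    global_er = unname(ratio(f_t, f_e)),
    local_er = unname(ratio(f_t, f_p))
  )
}

#' Rank clones by a metric and keep the top K
#'
#' Descending order on the metric; clones with an undefined (`NA`) value are
#' excluded; ties are broken lexicographically on the mutation string so
#' rankings are deterministic.
#'
#' @param scores Tibble with a `mutation_string` column and the metric
#'   column.
#' @param metric Name of the metric column.
#' @param k Number of clones to keep (default 40).
#' @param exclude_wt Remove `wt_string` before ranking.
#' @param wt_string Wild-type mutation string (required if `exclude_wt`).
#' @return Tibble of at most `k` rows with a `rank` column prepended.
#' @export
rank_top_k <- function(scores, metric, k = 40L, exclude_wt = FALSE,
                       wt_string = NULL) {
  if (!metric %in% names(scores)) abort(sprintf("unknown metric '%s'", metric))
  out <- scores
  if (exclude_wt) {
    if (is.null(wt_string)) abort("`wt_string` needed when `exclude_wt = TRUE`")
    out <- dplyr::filter(out, .data$mutation_string != wt_string)
  }
  out |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::arrange(dplyr::desc(.data[[metric]]), .data$mutation_string) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}

#' Intersection of two top-K clone sets
#'
#' @param top_a,top_b Character vectors of mutation strings, or tibbles from
#'   [rank_top_k()].
#' @return Character vector (sorted) of clones present in both.
#' @export
overlap_selection <- function(top_a, top_b) {
  as_set <- function(x) if (is.data.frame(x)) x$mutation_string else x
  sort(intersect(as_set(top_a), as_set(top_b)))
}

#' Remove clones with an unpaired cysteine
#'
#' A cysteine introduced at a mutagenized CDR position has no disulfide
#' partner in the scaffold and is a developability liability; clones whose
#' mutation string contains a `C` are removed.
#'
#' @param strings Character vector of mutation strings.
#' @return List with `kept` and `removed` character vectors
#'   (`kept` + `removed` partition the input).
#' @export
cysteine_filter <- function(strings) {
  has_c <- grepl("C", strings, fixed = TRUE)
  list(kept = strings[!has_c], removed = strings[has_c])
}

#' Score, rank and select clones from a sorting campaign
#'
#' The full selection procedure: build the PSSMs and PSERMs for the
#' configured consecutive round pairs from `x`, score every candidate clone
#' under each PSERM and under the conventional metrics (terminal-round
#' frequency, global and local enrichment ratio), take the top `k` clones
#' per PSERM, intersect the two PSERM top-`k` sets, and remove clones
#' containing an unpaired cysteine.
#'
#' Matrices are built from `x` (typically the permissive replicate-common
#' table); scoring can be restricted to a stricter candidate set via
#' `candidates` (typically the clones observed in all replicates of every
#' non-terminal round).
#'
#' @param x A [clone_table()] used to build matrices and frequencies.
#' @param pserm_pairs List of two `c(late, early)` round-label pairs
#'   (default: the last two consecutive pairs of the round order).
#' @param candidates Optional character vector (or `clone_table`) giving the
#'   clones to score; defaults to all clones of `x`.
#' @param k Top-K cutoff per PSERM (default 40).
#' @param background PSSM background probability (default 0.05).
#' @param exclude_wt Exclude the wild-type clone from rankings (default
#'   `TRUE`); the wild type always contributes to matrix construction.
#' @param terminal,early,prior Round labels for the comparator metrics (see
#'   [enrichment_metrics()]).
#' @return A `selection_report`: list with `scores` (per-candidate tibble of
#'   all metric values), `pserms` (the two PSERM matrices), `top_k` (named
#'   list of top-K tibbles per metric), `overlap`, `removed_cysteine`,
#'   `final` (character vectors), plus `k`, `exclude_wt`, `wt_string`.
#' @export
select_clones <- function(x, pserm_pairs = NULL, candidates = NULL, k = 40L,
                          background = 0.05, exclude_wt = TRUE,
                          terminal = NULL, early = NULL, prior = NULL) {
  stopifnot(inherits(x, "clone_table"))
  nr <- length(x$rounds)
  if (nr < 3L) abort("need at least 3 rounds to form two PSERM pairs")
  pserm_pairs <- pserm_pairs %||% list(
    c(x$rounds[nr], x$rounds[nr - 1L]),
    c(x$rounds[nr - 1L], x$rounds[nr - 2L])
  )
  if (length(pserm_pairs) != 2L) {
    abort("exactly two PSERM pairs drive the top-K overlap rule")
  }
  for (pair in pserm_pairs) {
    d <- diff(match(rev(pair), x$rounds))
    if (is.na(d) || d != 1L) {
      abort("each PSERM pair must be consecutive rounds of the round order, as c(late, early)")
    }
  }
  if (exclude_wt && is.null(x$wt_string)) {
    abort("`exclude_wt = TRUE` requires the clone table to carry `wt_string`")
  }

  pserms <- purrr::map(pserm_pairs, function(pair) {
    round_pserm(x, late = pair[[1L]], early = pair[[2L]],
                background = background)
  })
  names(pserms) <- purrr::map_chr(pserms, matrix_label)

  cand <- candidates %||% x$clones$mutation_string
  if (inherits(cand, "clone_table")) cand <- cand$clones$mutation_string
  cand <- intersect(x$clones$mutation_string, cand)

  scores <- tibble(mutation_string = cand)
  for (nm in names(pserms)) {
    scores[[nm]] <- unname(score_clones(cand, pserms[[nm]]))
  }
  scores <- dplyr::left_join(
    scores, enrichment_metrics(x, terminal, early, prior),
    by = "mutation_string")

  metrics <- c(names(pserms), "freq_terminal", "global_er", "local_er")
  top_k <- purrr::map(setNames(metrics, metrics), function(mtr) {
    rank_top_k(scores, mtr, k = k, exclude_wt = exclude_wt,
               wt_string = x$wt_string)
  })
  overlap <- overlap_selection(top_k[[1L]], top_k[[2L]])
  cys <- cysteine_filter(overlap)

  structure(
    list(scores = scores, pserms = pserms, top_k = top_k,
         overlap = overlap, removed_cysteine = cys$removed,
         final = cys$kept, k = k, exclude_wt = exclude_wt,
         wt_string = x$wt_string, metrics = metrics),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d candidates scored; top-%d per PSERM; overlap %d; %d removed (unpaired Cys); %d selected\n",
    nrow(x$scores), x$k, length(x$overlap), length(x$removed_cysteine),
    length(x$final)))
  if (length(x$final)) cat("  selected:", paste(x$final, collapse = " "), "\n")
  invisible(x)
}

#' Tidy a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return Per-candidate tibble: every metric value, per-metric rank (`NA`
#'   outside the top-K), and logical flags `in_overlap`, `removed_cysteine`,
#'   `selected`.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  out <- x$scores
  for (nm in names(x$top_k)) {
    rk <- x$top_k[[nm]]
    out[[paste0("rank_", nm)]] <-
      match(out$mutation_string, rk$mutation_string)
  }
  out$in_overlap <- out$mutation_string %in% x$overlap
  out$removed_cysteine <- out$mutation_string %in% x$removed_cysteine
  out$selected <- out$mutation_string %in% x$final
  out
}

#' One-row summary of a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$scores), k = x$k,
    n_overlap = length(x$overlap),
    n_removed_cysteine = length(x$removed_cysteine),
    n_selected = length(x$final),
    exclude_wt = x$exclude_wt
  )
}

#' Scatter plot of the two PSERM scores
#'
#' Reproduces the standard two-matrix selection view: each candidate plotted
#' by its two PSERM scores, with selected clones highlighted.
#'
#' @param object A `selection_report`.
#' @param ... Unused.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- tidy(object)
  nms <- names(object$pserms)
  df$status <- dplyr::case_when(
    df$selected ~ "selected",
    df$removed_cysteine ~ "removed (Cys)",
    df$in_overlap ~ "overlap",
    TRUE ~ "candidate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nms[1L]]], y = .data[[nms[2L]]],
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste(nms[1L], "score (bits)"),
                  y = paste(nms[2L], "score (bits)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a selection report (TSV + JSON summary)
#'
#' @param x A `selection_report`.
#' @param tsv_path Path for the per-candidate table ([tidy()] output).
#' @param json_path Optional path for a JSON summary (top-K sets, overlap,
#'   cysteine removals, final list).
#' @return `tsv_path`, invisibly.
#' @export
write_selection_report <- function(x, tsv_path, json_path = NULL) {
  readr::write_tsv(tidy(x), tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      k = x$k, exclude_wt = x$exclude_wt,
      top_k = purrr::map(x$top_k, "mutation_string"),
      overlap = x$overlap, removed_cysteine = x$removed_cysteine,
      final = x$final
    ), json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
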