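#' Benchmark a selection report against simulated ground truth
#'
#' For each selection metric (the two PSERM scores, terminal-round
#' frequency, global and local enrichment ratio): the Spearman rank
#' correlation of the metric with true log fitness over the clones where the
#' metric is defined, and the fraction of the true top-fitness clones (top
#' `top_frac` of the scored candidates, wild type excluded) captured in the
#' metric's top-K set.
#'
#' @param report A [select_clones()] result.
#' @param fitness Named numeric ground-truth fitness (e.g.
#'   `sim_campaign$fitness`), covering every scored clone.
#' @param top_frac Fraction of candidates defining the "true best" set
#'   (default 0.01).
#' @return Tibble: `metric`, `spearman`, `capture`, `n_defined`, `n_true_top`.
#' @export
evaluate_recovery <- function(report, fitness, top_frac = 0.01) {
  stopifnot(inherits(report, "selection_report"))
  sc <- report$scores
  if (!is.null(report$wt_string)) {
    sc <- dplyr::filter(sc, .data$mutation_string != report$wt_string)
  }
  w <- fitness[sc$mutation_string]
  if (anyNA(w)) abort("`fitness` is missing values for some scored clones")
  log_w <- log(unname(w))
  n_top <- max(1L, ceiling(top_frac * nrow(sc)))
  true_top <- sc$mutation_string[order(-log_w)][seq_len(n_top)]
  purrr::map_dfr(report$metrics, function(mtr) {
    v <- sc[[mtr]]
    ok <- !is.na(v)
    captured <- mean(true_top %in% report$top_k[[mtr]]$mutation_string)
    tibble(metric = mtr,
           spearman = if (sum(ok) > 2L) cor(v[ok], log_w[ok], method = "spearman")
                      else NA_real_,
           capture = captured, n_defined = sum(ok), n_true_top = n_top)
  })
}

#' Mean true fitness of a selected clone set, as a library percentile
#'
#' @param clones Character vector of selected mutation strings.
#' @param fitness Named ground-truth fitness vector for the whole library.
#' @return List with `mean_fitness` and `percentile` (fraction of library
#'   clones with fitness below the selection's mean).
#' @export
selection_fitness_percentile <- function(clones, fitness) {
  if (length(clones) == 0L) return(list(mean_fitness = NA_real_, percentile = NA_real_))
  w <- fitness[clones]
  if (anyNA(w)) abort("`fitness` is missing values for some selected clones")
  m <- mean(w)
  list(mean_fitness = m, percentile = mean(fitness < m))
}
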