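#' NNK codon amino-acid frequencies
#'
#' Marginal amino-acid probabilities of an NNK degenerate codon (N = any
#' base, K = G or T): 32 codons covering all 20 amino acids plus one stop
#' (TAG). The stop codon is excluded and the remaining 31 codons
#' renormalized, so e.g. L, R and S (3 codons each) have probability 3/31.
#' This is the residue proposal distribution at saturation-mutagenized
#' sites.
#'
#' @return Named numeric vector over [AA_ALPHABET], summing to 1.
#' @export
nnk_frequencies <- function() {
  codons <- nnk_codons()
  tab <- table(factor(Biostrings::GENETIC_CODE[codons], levels = AA_ALPHABET))
  freq <- as.numeric(tab) / sum(tab)
  setNames(freq, AA_ALPHABET)
}

# internal: the 31 coding NNK codons
nnk_codons <- function() {
  codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("G", "T"), paste0))
  codons[Biostrings::GENETIC_CODE[codons] != "*"]
}

#' Configuration of a synthetic sorting campaign
#'
#' Defaults describe a typical antibody affinity-maturation campaign as the
#' analysis sees it: ten saturation-mutagenized CDR positions, a wild-type
#' clone dominating at ~90–95\% of every sequenced round, thousands of rare
#' variants reaching down to ~1e-5–1e-6 frequency, five sequenced selection
#' rounds of increasing stringency, and two independent sequencing
#' replicates.
#'
#' @param L Number of mutagenized positions (default 10).
#' @param wt_string Wild-type mutation string (length `L`).
#' @param n_variants Number of distinct non-wild-type clones (default 5000).
#' @param wt_fraction Initial wild-type frequency (default 0.92).
#' @param rounds Ordered labels of the sequenced rounds.
#' @param beta Per-round selection strength (>= 0, one per round); a round
#'   reweights clone frequencies by `fitness^beta`. Larger values model more
#'   stringent washes in later rounds.
#' @param depth Reads per replicate per round (default 1e6).
#' @param replicates Number of independent sequencing replicates (default 2).
#' @param n_mut_probs Probabilities of a variant carrying 1, 2, ... mutations
#'   relative to wild type (default mostly singles: 0.6/0.3/0.1).
#' @param effect_sd Standard deviation of the additive per-position fitness
#'   effects (log scale; wild-type residues are fixed at effect 0).
#' @param dirichlet_alpha Concentration of the Dirichlet draw spreading the
#'   non-wild-type mass across variants; < 1 gives the long tail of rare
#'   clones.
#' @param fitness_noise_sd Optional per-clone lognormal noise on fitness.
#' @param error_rate Optional per-residue substitution rate applied at the
#'   sequencing step (stresses the QC filter; default 0).
#' @param seed Default RNG seed for [simulate_campaign()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(L = 10L, wt_string = "TFSNYAWMSY", n_variants = 5000L,
                       wt_fraction = 0.92,
                       rounds = c("R2", "R3", "R5", "R6", "R7"),
                       beta = c(0.3, 0.5, 0.8, 1.1, 1.4),
                       depth = 1e6, replicates = 2L,
                       n_mut_probs = c(0.6, 0.3, 0.1),
                       effect_sd = 0.08, dirichlet_alpha = 0.5,
                       fitness_noise_sd = 0, error_rate = 0, seed = 1L) {
  check_mutation_strings(wt_string, L = L)
  if (length(beta) != length(rounds)) abort("`beta` needs one value per round")
  if (any(beta < 0)) abort("`beta` must be non-negative")
  if (wt_fraction < 0 || wt_fraction > 1) abort("`wt_fraction` must be in [0, 1]")
  if (depth < 1) abort("`depth` must be >= 1")
  if (replicates < 1) abort("`replicates` must be >= 1")
  ks <- seq_len(min(length(n_mut_probs), L))
  capacity <- sum(choose(L, ks) * 19^ks)
  if (n_variants > 0 && n_variants >= 0.5 * capacity) {
    abort("`n_variants` too large for the mutation space; distinct strings cannot be drawn reliably")
  }
  structure(list(
    L = as.integer(L), wt_string = wt_string,
    n_variants = as.integer(n_variants), wt_fraction = wt_fraction,
    rounds = rounds, beta = beta, depth = depth,
    replicates = as.integer(replicates), n_mut_probs = n_mut_probs,
    effect_sd = effect_sd, dirichlet_alpha = dirichlet_alpha,
    fitness_noise_sd = fitness_noise_sd, error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Random additive fitness landscape
#'
#' Per-residue, per-position effects on log fitness, drawn
#' `N(0, effect_sd)`; wild-type residues are fixed at 0, so the wild type
#' has fitness exactly 1. A clone's fitness is
#' `w(s) = exp(sum_j e[s_j, j])` — the latent binding quality the sorting
#' rounds select on.
#'
#' @param config A [sim_config()]. Uses the current RNG state.
#' @return A `fitness_landscape`: 20 x L effect matrix with attribute
#'   `wt_string`.
#' @export
fitness_landscape <- function(config) {
  e <- matrix(rnorm(20L * config$L, sd = config$effect_sd),
              nrow = 20L, ncol = config$L,
              dimnames = list(AA_ALPHABET, seq_len(config$L)))
  wt <- strsplit(config$wt_string, "", fixed = TRUE)[[1L]]
  e[cbind(match(wt, AA_ALPHABET), seq_len(config$L))] <- 0
  structure(e, wt_string = config$wt_string,
            class = c("fitness_landscape", "matrix", "array"))
}

#' Fitness of clones under an additive landscape
#'
#' @param strings Character vector of mutation strings.
#' @param landscape A [fitness_landscape()].
#' @return Named numeric vector of fitness values (wild type = 1).
#' @export
clone_fitness <- function(strings, landscape) {
  lw <- score_clones(strings, structure(unclass(landscape),
                                        class = c("position_matrix", "matrix", "array")))
  exp(lw)
}

#' Draw the initial clone pool
#'
#' The wild type is placed at `wt_fraction`; `n_variants` distinct variant
#' strings are drawn by mutating the wild type at 1–3 random positions with
#' substitutions from the NNK amino-acid marginals; the remaining frequency
#' mass is spread across variants by a Dirichlet draw with concentration
#' `dirichlet_alpha`, producing a long tail of rare clones.
#'
#' @param config A [sim_config()]. Uses the current RNG state (seed with
#'   `set.seed()` or use [simulate_campaign()]).
#' @return Tibble `mutation_string`, `freq`, wild type first; frequencies
#'   sum to 1.
#' @export
make_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  if (n == 0L) {
    return(tibble(mutation_string = config$wt_string, freq = 1))
  }
  wt <- strsplit(config$wt_string, "", fixed = TRUE)[[1L]]
  nnk <- nnk_frequencies()
  variants <- character(0L)
  while (length(variants) < n) {
    m <- ceiling(1.4 * (n - length(variants))) + 10L
    k_mut <- sample.int(length(config$n_mut_probs), m, replace = TRUE,
                        prob = config$n_mut_probs)
    batch <- vapply(k_mut, function(k) {
      s <- wt
      pos <- sample.int(config$L, k)
      s[pos] <- sample(AA_ALPHABET, k, replace = TRUE, prob = nnk)
      paste(s, collapse = "")
    }, character(1L))
    variants <- setdiff(unique(c(variants, batch)), config$wt_string)
  }
  variants <- variants[seq_len(n)]
  mass <- rgamma(n, shape = config$dirichlet_alpha)
  mass <- (1 - config$wt_fraction) * mass / sum(mass)
  tibble(mutation_string = c(config$wt_string, variants),
         freq = c(config$wt_fraction, mass))
}

#' One round of selection (deterministic expected update)
#'
#' Fitness-proportional survival: the new frequency of clone `s` is
#' proportional to `f(s) * w(s)^beta`. `beta = 0` leaves the pool unchanged;
#' larger `beta` models a more stringent sort.
#'
#' @param pool Tibble with `mutation_string` and `freq` (summing to 1).
#' @param fitness Named numeric fitness vector covering every pool clone.
#' @param beta Selection strength (>= 0).
#' @return Pool tibble with updated, renormalized `freq`.
#' @export
simulate_round <- function(pool, fitness, beta) {
  if (beta < 0) abort("`beta` must be non-negative")
  w <- fitness[pool$mutation_string]
  if (anyNA(w)) abort("`fitness` is missing values for some pool clones")
  f <- pool$freq * unname(w)^beta
  pool$freq <- f / sum(f)
  pool
}

#' Finite-depth replicate sequencing of a pool
#'
#' Each replicate is an independent multinomial draw of `depth` reads from
#' the pool frequencies. An optional per-residue substitution error rate
#' mutates sampled reads before tallying.
#'
#' @param pool Tibble with `mutation_string` and `freq`.
#' @param depth Reads per replicate.
#' @param replicates Number of replicates.
#' @param round Round label recorded in the output.
#' @param error_rate Per-residue substitution probability (default 0).
#' @return Tibble `mutation_string`, `round`, `replicate`, `count`
#'   (zero-count clones omitted); counts per replicate sum to `depth`.
#' @export
simulate_sequencing <- function(pool, depth, replicates = 2L, round = "R1",
                                error_rate = 0) {
  draws <- rmultinom(replicates, size = depth, prob = pool$freq)
  out <- purrr::map_dfr(seq_len(replicates), function(k) {
    cnt <- draws[, k]
    keep <- cnt > 0L
    tb <- tibble(mutation_string = pool$mutation_string[keep],
                 round = as.character(round), replicate = k,
                 count = as.integer(cnt[keep]))
    if (error_rate > 0) tb <- apply_read_errors(tb, error_rate)
    tb
  })
  out
}

# internal: resample per-residue substitution errors onto tallied reads
apply_read_errors <- function(tb, error_rate) {
  L <- nchar(tb$mutation_string[[1L]])
  n_err <- stats::rbinom(nrow(tb), size = tb$count * L, prob = error_rate)
  has_err <- which(n_err > 0L)
  if (length(has_err) == 0L) return(tb)
  extra <- purrr::map_dfr(has_err, function(i) {
    # place each substituted residue on a distinct read (rate is small)
    n <- min(n_err[[i]], tb$count[[i]])
    s <- strsplit(tb$mutation_string[[i]], "", fixed = TRUE)[[1L]]
    muts <- vapply(seq_len(n), function(.) {
      s2 <- s
      p <- sample.int(L, 1L)
      s2[p] <- sample(AA_ALPHABET, 1L)
      paste(s2, collapse = "")
    }, character(1L))
    tibble(mutation_string = muts, round = tb$round[[i]],
           replicate = tb$replicate[[i]], count = 1L)
  })
  tb$count[has_err] <- tb$count[has_err] - pmin(n_err[has_err], tb$count[has_err])
  dplyr::bind_rows(tb, extra) |>
    dplyr::group_by(.data$mutation_string, .data$round, .data$replicate) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$count > 0L)
}

#' Simulate a full sorting campaign with ground truth
#'
#' Draws the initial pool and fitness landscape, applies the per-round
#' selection update, sequences each round at finite depth in replicate, and
#' assembles the resulting clone table — everything a real campaign hands to
#' the analysis, plus the ground truth it never reveals.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default `config$seed`). Identical seed + config
#'   give a bit-identical campaign.
#' @return A `sim_campaign` list: `config`, `library` (initial pool),
#'   `landscape`, `fitness` (named, ground truth), `true_freqs` (long tibble
#'   of post-selection pool frequencies per round), `tallies` (sequenced
#'   counts), `clone_table` (replicate-common table with totals and
#'   frequencies).
#' @export
simulate_campaign <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pool0 <- make_library(config)
  land <- fitness_landscape(config)
  fitness <- setNames(clone_fitness(pool0$mutation_string, land),
                      pool0$mutation_string)
  if (config$fitness_noise_sd > 0) {
    fitness <- fitness * exp(rnorm(length(fitness),
                                   sd = config$fitness_noise_sd))
    fitness[config$wt_string] <- 1
  }
  pool <- pool0
  tallies <- vector("list", length(config$rounds))
  truth <- vector("list", length(config$rounds))
  for (r in seq_along(config$rounds)) {
    pool <- simulate_round(pool, fitness, config$beta[[r]])
    truth[[r]] <- tibble(mutation_string = pool$mutation_string,
                         round = config$rounds[[r]], freq = pool$freq)
    tallies[[r]] <- simulate_sequencing(pool, config$depth,
                                        config$replicates,
                                        round = config$rounds[[r]],
                                        error_rate = config$error_rate)
  }
  tallies <- dplyr::bind_rows(tallies)
  attr(tallies, "rounds") <- config$rounds
  attr(tallies, "wt_string") <- config$wt_string
  ct <- clone_table(tallies, rounds = config$rounds,
                    wt_string = config$wt_string,
                    filter = "common_any_round")
  structure(list(config = config, library = pool0, landscape = land,
                 fitness = fitness, true_freqs = dplyr::bind_rows(truth),
                 tallies = tallies, clone_table = ct),
            class = "sim_campaign")
}

#' @export
print.sim_campaign <- function(x, ...) {
  wt_f <- x$clone_table$clones |>
    dplyr::filter(.data$mutation_string == x$config$wt_string)
  cat(sprintf(
    "<sim_campaign> %d clones drawn, %d rounds x %d replicates at depth %g\n",
    nrow(x$library), length(x$config$rounds), x$config$replicates,
    x$config$depth))
  cat(sprintf("  replicate-common clones: %d; sequenced WT frequency %s\n",
              nrow(x$clone_table$clones),
              paste(sprintf("%s=%.3f", x$config$rounds,
                            unlist(wt_f[paste0("f_", x$config$rounds)])),
                    collapse = " ")))
  invisible(x)
}
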