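small_cfg <- function(...) {
  sim_config(n_variants = 200L, depth = 5e3, seed = 11, ...)
}

test_that("NNK proposal frequencies are the codon-table marginals", {
  f <- nnk_frequencies()
  expect_equal(sum(f), 1)
  # 3-codon residues (L, R, S), 1-codon residues (e.g. M, W)
  expect_equal(unname(f[c("L", "R", "S")]), rep(3 / 31, 3))
  expect_equal(unname(f[c("M", "W", "D", "F")]), rep(1 / 31, 4))
  expect_equal(unname(f["A"]), 2 / 31)
})

test_that("the initial pool respects the configured composition", {
  cfg <- sim_config(n_variants = 0L, wt_fraction = 1)
  set.seed(1)
  pool <- make_library(cfg)
  expect_equal(pool, tibble::tibble(mutation_string = cfg$wt_string, freq = 1))

  cfg <- small_cfg()
  set.seed(5); p1 <- make_library(cfg)
  set.seed(5); p2 <- make_library(cfg)
  expect_identical(p1, p2)  # determinism under a fixed seed
  expect_equal(sum(p1$freq), 1)
  expect_equal(p1$freq[1], 0.92)
  expect_equal(anyDuplicated(p1$mutation_string), 0L)
  expect_equal(nrow(p1), 201L)
  expect_true(all(nchar(p1$mutation_string) == 10L))
})

test_that("selection reweights frequencies by fitness^beta", {
  pool <- tibble::tibble(mutation_string = c("AA", "YY"), freq = c(0.5, 0.5))
  w <- c(AA = 2, YY = 1)
  expect_equal(simulate_round(pool, w, beta = 0)$freq, c(0.5, 0.5))
  expect_equal(simulate_round(pool, w, beta = 1)$freq, c(2 / 3, 1 / 3))
  expect_equal(simulate_round(pool, c(AA = 3, YY = 3), beta = 2)$freq,
               c(0.5, 0.5))  # uniform fitness: unchanged for any beta
  expect_error(simulate_round(pool, c(AA = 1), 1), "missing")

  # closed-form limit: log-frequency change = beta*log(w) - log(Z)
  set.seed(2)
  pool <- tibble::tibble(
    mutation_string = replicate(20, paste(sample(AA, 2, TRUE), collapse = "")),
    freq = as.vector(prop.table(runif(20))))
  pool <- dplyr::distinct(pool, mutation_string, .keep_all = TRUE)
  pool$freq <- pool$freq / sum(pool$freq)
  w <- setNames(exp(rnorm(nrow(pool))), pool$mutation_string)
  beta <- 1.3
  out <- simulate_round(pool, w, beta)
  Z <- sum(pool$freq * w^beta)
  expect_equal(log(out$freq) - log(pool$freq),
               beta * log(unname(w)) - log(Z), tolerance = 1e-12)
  expect_equal(sum(out$freq), 1)
})

test_that("sequencing draws conserve depth and are seed-deterministic", {
  pool <- tibble::tibble(mutation_string = "AAAA", freq = 1)
  sq <- simulate_sequencing(pool, depth = 100, replicates = 2, round = "R1")
  expect_equal(sq$count, c(100L, 100L))

  set.seed(4)
  pool <- tibble::tibble(mutation_string = c("AA", "YY", "WW"),
                         freq = c(0.1, 0.3, 0.6))
  sq <- simulate_sequencing(pool, depth = 1000, replicates = 3, round = "Rx")
  expect_equal(as.vector(tapply(sq$count, sq$replicate, sum)), rep(1000L, 3))
  set.seed(4)
  expect_identical(sq, simulate_sequencing(pool, 1000, 3, "Rx"))
})

test_that("campaigns are reproducible and carry coherent ground truth", {
  cfg <- small_cfg()
  c1 <- simulate_campaign(cfg)
  c2 <- simulate_campaign(cfg)
  expect_identical(c1$tallies, c2$tallies)
  expect_identical(c1$fitness, c2$fitness)

  # frequencies sum to 1 after every round
  sums <- c1$true_freqs |>
    dplyr::group_by(round) |>
    dplyr::summarise(s = sum(freq))
  expect_equal(sums$s, rep(1, 5))
  # wild type has fitness exactly 1; all fitness positive
  expect_equal(unname(c1$fitness[cfg$wt_string]), 1)
  expect_true(all(c1$fitness > 0))
  # sequenced counts per replicate sum to the depth
  per_rep <- c1$tallies |>
    dplyr::group_by(round, replicate) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(per_rep$n == cfg$depth))
})

test_that("a neutral campaign (beta = 0) centers PSERM scores on zero", {
  cfg <- sim_config(n_variants = 150L, depth = 5e4,
                    beta = rep(0, 5), seed = 19)
  camp <- simulate_campaign(cfg)
  rep <- select_clones(camp$clone_table, k = 20)
  for (nm in names(rep$pserms)) {
    sc <- rep$scores[[nm]]
    expect_lt(abs(mean(sc)), 0.25)
    expect_lt(abs(stats::median(sc)), 0.25)
  }
})

test_that("recovery evaluation recognizes perfect and missing truth", {
  cfg <- small_cfg()
  camp <- simulate_campaign(cfg)
  rep <- select_clones(camp$clone_table, k = 20)
  rec <- evaluate_recovery(rep, camp$fitness)
  expect_setequal(rec$metric, rep$metrics)
  expect_true(all(rec$capture >= 0 & rec$capture <= 1))

  # scores equal to log-fitness give rank correlation exactly 1
  fake <- rep
  fake$scores[[rep$metrics[1]]] <-
    log(unname(camp$fitness[fake$scores$mutation_string]))
  rec2 <- evaluate_recovery(fake, camp$fitness)
  expect_equal(rec2$spearman[rec2$metric == rep$metrics[1]], 1)

  expect_error(evaluate_recovery(rep, camp$fitness[-2]), "missing")
})

test_that("sequencing errors perturb reads but conserve depth", {
  set.seed(6)
  pool <- tibble::tibble(mutation_string = c("AAAA", "YYYY"),
                         freq = c(0.7, 0.3))
  sq <- simulate_sequencing(pool, depth = 2000, replicates = 2,
                            round = "R1", error_rate = 0.01)
  expect_equal(as.vector(tapply(sq$count, sq$replicate, sum)), rep(2000L, 2))
  expect_gt(length(unique(sq$mutation_string)), 2)
})
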