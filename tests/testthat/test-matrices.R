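test_that("a clone's observations land in one cell per column", {
  ct <- manual_clone_table(
    list(SASFYYATYI = rbind(c(0, 0), c(4, 4))), c("R3", "R5"),
    wt_string = NULL)
  cm <- count_matrix(ct, "R5")
  expect_equal(attr(cm, "N"), 8L)
  res <- strsplit("SASFYYATYI", "")[[1]]
  for (j in 1:10) {
    expect_equal(cm[res[j], j], 8L)
    expect_equal(sum(cm[, j]), 8L)  # everything else in the column is 0
  }
})

test_that("count matrices sum replicate counts and can exclude wild type", {
  # AA is replicate-common only in Ra; in R1 the clones have 3 and 1
  # observations (summed across replicates)
  counts <- list(AY = rbind(c(0, 0), c(2, 1)), AA = rbind(c(1, 1), c(1, 0)))
  ct <- manual_clone_table(counts, c("Ra", "R1"), wt_string = "AY")
  cm <- count_matrix(ct, "R1")
  expect_equal(cm["A", 1], 4L)
  expect_equal(cm["Y", 2], 3L)
  expect_equal(cm["A", 2], 1L)
  expect_equal(attr(cm, "N"), 4L)

  cm_nowt <- count_matrix(ct, "R1", exclude_wt = TRUE)
  expect_equal(attr(cm_nowt, "N"), 1L)
  expect_equal(cm_nowt["A", 1], 1L)
})

test_that("PPM applies the square-root pseudocount and normalizes columns", {
  ct <- manual_clone_table(list(AW = rbind(c(2, 2))), "R1", wt_string = NULL)
  p <- ppm(count_matrix(ct, "R1"))
  # N = 4, pseudocount = 2: observed residue (4+2)/(4+40), others 2/44
  expect_equal(attr(p, "pseudocount"), 2)
  expect_equal(p["A", 1], 6 / 44)
  expect_equal(p["C", 1], 2 / 44)
  expect_equal(colSums(p), c(`1` = 1, `2` = 1), tolerance = 1e-9)
  expect_true(all(p > 0))

  # uniform counts give 1/20 regardless of pseudocount
  cm_u <- structure(matrix(5L, 20, 2, dimnames = list(AA_ALPHABET, 1:2)),
                    round = "R1", N = 100L,
                    class = c("count_matrix", "position_matrix", "matrix", "array"))
  expect_equal(bare(ppm(cm_u)), matrix(1 / 20, 20, 2,
               dimnames = list(AA_ALPHABET, 1:2)), tolerance = 1e-12)

  cm0 <- structure(matrix(0L, 20, 1, dimnames = list(AA_ALPHABET, 1)),
                   round = "R0", N = 0L,
                   class = c("count_matrix", "position_matrix", "matrix", "array"))
  expect_error(ppm(cm0), "N = 0")
})

test_that("PSSM is the log2 odds against the flat background", {
  make_ppm <- function(vals) {
    structure(matrix(vals, 20, 1, dimnames = list(AA_ALPHABET, 1)),
              round = "Rx", N = 10L, pseudocount = 1,
              class = c("ppm", "position_matrix", "matrix", "array"))
  }
  p <- make_ppm(c(0.05, 0.10, 0.025, rep(0.825 / 17, 17)))
  s <- pssm(p, background = 0.05)
  expect_equal(s[1, 1], 0)    # p = b
  expect_equal(s[2, 1], 1)    # p = 2b -> +1 bit
  expect_equal(s[3, 1], -1)   # p = b/2 -> -1 bit
  expect_error(pssm(p, background = 1.5), "background")
})

test_that("PSERM differences PSSMs and cancels the background", {
  set.seed(11)
  ct <- clone_table(random_tallies(n_clones = 8, L = 3),
                    rounds = c("Ra", "Rb", "Rc"))
  s_same <- pserm(round_pssm(ct, "Rb"), round_pssm(ct, "Rb"))
  expect_equal(max(abs(s_same)), 0)

  for (b in c(0.05, 0.01)) {
    d <- pserm(round_pssm(ct, "Rc", background = b),
               round_pssm(ct, "Rb", background = b))
    if (b == 0.05) d_ref <- d
    expect_equal(bare(d), bare(d_ref), tolerance = 1e-12)
  }

  expect_error(pserm(round_pssm(ct, "Rc", background = 0.05),
                     round_pssm(ct, "Rb", background = 0.01)),
               "background")
})

test_that("a >=90% dominant clone attains the column-max PSSM scores", {
  set.seed(21)
  for (i in 1:10) {
    wt <- paste(sample(AA, 4, TRUE), collapse = "")
    others <- setdiff(unique(replicate(8, paste(sample(AA, 4, TRUE), collapse = ""))), wt)
    counts <- c(950L, rpois(length(others), 5) + 1L)
    counts <- setNames(counts, c(wt, others))
    counts[1] <- max(counts[1], ceiling(9 * sum(counts[-1])))  # ensure >= 90%
    lst <- lapply(counts, function(n) rbind(c(n, n)))
    ct <- manual_clone_table(lst, "R1", wt_string = wt)
    s <- round_pssm(ct, "R1")
    res <- strsplit(wt, "")[[1]]
    for (j in 1:4) expect_equal(s[res[j], j], max(s[, j]))
  }
})

test_that("matrix chain matches the brute-force reference on random tables", {
  set.seed(5)
  for (i in 1:100) {
    L <- sample(2:4, 1)
    n <- sample(1:8, 1)
    strings <- unique(replicate(n, paste(sample(AA, L, TRUE), collapse = "")))
    cnt_b <- rpois(length(strings), 10) + 1L
    cnt_c <- rpois(length(strings), 10) + 1L
    lst <- Map(function(b, cc) rbind(c(b, b), c(cc, cc)),
               cnt_b, cnt_c)
    names(lst) <- strings
    ct <- manual_clone_table(lst, c("Rb", "Rc"), wt_string = NULL)

    for (r in c("Rb", "Rc")) {
      N <- sum(round_counts(ct, r))
      cm_ref <- ref_count_matrix(ct$clones$mutation_string,
                                 round_counts(ct, r)[ct$clones$mutation_string], L)
      expect_equal(bare(count_matrix(ct, r)) * 1.0, cm_ref,
                   tolerance = 1e-15)
      expect_equal(bare(ppm(count_matrix(ct, r))), ref_ppm(cm_ref, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("position matrices tidy and write with full provenance", {
  ct <- manual_clone_table(list(AW = rbind(c(3, 3), c(5, 5))), c("Rb", "Rc"))
  s <- round_pserm(ct, "Rc", "Rb")
  td <- tidy(s)
  expect_equal(nrow(td), 40)
  expect_equal(unique(td$kind), "pserm")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_position_matrix(s, path)
  lines <- readLines(path)
  expect_true(any(grepl("^#kind=pserm", lines)))
  expect_true(any(grepl("^#late=Rc", lines)))
  expect_equal(length(lines), sum(startsWith(lines, "#")) + 1 + 20)
})
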