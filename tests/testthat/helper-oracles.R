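# Brute-force reference implementations, kept deliberately naive (explicit
# loops, one value at a time) and independent of the package internals.

AA <- pserm::AA_ALPHABET

# strip every attribute except dim/dimnames for bare-matrix comparison
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# reference count matrix: loop over clones and positions
ref_count_matrix <- function(strings, counts, L) {
  cm <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA, seq_len(L)))
  for (i in seq_along(strings)) {
    for (j in seq_len(L)) {
      a <- substr(strings[i], j, j)
      cm[a, j] <- cm[a, j] + counts[i]
    }
  }
  cm
}

# reference PPM: pseudocount sqrt(N) added to every cell
ref_ppm <- function(cm, N) {
  c0 <- sqrt(N)
  p <- cm
  for (a in rownames(cm)) {
    for (j in seq_len(ncol(cm))) {
      p[a, j] <- (cm[a, j] + c0) / (N + 20 * c0)
    }
  }
  p
}

ref_pssm <- function(p, b) {
  s <- p
  for (a in rownames(p)) {
    for (j in seq_len(ncol(p))) s[a, j] <- log2(p[a, j] / b)
  }
  s
}

ref_score <- function(string, m) {
  total <- 0
  for (j in seq_len(nchar(string))) {
    total <- total + m[substr(string, j, j), j]
  }
  total
}

# reference read pipeline: translate by codon lookup, QC, slice, count
ref_read_pipeline <- function(nt, offset, anchor, expected_length, positions) {
  code <- Biostrings::GENETIC_CODE
  out <- character(0)
  for (r in nt) {
    body <- substr(r, offset + 1, nchar(r))
    n_cod <- nchar(body) %/% 3
    aa <- ""
    bad <- FALSE
    for (i in seq_len(n_cod)) {
      codon <- substr(body, 3 * i - 2, 3 * i)
      if (grepl("N", codon)) { bad <- TRUE; break }
      res <- code[[codon]]
      if (res == "*" && i <= expected_length) { bad <- TRUE; break }
      aa <- paste0(aa, res)
    }
    if (bad || nchar(aa) != expected_length) next
    mm <- 0
    for (j in 1:6) {
      if (substr(aa, j, j) != substr(anchor, j, j)) mm <- mm + 1
    }
    if (mm > 1) next
    s <- ""
    for (p in positions) s <- paste0(s, substr(aa, p, p))
    out <- c(out, s)
  }
  tab <- table(out)
  setNames(as.integer(tab), names(tab))
}

# random tallies over a small clone universe, guaranteed to have at least
# one replicate-common clone
random_tallies <- function(n_clones = 6, L = 3, rounds = c("Ra", "Rb", "Rc"),
                           replicates = 2) {
  strings <- unique(replicate(n_clones * 2, paste(sample(AA, L, TRUE), collapse = "")))
  strings <- strings[seq_len(min(n_clones, length(strings)))]
  rows <- list()
  for (r in rounds) {
    for (k in seq_len(replicates)) {
      present <- c(TRUE, runif(length(strings) - 1) > 0.3)
      cnt <- ifelse(present, rpois(length(strings), 20) + 1L, 0L)
      rows[[paste(r, k)]] <- tibble::tibble(
        mutation_string = strings, round = r, replicate = k,
        count = as.integer(cnt))
    }
  }
  dplyr::bind_rows(rows)
}

# clone table with explicit per-sample counts, for hand-checked examples:
# counts is a named list string -> matrix [round x replicate]
manual_clone_table <- function(counts, rounds, wt_string = NULL, ...) {
  rows <- list()
  for (s in names(counts)) {
    m <- counts[[s]]
    for (r in seq_along(rounds)) {
      for (k in seq_len(ncol(m))) {
        rows[[paste(s, r, k)]] <- tibble::tibble(
          mutation_string = s, round = rounds[r], replicate = k,
          count = as.integer(m[r, k]))
      }
    }
  }
  pserm::clone_table(dplyr::bind_rows(rows), rounds = rounds,
                     wt_string = wt_string, ...)
}
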