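#' Per-round residue count matrix
#'
#' Builds the 20 x L count matrix for one round of sorting: every clone with
#' residue `a` at position `j` contributes its round observation count to
#' cell `(a, j)`. Round observations are the clone's counts summed across
#' sequencing replicates (after the replicate-consistency filter of the
#' clone table). A clone observed 8 times therefore adds 8 to one cell in
#' every column.
#'
#' @param x A [clone_table()].
#' @param round Round label to tabulate.
#' @param exclude_wt Drop the wild-type clone before counting.
#' @return A `count_matrix`: integer matrix with rows [AA_ALPHABET] and one
#'   column per mutagenized position, with attributes `round` and `N` (total
#'   observations tabulated).
#' @export
count_matrix <- function(x, round, exclude_wt = FALSE) {
  counts <- round_counts(x, round)
  if (exclude_wt && !is.null(x$wt_string)) {
    counts <- counts[names(counts) != x$wt_string]
  }
  counts <- counts[counts > 0L]
  L <- if (nrow(x$clones) > 0L) nchar(x$clones$mutation_string[[1L]]) else 0L
  cm <- matrix(0L, nrow = 20L, ncol = L,
               dimnames = list(AA_ALPHABET, seq_len(L)))
  if (length(counts) > 0L) {
    chars <- string_matrix(names(counts))
    for (j in seq_len(ncol(chars))) {
      sums <- rowsum(counts, chars[, j])
      cm[rownames(sums), j] <- as.integer(sums)
    }
  }
  structure(cm, round = round, N = sum(counts),
            class = c("count_matrix", "position_matrix", class(cm)))
}

#' Position probability matrix with square-root pseudocounts
#'
#' Converts a count matrix to a position probability matrix (PPM) by adding
#' a pseudocount to every cell and renormalizing each column:
#' `p[a, j] = (c[a, j] + c0) / (N + 20 * c0)`. The default pseudocount is
#' `c0 = sqrt(N)`, where `N` is the total number of observations in the
#' round — large rounds are damped less, but no residue ever has probability
#' zero, so downstream log-scores stay finite.
#'
#' @param counts A [count_matrix()].
#' @param pseudocount Pseudocount added to each cell; default `sqrt(N)`.
#' @return A `ppm` matrix (attributes `round`, `N`, `pseudocount`); every
#'   column sums to 1 and every entry is strictly positive.
#' @export
ppm <- function(counts, pseudocount = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- attr(counts, "N")
  if (N == 0L) abort("cannot build a PPM for an empty round (N = 0)")
  c0 <- pseudocount %||% sqrt(N)
  if (c0 < 0) abort("`pseudocount` must be non-negative")
  p <- (unclass(counts) + c0) / (N + nrow(counts) * c0)
  structure(p, round = attr(counts, "round"), N = N, pseudocount = c0,
            class = c("ppm", "position_matrix", "matrix", "array"))
}

#' Position-specific scoring matrix (log-odds over a flat background)
#'
#' `s[a, j] = log2(p[a, j] / b)` in bits, with a uniform background
#' `b` (default 5\% = 1/20). A score of 0 means the residue occurs at
#' exactly the background rate; +1 bit means twice the background.
#'
#' @param p A [ppm()].
#' @param background Background probability per residue, in (0, 1).
#' @return A `pssm` matrix (attributes `round`, `background`).
#' @export
pssm <- function(p, background = 0.05) {
  stopifnot(inherits(p, "ppm"))
  if (background <= 0 || background >= 1) abort("`background` must be in (0, 1)")
  if (any(p <= 0)) abort("PPM entries must all be positive")
  s <- log2(unclass(p) / background)
  structure(s, round = attr(p, "round"), background = background,
            class = c("pssm", "position_matrix", "matrix", "array"))
}

#' Position-specific enrichment ratio matrix (consecutive-round PSSM difference)
#'
#' The PSERM for a pair of consecutive sorting rounds is the elementwise
#' difference of their PSSMs, `late - early`. Because the flat background
#' cancels, entry `(a, j)` equals `log2(p_late[a, j] / p_early[a, j])`:
#' per-residue, per-position enrichment between rounds, in bits. Differencing
#' removes the dominant wild-type signal that saturates single-round PSSMs
#' when the parental clone makes up ~90\% of every round.
#'
#' @param late,early `pssm` matrices of the same dimensions and background.
#' @return A `pserm` matrix (attributes `late`, `early`, `background`).
#' @export
pserm <- function(late, early) {
  stopifnot(inherits(late, "pssm"), inherits(early, "pssm"))
  if (!identical(dim(late), dim(early))) abort("PSSM dimensions differ")
  if (!isTRUE(all.equal(attr(late, "background"), attr(early, "background")))) {
    abort("PSSM backgrounds differ")
  }
  s <- unclass(late) - unclass(early)
  structure(s, late = attr(late, "round"), early = attr(early, "round"),
            background = attr(late, "background"),
            class = c("pserm", "position_matrix", "matrix", "array"))
}

#' Build the PSSM for one round of a clone table
#'
#' Convenience chain `count_matrix() |> ppm() |> pssm()`.
#'
#' @inheritParams count_matrix
#' @inheritParams pssm
#' @export
round_pssm <- function(x, round, background = 0.05, exclude_wt = FALSE) {
  pssm(ppm(count_matrix(x, round, exclude_wt = exclude_wt)), background)
}

#' Build the PSERM for a pair of rounds of a clone table
#'
#' @inheritParams round_pssm
#' @param late,early Round labels; `late` is typically the round immediately
#'   after `early` in the sorting campaign.
#' @export
round_pserm <- function(x, late, early, background = 0.05,
                        exclude_wt = FALSE) {
  pserm(round_pssm(x, late, background, exclude_wt),
        round_pssm(x, early, background, exclude_wt))
}

matrix_kind <- function(m) intersect(class(m), c("count_matrix", "ppm", "pssm", "pserm"))[1]

matrix_label <- function(m) {
  kind <- matrix_kind(m)
  if (kind == "pserm") sprintf("pserm_%s-%s", attr(m, "late"), attr(m, "early"))
  else sprintf("%s_%s", kind, attr(m, "round"))
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d residues x %d positions\n", matrix_label(x),
              nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy a position matrix into long format
#'
#' @param x A `count_matrix`, `ppm`, `pssm` or `pserm`.
#' @param ... Unused.
#' @return Tibble with `residue`, `position`, `value`, `kind`.
#' @method tidy position_matrix
#' @export
tidy.position_matrix <- function(x, ...) {
  tibble(
    residue = rep(rownames(x), times = ncol(x)),
    position = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(unclass(x)),
    kind = matrix_kind(x)
  )
}

#' Heatmap of a position matrix
#'
#' @param object A `count_matrix`, `ppm`, `pssm` or `pserm`.
#' @param ... Unused.
#' @return A ggplot: residues x positions, fill = value (diverging scale for
#'   log-score matrices, centered at 0).
#' @method autoplot position_matrix
#' @export
autoplot.position_matrix <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position),
    y = factor(.data$residue, levels = rev(AA_ALPHABET)),
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "position", y = "residue", fill = matrix_label(object),
                  title = matrix_label(object)) +
    ggplot2::theme_minimal()
  if (matrix_kind(object) %in% c("pssm", "pserm")) {
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                           high = "#B2182B", midpoint = 0)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a position matrix as TSV
#'
#' Rows are the 20 residues, columns the positions; a `#key=value` header
#' block records the matrix kind, round provenance, `N`, pseudocount and
#' background as applicable.
#'
#' @param m A position matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_position_matrix <- function(m, path) {
  meta <- c(sprintf("#kind=%s", matrix_kind(m)),
            sprintf("#label=%s", matrix_label(m)))
  for (a in c("round", "late", "early", "N", "pseudocount", "background")) {
    if (!is.null(attr(m, a))) {
      meta <- c(meta, sprintf("#%s=%s", a,
                              format(attr(m, a), digits = 17)))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("residue", colnames(m)), collapse = "\t"), con)
  vals <- apply(unclass(m), 1L, function(row) {
    paste(format(row, digits = 17, trim = TRUE), collapse = "\t")
  })
  writeLines(paste(rownames(m), vals, sep = "\t"), con)
  invisible(path)
}
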