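#' Translate merged amplicon reads
#'
#' Translates each nucleotide read in-frame from `frame_offset`, using the
#' standard genetic code. Amplicon libraries are often sequenced with a
#' deliberate per-sample single-base shift to decrease sequence homology on
#' the flow cell; `frame_offset` removes that shift before translation.
#'
#' A read is rejected (translation `NA`) when any in-frame codon contains an
#' `N`, or when a stop codon occurs within the expected coding span
#' (`expected_codons`; when `NULL`, a stop anywhere rejects the read).
#' Trailing bases that do not complete a codon are ignored.
#'
#' @param nucleotides Character vector of reads over `{A,C,G,T,N}`.
#' @param frame_offset Integer 0-2 (scalar or one per read): bases to skip
#'   before the first codon.
#' @param expected_codons Optional integer: length of the expected coding
#'   span, in codons. Stop codons beyond it do not reject the read.
#' @return A tibble with one row per read: `aa` (amino-acid translation, `NA`
#'   when rejected) and `reject_reason` (`NA`, `"ambiguous_base"` or
#'   `"stop_codon"`).
#' @examples
#' translate_reads(c("ATGGCT", "TATGGCT"), frame_offset = c(0, 1))
#' @export
translate_reads <- function(nucleotides, frame_offset = 0L,
                            expected_codons = NULL) {
  if (length(nucleotides) == 0L) {
    return(tibble(aa = character(), reject_reason = character()))
  }
  if (any(frame_offset < 0L | frame_offset > 2L)) {
    abort("`frame_offset` must be 0, 1 or 2")
  }
  bad <- grepl("[^ACGTN]", nucleotides)
  if (any(bad)) {
    abort(sprintf("malformed read(s): nucleotide symbols other than A/C/G/T/N (e.g. %s)",
                  head(nucleotides[bad], 1L)))
  }
  frame_offset <- rep_len(as.integer(frame_offset), length(nucleotides))
  n_codon <- (nchar(nucleotides) - frame_offset) %/% 3L
  if (any(n_codon < 1L)) {
    abort("each read must contain at least one full codon after `frame_offset`")
  }
  framed <- substr(nucleotides, frame_offset + 1L, frame_offset + 3L * n_codon)

  has_n <- grepl("N", framed, fixed = TRUE)
  aa <- rep(NA_character_, length(framed))
  if (any(!has_n)) {
    aa[!has_n] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(framed[!has_n]),
      no.init.codon = TRUE
    ))
  }

  # stop codons translate to '*'; reject when one falls in the coding span
  span <- if (is.null(expected_codons)) nchar(aa) else
    pmin(expected_codons, nchar(aa))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  has_stop <- !is.na(aa) & stop_pos > 0L & stop_pos <= span

  reason <- rep(NA_character_, length(aa))
  reason[has_n] <- "ambiguous_base"
  reason[has_stop] <- "stop_codon"
  aa[has_stop] <- NA_character_
  tibble(aa = aa, reject_reason = reason)
}

#' Quality-control filter for translated amplicon reads
#'
#' Keeps a translated read iff it has exactly the expected amino-acid length
#' and its first six residues match the expected anchor with at most
#' `max_mismatch` substitutions. This reproduces the standard amplicon QC
#' used for site-saturation antibody libraries: correct length, correct
#' leading six amino acids, one amino-acid change in the anchor tolerated.
#'
#' @param aa Character vector of amino-acid sequences (`NA` allowed; `NA`
#'   never passes).
#' @param expected_length Integer, required amino-acid length.
#' @param anchor Six-residue character scalar the sequence must start with.
#' @param max_mismatch Maximum Hamming distance tolerated over the first six
#'   residues (default 1).
#' @return Logical vector, `TRUE` for reads to keep.
#' @export
qc_filter <- function(aa, expected_length, anchor, max_mismatch = 1L) {
  if (nchar(anchor) != 6L) abort("`anchor` must be exactly 6 residues")
  if (expected_length < 6L) abort("`expected_length` must be at least 6")
  ok_len <- !is.na(aa) & nchar(aa) == expected_length
  mm <- integer(length(aa))
  for (j in 1:6) {
    mm <- mm + (substr(aa, j, j) != substr(anchor, j, j))
  }
  ok_len & !is.na(mm) & mm <= max_mismatch
}

#' Extract the mutation string from a translated read
#'
#' Concatenates the residues at the mutagenized positions (1-based indices
#' into the amino-acid sequence, strictly increasing). The resulting short
#' string is the clone identifier used throughout the package.
#'
#' @param aa Character vector of amino-acid sequences.
#' @param positions Integer vector of 1-based positions, strictly increasing.
#' @return Character vector of mutation strings.
#' @examples
#' extract_mutation_string("QSVSASFYYATYIK", positions = c(4:8, 9:13))
#' @export
extract_mutation_string <- function(aa, positions) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing")
  }
  if (length(aa) > 0L && any(positions > min(nchar(aa)) | positions < 1L)) {
    abort("`positions` out of range for at least one sequence")
  }
  do.call(paste0, lapply(positions, function(p) substr(aa, p, p)))
}

#' Tally mutation strings for one sequencing sample
#'
#' Exact multiset counts of the mutation strings observed in one
#' (round, replicate) sample.
#'
#' @param strings Character vector of mutation strings (all the same length).
#' @param round Round label (e.g. `"R5"`).
#' @param replicate Integer replicate index (>= 1).
#' @return Tibble with columns `mutation_string`, `round`, `replicate`,
#'   `count`, one row per unique string, ordered by descending count then
#'   lexicographically.
#' @export
tally_reads <- function(strings, round, replicate = 1L) {
  check_mutation_strings(strings)
  if (length(unique(nchar(strings))) > 1L) {
    abort("all mutation strings must have the same length")
  }
  if (length(strings) == 0L) {
    return(tibble(mutation_string = character(), round = character(),
                  replicate = integer(), count = integer()))
  }
  tab <- table(strings)
  tibble(
    mutation_string = names(tab),
    round = as.character(round),
    replicate = as.integer(replicate),
    count = as.integer(tab)
  ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$mutation_string)
}

#' Tally one merged-read file into mutation-string counts
#'
#' Runs the full per-sample read pipeline: parse FASTA/FASTQ, translate from
#' the sample's frame offset, apply the length + anchor QC filter, extract
#' the mutation string, and count unique strings.
#'
#' @param file Path to a FASTA or FASTQ file of merged reads (gzip accepted;
#'   format detected from the extension, `.fastq`/`.fq` vs anything else).
#' @param round,replicate Sample labels recorded in the output.
#' @param frame_offset Bases to skip before the first codon (see
#'   [translate_reads()]).
#' @param anchor,expected_length,max_mismatch QC parameters (see
#'   [qc_filter()]).
#' @param positions 1-based mutagenized positions (see
#'   [extract_mutation_string()]).
#' @param verbose Emit a one-line QC attrition summary.
#' @return A tibble as from [tally_reads()], with a `"qc"` attribute: a
#'   one-row tibble of reads seen / rejected by reason / kept.
#' @export
tally_sample <- function(file, round, replicate, frame_offset, anchor,
                         expected_length, positions, max_mismatch = 1L,
                         verbose = TRUE) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", file)) "fastq" else "fasta"
  reads <- Biostrings::readDNAStringSet(file, format = fmt)
  nt <- as.character(reads)
  tr <- translate_reads(nt, frame_offset = frame_offset,
                        expected_codons = expected_length)
  keep <- qc_filter(tr$aa, expected_length, anchor, max_mismatch)
  strings <- extract_mutation_string(tr$aa[keep], positions)
  qc <- tibble(
    round = as.character(round), replicate = as.integer(replicate),
    reads = length(nt),
    rejected_ambiguous_base = sum(tr$reject_reason == "ambiguous_base", na.rm = TRUE),
    rejected_stop_codon = sum(tr$reject_reason == "stop_codon", na.rm = TRUE),
    rejected_qc = sum(!keep) -
      sum(!is.na(tr$reject_reason)),
    kept = sum(keep)
  )
  if (verbose) {
    inform(sprintf(
      "[%s rep %d] %d reads: %d kept, %d ambiguous-base, %d stop-codon, %d failed length/anchor QC",
      qc$round, qc$replicate, qc$reads, qc$kept, qc$rejected_ambiguous_base,
      qc$rejected_stop_codon, qc$rejected_qc))
  }
  out <- tally_reads(strings, round = round, replicate = replicate)
  attr(out, "qc") <- qc
  out
}

#' Read a sequencing-sample manifest
#'
#' A manifest (YAML or JSON) declares the amplicon layout once and lists one
#' merged-read file per (round, replicate):
#'
#' ```yaml
#' rounds: [R2, R3, R5, R6, R7]
#' anchor: DIQMTQ
#' expected_length: 30
#' positions: [8, 9, 10, 11, 12, 20, 21, 22, 23, 24]
#' wt_string: TFSNYAWMSY
#' samples:
#'   - {file: R2_rep1.fastq, round: R2, replicate: 1, frame_offset: 0}
#'   - ...
#' ```
#'
#' Per-sample keys override the top-level defaults. Relative file paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to the manifest file (`.yaml`/`.yml` or `.json`).
#' @return A tibble with one row per sample (`file`, `round`, `replicate`,
#'   `frame_offset`, `anchor`, `expected_length`, `positions` list-column),
#'   with attributes `rounds` (ordered round labels) and `wt_string`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  for (key in c("rounds", "samples")) {
    if (is.null(m[[key]])) abort(sprintf("manifest is missing `%s`", key))
  }
  samples <- m$samples
  if (is.data.frame(samples)) samples <- split(samples, seq_len(nrow(samples)))
  rows <- purrr::map(samples, function(s) {
    s <- as.list(s)
    get <- function(key, default = NULL) s[[key]] %||% m[[key]] %||% default
    for (key in c("file", "round", "replicate", "anchor", "expected_length",
                  "positions")) {
      if (is.null(get(key))) {
        abort(sprintf("manifest sample is missing `%s` (no top-level default)", key))
      }
    }
    f <- get("file")
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(dirname(path), f)
    tibble(
      file = f,
      round = as.character(get("round")),
      replicate = as.integer(get("replicate")),
      frame_offset = as.integer(get("frame_offset", 0L)),
      anchor = as.character(get("anchor")),
      expected_length = as.integer(get("expected_length")),
      positions = list(as.integer(unlist(get("positions"))))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!all(out$round %in% m$rounds)) {
    abort("manifest sample uses a round label not listed in `rounds`")
  }
  attr(out, "rounds") <- as.character(m$rounds)
  attr(out, "wt_string") <- if (!is.null(m$wt_string)) as.character(m$wt_string) else NULL
  out
}

#' Tally every sample in a manifest
#'
#' @param manifest Path to a manifest file, or the tibble returned by
#'   [read_manifest()].
#' @param verbose Emit per-sample QC summaries.
#' @return A tibble of per-(round, replicate) mutation-string counts
#'   (rows from [tally_sample()] bound together), with attributes `rounds`,
#'   `wt_string` and `qc` (per-sample attrition table).
#' @export
tally_manifest <- function(manifest, verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tallies <- purrr::pmap(manifest, function(file, round, replicate,
                                            frame_offset, anchor,
                                            expected_length, positions) {
    tally_sample(file, round, replicate, frame_offset, anchor,
                 expected_length, positions, verbose = verbose)
  })
  qc <- dplyr::bind_rows(purrr::map(tallies, attr, "qc"))
  out <- dplyr::bind_rows(tallies)
  attr(out, "rounds") <- attr(manifest, "rounds")
  attr(out, "wt_string") <- attr(manifest, "wt_string")
  attr(out, "qc") <- qc
  out
}
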