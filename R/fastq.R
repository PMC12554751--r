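#' Amplicon read layout for simulated FASTQ emission
#'
#' Describes how a mutation string is embedded in a merged amplicon read:
#' a six-residue anchor at the start, a fixed amino-acid template, and the
#' 1-based template positions carrying the mutagenized residues (two
#' five-site CDR blocks by default, mirroring a heavy-CDR1 + light-CDR2
#' library). Nucleotide reads are built by reverse-translating the template
#' with one fixed NNK codon per amino acid, so emitted reads are valid
#' inputs for the read-tallying pipeline.
#'
#' @param L Number of mutagenized positions (must match the campaign).
#' @param anchor Six leading residues of every correct read.
#' @return A `read_layout` list: `anchor`, `template` (amino-acid string with
#'   placeholder residues at the mutated sites), `positions`,
#'   `expected_length`.
#' @export
read_layout <- function(L = 10L, anchor = "DIQMTQ") {
  if (nchar(anchor) != 6L) abort("`anchor` must be 6 residues")
  half <- ceiling(L / 2L)
  gap <- 7L
  positions <- c(seq.int(8L, 7L + half),
                 seq.int(7L + half + gap + 1L, 7L + gap + L))
  expected_length <- max(positions) + 6L
  template <- rep("G", expected_length)
  template[seq_len(6L)] <- strsplit(anchor, "", fixed = TRUE)[[1L]]
  filler <- setdiff(seq_len(expected_length), c(seq_len(6L), positions))
  template[filler] <- rep(c("S", "T", "G", "L"), length.out = length(filler))
  structure(list(anchor = anchor, template = paste(template, collapse = ""),
                 positions = positions, expected_length = expected_length),
            class = "read_layout")
}

# internal: one fixed NNK codon per amino acid (alphabetically first)
nnk_codon_map <- function() {
  codons <- sort(nnk_codons())
  aa <- Biostrings::GENETIC_CODE[codons]
  codons[!duplicated(aa)] |> setNames(aa[!duplicated(aa)]) |>
    (\(x) x[AA_ALPHABET])()
}

# internal: nucleotide read for each mutation string under a layout
reads_for_strings <- function(strings, layout) {
  cmap <- nnk_codon_map()
  tpl <- strsplit(layout$template, "", fixed = TRUE)[[1L]]
  tpl_codons <- cmap[tpl]
  vapply(strsplit(strings, "", fixed = TRUE), function(res) {
    cods <- tpl_codons
    cods[layout$positions] <- cmap[res]
    paste(cods, collapse = "")
  }, character(1L))
}

#' Emit simulated FASTQ files and a manifest for a campaign
#'
#' Writes one FASTQ file per (round, replicate) whose reads reproduce the
#' campaign's sequenced tallies exactly, plus a YAML manifest declaring the
#' amplicon layout, so `tally_manifest()` on the emitted files round-trips
#' the campaign's clone counts. Each sample gets a single-base frame shift
#' (cycling 0/1/2), as amplicon designs use to decrease flow-cell sequence
#' homology; shifted reads are padded with leading/trailing bases.
#'
#' @param campaign A [simulate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @param layout A [read_layout()]; defaults to the campaign's `L`.
#' @param gzip Write gzipped FASTQ (default `FALSE`).
#' @return Path to the written manifest (`manifest.yaml`), invisibly.
#' @export
write_campaign_fastq <- function(campaign, dir, layout = NULL, gzip = FALSE) {
  stopifnot(inherits(campaign, "sim_campaign"))
  layout <- layout %||% read_layout(L = campaign$config$L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- campaign$config
  samples <- list()
  i <- 0L
  for (r in cfg$rounds) {
    for (k in seq_len(cfg$replicates)) {
      i <- i + 1L
      offset <- (i - 1L) %% 3L
      tb <- dplyr::filter(campaign$tallies, .data$round == r,
                          .data$replicate == k)
      nt <- reads_for_strings(tb$mutation_string, layout)
      nt <- paste0(substr("GT", 1L, offset), nt)
      seqs <- rep(nt, tb$count)
      fn <- sprintf("%s_rep%d.fastq%s", r, k, if (gzip) ".gz" else "")
      path <- file.path(dir, fn)
      con <- if (gzip) gzfile(path, "w") else file(path, "w")
      if (length(seqs) > 0L) {
        qual <- strrep("I", nchar(seqs[[1L]]))
        writeLines(paste0("@", r, "_", k, "_", seq_along(seqs), "\n",
                          seqs, "\n+\n", qual), con)
      }
      close(con)
      samples[[i]] <- list(file = fn, round = r, replicate = k,
                           frame_offset = offset)
    }
  }
  manifest <- list(
    rounds = as.list(cfg$rounds), anchor = layout$anchor,
    expected_length = layout$expected_length,
    positions = as.list(layout$positions),
    wt_string = cfg$wt_string, samples = samples
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
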