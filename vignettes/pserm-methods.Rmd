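---
title: "Scoring directed-evolution deep sequencing with PSERMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring directed-evolution deep sequencing with PSERMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pserm)
library(dplyr)
```

## The problem

Directed-evolution campaigns — here, yeast-display affinity maturation of an
antibody against a conformational amyloid epitope — end with deep sequencing
of several sorting rounds and a question: *which of the thousands of observed
variants should be expressed and characterized?* Two features of real
campaigns make the obvious answers unreliable:

* the parental (wild-type) clone dominates every sequenced round, typically
  at 90–95% of reads, so single-round frequency mostly measures how well a
  clone has always been there, not how fast it is improving;
* the most interesting variants can sit at frequencies of $10^{-5}$–$10^{-6}$,
  where per-clone read counts are single digits and clone-level enrichment
  ratios between rounds are dominated by sampling noise.

Position-specific enrichment ratio matrices (PSERMs) address both problems by
pooling evidence across clones at the level of residues. Every read that
carries a given residue at a given mutagenized position contributes to that
residue's enrichment estimate, so a rare clone is scored by the behaviour of
its ten residues across the whole library rather than by its own handful of
reads.

## From reads to a clone table

The unit of identity is the **mutation string**: the concatenated amino acids
at the `L` mutagenized CDR positions (ten in the motivating campaign: five in
heavy-chain CDR1, five in light-chain CDR2). Merged amplicon reads are
processed per (round, replicate) sample:

1. translate from the sample's configured frame offset (amplicon designs
   often stagger samples by one base to decrease flow-cell homology); reads
   with an ambiguous base in an in-frame codon, or a stop codon inside the
   expected coding span, are rejected;
2. keep reads of exactly the expected amino-acid length whose first six
   residues match the expected anchor with at most one substitution;
3. slice out the mutation string and tally unique strings.

Replicate samples are then merged into a **clone table**. A clone's frequency
in a replicate is its count over that replicate's total QC-passing reads;
per-round frequencies are replicate means, with an unobserved
(round, replicate) contributing zero. Two consistency filters are provided:
the permissive set (present in all replicates of *some* round) used for
matrix construction, and the strict candidate set (present in all replicates
of *every* non-terminal round, terminal-round presence optional) used for
scoring. Totals are always taken from the unfiltered tallies, so filtering
never changes a frequency.

Positions are supplied 1-based, as is idiomatic in R; the mapping from
antibody numbering schemes (Kabat H27, L50, ...) to read coordinates is
configuration, not code. The amino-acid length is what is checked against
`expected_length` (the read's trailing bases beyond the coding span are
ignored); only the first six residues are compared to a template, a literal
reading of the QC rule this pipeline reproduces.

## Matrices

For round $r$ with $N$ total clone observations (reads assigned to clones in
the table, replicates summed):

* **Count matrix** $c_{a,j}$: each clone with residue $a$ at position $j$
  adds its observation count — a clone seen 8 times adds 8 to one cell of
  every column.
* **Position probability matrix (PPM)** with square-root pseudocounts:
  $$p_{a,j} = \frac{c_{a,j} + \sqrt{N}}{N + 20\sqrt{N}}.$$
  The pseudocount grows with round depth but its *relative* weight
  $\sqrt{N}/N$ shrinks, and every entry stays strictly positive so log
  scores are finite.
* **PSSM** in bits against a flat background $b$ (default 5% $= 1/20$):
  $s_{a,j} = \log_2(p_{a,j}/b)$.
* **PSERM** for a consecutive round pair: the elementwise PSSM difference
  $s^{\text{late}}_{a,j} - s^{\text{early}}_{a,j} = \log_2(p^{\text{late}}_{a,j}/p^{\text{early}}_{a,j})$.
  The background cancels; what remains is per-residue enrichment between
  rounds. Differencing also removes the wild-type saturation: a dominant
  parental clone gives its residues the column-maximum PSSM score in every
  round, but contributes nothing to the difference unless it is actually
  still enriching.

Two interpretation choices here were genuinely open and are recorded as
explicit arguments rather than hidden constants:

* "pseudocounts added to each amino acid at every position" is implemented
  as $\sqrt N$ added to **every cell** (denominator $N + 20\sqrt N$); the
  `pseudocount` argument of `ppm()` lets a user divide $\sqrt N$ across the
  alphabet instead.
* "total number of sequences observed in the round" is read as total
  **observations** (consistent with a worked count-matrix example where one
  clone contributes 8 counts per column), not unique clones.
* matrices are built from replicate-summed integer counts; the
  replicate-averaged frequencies are reserved for the comparator metrics
  below.

## Scoring and selection

A clone's score under a PSERM is the sum of its $L$ matrix lookups,
$S_i = \sum_j s_{s_i[j],\,j}$, in bits. The default selection procedure
mirrors standard practice:

1. build PSERMs for the last two consecutive round pairs (R7−R6 and R6−R5 in
   the default round order);
2. rank candidates under each PSERM (wild type excluded by default;
   `exclude_wt = FALSE` reruns everything with it retained — the two modes
   give highly correlated scores since the wild type enters only through
   matrix construction either way);
3. intersect the two top-$K$ sets ($K = 40$ by default, a configurable
   argument);
4. remove clones whose mutation string contains a cysteine — introduced at a
   mutagenized CDR position it has no disulfide partner and is a
   developability liability.

Comparator metrics computed alongside: terminal-round frequency
$f_{i,R7}$, global enrichment ratio $\log_2(f_{i,R7}/f_{i,R2})$ and local
enrichment ratio $\log_2(f_{i,R7}/f_{i,R6})$. A ratio with a zero numerator
or denominator is undefined; such clones are **excluded from that metric's
ranking** rather than imputed with a pseudo-frequency — imputation would
amount to inventing a prior, and the exclusion is visible per clone in the
tidied report. Ties in any ranking are broken lexicographically on the
mutation string, so rankings are deterministic.

`net_charge()` implements the Henderson–Hasselbalch sum over ionizable side
chains (R, K, H positive; D, E, C, Y negative) at pH 7.4 by default, with
termini off — the convention for CDR fragments inside an intact chain. The
default pKa set (D 3.65, E 4.25, H 6.00, C 8.30, Y 10.07, K 10.53, R 12.48)
is a standard side-chain table; published per-antibody totals shift by a few
tenths under different tables or CDR definitions, so tests assert signs and
term-by-term values, not literature totals.

## The synthetic campaign generator

`simulate_campaign()` generates the full object the analysis consumes, plus
the ground truth it never sees:

* **Initial pool**: wild type at `wt_fraction` (default 0.92); `n_variants`
  (default 5000) distinct strings mutated at 1–3 positions with
  substitutions drawn from the exact NNK codon-table marginals (stop
  excluded, so L/R/S at 3/31, most residues 1/31); the residual mass spread
  by a Dirichlet(0.5) draw, giving a long tail of clones down to
  $10^{-5}$–$10^{-6}$.
* **Fitness**: additive per-position effects $e_{a,j} \sim N(0, 0.08)$ with
  wild-type residues pinned at 0, so $w(s) = \exp\sum_j e_{s[j],j}$ and
  $w(\text{WT}) = 1$.
* **Selection round**: the deterministic expected update
  $f'(s) \propto f(s)\,w(s)^{\beta_r}$. Stringency increases over the five
  sequenced rounds (default $\beta$ = 0.3, 0.5, 0.8, 1.1, 1.4), standing in
  for progressively harsher washes; $\beta = 0$ is a neutral pass-through.
* **Sequencing**: independent multinomial draws of `depth` reads (default
  $10^6$) per replicate (default 2), optionally with a per-residue
  substitution error rate, and optional FASTQ emission (anchor + template +
  per-clone codons, per-sample frame shifts) that round-trips exactly
  through the read pipeline.

The defaults were fixed once to reproduce the campaign regime the analysis
is designed for — a wild type holding 90–95% of reads in **every** sequenced
round, thousands of rare variants, increasing stringency, duplicate
sequencing. The effect scale is the one free parameter with no reported
counterpart; 0.08 keeps the wild type inside the 90–95% band across seeds
while leaving enough fitness signal that selection visibly enriches
(larger values let occasional lucky landscapes push the wild type below
90% by the terminal round, leaving the intended regime).

What the generator deliberately does **not** model: bead-capture physics and
off-rate-dependent wash survival (selection is a single scalar fitness),
negative sorting against a second antigen form (conformational
counter-selection would need a second latent trait), epistasis (the
landscape is additive, which also makes the closed-form round update
testable), PCR amplification bias, and read-quality structure. Passing
benchmarks therefore demonstrate that the *analysis* behaves correctly in
this regime — they are not evidence about selection physics, and real
campaigns with strong epistasis or correlated sequencing artifacts can
degrade any residue-additive score.

## Numerical choices and degenerate inputs

* A PPM cannot be built for an empty round ($N = 0$: the pseudocount rule
  degenerates); this is an error, not a silent uniform matrix.
* PSERM background invariance is exact in real arithmetic but only
  equal to rounding (~1 ulp) in floating point, since
  $\log_2(p/b) - \log_2(q/b)$ is not evaluated as $\log_2(p/q)$; numerical
  tests compare at $10^{-12}$.
* Oracle-equivalence tests run the whole chain against naive loop-based
  references on 1000 random instances (≤ 10 clones, L ≤ 4) at $10^{-12}$.
* Clone tables are written as TSV with full-precision doubles and
  `#key=value` metadata headers, so a write/read round trip reproduces
  counts exactly and frequencies to machine precision.
* All simulator randomness flows through a single `set.seed()` call per
  campaign; identical config + seed gives bit-identical output.

## Problem sizes used by the test suite

The packaged checks use campaign sizes chosen to exercise the full regime at
desk scale: the FASTQ round trip runs the default library at $10^5$ reads ×
2 replicates × 5 rounds (a million reads end to end), and the recovery
benchmark runs ten independent campaigns at the full default depth of
$10^6$ reads per replicate (counts only, no FASTQ materialization). In that
benchmark the mean true fitness of the final PSERM-overlap selection sits
above the library's 99th fitness percentile, and the terminal PSERM's top-40
capture of the true top-1% fitness clones exceeds terminal-frequency,
global- and local-enrichment-ratio capture in essentially every campaign —
the in-silico counterpart of the empirical observation that PSERM scoring
was the only metric to recover all validated high-affinity variants.

## Known limitations

* Reading-frame offsets are per-sample configuration; there is no
  auto-detection of frames or of the amplicon layout.
* The QC template covers only the six anchor residues; downstream read
  positions outside the mutated sites are not validated against the
  scaffold.
* Enrichment-ratio exclusions mean very rare clones may simply have no
  defined comparator metric; this is reported, not worked around.
* Reproducing a full campaign's milestone counts (thousands of
  replicate-common clones, hundreds of multi-round-common candidates)
  requires the original raw reads and amplicon configuration; the pipeline
  logs exactly these milestone counts so the comparison is mechanical once
  data are in hand.
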