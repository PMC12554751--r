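#' Default side-chain pKa values
#'
#' Ionizable side chains only: basic R, K, H and acidic D, E, C, Y.
#' Values are standard textbook side-chain pKa's; published net charges for
#' a given antibody can shift by a few tenths under a different table or
#' CDR definition.
#'
#' @format Named numeric vector.
#' @export
DEFAULT_PKA <- c(D = 3.65, E = 4.25, H = 6.00, C = 8.30, Y = 10.07,
                 K = 10.53, R = 12.48)

#' Net charge of a peptide at a given pH
#'
#' Henderson–Hasselbalch sum over ionizable groups, in elementary charges:
#' each basic side chain (R, K, H) contributes `+1 / (1 + 10^(pH - pKa))`
#' and each acidic side chain (D, E, C, Y) contributes
#' `-1 / (1 + 10^(pKa - pH))`. Chain termini are excluded by default, which
#' is the convention for scoring CDR fragments that sit inside an intact
#' antibody chain. Positively charged CDRs are associated with increased
#' nonspecific binding, which is why this quantity is a routine
#' developability check.
#'
#' @param seq Character vector of amino-acid sequences (canonical residues).
#' @param pH pH at which to evaluate (default 7.4, physiological).
#' @param pKa Named pKa table for side chains (default [DEFAULT_PKA]).
#' @param include_termini Add the free alpha-amino (+) and alpha-carboxyl
#'   (-) terminal groups (pKa 9.0 and 3.1).
#' @return Numeric vector of net charges, one per sequence.
#' @examples
#' net_charge("DRGIGARRGPYYMD")      # arginine-rich: positive at pH 7.4
#' net_charge("DGYDGSYFVGYDYNDFYDY") # acidic: negative at pH 7.4
#' @export
net_charge <- function(seq, pH = 7.4, pKa = DEFAULT_PKA,
                       include_termini = FALSE) {
  if (any(pKa <= 0 | pKa >= 14)) abort("pKa values must be in (0, 14)")
  check_mutation_strings(seq)
  if (any(!nzchar(seq))) abort("`seq` must be non-empty")
  basic <- intersect(names(pKa), c("R", "K", "H"))
  acidic <- intersect(names(pKa), c("D", "E", "C", "Y"))
  vapply(seq, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    q <- 0
    for (a in basic) {
      q <- q + sum(res == a) / (1 + 10^(pH - pKa[[a]]))
    }
    for (a in acidic) {
      q <- q - sum(res == a) / (1 + 10^(pKa[[a]] - pH))
    }
    if (include_termini) {
      q <- q + 1 / (1 + 10^(pH - 9.0)) - 1 / (1 + 10^(3.1 - pH))
    }
    q
  }, numeric(1L), USE.NAMES = FALSE)
}
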