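# The degradation channel as the decoder sees it: whole-strand erasures
# from breakage (mitigated by physical copies) and per-symbol errors from
# synthesis/sequencing noise.

#' Channel parameters for a DNA storage system
#'
#' Bundles the physical parameters that determine what the decoder sees:
#' strand length, number of molecular copies of each distinct strand,
#' per-nucleotide symbol-error rate, and the per-nucleotide breakage
#' coefficient. The breakage coefficient default (5e-3) follows the
#' linear-in-length erasure model used in published tradeoff analyses,
#' `p_erasure = (L * 5e-3)^c`; note that the same analyses also describe a
#' calibration ("1000-nt strands erase with probability 50% or less")
#' that corresponds to 5e-4, so the coefficient is deliberately a free
#' parameter rather than a constant.
#'
#' @param strand_length Strand length in nt (>= 1).
#' @param copies Number of physical copies of each distinct strand
#'   (integer >= 1). A strand is erased only if every copy is lost.
#' @param p_error_per_nt Probability of a substitution/insertion/deletion
#'   per nucleotide, in \[0, 1\]. Insertions and deletions are folded into
#'   the per-symbol error probability.
#' @param breakage_factor Per-nucleotide erasure coefficient (default
#'   5e-3). `strand_length * breakage_factor` is clamped to \[0, 1\]
#'   before exponentiation so the result is a probability.
#' @param nt_per_symbol Nucleotides per 8-bit code symbol (default 4:
#'   2 bits per nt).
#' @return An object of class `channel_params`.
#' @export
#' @examples
#' ch <- channel_params(strand_length = 100, copies = 2)
#' strand_erasure_prob(ch) # (100 * 5e-3)^2 = 0.25
channel_params <- function(strand_length, copies = 1, p_error_per_nt = 0,
                           breakage_factor = 5e-3, nt_per_symbol = 4) {
  check_scalar(strand_length, "strand_length", lower = 1)
  check_count(copies, "copies", min = 1L)
  check_scalar(p_error_per_nt, "p_error_per_nt", lower = 0, upper = 1)
  check_scalar(breakage_factor, "breakage_factor", lower = 0)
  check_count(nt_per_symbol, "nt_per_symbol", min = 1L)
  structure(list(strand_length = strand_length,
                 copies = as.integer(copies),
                 p_error_per_nt = p_error_per_nt,
                 breakage_factor = breakage_factor,
                 nt_per_symbol = as.integer(nt_per_symbol)),
            class = "channel_params")
}

#' Probability that a strand is erased (all copies lost)
#'
#' `min(1, L * breakage_factor)^copies`. Monotone increasing in strand
#' length; each additional physical copy multiplies the loss probability
#' by the per-copy loss probability, so redundant copies suppress erasure
#' geometrically.
#'
#' @param params A [channel_params()] object.
#' @return Erasure probability in \[0, 1\].
#' @export
strand_erasure_prob <- function(params) {
  stopifnot(inherits(params, "channel_params"))
  min(1, params$strand_length * params$breakage_factor)^params$copies
}

#' Probability that a code symbol is corrupted
#'
#' A symbol spans `nt_per_symbol` nucleotides and is wrong if any of them
#' is: `1 - (1 - p_error_per_nt)^nt_per_symbol`, always at most the union
#' bound `nt_per_symbol * p_error_per_nt`.
#'
#' @param params A [channel_params()] object.
#' @return Symbol error probability in \[0, 1\].
#' @export
symbol_error_prob <- function(params) {
  stopifnot(inherits(params, "channel_params"))
  1 - (1 - params$p_error_per_nt)^params$nt_per_symbol
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf(
    "Channel: L = %g nt, copies = %d, p_error = %.3g/nt, breakage = %.3g/nt\n",
    x$strand_length, x$copies, x$p_error_per_nt, x$breakage_factor))
  cat(sprintf("  strand erasure prob %.4g, symbol error prob %.4g\n",
              strand_erasure_prob(x), symbol_error_prob(x)))
  invisible(x)
}
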