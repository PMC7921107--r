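# Analytic decoding-failure probabilities for the concatenated
# inner-outer Reed-Solomon architecture: the inner code corrects symbol
# errors within one strand, the outer code spans 255 strands (one outer
# symbol per strand) and corrects whole-strand erasures and erroneous
# strands.

#' Reed-Solomon block code
#'
#' An \[n, k\] Reed-Solomon code over 8-bit symbols with minimum distance
#' `d = n - k + 1`. RS decoding succeeds whenever `2t + e <= d - 1` for
#' `t` symbol errors and `e` erasures.
#'
#' @param n Block length in symbols, 1..255.
#' @param k Message length in symbols, 1..n.
#' @return An object of class `rs_code` with fields `n`, `k`, `d`.
#' @export
#' @examples
#' rs_code(255, 223) # the classic outer code, d = 33
rs_code <- function(n, k) {
  check_count(n, "n", min = 1L)
  check_count(k, "k", min = 1L)
  if (n > 255) stop("`n` must be <= 255 for 8-bit symbols", call. = FALSE)
  if (k > n) stop("`k` must be <= `n`", call. = FALSE)
  structure(list(n = as.integer(n), k = as.integer(k),
                 d = as.integer(n - k + 1L)), class = "rs_code")
}

#' Concatenated inner-outer code design
#'
#' The physical layout of one outer block: 255 strands (by default), each
#' carrying one inner codeword of `inner$n` symbols plus `address_nt`
#' nucleotides of primer/address overhead. The first `index_symbols`
#' payload symbols of each strand hold its position within the block.
#'
#' @param outer Outer [rs_code()] across strands (default RS\[255,223\]).
#' @param inner Inner [rs_code()] within each strand.
#' @param index_symbols Symbols of index overhead carried inside the inner
#'   payload (default 4). Must be < `inner$k`.
#' @param address_nt Nucleotides of address/primer overhead per strand
#'   (default 40: a 20-nt primer target at each end).
#' @param nt_per_symbol Nucleotides per 8-bit symbol (default 4).
#' @return An object of class `concatenated_design`.
#' @export
concatenated_design <- function(outer = rs_code(255, 223), inner,
                                index_symbols = 4, address_nt = 40,
                                nt_per_symbol = 4) {
  stopifnot(inherits(outer, "rs_code"), inherits(inner, "rs_code"))
  check_count(index_symbols, "index_symbols")
  check_count(address_nt, "address_nt")
  check_count(nt_per_symbol, "nt_per_symbol", min = 1L)
  if (inner$k <= index_symbols) {
    stop("inner code must have k > index_symbols (no payload otherwise)",
         call. = FALSE)
  }
  structure(list(outer = outer, inner = inner,
                 index_symbols = as.integer(index_symbols),
                 address_nt = as.integer(address_nt),
                 nt_per_symbol = as.integer(nt_per_symbol)),
            class = "concatenated_design")
}

#' Physical strand length of a design, in nucleotides
#' @param design A [concatenated_design()].
#' @return Strand length `address_nt + inner$n * nt_per_symbol`.
#' @export
strand_length_nt <- function(design) {
  stopifnot(inherits(design, "concatenated_design"))
  design$address_nt + design$inner$n * design$nt_per_symbol
}

#' Can an RS code correct a given error/erasure pattern?
#'
#' @param code An [rs_code()].
#' @param errors Number of symbol errors t (vectorized).
#' @param erasures Number of erasures e (vectorized).
#' @return Logical: `2t + e <= d - 1`.
#' @export
correctable <- function(code, errors, erasures) {
  stopifnot(inherits(code, "rs_code"))
  check_count(errors, "errors")
  check_count(erasures, "erasures")
  if (any(errors + erasures > code$n)) {
    stop("errors + erasures cannot exceed the block length", call. = FALSE)
  }
  2 * errors + erasures <= code$d - 1
}

#' Probability the inner decode of one strand fails
#'
#' The inner code corrects up to `t = floor((d - 1) / 2)` symbol errors;
#' with i.i.d. symbol corruption the failure probability is the binomial
#' upper tail `P[X > t]`, `X ~ Binomial(inner$n, p_symbol)`, evaluated in
#' the log domain so tails far below 1e-30 retain relative accuracy.
#'
#' @param inner An [rs_code()].
#' @param p_symbol Per-symbol corruption probability in \[0, 1\].
#' @return Failure probability in \[0, 1\].
#' @export
inner_failure_prob <- function(inner, p_symbol) {
  stopifnot(inherits(inner, "rs_code"))
  check_scalar(p_symbol, "p_symbol", lower = 0, upper = 1)
  t <- (inner$d - 1) %/% 2
  exp(lbinom_tail(inner$n, p_symbol, t + 1L))
}

#' Erasure and error probabilities of one outer-code symbol
#'
#' One outer symbol is carried per strand, so it is erased when the
#' strand is physically lost, or when the strand survives but its inner
#' decode fails (inner failures are detected and flagged to the outer
#' decoder as erasures). Silent inner miscorrections are not modeled by
#' default, so the symbol-error component is 0; the slot exists so the
#' fully general trinomial outer analysis stays available.
#'
#' @param design A [concatenated_design()].
#' @param channel A [channel_params()] whose `strand_length` equals the
#'   design's [strand_length_nt()].
#' @return A list with `p_symbol_erasure` and `p_symbol_error`.
#' @export
outer_symbol_channel <- function(design, channel) {
  stopifnot(inherits(design, "concatenated_design"),
            inherits(channel, "channel_params"))
  if (channel$strand_length != strand_length_nt(design)) {
    stop(sprintf(
      "channel strand_length (%g nt) does not match the design (%d nt)",
      channel$strand_length, strand_length_nt(design)), call. = FALSE)
  }
  p_lost <- strand_erasure_prob(channel)
  p_if <- inner_failure_prob(design$inner, symbol_error_prob(channel))
  list(p_symbol_erasure = p_lost + (1 - p_lost) * p_if,
       p_symbol_error = 0)
}

# log P[outer decode fails]: exact trinomial sum over the (errors T,
# erasures E) lattice of n symbols, each independently erroneous /
# erased / clean; failure iff 2T + E > d - 1. O(n^2) terms, log domain.
outer_decoding_lfail <- function(outer, p_erasure, p_error = 0) {
  stopifnot(inherits(outer, "rs_code"))
  check_scalar(p_erasure, "p_erasure", lower = 0, upper = 1)
  check_scalar(p_error, "p_error", lower = 0, upper = 1)
  if (p_erasure + p_error > 1 + 1e-12) {
    stop("p_erasure + p_error must be <= 1", call. = FALSE)
  }
  n <- outer$n
  d <- outer$d
  p_clean <- max(0, 1 - p_erasure - p_error)
  terms <- vector("list", n + 1L)
  for (t in 0:n) {
    e_min <- max(0L, d - 2L * t)
    e_max <- n - t
    if (e_min > e_max) next
    e <- e_min:e_max
    terms[[t + 1L]] <- lchoose(n, t) + lchoose(n - t, e) +
      xlogy(t, p_error) + xlogy(e, p_erasure) + xlogy(n - t - e, p_clean)
  }
  lf <- logsumexp(unlist(terms))
  min(lf, 0) # guard against rounding slightly above log(1)
}

#' Probability the outer RS decode fails
#'
#' Each of the outer code's `n` symbols is independently erased (with
#' probability `p_erasure`), silently erroneous (`p_error`), or clean.
#' The decode fails when `2T + E > d - 1`; this function evaluates that
#' trinomial tail exactly (O(n^2) terms, log-domain accumulation). Use
#' [log10_outer_decoding_error()] when the value itself would underflow
#' double precision.
#'
#' @param outer An [rs_code()].
#' @param p_erasure Per-symbol erasure probability.
#' @param p_error Per-symbol silent-error probability
#'   (`p_erasure + p_error <= 1`).
#' @return Failure probability in \[0, 1\].
#' @export
#' @examples
#' outer_decoding_error_prob(rs_code(3, 1), p_erasure = 0.5) # 0.125
outer_decoding_error_prob <- function(outer, p_erasure, p_error = 0) {
  exp(outer_decoding_lfail(outer, p_erasure, p_error))
}

#' Base-10 log of the outer decoding failure probability
#'
#' @inheritParams outer_decoding_error_prob
#' @return `log10` of the failure probability (`-Inf` at 0); finite and
#'   accurate even when the probability is far below 1e-300.
#' @export
log10_outer_decoding_error <- function(outer, p_erasure, p_error = 0) {
  outer_decoding_lfail(outer, p_erasure, p_error) / log(10)
}

#' Decoder error probability versus strand length
#'
#' Re-evaluates the full chain (channel -> inner code -> outer code) over
#' a grid of strand lengths. For each length the inner block length is
#' recomputed from the fixed address overhead and symbol size,
#' `inner_n = floor((L - address_nt) / nt_per_symbol)`, while the inner
#' code keeps the template design's redundancy `inner$n - inner$k`; the
#' outer code, index, and address overhead are held fixed. Under the
#' linear-breakage channel the resulting decoder error probability is
#' non-decreasing in strand length, non-increasing in copies, and
#' non-increasing as the per-nt error rate drops.
#'
#' @param design Template [concatenated_design()] providing the outer
#'   code, inner redundancy, index, address, and symbol size.
#' @param lengths Strand lengths (nt) to evaluate. Each must be long
#'   enough to hold the address plus index, one payload symbol, and the
#'   inner parity.
#' @param copies Physical copy number (default 1).
#' @param p_error_per_nt Per-nucleotide error rate.
#' @param breakage_factor Per-nucleotide erasure coefficient (default
#'   5e-3).
#' @return A data frame with one row per length: `length`, `copies`,
#'   `p_error`, `inner_n`, `inner_k`, `p_symbol_erasure`,
#'   `p_symbol_error`, `decoder_error_prob`, `log10_decoder_error`.
#' @export
system_error_curve <- function(design, lengths, copies = 1,
                               p_error_per_nt = 1e-3,
                               breakage_factor = 5e-3) {
  stopifnot(inherits(design, "concatenated_design"))
  check_count(copies, "copies", min = 1L)
  redundancy <- design$inner$n - design$inner$k
  min_inner_n <- design$index_symbols + 1L + redundancy
  rows <- lapply(lengths, function(L) {
    inner_n <- (L - design$address_nt) %/% design$nt_per_symbol
    if (inner_n < min_inner_n) {
      stop(sprintf(
        "length %g nt is too short: inner block of %d symbols cannot hold index + 1 data symbol + %d parity",
        L, inner_n, redundancy), call. = FALSE)
    }
    inner_n <- min(inner_n, 255L)
    d <- concatenated_design(outer = design$outer,
                             inner = rs_code(inner_n, inner_n - redundancy),
                             index_symbols = design$index_symbols,
                             address_nt = design$address_nt,
                             nt_per_symbol = design$nt_per_symbol)
    ch <- channel_params(strand_length = strand_length_nt(d),
                         copies = copies, p_error_per_nt = p_error_per_nt,
                         breakage_factor = breakage_factor)
    sym <- outer_symbol_channel(d, ch)
    lfail <- outer_decoding_lfail(design$outer, sym$p_symbol_erasure,
                                  sym$p_symbol_error)
    data.frame(length = L, copies = copies, p_error = p_error_per_nt,
               inner_n = inner_n, inner_k = inner_n - redundancy,
               p_symbol_erasure = sym$p_symbol_erasure,
               p_symbol_error = sym$p_symbol_error,
               decoder_error_prob = exp(lfail),
               log10_decoder_error = lfail / log(10))
  })
  do.call(rbind, rows)
}

#' @export
print.rs_code <- function(x, ...) {
  cat(sprintf("RS[%d,%d,%d]: corrects t errors, e erasures with 2t + e <= %d\n",
              x$n, x$k, x$d, x$d - 1L))
  invisible(x)
}

#' @export
print.concatenated_design <- function(x, ...) {
  cat(sprintf(
    "Concatenated design: outer RS[%d,%d], inner RS[%d,%d], index %d sym, address %d nt\n",
    x$outer$n, x$outer$k, x$inner$n, x$inner$k, x$index_symbols,
    x$address_nt))
  cat(sprintf("  strand length %d nt, payload %d bytes/strand\n",
              strand_length_nt(x), x$inner$k - x$index_symbols))
  invisible(x)
}
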