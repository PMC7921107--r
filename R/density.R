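# Information-density optimization: search concatenated-code designs for
# the maximum payload bits per synthesized nucleotide subject to a
# residual decoder-error constraint.

#' Information density of a concatenated design, bits per nucleotide
#'
#' `density = (outer_k / outer_n) * (inner_k - index_symbols) * 8 /
#' strand_length_nt`. With no coding, no index, and no address this is
#' exactly 2 bits/nt (8 bits per 4-nt symbol); every form of overhead
#' (outer parity strands, inner parity symbols, index, address) only
#' reduces it.
#'
#' @param design A [concatenated_design()].
#' @return Information density in bits per nt.
#' @export
#' @examples
#' d <- concatenated_design(outer = rs_code(255, 223),
#'                          inner = rs_code(35, 29),
#'                          index_symbols = 4, address_nt = 20)
#' info_density(d) # 1.0931
info_density <- function(design) {
  stopifnot(inherits(design, "concatenated_design"))
  payload_bits <- (design$inner$k - design$index_symbols) * 8
  (design$outer$k / design$outer$n) * payload_bits / strand_length_nt(design)
}

#' Density optimization query
#'
#' One point of the density/stability tradeoff: a strand length, a
#' per-nucleotide breakage probability (this is the quantity swept from
#' 1e-3 down to 1e-8 in tradeoff analyses, and it replaces the channel
#' module's default breakage coefficient), a copy number (default 1 -
#' single copy maximizes density and exercises the code fully), a per-nt
#' error rate, and the residual-error ceiling the design must satisfy
#' (default 1e-14, comparable to hard-drive bit error rates).
#'
#' @param strand_length Target strand length in nt.
#' @param breakage_prob_per_nt Per-nucleotide breakage probability.
#' @param copies Physical copy number (default 1).
#' @param p_error_per_nt Per-nucleotide symbol error rate (default 1e-3).
#' @param reliability_target Residual decoder-error ceiling (default
#'   1e-14).
#' @param outer_n Outer block length (default and convention: 255).
#' @param index_symbols Index overhead in symbols (default 4).
#' @param address_nt Address overhead in nt (default 40).
#' @param nt_per_symbol Nucleotides per symbol (default 4).
#' @return An object of class `density_query`.
#' @export
density_query <- function(strand_length, breakage_prob_per_nt, copies = 1,
                          p_error_per_nt = 1e-3, reliability_target = 1e-14,
                          outer_n = 255, index_symbols = 4, address_nt = 40,
                          nt_per_symbol = 4) {
  check_scalar(strand_length, "strand_length", lower = 1)
  check_scalar(breakage_prob_per_nt, "breakage_prob_per_nt", lower = 0,
               upper = 1)
  check_count(copies, "copies", min = 1L)
  check_scalar(p_error_per_nt, "p_error_per_nt", lower = 0, upper = 1)
  check_scalar(reliability_target, "reliability_target", lower = 0,
               allow_lower = FALSE)
  check_count(outer_n, "outer_n", min = 1L)
  if (outer_n > 255) stop("`outer_n` must be <= 255", call. = FALSE)
  check_count(index_symbols, "index_symbols")
  check_count(address_nt, "address_nt")
  check_count(nt_per_symbol, "nt_per_symbol", min = 1L)
  structure(list(strand_length = strand_length,
                 breakage_prob_per_nt = breakage_prob_per_nt,
                 copies = as.integer(copies),
                 p_error_per_nt = p_error_per_nt,
                 reliability_target = reliability_target,
                 outer_n = as.integer(outer_n),
                 index_symbols = as.integer(index_symbols),
                 address_nt = as.integer(address_nt),
                 nt_per_symbol = as.integer(nt_per_symbol)),
            class = "density_query")
}

#' Find the densest design meeting the reliability constraint
#'
#' Exhaustive search over inner message lengths `k_in` (from
#' `index_symbols + 1` to the inner block length fixed by the strand
#' length) and outer message lengths `k_out` (1..outer_n). For each
#' `k_in` the outer-symbol erasure probability is computed through the
#' channel and inner code, and the decoder failure probability of every
#' `k_out` is read off one shared log-domain binomial tail; the feasible
#' design of maximum density wins, ties broken toward larger `k_out`,
#' then larger `k_in`. The winning design's residual error is then
#' re-verified through the general trinomial
#' [outer_decoding_error_prob()] rather than trusted from the search.
#'
#' Inner-decode failures are detected erasures, so with no silent symbol
#' errors the outer failure event is the binomial erasure tail
#' `P[E >= d_out]`.
#'
#' @param query A [density_query()].
#' @return An object of class `tradeoff_point`: the query, `feasible`,
#'   the best `design` (NULL when infeasible), `density_bits_per_nt`
#'   (NA when infeasible), and `achieved_error`.
#' @export
optimize_design <- function(query) {
  stopifnot(inherits(query, "density_query"))
  q <- query
  inner_n <- (q$strand_length - q$address_nt) %/% q$nt_per_symbol
  inner_n <- min(inner_n, 255L)
  infeasible <- function() {
    structure(list(query = q, feasible = FALSE, design = NULL,
                   density_bits_per_nt = NA_real_,
                   achieved_error = NA_real_),
              class = "tradeoff_point")
  }
  if (inner_n < q$index_symbols + 1L) return(infeasible())
  L <- q$address_nt + inner_n * q$nt_per_symbol
  p_lost <- min(1, L * q$breakage_prob_per_nt)^q$copies
  p_sym <- 1 - (1 - q$p_error_per_nt)^q$nt_per_symbol
  ltarget <- log(q$reliability_target)
  n_out <- q$outer_n
  ko_grid <- seq_len(n_out)

  best <- NULL
  for (ki in (q$index_symbols + 1L):inner_n) {
    p_if <- inner_failure_prob(rs_code(inner_n, ki), p_sym)
    pse <- p_lost + (1 - p_lost) * p_if
    if (pse >= 1) next
    ltail <- lbinom_tail_all(n_out, pse)
    # outer [n_out, ko] fails iff E >= d = n_out - ko + 1
    lfail <- ltail[n_out - ko_grid + 2L]
    ok <- lfail < ltarget
    if (!any(ok)) next
    ko <- max(ko_grid[ok])
    dens <- (ko / n_out) * ((ki - q$index_symbols) * 8) / L
    if (is.null(best) || dens > best$dens + 1e-15 ||
        (abs(dens - best$dens) <= 1e-15 &&
         (ko > best$ko || (ko == best$ko && ki > best$ki)))) {
      best <- list(dens = dens, ko = ko, ki = ki, pse = pse,
                   lfail = lfail[ko])
    }
  }
  if (is.null(best)) return(infeasible())

  design <- concatenated_design(outer = rs_code(n_out, best$ko),
                                inner = rs_code(inner_n, best$ki),
                                index_symbols = q$index_symbols,
                                address_nt = q$address_nt,
                                nt_per_symbol = q$nt_per_symbol)
  # independent post-hoc verification via the general trinomial tail
  achieved <- outer_decoding_error_prob(design$outer, best$pse, 0)
  if (!(achieved < q$reliability_target)) {
    stop("internal error: selected design failed post-hoc verification")
  }
  structure(list(query = q, feasible = TRUE, design = design,
                 density_bits_per_nt = info_density(design),
                 achieved_error = achieved,
                 log10_achieved_error = best$lfail / log(10)),
            class = "tradeoff_point")
}

#' Full factorial density sweep over strand lengths and breakage rates
#'
#' Runs [optimize_design()] on every (length, breakage) pair. The
#' returned table carries one row per pair; infeasible pairs (no design
#' meets the reliability target) have `feasible = FALSE` and NA density.
#' Use [density_optima()] to extract, per breakage rate, the strand
#' length achieving the best density - the interior optimum that
#' balances address/index overhead against error-correction overhead.
#'
#' @param lengths Strand lengths in nt.
#' @param breakage_probs Per-nucleotide breakage probabilities (e.g.
#'   `10^-(3:8)`).
#' @param ... Further arguments passed to [density_query()] (copies,
#'   p_error_per_nt, reliability_target, ...).
#' @return A data frame of class `density_sweep` with columns `length`,
#'   `breakage`, `feasible`, `outer_k`, `inner_n`, `inner_k`,
#'   `density_bits_per_nt`, `achieved_error`.
#' @export
density_sweep <- function(lengths, breakage_probs, ...) {
  if (!length(lengths) || !length(breakage_probs)) {
    stop("`lengths` and `breakage_probs` must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(length = lengths, breakage = breakage_probs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pt <- optimize_design(density_query(
      strand_length = grid$length[i],
      breakage_prob_per_nt = grid$breakage[i], ...))
    data.frame(length = grid$length[i], breakage = grid$breakage[i],
               feasible = pt$feasible,
               outer_k = if (pt$feasible) pt$design$outer$k else NA_integer_,
               inner_n = if (pt$feasible) pt$design$inner$n else NA_integer_,
               inner_k = if (pt$feasible) pt$design$inner$k else NA_integer_,
               density_bits_per_nt = pt$density_bits_per_nt,
               achieved_error = pt$achieved_error)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("density_sweep", "data.frame")
  out
}

#' Best strand length per breakage rate in a density sweep
#'
#' @param sweep A [density_sweep()] result.
#' @return A data frame with one row per breakage rate: the strand
#'   length of maximum feasible density and that density. Breakage rates
#'   with no feasible design are dropped.
#' @export
density_optima <- function(sweep) {
  stopifnot(inherits(sweep, "density_sweep"))
  feas <- sweep[sweep$feasible, , drop = FALSE]
  if (!nrow(feas)) return(data.frame(breakage = numeric(0),
                                     best_length = numeric(0),
                                     density_bits_per_nt = numeric(0)))
  parts <- split(feas, feas$breakage)
  out <- do.call(rbind, lapply(parts, function(df) {
    i <- which.max(df$density_bits_per_nt)
    data.frame(breakage = df$breakage[1], best_length = df$length[i],
               density_bits_per_nt = df$density_bits_per_nt[i])
  }))
  rownames(out) <- NULL
  out[order(out$breakage), ]
}

#' @export
print.tradeoff_point <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf(
      "Tradeoff point: INFEASIBLE (L = %g nt, breakage %.3g/nt, target %.3g)\n",
      x$query$strand_length, x$query$breakage_prob_per_nt,
      x$query$reliability_target))
    return(invisible(x))
  }
  cat(sprintf(
    "Tradeoff point: L = %g nt, breakage %.3g/nt -> %.4f bits/nt\n",
    x$query$strand_length, x$query$breakage_prob_per_nt,
    x$density_bits_per_nt))
  cat(sprintf("  outer RS[%d,%d], inner RS[%d,%d], residual error %.3g\n",
              x$design$outer$n, x$design$outer$k, x$design$inner$n,
              x$design$inner$k, x$achieved_error))
  invisible(x)
}
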