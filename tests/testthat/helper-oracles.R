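# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Exhaustive trinomial oracle: enumerate all 3^n per-symbol outcome
# vectors (clean / error / erasure) and sum the probability of patterns
# an RS code with minimum distance d cannot correct (2T + E > d - 1).
enum_outer_fail_prob <- function(n, d, p_error, p_erasure) {
  ids <- 0:(3^n - 1)
  t_cnt <- integer(length(ids))
  e_cnt <- integer(length(ids))
  x <- ids
  for (i in seq_len(n)) {
    dig <- x %% 3L
    t_cnt <- t_cnt + (dig == 1L)
    e_cnt <- e_cnt + (dig == 2L)
    x <- x %/% 3L
  }
  p_clean <- 1 - p_error - p_erasure
  p <- p_error^t_cnt * p_erasure^e_cnt * p_clean^(n - t_cnt - e_cnt)
  list(fail = sum(p[2 * t_cnt + e_cnt > d - 1]), total = sum(p))
}

# Randomized-restart hill climb over the inner message length, with the
# outer message length solved by bisection on the (monotone) feasibility
# of outer_decoding_error_prob. Cross-validates the optimizer's
# exhaustive enumeration bounds without reusing its search loop.
hill_climb_density <- function(query, restarts = 10) {
  inner_n <- (query$strand_length - query$address_nt) %/% query$nt_per_symbol
  inner_n <- min(inner_n, 255L)
  ki_min <- query$index_symbols + 1L
  if (inner_n < ki_min) return(NA_real_)
  L <- query$address_nt + inner_n * query$nt_per_symbol
  p_lost <- min(1, L * query$breakage_prob_per_nt)^query$copies
  p_sym <- 1 - (1 - query$p_error_per_nt)^query$nt_per_symbol

  value <- function(ki) {
    pse <- p_lost + (1 - p_lost) * inner_failure_prob(rs_code(inner_n, ki), p_sym)
    if (pse >= 1) return(NA_real_)
    feasible <- function(ko) {
      outer_decoding_error_prob(rs_code(query$outer_n, ko), pse, 0) <
        query$reliability_target
    }
    if (!feasible(1L)) return(NA_real_)
    lo <- 1L
    hi <- query$outer_n
    if (feasible(hi)) {
      ko <- hi
    } else {
      while (hi - lo > 1L) { # invariant: lo feasible, hi not
        mid <- (lo + hi) %/% 2L
        if (feasible(mid)) lo <- mid else hi <- mid
      }
      ko <- lo
    }
    (ko / query$outer_n) * ((ki - query$index_symbols) * 8) / L
  }

  best <- NA_real_
  for (r in seq_len(restarts)) {
    ki <- sample(ki_min:inner_n, 1)
    v <- value(ki)
    repeat {
      # +/-2 neighborhood: the inner correction radius floor((n - k) / 2)
      # only changes every second k, so the density profile has period-2
      # steps that a +/-1 walk cannot escape
      cand <- ki + c(-2L, -1L, 1L, 2L)
      cand <- cand[cand >= ki_min & cand <= inner_n]
      vals <- vapply(cand, value, numeric(1))
      if (all(is.na(vals)) || all(vals <= v, na.rm = TRUE) ||
          (is.na(v) && all(is.na(vals)))) break
      if (is.na(v)) {
        i <- which(!is.na(vals))[1]
      } else {
        i <- which.max(ifelse(is.na(vals), -Inf, vals))
        if (vals[i] <= v) break
      }
      ki <- cand[i]
      v <- vals[i]
    }
    if (!is.na(v) && (is.na(best) || v > best)) best <- v
  }
  best
}

# Full-chain parameter grid for analytic-vs-Monte-Carlo comparison; the
# analytic failure probabilities span ~2e-3 to ~0.95 so that a 1e5-trial
# simulation observes plenty of failures at every point.
mc_agreement_grid <- function() {
  raw <- list(
    c(255, 223, 40, 36, 4, 40, 4e-04, 1, 1e-3),
    c(255, 223, 40, 36, 4, 40, 5e-04, 1, 1e-3),
    c(255, 223, 40, 34, 4, 40, 3e-04, 1, 1e-2),
    c(255, 239, 60, 56, 4, 40, 1.5e-04, 1, 1e-3),
    c(255, 239, 60, 56, 4, 40, 7e-04, 2, 1e-3),
    c(255, 191, 90, 82, 4, 40, 5e-04, 1, 1e-3),
    c(127, 111, 40, 36, 4, 40, 3e-04, 1, 1e-3),
    c(127, 111, 40, 36, 4, 40, 1.4e-03, 2, 1e-3),
    c(63, 47, 50, 44, 4, 40, 5e-04, 1, 1e-2),
    c(31, 21, 30, 26, 4, 20, 1e-03, 1, 1e-3),
    c(255, 223, 90, 86, 4, 40, 2e-04, 1, 1e-3),
    c(255, 223, 40, 30, 4, 40, 2e-03, 2, 1e-2))
  lapply(raw, function(g) {
    design <- concatenated_design(outer = rs_code(g[1], g[2]),
                                  inner = rs_code(g[3], g[4]),
                                  index_symbols = g[5], address_nt = g[6])
    channel <- channel_params(strand_length_nt(design), copies = g[8],
                              p_error_per_nt = g[9], breakage_factor = g[7])
    list(design = design, channel = channel)
  })
}
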