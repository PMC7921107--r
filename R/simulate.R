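# Seeded Monte-Carlo simulation of the strand channel and the
# concatenated decode-success predicate; the independent oracle for the
# analytic failure probabilities. Two depths are available: the
# threshold predicate (2T + E <= d - 1, the event the analytic model
# computes) and a full encode/corrupt/decode round trip through the
# GF(256) codec.

.SIM_BLOCK <- 10000L

#' Monte-Carlo simulation specification
#'
#' @param design A [concatenated_design()].
#' @param channel A [channel_params()] with `strand_length` equal to the
#'   design's [strand_length_nt()].
#' @param trials Number of independent trials (>= 1).
#' @param seed Integer seed. A fixed seed gives bit-identical results;
#'   trials are drawn in fixed blocks with per-block seeds derived from
#'   this one, so increasing `trials` never changes earlier trials.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(design, channel, trials, seed) {
  stopifnot(inherits(design, "concatenated_design"),
            inherits(channel, "channel_params"))
  if (channel$strand_length != strand_length_nt(design)) {
    stop("channel strand_length must match the design", call. = FALSE)
  }
  check_count(trials, "trials", min = 1L)
  check_count(seed, "seed")
  structure(list(design = design, channel = channel,
                 trials = as.integer(trials), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate the concatenated decode-success predicate
#'
#' Per trial: each of the `outer_n` strands is erased when all its
#' physical copies are lost (per-strand probability `q^c`, `q = min(1,
#' L * breakage_factor)` - sampled at strand level, which is
#' distributionally identical to sampling the `c` copies one by one);
#' each surviving strand draws a Binomial(`inner_n`, `p_symbol`) count of
#' corrupted symbols and its inner decode fails - counting as a detected
#' outer erasure - when that count exceeds the inner correction radius.
#' The outer decode fails when erasures exceed `d_out - 1`.
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `simulation_result`: `failures`, `trials`,
#'   `estimate`, `std_error` (binomial), and the `seed`.
#' @export
simulate_decode <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  design <- spec$design
  channel <- spec$channel
  n_out <- design$outer$n
  d_out <- design$outer$d
  inner_n <- design$inner$n
  t_in <- (design$inner$d - 1L) %/% 2L
  p_erase <- strand_erasure_prob(channel)
  p_sym <- symbol_error_prob(channel)

  nblocks <- ceiling(spec$trials / .SIM_BLOCK)
  seeds <- block_seeds(spec$seed, nblocks)
  failures <- 0L
  done <- 0L
  for (b in seq_len(nblocks)) {
    want <- min(.SIM_BLOCK, spec$trials - done)
    fails_b <- with_preserved_rng(seeds[b], {
      # always draw the full block, then truncate: trial i's draws do
      # not depend on the total trial count
      e_break <- stats::rbinom(.SIM_BLOCK, n_out, p_erase)
      inner_f <- integer(.SIM_BLOCK)
      if (p_sym > 0) {
        surv <- n_out - e_break
        tot <- sum(surv)
        if (tot > 0) {
          errs <- stats::rbinom(tot, inner_n, p_sym)
          failed <- as.numeric(errs > t_in)
          idx <- rep.int(seq_len(.SIM_BLOCK), surv)
          agg <- rowsum(failed, idx)
          inner_f[as.integer(rownames(agg))] <- as.integer(agg)
        }
      }
      e_tot <- e_break + inner_f
      sum((e_tot > d_out - 1L)[seq_len(want)])
    })
    failures <- failures + fails_b
    done <- done + want
  }
  est <- failures / spec$trials
  structure(list(failures = as.integer(failures), trials = spec$trials,
                 estimate = est,
                 std_error = sqrt(est * (1 - est) / spec$trials),
                 seed = spec$seed),
            class = "simulation_result")
}

int_to_bytes <- function(x, nbytes) {
  out <- integer(nbytes)
  for (i in nbytes:1) {
    out[i] <- x %% 256L
    x <- x %/% 256L
  }
  out
}

bytes_to_int <- function(b) {
  x <- 0
  for (v in b) x <- x * 256 + v
  x
}

#' Encode a payload into physical strands
#'
#' Lays a payload of at most `outer_k * (inner_k - index_symbols)` bytes
#' into an outer block: the payload fills a `outer_k x payload_cols`
#' matrix row by row (zero padded), each column is outer-encoded across
#' strands, and each strand (index bytes + its row of outer symbols) is
#' inner-encoded.
#'
#' @param design A [concatenated_design()].
#' @param payload Integer vector of bytes (0..255).
#' @return Integer matrix, `outer_n` rows (strands) by `inner_n` columns
#'   (symbols).
#' @export
codec_encode_file <- function(design, payload) {
  stopifnot(inherits(design, "concatenated_design"))
  payload <- as.integer(payload)
  cols <- design$inner$k - design$index_symbols
  capacity <- design$outer$k * cols
  if (length(payload) > capacity) {
    stop(sprintf("payload of %d bytes exceeds design capacity %d",
                 length(payload), capacity), call. = FALSE)
  }
  if (any(payload < 0L | payload > 255L)) {
    stop("payload bytes must be in 0..255", call. = FALSE)
  }
  M <- matrix(c(payload, integer(capacity - length(payload))),
              nrow = design$outer$k, ncol = cols, byrow = TRUE)
  nsym_out <- design$outer$n - design$outer$k
  C <- apply(M, 2L, function(col) {
    if (nsym_out > 0) rs_encode_block(col, nsym_out) else col
  })
  C <- matrix(C, nrow = design$outer$n, ncol = cols)
  nsym_in <- design$inner$n - design$inner$k
  strands <- matrix(0L, nrow = design$outer$n, ncol = design$inner$n)
  for (i in seq_len(design$outer$n)) {
    msg <- c(int_to_bytes(i - 1L, design$index_symbols), C[i, ])
    strands[i, ] <- if (nsym_in > 0) rs_encode_block(msg, nsym_in) else msg
  }
  strands
}

#' Decode physical strands back to the payload
#'
#' Inner-decodes every present strand (an inner failure marks the strand
#' as an outer erasure), places surviving strands by their decoded index
#' (out-of-range or duplicate indices are discarded as erasures), then
#' outer-decodes each byte column with the missing strands as erasures.
#'
#' @param design A [concatenated_design()].
#' @param strands Integer matrix from [codec_encode_file()], possibly
#'   corrupted.
#' @param present Logical vector: which strands were physically
#'   recovered (default all).
#' @return A list: `ok`, `payload` (full-capacity byte vector, or NULL),
#'   `strands_recovered`.
#' @export
codec_decode_file <- function(design, strands,
                              present = rep(TRUE, nrow(strands))) {
  stopifnot(inherits(design, "concatenated_design"))
  n_out <- design$outer$n
  cols <- design$inner$k - design$index_symbols
  nsym_in <- design$inner$n - design$inner$k
  nsym_out <- design$outer$n - design$outer$k

  rows <- matrix(0L, nrow = n_out, ncol = cols)
  have <- logical(n_out)
  for (i in which(present)) {
    dec <- if (nsym_in > 0) {
      rs_decode_block(strands[i, ], nsym_in)
    } else {
      list(ok = TRUE, message = strands[i, ])
    }
    if (!dec$ok) next
    idx <- bytes_to_int(dec$message[seq_len(design$index_symbols)]) + 1
    if (idx < 1 || idx > n_out) next
    if (have[idx]) { # conflicting duplicate: trust neither
      have[idx] <- FALSE
      next
    }
    have[idx] <- TRUE
    rows[idx, ] <- dec$message[(design$index_symbols + 1L):design$inner$k]
  }
  erase_pos <- which(!have) - 1L
  if (length(erase_pos) > nsym_out) {
    return(list(ok = FALSE, payload = NULL, strands_recovered = sum(have)))
  }
  M <- matrix(0L, nrow = design$outer$k, ncol = cols)
  for (j in seq_len(cols)) {
    if (nsym_out > 0) {
      dec <- rs_decode_block(rows[, j], nsym_out, erase_pos = erase_pos)
      if (!dec$ok) {
        return(list(ok = FALSE, payload = NULL,
                    strands_recovered = sum(have)))
      }
      M[, j] <- dec$message
    } else {
      M[, j] <- rows[, j]
    }
  }
  list(ok = TRUE, payload = as.integer(t(M)), strands_recovered = sum(have))
}

#' Monte-Carlo round trip through the real GF(256) codec
#'
#' Per trial: draw a random payload, encode with [codec_encode_file()],
#' sample the channel (strand losses, then per-symbol corruption of the
#' surviving strands), decode with [codec_decode_file()], and compare
#' payloads. This is the deepest oracle: unlike the threshold predicate
#' it exercises actual algebraic decoding, including the possibility of
#' inner miscorrection.
#'
#' @param spec A [simulation_spec()] (keep `trials` modest; each trial
#'   performs full algebraic decoding).
#' @param payload_bytes Payload size per trial; must fit the design
#'   capacity.
#' @return Logical vector of per-trial round-trip successes.
#' @export
simulate_codec_roundtrip <- function(spec, payload_bytes) {
  stopifnot(inherits(spec, "simulation_spec"))
  design <- spec$design
  channel <- spec$channel
  cols <- design$inner$k - design$index_symbols
  capacity <- design$outer$k * cols
  check_count(payload_bytes, "payload_bytes")
  if (payload_bytes > capacity) {
    stop(sprintf("payload_bytes %d exceeds design capacity %d",
                 payload_bytes, capacity), call. = FALSE)
  }
  n_out <- design$outer$n
  inner_n <- design$inner$n
  p_erase <- strand_erasure_prob(channel)
  p_sym <- symbol_error_prob(channel)

  with_preserved_rng(block_seeds(spec$seed, 1L)[1L], {
    vapply(seq_len(spec$trials), function(trial) {
      payload <- sample.int(256L, payload_bytes, replace = TRUE) - 1L
      strands <- codec_encode_file(design, payload)
      present <- stats::runif(n_out) >= p_erase
      if (p_sym > 0 && any(present)) {
        for (i in which(present)) {
          hit <- which(stats::runif(inner_n) < p_sym)
          if (length(hit)) {
            # corrupt to a uniformly random *different* symbol value
            strands[i, hit] <- bitwXor(strands[i, hit],
                                       sample.int(255L, length(hit),
                                                  replace = TRUE))
          }
        }
      }
      dec <- codec_decode_file(design, strands, present)
      isTRUE(dec$ok) &&
        identical(dec$payload[seq_len(payload_bytes)], payload)
    }, logical(1))
  })
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo decode: %d/%d failures, estimate %.4g (SE %.2g), seed %d\n",
    x$failures, x$trials, x$estimate, x$std_error, x$seed))
  invisible(x)
}
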