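# A complete systematic Reed-Solomon codec over GF(2^8) (primitive
# polynomial x^8 + x^4 + x^3 + x^2 + 1, generator element 2), with
# errors-and-erasures decoding via Forney syndromes, Berlekamp-Massey,
# Chien search, and the Forney magnitude formula. Symbols are integers
# 0..255; codewords are vectors c(message, parity). Shortened codes
# (n < 255) work directly. This codec backs the Monte-Carlo round-trip
# oracle; the analytic modules never call it.

.gf_tables <- local({
  exps <- integer(512)
  logs <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exps[i + 1L] <- x
    logs[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exps[256:510] <- exps[1:255] # wraparound spares a modulo in hot paths
  list(exp = exps, log = logs)
})

gf_mul <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  out <- integer(n)
  nz <- a != 0L & b != 0L
  if (any(nz)) {
    out[nz] <- .gf_tables$exp[
      .gf_tables$log[a[nz] + 1L] + .gf_tables$log[b[nz] + 1L] + 1L]
  }
  out
}

gf_inv <- function(a) {
  if (any(a == 0L)) stop("0 has no inverse in GF(256)", call. = FALSE)
  .gf_tables$exp[(255L - .gf_tables$log[a + 1L]) %% 255L + 1L]
}

gf_div <- function(a, b) gf_mul(a, gf_inv(b))

gf_pow <- function(a, p) {
  if (a == 0L) return(if (p == 0) 1L else 0L)
  .gf_tables$exp[((.gf_tables$log[a + 1L] * p) %% 255L + 255L) %% 255L + 1L]
}

# Polynomials are integer vectors, highest-degree coefficient first.

gf_poly_scale <- function(p, s) gf_mul(p, rep_len(s, length(p)))

gf_poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  r <- integer(n)
  r[(n - length(p) + 1L):n] <- p
  idx <- (n - length(q) + 1L):n
  r[idx] <- bitwXor(r[idx], as.integer(q))
  r
}

gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (j in seq_along(q)) {
    if (q[j] != 0L) {
      idx <- j:(j + length(p) - 1L)
      r[idx] <- bitwXor(r[idx], gf_mul(p, q[j]))
    }
  }
  r
}

gf_poly_eval <- function(p, x) {
  y <- as.integer(p[1L])
  for (i in seq_along(p)[-1L]) {
    y <- bitwXor(gf_mul(y, x), as.integer(p[i]))
  }
  y
}

# Synthetic division; returns list(quotient, remainder)
gf_poly_div <- function(dividend, divisor) {
  out <- as.integer(dividend)
  steps <- length(dividend) - (length(divisor) - 1L)
  for (i in seq_len(steps)) {
    coef <- out[i]
    if (coef != 0L) {
      for (j in 2:length(divisor)) {
        if (divisor[j] != 0L) {
          out[i + j - 1L] <- bitwXor(out[i + j - 1L],
                                     gf_mul(divisor[j], coef))
        }
      }
    }
  }
  sep <- length(dividend) - (length(divisor) - 1L)
  list(quotient = out[seq_len(sep)], remainder = out[(sep + 1L):length(out)])
}

.rs_gen_cache <- new.env(parent = emptyenv())

rs_generator_poly <- function(nsym) {
  key <- as.character(nsym)
  if (!is.null(.rs_gen_cache[[key]])) return(.rs_gen_cache[[key]])
  g <- 1L
  for (i in 0:(nsym - 1L)) {
    g <- gf_poly_mul(g, c(1L, gf_pow(2L, i)))
  }
  .rs_gen_cache[[key]] <- g
  g
}

#' Systematic Reed-Solomon encoding of one block
#'
#' Appends `nsym` parity symbols to the message (symbols are integers
#' 0..255). The codeword is `c(message, parity)` with total length
#' `length(message) + nsym <= 255`.
#'
#' @param message Integer vector of message symbols (0..255).
#' @param nsym Number of parity symbols (n - k).
#' @return Integer codeword of length `length(message) + nsym`.
#' @export
#' @examples
#' cw <- rs_encode_block(c(1, 2, 3), nsym = 4)
#' rs_decode_block(cw, nsym = 4)$message
rs_encode_block <- function(message, nsym) {
  message <- as.integer(message)
  check_count(nsym, "nsym", min = 1L)
  if (any(message < 0L | message > 255L)) {
    stop("message symbols must be in 0..255", call. = FALSE)
  }
  if (length(message) + nsym > 255L) {
    stop("codeword length would exceed 255", call. = FALSE)
  }
  gen <- rs_generator_poly(nsym)
  rem <- gf_poly_div(c(message, integer(nsym)), gen)$remainder
  c(message, rem)
}

rs_calc_syndromes <- function(msg, nsym) {
  synd <- integer(nsym)
  for (i in 0:(nsym - 1L)) {
    synd[i + 1L] <- gf_poly_eval(msg, gf_pow(2L, i))
  }
  c(0L, synd) # leading pad keeps Berlekamp-Massey indexing uniform
}

rs_find_errata_locator <- function(coef_pos) {
  loc <- 1L
  for (p in coef_pos) {
    loc <- gf_poly_mul(loc, gf_poly_add(1L, c(gf_pow(2L, p), 0L)))
  }
  loc
}

rs_find_error_evaluator <- function(synd, err_loc, nsym) {
  gf_poly_div(gf_poly_mul(synd, err_loc),
              c(1L, integer(nsym + 1L)))$remainder
}

rs_forney_syndromes <- function(synd, erase_pos, nmess) {
  fsynd <- synd[-1L]
  for (pos in erase_pos) {
    x <- gf_pow(2L, nmess - 1L - pos)
    for (j in seq_len(length(fsynd) - 1L)) {
      fsynd[j] <- bitwXor(gf_mul(fsynd[j], x), fsynd[j + 1L])
    }
  }
  fsynd
}

# Berlekamp-Massey on the (Forney) syndromes; returns the error locator
# polynomial or NULL when the pattern exceeds capability.
rs_find_error_locator <- function(synd, nsym, erase_count = 0L) {
  err_loc <- 1L
  old_loc <- 1L
  for (i in seq_len(nsym - erase_count)) {
    K <- i # fsynd has length nsym exactly; 1-based
    delta <- synd[K]
    if (length(err_loc) > 1L) {
      for (j in seq_len(length(err_loc) - 1L)) {
        delta <- bitwXor(delta,
                         gf_mul(err_loc[length(err_loc) - j], synd[K - j]))
      }
    }
    old_loc <- c(old_loc, 0L)
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- gf_poly_scale(old_loc, delta)
        old_loc <- gf_poly_scale(err_loc, gf_inv(delta))
        err_loc <- new_loc
      }
      err_loc <- gf_poly_add(err_loc, gf_poly_scale(old_loc, delta))
    }
  }
  while (length(err_loc) > 0L && err_loc[1L] == 0L) err_loc <- err_loc[-1L]
  errs <- length(err_loc) - 1L
  if (errs * 2L + erase_count > nsym) return(NULL)
  err_loc
}

# Chien search over the shortened block; err_loc is reversed (lowest
# degree first). Returns 0-based codeword positions or NULL.
rs_find_errors <- function(err_loc_rev, nmess) {
  errs <- length(err_loc_rev) - 1L
  if (errs == 0L) return(integer(0))
  pos <- integer(0)
  for (i in 0:(nmess - 1L)) {
    if (gf_poly_eval(err_loc_rev, gf_pow(2L, i)) == 0L) {
      pos <- c(pos, nmess - 1L - i)
    }
  }
  if (length(pos) != errs) return(NULL)
  pos
}

# Forney magnitudes at the known errata positions (0-based).
rs_correct_errata <- function(msg, synd, errata_pos) {
  nmess <- length(msg)
  coef_pos <- nmess - 1L - errata_pos
  err_loc <- rs_find_errata_locator(coef_pos)
  err_eval <- rev(rs_find_error_evaluator(rev(synd), err_loc,
                                          length(err_loc) - 1L))
  X <- vapply(coef_pos, function(cp) gf_pow(2L, -(255L - cp)), integer(1))
  E <- integer(nmess)
  for (i in seq_along(X)) {
    Xi <- X[i]
    Xi_inv <- gf_inv(Xi)
    prime <- 1L
    for (j in seq_along(X)) {
      if (j != i) {
        prime <- gf_mul(prime, bitwXor(1L, gf_mul(Xi_inv, X[j])))
      }
    }
    if (prime == 0L) return(NULL)
    y <- gf_poly_eval(rev(err_eval), Xi_inv)
    y <- gf_mul(Xi, y)
    E[errata_pos[i] + 1L] <- gf_div(y, prime)
  }
  bitwXor(as.integer(msg), E)
}

#' Errors-and-erasures Reed-Solomon decoding of one block
#'
#' Decodes a received codeword with `nsym` parity symbols, given the
#' 0-based positions of any erased symbols (their stored values are
#' ignored). Succeeds for any pattern of `t` errors and `e` erasures
#' with `2t + e <= nsym`; otherwise returns `ok = FALSE` (detection is
#' checked by re-evaluating the syndromes of the corrected word).
#'
#' @param received Integer vector: the (possibly corrupted) codeword.
#' @param nsym Number of parity symbols.
#' @param erase_pos Integer vector of 0-based erased positions.
#' @return A list: `ok` (logical), `codeword` (corrected, or NULL),
#'   `message` (first n - nsym symbols, or NULL).
#' @export
rs_decode_block <- function(received, nsym, erase_pos = integer(0)) {
  msg <- as.integer(received)
  nsym <- as.integer(nsym)
  erase_pos <- as.integer(erase_pos)
  fail <- list(ok = FALSE, codeword = NULL, message = NULL)
  if (length(erase_pos) > nsym) return(fail)
  if (length(erase_pos)) msg[erase_pos + 1L] <- 0L
  synd <- rs_calc_syndromes(msg, nsym)
  if (max(synd) == 0L) {
    return(list(ok = TRUE, codeword = msg,
                message = msg[seq_len(length(msg) - nsym)]))
  }
  fsynd <- rs_forney_syndromes(synd, erase_pos, length(msg))
  err_loc <- rs_find_error_locator(fsynd, nsym,
                                   erase_count = length(erase_pos))
  if (is.null(err_loc)) return(fail)
  err_pos <- rs_find_errors(rev(err_loc), length(msg))
  if (is.null(err_pos)) return(fail)
  corrected <- rs_correct_errata(msg, synd, c(erase_pos, err_pos))
  if (is.null(corrected)) return(fail)
  if (max(rs_calc_syndromes(corrected, nsym)) != 0L) return(fail)
  list(ok = TRUE, codeword = corrected,
       message = corrected[seq_len(length(corrected) - nsym)])
}
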