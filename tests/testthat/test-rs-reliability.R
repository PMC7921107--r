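# Analytic reliability of the concatenated inner-outer RS scheme.

test_that("RS correction capability follows 2t + e <= d - 1", {
  outer <- rs_code(255, 223) # d = 33
  expect_true(correctable(outer, 16, 0))
  expect_false(correctable(outer, 17, 0))
  expect_true(correctable(outer, 0, 32))
  expect_false(correctable(outer, 0, 33))
  # brute force over every pattern for RS[7,3] (d = 5)
  code <- rs_code(7, 3)
  for (t in 0:7) {
    for (e in 0:(7 - t)) {
      expect_identical(correctable(code, t, e), 2 * t + e <= 4)
    }
  }
})

test_that("inner failure probability is the exact binomial tail", {
  expect_identical(inner_failure_prob(rs_code(15, 11), 0), 0)
  # rate-1 inner code: any symbol error defeats it
  q <- 0.037
  expect_equal(inner_failure_prob(rs_code(5, 5), q), 1 - (1 - q)^5)
  # RS[15,11] corrects t = 2; frozen against a direct tail sum
  direct <- sum(dbinom(3:15, 15, 0.01))
  expect_equal(inner_failure_prob(rs_code(15, 11), 0.01), direct)
  expect_equal(direct, 4.158027e-4, tolerance = 1e-6)
  # log-domain evaluation stays accurate deep in the tail
  deep <- inner_failure_prob(rs_code(40, 30), 1e-8)
  expect_gt(deep, 0)
  expect_lt(deep, 1e-30)
  expect_equal(log(deep),
               lchoose(40, 6) + 6 * log(1e-8) + 34 * log(1 - 1e-8),
               tolerance = 1e-6)
})

test_that("outer symbol channel composes strand loss with detected inner failures", {
  inner <- rs_code(40, 36)
  design <- concatenated_design(inner = inner)
  L <- strand_length_nt(design) # 40 + 160 = 200 nt
  expect_identical(L, 200L)
  # zero breakage, zero error -> clean symbols
  clean <- outer_symbol_channel(design, channel_params(
    L, breakage_factor = 0, p_error_per_nt = 0))
  expect_identical(clean$p_symbol_erasure, 0)
  expect_identical(clean$p_symbol_error, 0)
  # breakage only
  ch <- channel_params(L, breakage_factor = 0.5 / L)
  expect_equal(outer_symbol_channel(design, ch)$p_symbol_erasure, 0.5)
  # composition: p_lost + (1 - p_lost) * p_inner_fail
  ch2 <- channel_params(L, breakage_factor = 0.2 / L, p_error_per_nt = 5e-3)
  pif <- inner_failure_prob(inner, symbol_error_prob(ch2))
  expect_equal(outer_symbol_channel(design, ch2)$p_symbol_erasure,
               0.2 + 0.8 * pif)
  # inconsistent strand length rejected
  expect_error(outer_symbol_channel(design, channel_params(150)),
               "does not match")
})

test_that("outer decoding failure matches hand enumeration and the binomial erasure tail", {
  # RS[3,1], d = 3: decoding fails only when all 3 symbols are erased
  expect_equal(outer_decoding_error_prob(rs_code(3, 1), 0.5), 0.125)
  # erasure-only: trinomial collapses to P[Binom(n, p) >= d]
  expect_equal(outer_decoding_error_prob(rs_code(255, 223), 0.05),
               pbinom(32, 255, 0.05, lower.tail = FALSE), tolerance = 1e-12)
  expect_identical(outer_decoding_error_prob(rs_code(255, 223), 0, 0), 0)
})

test_that("trinomial tail agrees with exhaustive 3^n enumeration to machine precision", {
  cases <- expand.grid(n = 8, k = c(2, 5), p_error = c(0, 0.03, 0.12),
                       p_erasure = c(0.05, 0.25))
  cases <- rbind(cases,
                 data.frame(n = c(11, 12, 12), k = c(5, 2, 7),
                            p_error = c(0.05, 0, 0.08),
                            p_erasure = c(0.10, 0.30, 0.15)))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]
    k <- min(cases$k[i], n)
    code <- rs_code(n, k)
    oracle <- enum_outer_fail_prob(n, code$d, cases$p_error[i],
                                   cases$p_erasure[i])
    expect_equal(oracle$total, 1, tolerance = 1e-12) # lattice is normalized
    expect_equal(outer_decoding_error_prob(code, cases$p_erasure[i],
                                           cases$p_error[i]),
                 oracle$fail, tolerance = 1e-12)
  }
})

test_that("decoder error is monotone in channel severity and redundancy", {
  outer <- rs_code(255, 223)
  pe <- seq(0, 0.2, by = 0.04)
  f_erasure <- vapply(pe, function(p) outer_decoding_error_prob(outer, p, 0),
                      numeric(1))
  expect_true(all(diff(f_erasure) >= 0))
  f_error <- vapply(pe / 2, function(p)
    outer_decoding_error_prob(outer, 0.05, p), numeric(1))
  expect_true(all(diff(f_error) >= 0))
  # more outer parity (smaller k) never hurts
  ks <- c(253, 239, 223, 191, 127)
  f_k <- vapply(ks, function(k)
    outer_decoding_error_prob(rs_code(255, k), 0.08, 0.01), numeric(1))
  expect_true(all(diff(f_k) <= 0))
})

test_that("log10 failure probabilities stay finite far below double underflow", {
  l10 <- log10_outer_decoding_error(rs_code(255, 223), 1e-6)
  expect_true(is.finite(l10))
  expect_lt(l10, -150)
  expect_identical(log10_outer_decoding_error(rs_code(255, 223), 0), -Inf)
})

test_that("system error curves reproduce the qualitative length/copies/error trends", {
  tmpl <- concatenated_design(outer = rs_code(255, 223),
                              inner = rs_code(40, 34))
  lengths <- seq(100, 1000, by = 100)
  # a perfect channel is perfectly decodable at every length
  perfect <- system_error_curve(tmpl, lengths, p_error_per_nt = 0,
                                breakage_factor = 0)
  expect_true(all(perfect$decoder_error_prob == 0))
  # calibrated breakage (5e-4/nt): error grows with length, shrinks with
  # copies and with a cleaner channel
  c1 <- system_error_curve(tmpl, lengths, copies = 1,
                           p_error_per_nt = 1e-3, breakage_factor = 5e-4)
  c2 <- system_error_curve(tmpl, lengths, copies = 2,
                           p_error_per_nt = 1e-3, breakage_factor = 5e-4)
  hi <- system_error_curve(tmpl, lengths, copies = 1,
                           p_error_per_nt = 1e-2, breakage_factor = 5e-4)
  expect_true(all(diff(c1$log10_decoder_error) >= -1e-9))
  expect_true(all(c2$log10_decoder_error <= c1$log10_decoder_error + 1e-9))
  expect_true(all(c1$log10_decoder_error <= hi$log10_decoder_error + 1e-9))
  expect_gt(max(c1$log10_decoder_error) - min(c1$log10_decoder_error), 1)
  # strands too short for index + payload + parity are rejected
  expect_error(system_error_curve(tmpl, 60), "too short")
})
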