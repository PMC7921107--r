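# Degradation kinetics: closed-form models and calibration helpers.

test_that("Poisson breakage survival matches the fossil-DNA worked example", {
  fossil <- first_order_breakage(5.5e-6)
  # exp(-5.5e-6 * 242 * 500): about half the 242-nt strands fragmented
  expect_equal(intact_fraction_breakage(fossil, 242, 500), 0.5140165,
               tolerance = 1e-6)
  # doubling the length squares the survival (independent scission sites)
  expect_equal(intact_fraction_breakage(fossil, 484, 500), 0.5140165^2,
               tolerance = 1e-6)
  expect_identical(intact_fraction_breakage(fossil, 242, 0), 1)
})

test_that("breakage survival is multiplicative in time and length", {
  set.seed(11)
  for (i in 1:20) {
    m <- first_order_breakage(10^runif(1, -7, -4))
    L <- sample(50:1000, 2)
    t <- runif(2, 0, 2000)
    expect_equal(intact_fraction_breakage(m, L[1], t[1] + t[2]),
                 intact_fraction_breakage(m, L[1], t[1]) *
                   intact_fraction_breakage(m, L[1], t[2]))
    expect_equal(intact_fraction_breakage(m, L[1] + L[2], t[1]),
                 intact_fraction_breakage(m, L[1], t[1]) *
                   intact_fraction_breakage(m, L[2], t[1]))
  }
})

test_that("half-life inversion round-trips through the survival model", {
  m <- rate_from_half_life(242, 500)
  expect_equal(m$rate_per_nt_per_year, log(2) / (242 * 500))
  expect_equal(m$rate_per_nt_per_year, 5.73e-6, tolerance = 1e-3)
  expect_equal(rate_from_half_life(1, log(2))$rate_per_nt_per_year, 1)
  set.seed(12)
  for (i in 1:20) {
    L <- sample(10:2000, 1)
    h <- runif(1, 1, 5000)
    expect_equal(intact_fraction_breakage(rate_from_half_life(L, h), L, h),
                 0.5)
  }
})

test_that("freeze-thaw decay reproduces the published lambda-DNA fit", {
  m <- freeze_thaw_model() # amplitude 0.9484, decay 0.068/cycle
  expect_equal(freeze_thaw_intact(m, 0), 0.9484)
  # ~11% degraded after one cycle, ~76% after twenty
  expect_equal(freeze_thaw_intact(m, 1), 0.8860526, tolerance = 1e-6)
  expect_equal(freeze_thaw_intact(m, 20), 0.2434171, tolerance = 1e-6)
  expect_error(freeze_thaw_intact(m, -1), "cycles")
})

test_that("log-linear decay fitting is exact on noiseless data", {
  # two points determine the exponential exactly
  m <- fit_exponential_decay(data.frame(cycles = c(1, 20),
                                        intact_fraction = c(0.90, 0.25)))
  expect_equal(m$decay_per_cycle, (log(0.90) - log(0.25)) / 19)
  expect_equal(m$amplitude, 0.90 * exp(m$decay_per_cycle))
  expect_equal(m$decay_per_cycle, 0.0674, tolerance = 1e-2)
  expect_equal(m$amplitude, 0.963, tolerance = 1e-2)
  # flat data: no decay
  flat <- fit_exponential_decay(data.frame(cycles = c(0, 10),
                                           intact_fraction = c(1, 1)))
  expect_equal(flat$decay_per_cycle, 0)
  expect_equal(flat$amplitude, 1)
  # noiseless multi-point data recovered to machine precision
  truth <- freeze_thaw_model(0.93, 0.05)
  pts <- data.frame(cycles = 0:8,
                    intact_fraction = freeze_thaw_intact(truth, 0:8))
  fit <- fit_exponential_decay(pts)
  expect_equal(fit$amplitude, 0.93, tolerance = 1e-12)
  expect_equal(fit$decay_per_cycle, 0.05, tolerance = 1e-12)
})

test_that("decay fitting rejects degenerate inputs", {
  expect_error(fit_exponential_decay(
    data.frame(cycles = c(3, 3), intact_fraction = c(0.5, 0.6))), "distinct")
  expect_error(fit_exponential_decay(
    data.frame(cycles = c(1, 2), intact_fraction = c(0.5, 0))), "\\(0, 1\\]")
  expect_error(fit_exponential_decay(
    data.frame(cycles = 1, intact_fraction = 0.5)), "two points")
})

test_that("decay fitting accepts CSV input", {
  path <- tempfile(fileext = ".csv")
  truth <- freeze_thaw_model()
  write.csv(data.frame(cycles = 0:5,
                       intact_fraction = freeze_thaw_intact(truth, 0:5)),
            path, row.names = FALSE)
  fit <- fit_exponential_decay(read_decay_csv(path))
  expect_equal(fit$decay_per_cycle, 0.068, tolerance = 1e-10)
  unlink(path)
})

test_that("Arrhenius scaling is the identity at the reference temperature and monotone in T", {
  m <- arrhenius_model(activation_energy = 120e3, reference_rate = 2.5,
                       reference_temperature = 343.15)
  expect_equal(arrhenius_scale(m, 343.15), 2.5)
  # 70 C -> 25 C at Ea = 120 kJ/mol: ~570-fold slowdown
  expect_equal(arrhenius_scale(m, 298.15) / 2.5, 1.7495e-3,
               tolerance = 1e-4)
  temps <- seq(260, 380, by = 10)
  expect_true(all(diff(arrhenius_scale(m, temps)) > 0))
  expect_error(arrhenius_scale(m, -5), "> 0 K")
  expect_equal(celsius_to_kelvin(25), 298.15)
})

test_that("lesion accumulation is anchored at 6%/yr for a 200-nt strand", {
  m <- lesion_model() # default rate -log(0.94)/200 per nt per year
  expect_equal(lesion_probability(m, 200, 1), 0.06)
  expect_equal(lesion_probability(m, 200, 2), 1 - 0.94^2)
  expect_identical(lesion_probability(m, 200, 0), 0)
  expect_error(lesion_probability(m, 200, -1), "time")
})

test_that("kinetics outputs typed as fractions stay in [0, 1]", {
  set.seed(13)
  for (i in 1:30) {
    r <- 10^runif(1, -8, -2)
    L <- sample(1:5000, 1)
    t <- runif(1, 0, 1e4)
    f <- intact_fraction_breakage(first_order_breakage(r), L, t)
    g <- lesion_probability(lesion_model(r), L, t)
    h <- freeze_thaw_intact(freeze_thaw_model(runif(1, 0.5, 1), runif(1, 0, 0.3)),
                            sample(0:50, 1))
    expect_true(f >= 0 && f <= 1)
    expect_true(g >= 0 && g <= 1)
    expect_true(h >= 0 && h <= 1)
  }
})
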