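test_that("reference angles reproduce the published rows at two decimals", {
  reps <- c(10000, 25000, 1e5, 2.5e5, 5e5)
  g <- reference_angle(reps)
  expect_equal(round(g, 2), c(61.18, 152.95, 251.80, 89.49, 178.99),
               ignore_attr = TRUE)
  r <- reference_angle(reps, "raga", scheme = scheme_233_ext())
  expect_equal(round(r, 2), c(46.35, 115.88, 103.52, 78.80, 157.60),
               ignore_attr = TRUE)
  expect_identical(reference_angle(0)[1], 0)
})

test_that("reference is self-consistent when the working precision doubles", {
  reps <- c(10000, 5e5)
  s50 <- attr(reference_angle(reps, digits = 50), "strings")
  s100 <- attr(reference_angle(reps, digits = 100), "strings")
  # agreement of the first 40 decimals implies a difference < 1e-20 deg
  trim <- function(s, k) substr(s, 1, regexpr(".", s, fixed = TRUE) + k)
  expect_identical(trim(s50, 40), trim(s100, 40))
})

test_that("float32 rounding primitive and additive emulation are consistent", {
  cst <- golden_constants_cpp()
  # reconstruct the first emulated steps with the exposed rounding primitive
  phi <- 0
  for (k in 1:6) phi <- float32_round_cpp(phi + cst$psi_single)
  expect_identical(emulated_angle(6, "additive", "single"), phi)
  phi_d <- 0
  for (k in 1:6) phi_d <- phi_d + cst$psi_double
  expect_identical(emulated_angle(6, "additive", "double"), phi_d)
  # t = 0 is exact for every rule
  for (rule in c("multiplicative", "additive", "additive_mod")) {
    for (prec in c("single", "double")) {
      expect_identical(emulated_angle(0, rule, prec), 0)
    }
  }
  expect_identical(
    emulated_angle(0, "raga", "single", scheme = scheme_233_ext()), 0)
})

test_that("multiplicative double errors stay below 1e-8 degrees", {
  reps <- c(10000, 1e5, 5e5)
  emu <- emulated_angle(reps, "multiplicative", "double")
  ref <- reference_angle(reps)
  err <- abs((emu * 180 / pi) %% 360 - ref)
  expect_true(all(err < 1e-8))
})

test_that("RAGA double errors sit at machine epsilon with no growth", {
  s <- scheme_233_ext()
  t <- c(1:50, 10000, 123456, 499999, 5e5)
  emu <- emulated_angle(t, "raga", "double", scheme = s)
  refs <- raga:::reference_angle_fx(t, "raga", scheme = s, digits = 50)
  err <- raga:::drift_error(emu, refs)
  expect_true(all(abs(err) < 1e-13))
  # no accumulation: late errors are no larger than the early maximum x10
  expect_lte(max(abs(err[t > 1e5])), 10 * max(abs(err[t <= 50])))
})

test_that("drift table reproduces the published error structure", {
  d <- drift_table()
  expect_equal(round(d$reference_golden_deg, 2),
               c(61.18, 152.95, 251.80, 89.49, 178.99))
  err <- function(prec, rule) {
    unlist(d$errors[d$errors$precision == prec & d$errors$rule == rule,
                    -(1:2)], use.names = FALSE)
  }
  # double rows: printed cells match in sign and exponent
  expect_exponent_sign(err("double", "multiplicative"),
                       c(1.3e-10, 2.2e-10, 8.6e-10, 4.9e-10, 9.8e-10))
  expect_exponent_sign(err("double", "additive"),
                       c(2.5e-07, 9.4e-07, 4.4e-06, -1.8e-04, -5.9e-04))
  expect_exponent_sign(err("double", "additive_mod"),
                       c(7.2e-11, 1.8e-10, 7.2e-10, 1.8e-09, 3.6e-09))
  # single rows: within one order of magnitude and matching sign
  chk_single <- function(rule, printed) {
    e <- err("single", rule)
    expect_equal(sign(e), sign(printed))
    expect_true(all(abs(log10(abs(e)) - log10(abs(printed))) <= 1))
  }
  chk_single("multiplicative", c(-2.3e-02, -1.4e-03, -5.7e-03, -4.6e-01,
                                 -9.2e-01))
  chk_single("additive", c(-2.7e+02, -9.5e+01, 1.7e+02, -1.4e+02, 7.0e+01))
  chk_single("additive_mod", c(-1.1e-01, -2.7e-01, -1.1e+00, -2.7e+00,
                               -5.4e+00))
  # RAGA rows: bounded at the machine-epsilon scale of the angle range
  # (2 pi scaled to degrees: 6.8e-6 single, 1.3e-14 double), no growth
  expect_lt(max(abs(err("double", "raga"))), 3 * 1.3e-14)
  expect_lt(max(abs(err("single", "raga"))), 3 * 6.8e-06)
  expect_identical(d$acquisition_s, c(20, 50, 200, 500, 1000))
})
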