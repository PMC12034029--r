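test_that("scheme construction resolves the published integers", {
  s5 <- raga_scheme(1, 5)
  expect_identical(s5$S, 5)
  expect_identical(s5$increment, 3)
  expect_identical(s5$index_space, 5)
  expect_equal(s5$base_angle_deg, 36)

  se <- scheme_233_ext()
  expect_identical(se$S, 233)
  expect_identical(se$increment, 144)
  expect_identical(se$index_space, 466)
  expect_identical(se$period, 233)
  expect_warning(raga_scheme(1, 13, "extended"), "even increment")

  sd <- raga_scheme(2, 13, "doubled")
  expect_identical(sd$S, 377)
  expect_true(sd$S %% 2 == 1)
  expect_equal(sd$base_angle_deg, 360 / 377)

  # G_12^3 = 322 is even: doubled variant must refuse it
  expect_error(raga_scheme(3, 12, "doubled"), "odd")
  expect_error(raga_scheme(1, 5, increment = 2),
               NA)  # gcd(2,5)=1 is fine, even if hand-crafted
  expect_error(raga_scheme(1, 6, increment = 4), "coprime")  # gcd(4,8)=4
})

test_that("temporal index map matches the worked examples", {
  s5 <- raga_scheme(1, 5)
  expect_identical(spoke_index(0:4, s5), c(0, 3, 1, 4, 2))
  se <- scheme_233_ext()
  expect_identical(spoke_index(0, se), 0)
  expect_identical(spoke_index(10000, se), 60)
  expect_equal(round(spoke_angle(10000, se), 2), 46.35)
  expect_equal(round(spoke_angle(500000, se), 2), 157.60)
  expect_equal(spoke_angle(1, s5), 108)  # increment x base angle = psi_5^1
  expect_error(spoke_index(-1, s5), "non-negative")
})

test_that("index arithmetic is exact and reproducible", {
  se <- scheme_233_ext()
  t <- c(0:50, 10^(3:8), 2^c(40, 50))
  a <- spoke_index(t, se)
  b <- spoke_index(t, se)
  expect_identical(a, b)
  expect_true(all(a == floor(a) & a >= 0 & a < se$index_space))
  # against plain modular arithmetic on small t
  expect_identical(spoke_index(0:465, se), (0:465 * 144) %% 466)
})

test_that("index map is a permutation for all small schemes", {
  for (N in 1:10) {
    for (i in 4:16) {
      s <- raga_scheme(N, i)
      ind <- spoke_index(seq_len(s$S) - 1, s)
      expect_identical(sort(ind), as.numeric(0:(s$S - 1)))
      if (s$S %% 2 == 1) {
        sd <- raga_scheme(N, i, "doubled")
        indd <- spoke_index(seq_len(sd$S) - 1, sd)
        expect_identical(sort(indd), as.numeric(0:(sd$S - 1)))
      }
    }
  }
})

test_that("bijectivity verification and periodicity", {
  v <- verify_bijectivity(raga_scheme(1, 5))
  expect_identical(v$bijective_over, 5)
  expect_identical(v$distinct_angles, 5)

  v13 <- verify_bijectivity(raga_scheme(1, 13))
  expect_identical(v13$bijective_over, 233)

  ve <- verify_bijectivity(scheme_233_ext())
  expect_identical(ve$bijective_over, 233)   # even indices only
  expect_identical(ve$distinct_angles, 233)

  s <- raga_scheme(3, 9)
  t <- 0:(3 * s$period - 1)
  expect_identical(spoke_index(t, s), spoke_index(t + s$period, s))
})

test_that("angle between consecutive spokes equals increment times base angle", {
  for (s in list(raga_scheme(1, 8), raga_scheme(4, 9), scheme_233_ext(),
                 raga_scheme(2, 13, "doubled"))) {
    # angles live on a circle of index_space * base_angle degrees (180 for
    # the half-circle pattern, 360 otherwise)
    circle <- s$index_space * s$base_angle_deg
    t <- 0:(min(s$period, 300) - 1)
    d <- diff(spoke_angle(t, s)) %% circle
    step <- (s$increment * s$base_angle_deg) %% circle
    expect_equal(d, rep(step, length(d)), tolerance = 1e-12)
  }
})

test_that("index inversion recovers the temporal order", {
  s5 <- raga_scheme(1, 5)
  expect_identical(invert_index(4, s5), 3)
  expect_identical(invert_index(0, s5), 0)
  for (s in list(raga_scheme(1, 11), raga_scheme(5, 8), scheme_233_ext())) {
    t <- seq_len(s$period) - 1
    expect_identical(invert_index(spoke_index(t, s), s), t)
  }
  # extended variant with even increment never acquires odd indices
  expect_error(invert_index(1, scheme_233_ext()), "never acquired")
})

test_that("binning produces full frames and repeating masks", {
  s5 <- raga_scheme(1, 5)
  fr <- bin_frames(s5, 5, 3)
  for (f in fr) expect_identical(f, as.numeric(0:4))
  expect_identical(bin_frames(s5, 1, 4), as.list(as.numeric(c(0, 3, 1, 4))))

  s377 <- raga_scheme(2, 13)          # period 377
  masks <- bin_frames(s377, 29, 27)
  keys <- vapply(masks, paste, character(1), collapse = ",")
  expect_identical(keys[14:26], keys[1:13])   # repeats after 13 frames
  expect_identical(length(unique(keys)), 13L)
})

test_that("distinct frame patterns follow period / gcd(period, p)", {
  s377 <- raga_scheme(2, 13)
  expect_identical(distinct_frame_patterns(s377, 29), 13)
  expect_identical(distinct_frame_patterns(s377, s377$period), 1)
  s233 <- raga_scheme(1, 13)
  expect_identical(distinct_frame_patterns(s233, 20), 233)
})

test_that("extended indices fold onto the half circle with a flip flag", {
  se <- scheme_233_ext()
  f <- fold_half_circle(c(0, 232, 233, 465), se)
  expect_identical(f$index, c(0, 232, 0, 232))
  expect_identical(f$flipped, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(fold_half_circle(0, raga_scheme(1, 5)), "extended")
})
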