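test_that("normalisation divides by thickness once", {
  cv <- fd_curve(c(0, 1, 2), c(0, 5, 10), thickness = 0.5)
  n <- normalize_curve(cv)
  expect_equal(n$force, c(0, 10, 20))
  expect_true(n$normalized)
  expect_error(normalize_curve(n), "already")
  expect_error(fd_curve(c(0, 1), c(0, 1), thickness = 0), "thickness")
  cv2 <- fd_curve(c(0, 1, 2), c(0, 5, 10), thickness = 1.02)
  expect_equal(normalize_curve(cv2)$force[3], 10 / 1.02)
})

test_that("peak detection finds planted teeth and nothing else", {
  # strictly monotone curve: no peaks
  mono <- fd_curve(seq(0, 5, 0.01), seq(0, 5, 0.01)^1.5, normalized = TRUE)
  expect_length(detect_peaks(mono), 0L)
  # clean triangle wave with 5 teeth
  x <- seq(0, 5, by = 0.005)
  f <- 2 * abs((x %% 1) - 0.5)
  tw <- fd_curve(x, max(f) - f, normalized = TRUE)
  expect_length(detect_peaks(tw, min_spacing = 0.3), 5L)
  # generated sawtooth with noise at SNR ~ 10: all planted peaks, no
  # extras; noise at this level needs light smoothing and a prominence
  # threshold above the noise band
  plan <- cbind(c(1, 0, 1, 2, 0, 1), c(0, 1, 1, 0, 1, 1))
  for (seed in c(42, 7, 99)) {
    cv <- gen_sawtooth_curve(plan, peak_force = 3, noise_sd = 0.3,
                             seed = seed)
    pk <- detect_peaks(cv, min_prominence = 1, min_spacing = 0.17,
                       smooth = 5)
    truth <- attr(cv, "true_peaks")
    expect_length(pk, length(truth))
    expect_lt(max(abs(cv$displacement[pk] - truth)), 0.15)
  }
})

test_that("intervals are successive peak spacings", {
  cv <- fd_curve(seq(0, 3, 0.001), rep(1, 3001), normalized = TRUE)
  pk <- c(1001L, 1675L, 2349L)
  expect_equal(extract_intervals(pk, cv), c(0.674, 0.674))
  expect_length(extract_intervals(pk[1], cv), 0L)
})

test_that("interval decomposition matches printed boundary combinations", {
  d1 <- decompose_interval(0.674)
  expect_equal(c(d1$a, d1$b), c(1, 0))
  expect_equal(d1$residual, 0)
  expect_true(d1$decomposable)
  d2 <- decompose_interval(1.014)
  expect_equal(c(d2$a, d2$b), c(1, 1))
  expect_equal(d2$residual, 0, tolerance = 1e-12)
  d3 <- decompose_interval(0.50, tol = 0.03, max_count = 10)
  expect_false(d3$decomposable)
  expect_error(decompose_interval(-1), "delta")
})

test_that("decomposition agrees with the exhaustive oracle", {
  set.seed(7)
  for (k in 1:200) {
    delta <- stats::runif(1, 0.05, 4)
    got <- decompose_interval(delta, 0.674, 0.340, tol = 0.05, max_count = 6)
    want <- oracle_decompose(delta, 0.674, 0.340, 6)
    expect_lt(abs(abs(got$residual) - abs(unname(want["resid"]))), 1e-9)
  }
})

test_that("discreteness test is seeded, bounded and sharp on exact data", {
  exact <- c(0.674, 0.340, 1.014, 0.674 * 2, 0.340 * 2)
  dt <- discreteness_test(exact, n_mc = 199, seed = 5)
  expect_equal(dt$statistic, 0)
  expect_equal(dt$p_value, 1 / 200)
  # add-one bound
  vague <- c(0.5, 0.81, 0.99, 1.2)
  dt2 <- discreteness_test(vague, n_mc = 99, seed = 5)
  expect_gte(dt2$p_value, 0.01)
  # reproducibility
  dt3 <- discreteness_test(vague, n_mc = 99, seed = 5)
  expect_identical(dt2$p_value, dt3$p_value)
  expect_error(discreteness_test(c(0.6, 0.7), n_mc = 199), "3 intervals")
  expect_error(discreteness_test(exact, n_mc = 50), "n_mc")
})

test_that("worm-like-chain fitting recovers parameters", {
  cv <- gen_wlc_curve(amplitude = 2, contour_length = 30,
                      max_displacement = 20, noise_sd = 0, seed = 1)
  fit <- fit_wlc(cv)
  expect_lt(abs(fit$amplitude - 2) / 2, 0.001)
  expect_lt(abs(fit$contour_length - 30) / 30, 0.001)
  # model identities
  expect_equal(predict(fit, 0), 0)
  pr <- predict(fit, seq(0, 20, 0.1))
  expect_true(all(diff(pr) > 0))
  expect_equal(unname(coef(fit)["contour_length"]), fit$contour_length)
})

test_that("curves classify into sawtooth and smooth classes", {
  st <- gen_sawtooth_curve(cbind(c(1, 0, 1, 1), c(0, 1, 1, 0)), seed = 2)
  expect_equal(as.character(classify_curve(st)), "sawtooth")
  wl <- gen_wlc_curve(noise_sd = 0.04, seed = 2)
  expect_equal(as.character(classify_curve(wl)), "smooth")
  flat <- fd_curve(seq(0, 5, 0.01), rep(0, 501), normalized = TRUE)
  cls <- classify_curve(flat)
  expect_equal(as.character(cls), "smooth")
  expect_match(attr(cls, "warning"), "degenerate")
})

test_that("maximum normalised strength is the curve maximum", {
  cv <- fd_curve(c(0, 1, 2), c(70, 70, 70), normalized = TRUE)
  expect_equal(max_normalized_strength(cv), 70)
  z <- fd_curve(c(0, 1), c(0, 0), normalized = TRUE)
  expect_equal(max_normalized_strength(z), 0)
})
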