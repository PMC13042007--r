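test_that("generators are pure functions of parameters and seed", {
  plan <- cbind(c(1, 1), c(0, 1))
  a <- gen_sawtooth_curve(plan, seed = 9)
  b <- gen_sawtooth_curve(plan, seed = 9)
  expect_identical(a$force, b$force)
  c_ <- gen_sawtooth_curve(plan, seed = 10)
  expect_false(identical(a$force, c_$force))
  w1 <- gen_wlc_curve(noise_sd = 0.1, seed = 4)
  w2 <- gen_wlc_curve(noise_sd = 0.1, seed = 4)
  expect_identical(w1$force, w2$force)
})

test_that("sawtooth teeth have the planned widths", {
  plan <- cbind(c(1, 1), c(0, 0))
  cv <- gen_sawtooth_curve(plan, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(attr(cv, "true_peaks")), c(0.674, 1.348))
  plan2 <- cbind(1, 1)
  cv2 <- gen_sawtooth_curve(plan2, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(attr(cv2, "true_peaks")), 0.674 + 0.340)
  expect_error(gen_sawtooth_curve(cbind(0, 0)), "a \\+ b")
  expect_error(gen_sawtooth_curve(plan, sample_pitch = 0.2), "sample_pitch")
})

test_that("worm-like-chain generator round-trips through the fitter", {
  cv <- gen_wlc_curve(amplitude = 1.5, contour_length = 25,
                      max_displacement = 16, noise_sd = 0, seed = 1)
  fit <- fit_wlc(cv)
  expect_lt(abs(fit$amplitude - 1.5) / 1.5, 1e-3)
  expect_lt(abs(fit$contour_length - 25) / 25, 1e-3)
  expect_error(gen_wlc_curve(contour_length = 10, max_displacement = 12),
               "contour")
  z <- gen_wlc_curve(amplitude = 0, noise_sd = 0)
  expect_true(all(z$force == 0))
})

test_that("the fixture suite is reproducible and self-labelling", {
  d1 <- file.path(tempdir(), "fxa")
  d2 <- file.path(tempdir(), "fxb")
  m1 <- gen_fixture_suite(d1, seed = 3)
  m2 <- gen_fixture_suite(d2, seed = 3)
  expect_equal(m1$n_files, 9L)   # 6 curves + 3 configs
  for (e in m1$entries) {
    f1 <- readLines(file.path(d1, e$file))
    f2 <- readLines(file.path(d2, e$file))
    expect_identical(f1, f2)
  }
  # every curve classifies as its ground-truth label
  for (e in m1$entries) {
    if (!e$label %in% c("sawtooth", "smooth")) next
    cv <- read_curve_csv(file.path(d1, e$file))
    expect_equal(as.character(classify_curve(cv)), e$label,
                 label = e$file)
  }
  # configs load back
  cfg <- load_config(file.path(d1, "defect_ripped.yaml"))
  expect_equal(cfg$defect$kind, "ripped_units")
  expect_equal(cfg$defect$n_units, 254L)
})
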