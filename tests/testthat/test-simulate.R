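test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  d1 <- garriott_like(seed = 3)
  d2 <- garriott_like(seed = 3)
  expect_identical(d1$data, d2$data)
  expect_false(identical(garriott_like(seed = 4)$data, d1$data))
  # caller RNG stream unaffected by the internal seeding
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("vanishing variance puts every response on the curve", {
  p <- mn_params("exponential", a = c(all = 1), b = c(all = 0.05),
                 c = 4, d = 1, var = c(all = 1e-12))
  ds <- generate_dataset(p, c(0, 5, 25), n_per_group = 3, seed = 1)
  expected <- predict_response(p, "all", ds$data$dose)
  expect_equal(ds$data$response, expected, tolerance = 1e-4)
})

test_that("log-residual spread matches the nominal variance at large n", {
  p <- mn_params("exponential", a = c(all = 1), b = c(all = 0.05),
                 c = 4, d = 1, var = c(all = 0.1))
  ds <- generate_dataset(p, c(0, 10), n_per_group = 10000, seed = 6)
  ctrl <- ds$data$response[ds$data$dose == 0]
  expect_equal(stats::sd(log(ctrl)), sqrt(0.1), tolerance = 0.02)
  # and the residuals look normal on the log scale
  pv <- stats::shapiro.test(sample(log(ctrl), 500))$p.value
  expect_gt(pv, 1e-4)
})

test_that("the two emulated designs reproduce the printed response regimes", {
  g <- garriott_like(seed = 1)
  means <- tapply(g$data$response,
                  list(g$data$covariate_level, g$data$dose), mean)
  # males span low through high response
  expect_lte(min(means["male", ]), 0.2)
  expect_gte(max(means["male", ]), 6)
  # females stay an order of magnitude lower at the top dose
  expect_lt(max(means["female", ]), 3)

  f <- fiedler_like(seed = 1)
  fmeans <- tapply(f$data$response, f$data$dose, mean)
  expect_true(all(fmeans >= 1 & fmeans <= 8))

  # both satisfy the dataset invariants by construction
  expect_true(all(g$data$response > 0))
  expect_true(all(f$data$response > 0))
  expect_s3_class(mn_dataset(g$data), "mn_dataset")
  expect_gte(length(unique(f$data$dose)), 3)
})

test_that("frozen truths sit at the calibration anchors", {
  g <- garriott_true_params()
  expect_equal(predict_response(g, "male", 0), 0.1)
  expect_equal(predict_response(g, "male", 57), 8.7, tolerance = 1e-10)
  expect_equal(predict_response(g, "female", 57), 1.86,
               tolerance = 1e-10)
  f <- fiedler_true_params()
  expect_equal(predict_response(f, "male", 14.3), 2.3, tolerance = 1e-9)
  expect_equal(predict_response(f, "male", 114), 4.9, tolerance = 1e-9)
})

test_that("recovery study tracks the true BMD and reports failures", {
  p <- mn_params("exponential", a = c(all = 1), b = c(all = 0.05),
                 c = 4, d = 1, var = c(all = 0.05))
  r <- parameter_recovery_study(p, c(0, 3, 12, 48), "all",
                                n_per_group = 10, n_reps = 12, seed = 50)
  expect_equal(r$true_bmd, compute_bmd(p, "all", 0.5))
  expect_lt(abs(r$summary$rel_bias), 0.25)
  expect_equal(r$summary$n_failed, 0)
  expect_equal(nrow(r$results), 12)
  expect_true(all(r$results$bmdl <= r$results$bmd + 1e-8))
})
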