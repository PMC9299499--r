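test_that("predict_response matches hand-evaluated closed forms", {
  p <- mn_params("exponential", a = c(all = 0.1), b = c(all = log(2)),
                 c = 3, d = 1, var = c(all = 0.1))
  expect_equal(predict_response(p, "all", 1), 0.1 * (3 - 2 * exp(-log(2))))
  expect_equal(predict_response(p, "all", 1), 0.2)
  expect_equal(predict_response(p, "all", 0), 0.1)

  h <- mn_params("hill", a = c(all = 1), b = c(all = 2), c = 2, d = 1,
                 var = c(all = 0.1))
  expect_equal(predict_response(h, "all", 2), 1.5)
  expect_equal(predict_response(h, "all", 0), 1)
})

test_that("background and plateau identities hold for both families", {
  for (fam in c("exponential", "hill")) {
    p <- mn_params(fam, a = c(all = 0.5), b = c(all = 0.2), c = 6,
                   d = 1.5, var = c(all = 0.1))
    expect_identical(predict_response(p, "all", 0), 0.5)
    expect_equal(predict_response(p, "all", 1e8), 0.5 * 6,
                 tolerance = 1e-4)
  }
})

test_that("curves are monotone non-decreasing in dose when c > 1", {
  set.seed(7)
  doses <- c(0, 10^seq(-3, 3, length.out = 40))
  for (fam in c("exponential", "hill")) {
    for (i in 1:25) {
      p <- random_params(fam)
      m <- predict_response(p, "all", doses)
      expect_true(all(diff(m) >= -1e-12))
      expect_true(all(m > 0))
    }
  }
})

test_that("unknown level and invalid inputs are rejected", {
  p <- toy_exp_params()
  expect_error(predict_response(p, "nope", 1), "unknown covariate level")
  expect_error(predict_response(p, "all", -1), "non-negative")
  expect_error(mn_params("exponential", a = c(x = -1), b = c(x = 1),
                         c = 2, d = 1, var = c(x = 0.1)), "positive")
  expect_error(mn_params("exponential", a = c(x = 1), b = c(x = 1),
                         c = 2, d = 1, var = c(y = 0.1)), "level")
})

test_that("log-likelihood reproduces the zero-residual normal density", {
  p <- mn_params("exponential", a = c(all = 1), b = c(all = 0.1),
                 c = 3, d = 1, var = c(all = 1))
  m5 <- predict_response(p, "all", 5)
  ds <- mn_dataset(data.frame(dataset_id = "t", covariate_level = "all",
                              dose = 5, response = m5))
  expect_equal(log_likelihood(ds, p), -0.5 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("log-likelihood is additive, order-invariant and matches a brute-force oracle", {
  p <- mn_params("exponential",
                 a = c(f = 0.9, m = 1.1), b = c(f = 0.02, m = 0.08),
                 c = 5, d = 1.2, var = c(f = 0.15, m = 0.08))
  ds <- generate_dataset(p, c(0, 2, 10, 50), n_per_group = 4, seed = 11)
  df <- ds$data

  expect_equal(log_likelihood(ds, p), brute_force_ll(df, p),
               tolerance = 1e-10)

  # order invariance
  perm <- mn_dataset(df[sample(nrow(df)), ])
  expect_equal(log_likelihood(perm, p), log_likelihood(ds, p),
               tolerance = 1e-10)

  # additivity over a split into per-level subsets
  a_part <- mn_dataset(df[df$covariate_level == "f", ])
  b_part <- mn_dataset(df[df$covariate_level == "m", ])
  expect_equal(log_likelihood(a_part, p) + log_likelihood(b_part, p),
               log_likelihood(ds, p), tolerance = 1e-10)
})

test_that("summary-form intake maps arithmetic moments to the log scale", {
  # independent evaluation of the lognormal moment map
  m <- 2.4; s <- 0.9; n <- 8; dose <- c(0, 3, 12)
  df <- data.frame(dataset_id = "s", covariate_level = "all",
                   dose = dose, n = n, mean = m, sd = s)
  ds <- mn_dataset(df)
  expect_identical(ds$form, "summary")
  p <- mn_params("exponential", a = c(all = 2), b = c(all = 0.05),
                 c = 3, d = 1, var = c(all = 0.2))
  lv <- log(1 + (s / m)^2)
  lm <- log(m) - lv / 2
  mu <- log(predict_response(p, "all", dose))
  expected <- sum(-n / 2 * log(2 * pi * 0.2) -
                    (n * lv + n * (lm - mu)^2) / (2 * 0.2))
  expect_equal(log_likelihood(ds, p), expected, tolerance = 1e-10)
})

test_that("fit recovers generating parameters from near-noise-free data", {
  for (fam in c("exponential", "hill")) {
    b0 <- if (fam == "hill") 12 else 0.06
    truth <- mn_params(fam, a = c(all = 1), b = c(all = b0), c = 4,
                       d = 1.5, var = c(all = 1e-4))
    ds <- generate_dataset(truth, c(0, 2, 6, 18, 54), n_per_group = 5,
                           seed = 3)
    fit <- fit_single_structure(ds, fam)
    expect_equal(fit$params$a[["all"]], 1, tolerance = 0.05)
    expect_equal(fit$params$b[["all"]], b0, tolerance = 0.05)
    expect_equal(fit$params$c, 4, tolerance = 0.05)
    expect_equal(fit$params$d, 1.5, tolerance = 0.05)
  }
})

test_that("dose-independent data give a flat model with undefined BMD", {
  flat <- mn_params("exponential", a = c(all = 2), b = c(all = 1e-9),
                    c = 1 + 1e-6, d = 1, var = c(all = 0.05))
  ds <- generate_dataset(flat, c(0, 5, 25, 100), n_per_group = 8,
                         seed = 5)
  fit <- fit_single_structure(ds, "exponential")
  bmd <- compute_bmd(fit$params, "all", 0.5)
  expect_true(fit$diagnostics$flat || bmd > 1e4 || !is.finite(bmd))
})

test_that("all-shared fit on two levels equals a pooled single-level fit", {
  p <- toy_exp_params()
  ds <- generate_dataset(p, c(0, 3, 12, 48), n_per_group = 6, seed = 9)
  df2 <- ds$data
  df2$covariate_level <- rep(c("g1", "g2"), length.out = nrow(df2))
  two <- mn_dataset(df2)
  f_pool <- fit_single_structure(ds, "exponential")
  f_two <- fit_single_structure(two, "exponential", mn_structure())
  expect_equal(f_two$loglik, f_pool$loglik, tolerance = 1e-5)
  expect_equal(f_two$params$c, f_pool$params$c, tolerance = 1e-3)
})

test_that("widening the covariate structure never lowers the maximized loglik", {
  p <- mn_params("exponential",
                 a = c(f = 0.8, m = 1.3), b = c(f = 0.03, m = 0.07),
                 c = 4, d = 1, var = c(f = 0.1, m = 0.1))
  ds <- generate_dataset(p, c(0, 4, 16, 64), n_per_group = 5, seed = 21)
  ll <- c(
    shared = fit_single_structure(ds, "exponential",
                                  mn_structure())$loglik,
    a = fit_single_structure(ds, "exponential",
                             mn_structure("a"))$loglik,
    ab = fit_single_structure(ds, "exponential",
                              mn_structure(c("a", "b")))$loglik,
    abv = fit_single_structure(ds, "exponential",
                               mn_structure(c("a", "b", "var")))$loglik)
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("fitting precondition on dose levels is enforced", {
  p <- toy_exp_params()
  ds2 <- generate_dataset(p, c(0, 10), n_per_group = 5, seed = 2)
  expect_error(fit_single_structure(ds2, "exponential"),
               "3 distinct dose levels")
  no0 <- mn_dataset(
    within(generate_dataset(p, c(0, 5, 20), 5, 2)$data,
           dose[dose == 0] <- 1))
  expect_error(fit_single_structure(no0, "exponential"), "control")
})
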