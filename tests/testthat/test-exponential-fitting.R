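# Exponential fitting, model selection and residual diagnostics.

make_single <- function(k, dr = -0.12, rf = 0.19, n = 1000, t_end = NULL,
                        noise = 0, seed = NULL) {
  if (is.null(t_end)) t_end <- max(10 / k, 0.05)
  t <- seq(1e-3, t_end, length.out = n)
  y <- single_exponential(t, dr, k, rf)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, 0, noise)
  }
  kinetic_trace(t, y, "anisotropy")
}

test_that("noiseless single-exponential parameters are recovered exactly", {
  # rates spanning the full observed range of the study (about 6-430 s^-1)
  for (k in c(6.2, 26.2, 58.5, 104, 228, 406.2, 430)) {
    fit <- fit_single_exponential(make_single(k))
    expect_true(fit$converged)
    expect_equal(fit$coefficients[["k_obs"]], k, tolerance = 1e-6 * k)
    expect_equal(fit$coefficients[["delta_r"]], -0.12, tolerance = 1e-6)
    expect_equal(fit$coefficients[["r_f"]], 0.19, tolerance = 1e-6)
    expect_lt(fit$ssr, 1e-12)
  }
})

test_that("fitted rate is invariant under affine rescaling of the signal", {
  tr <- make_single(100, noise = 0.002, seed = 3)
  k1 <- fit_single_exponential(tr)$coefficients[["k_obs"]]
  tr2 <- kinetic_trace(tr$times, 50 * tr$signal - 7, "anisotropy")
  k2 <- fit_single_exponential(tr2)$coefficients[["k_obs"]]
  expect_equal(k1, k2, tolerance = 1e-7)
})

test_that("a flat trace is flagged with near-zero amplitude", {
  t <- seq(1e-3, 0.5, length.out = 200)
  tr <- kinetic_trace(t, rep(0.15, 200), "anisotropy")
  expect_warning(fit <- fit_single_exponential(tr), "flat")
  expect_equal(fit$coefficients[["delta_r"]], 0)
  expect_false(fit$converged)
  expect_true("amplitude_degenerate" %in% fit$flags)
})

test_that("noisy trace recovers the rate within a few standard errors", {
  tr <- make_single(406.2, noise = 0.002 / sqrt(5), seed = 1)
  fit <- fit_single_exponential(tr)
  expect_lt(abs(fit$coefficients[["k_obs"]] - 406.2), 3 * fit$se[["k_obs"]])
})

test_that("well-separated biphasic decays are recovered to 0.1%", {
  t <- seq(1e-3, 0.5, length.out = 2000)
  y <- double_exponential(t, 0.04, 20, 0.04, 500, 0.1)
  tr <- kinetic_trace(t, y, "anisotropy")
  fit <- fit_double_exponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$coefficients[["k_obs1"]], 20, tolerance = 0.001 * 20)
  expect_equal(fit$coefficients[["k_obs2"]], 500, tolerance = 0.001 * 500)
  expect_lt(fit$coefficients[["k_obs1"]], fit$coefficients[["k_obs2"]])
})

test_that("the double model never fits worse than the single model", {
  # mono-exponential truth, with and without noise
  for (tr in list(make_single(100),
                  make_single(100, noise = 0.002, seed = 5),
                  make_single(406.2, noise = 0.001, seed = 6))) {
    f1 <- fit_single_exponential(tr)
    f2 <- fit_double_exponential(tr)
    expect_lte(f2$ssr, f1$ssr + 1e-15)
  }
})

test_that("zero second amplitude reduces the double fit to the single one", {
  tr <- make_single(100)
  f1 <- fit_single_exponential(tr)
  f2 <- fit_double_exponential(tr, init = list(delta_r2 = 0))
  i <- f2$coefficients
  expect_equal(double_exponential(tr$times, i[["delta_r1"]], i[["k_obs1"]],
                                  0, 1, i[["r_f"]]),
               f1$fitted, tolerance = 1e-6)
})

test_that("model selection prefers single unless the F-test is significant", {
  tr <- make_single(100)
  f1 <- fit_single_exponential(tr)
  f2 <- fit_double_exponential(tr)
  sel <- select_model(f1, f2)
  expect_equal(sel$choice, "single")

  # rates 25x apart with noise: double wins decisively
  t <- seq(1e-3, 0.5, length.out = 1000)
  set.seed(8)
  y <- double_exponential(t, 0.05, 20, 0.05, 500, 0.1) + rnorm(1000, 0, 0.001)
  trb <- kinetic_trace(t, y, "anisotropy")
  selb <- select_model(fit_single_exponential(trb), fit_double_exponential(trb))
  expect_equal(selb$choice, "double")
  expect_lt(selb$p, 1e-6)
})

test_that("residual diagnostics separate correct from mis-specified models", {
  # correct model + Gaussian noise: white residuals
  tr <- make_single(100, noise = 0.002, seed = 9)
  f <- fit_single_exponential(tr)
  d <- residual_diagnostics(f)
  expect_lt(abs(d$lag1_autocorr), 0.15)
  expect_equal(d$residual_sd, 0.002, tolerance = 0.15)

  # single fit to biphasic truth: strongly structured residuals
  t <- seq(1e-3, 0.5, length.out = 1000)
  y <- double_exponential(t, 0.05, 20, 0.05, 500, 0.1)
  fb <- fit_single_exponential(kinetic_trace(t, y, "anisotropy"))
  db <- residual_diagnostics(fb)
  expect_gt(abs(db$lag1_autocorr), 0.9)

  # noiseless perfect fit: residual SD at numerical zero
  dp <- residual_diagnostics(fit_single_exponential(make_single(100)))
  expect_lt(dp$residual_sd, 1e-8)
})
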