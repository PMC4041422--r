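# k_obs regression, condition tables, folds, lifetimes, dilution analysis
# and the end-to-end pipeline.

test_that("noiseless k_obs regression returns the generating constants", {
  conc <- c(0.05, 0.2, 0.5, 1.0)
  rp <- fit_kobs_vs_concentration(conc, 400 * conc + 6.2)
  expect_equal(rp$k_on, 400, tolerance = 1e-10)
  expect_equal(rp$k_off, 6.2, tolerance = 1e-10)
  expect_equal(rp$K_d, 15.5, tolerance = 1e-9)

  rp2 <- fit_kobs_vs_concentration(conc, 51.5 * conc + 7.0)
  expect_equal(rp2$K_d, 135.922, tolerance = 1e-4)
  expect_equal(signif(rp2$K_d, 3), 136)
})

test_that("k_obs regression flags degenerate designs", {
  expect_warning(rp <- fit_kobs_vs_concentration(c(0.1, 1), c(46.2, 406.2)),
                 "2 distinct")
  expect_equal(rp$k_on, 400)
  expect_error(fit_kobs_vs_concentration(0.5, 206.2), "distinct")
  expect_error(suppressWarnings(
    fit_kobs_vs_concentration(c(0.1, 0.5, 1), c(10, 8, 6))), "slope")
  expect_warning(fit_kobs_vs_concentration(c(0.1, 0.5, 1.0),
                                           c(39, 199, 399.5)),
                 "negative fitted intercept")
})

test_that("dilution analysis inverts the dilution rate relation", {
  expect_equal(analyze_dilution(406.2, 1.0, 15.5), 6.2, tolerance = 1e-12)
  expect_equal(analyze_dilution(12.34, 0.7, Inf), 12.34)
  set.seed(13)
  for (i in 1:20) {
    k_off <- runif(1, 1, 20); kd <- runif(1, 5, 500); P <- runif(1, 0, 2)
    expect_equal(analyze_dilution(kobs_dilution(k_off, kd, P), P, kd), k_off,
                 tolerance = 1e-10)
  }
})

test_that("pipeline dilution k_off lands within 5% of the generating value", {
  res <- run_dilution_analysis(list(pair = "FRT_IRP1", noise_sd = 0, seed = 1))
  expect_equal(res$k_off, 6.2, tolerance = 0.05)
  # the intercept and dilution routes are two estimates of the same quantity
  rep <- run_titration_analysis(list(preset = "fig2_frt", noise_sd = 0))
  expect_equal(res$k_off, rep$rates[["0"]]$k_off, tolerance = 0.06)
})

test_that("fold helpers implement ratio and x-fold-decrease conventions", {
  expect_equal(fold_change(65, 400), 0.1625)
  expect_equal(round(fold_decrease(65, 400), 1), 6.2)
  expect_equal(round(fold_decrease(10.7, 51.5), 1), 4.8)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(1, 0), "non-zero")
})

test_that("condition tables carry K_d and ratio columns", {
  res <- list(`0` = rate_parameters(400, 6.2),
              `5` = rate_parameters(176, 9.7),
              `25` = rate_parameters(104, 11.7),
              `50` = rate_parameters(65, 12.0))
  tab <- build_condition_table(res, 0)
  expect_s3_class(tab, "titration_result")
  expect_equal(tab$mn_uM, c(0, 5, 25, 50))
  expect_equal(tab$K_d, 1000 * tab$k_off / tab$k_on, tolerance = 1e-9)
  expect_equal(signif(tab$K_d, 4), c(15.5, 55.11, 112.5, 184.6))
  expect_equal(tab$k_on_ratio[1], 1)
  expect_equal(tab$K_d_ratio[1], 1)
  # ACO2 k_on ratio at 50 uM Mn2+ rounds to the tabulated 0.21
  expect_equal(round(fold_change(10.7, 51.5), 2), 0.21)
  expect_error(build_condition_table(res, 10), "control")
})

test_that("lifetime comparison reproduces the eIF4F vs IRP1 contrast", {
  cmp <- compare_complex_lifetimes(rate_parameters(81, 4.8),
                                   rate_parameters(400, 6.2),
                                   list(rna = 0.5, protein = 0.1),
                                   list(rna = 0.05, protein = 1.0))
  expect_equal(1000 * cmp$tau1, 18.73, tolerance = 1e-3)
  expect_equal(cmp$ratio, 7.98, tolerance = 0.01)
  same <- compare_complex_lifetimes(rate_parameters(81, 4.8),
                                    rate_parameters(81, 4.8),
                                    list(rna = 0.5, protein = 0.1))
  expect_equal(same$ratio, 1)
  # zero-concentration limit: lifetimes scale inversely with k_off
  z <- compare_complex_lifetimes(rate_parameters(10, 2), rate_parameters(10, 4),
                                 list(rna = 0, protein = 0))
  expect_equal(z$ratio, 2)
})

test_that("end-to-end pipeline recovers every tabulated parameter set", {
  # noiseless generator -> fitter round trip across all pairs and Mn2+ levels
  for (preset in c("fig3_frt_mn", "fig3_aco2_mn", "fig7_eif4f_mn")) {
    rep <- run_titration_analysis(list(preset = preset, noise_sd = 0, seed = 1))
    pair <- design_preset(preset)$pair
    for (mn in c(0, 5, 25, 50)) {
      truth <- rate_lookup(pair, mn)
      got <- rep$rates[[format(mn)]]
      expect_equal(got$k_on, truth$k_on, tolerance = 0.01 * truth$k_on)
      expect_equal(got$k_off, truth$k_off, tolerance = 0.01 * truth$k_off)
    }
    # direction of the metal response at the K_d level
    kds <- rep$table$K_d
    if (grepl("eif4f", preset)) expect_true(all(diff(kds) < 0))
    else expect_true(all(diff(kds) > 0))
  }
})

test_that("pipeline model selection matches the mono-exponential truth", {
  rep <- run_titration_analysis(list(preset = "fig2_frt", seed = 2))
  expect_true(all(rep$fits$model == "single"))
})

test_that("pipeline is deterministic given config and seed", {
  a <- run_titration_analysis(list(preset = "fig2_frt", seed = 4))
  b <- run_titration_analysis(list(preset = "fig2_frt", seed = 4))
  expect_identical(a$fits, b$fits)
  expect_equal(a$rates[["0"]]$k_on, b$rates[["0"]]$k_on)
})

test_that("pipeline errors carry their stage label", {
  expect_error(run_titration_analysis(list(preset = "nope")), "\\[traces\\]")
  expect_error(run_titration_analysis(list(trace_files = character(0))),
               "empty trace set")
})
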