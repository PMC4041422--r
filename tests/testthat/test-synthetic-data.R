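# Synthetic trace generator: instrument emulation, presets, determinism.

test_that("rate lookup returns the tabulated constants", {
  r <- rate_lookup("FRT_IRP1", 0)
  expect_equal(c(r$k_on, r$k_off), c(400, 6.2))
  expect_equal(rate_lookup("FRT_IRP1", 50)$k_on, 65)
  expect_equal(rate_lookup("FRT_eIF4F", 25)$k_off, 2.5)
  expect_equal(rate_lookup("ACO2_IRP1", 25)$k_on, 17)
  # separators are normalised
  expect_equal(rate_lookup("FRT.IRP1", 5)$k_on, 176)
  expect_error(rate_lookup("FRT_IRP2", 0), "unknown pair")
  expect_error(rate_lookup("FRT_IRP1", 10), "not tabulated")
  expect_error(rate_lookup("FRT_IRP1", 60, interpolate = TRUE), "range")
})

test_that("log-linear Mn2+ interpolation is monotone between knots", {
  k10 <- rate_lookup("FRT_IRP1", 10, interpolate = TRUE)
  expect_lt(k10$k_on, rate_lookup("FRT_IRP1", 5)$k_on)
  expect_gt(k10$k_on, rate_lookup("FRT_IRP1", 25)$k_on)
  # knots are reproduced exactly
  expect_equal(rate_lookup("FRT_eIF4F", 25, interpolate = TRUE)$k_on, 159)
})

test_that("noiseless traces are flat without binding, exponential with it", {
  inert <- binding_system(0.05, binding_protein("P", 1, rate_parameters(1e-12, 0)))
  tr <- generate_trace(inert, signal_model("anisotropy", noise_sd = 0),
                       t_end = 0.05)
  expect_equal(tr$signal, rep(0.05, 1000), tolerance = 1e-9)

  tr2 <- noiseless_trace(frt_irp1(), rna = 0.05, protein = 1.0)
  k_fit <- fit_single_exponential(tr2)$coefficients[["k_obs"]]
  expect_equal(k_fit, 406.2, tolerance = 0.01 * 406.2)
  expect_gte(min(tr2$times), 1e-3) # dead time respected
  expect_length(tr2$times, 1000)
})

test_that("trace generation is deterministic given the seed", {
  sys <- one_protein_system()
  m <- signal_model("anisotropy")
  a <- generate_trace(sys, m, seed = 99)
  b <- generate_trace(sys, m, seed = 99)
  c <- generate_trace(sys, m, seed = 100)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("anisotropy traces stay within [baseline, baseline + span] up to noise", {
  tr <- noiseless_trace(frt_irp1(), rna = 0.05, protein = 1.0)
  expect_true(all(tr$signal >= 0.05 - 1e-9))
  expect_true(all(tr$signal <= 0.05 + 0.15 + 1e-9))
})

test_that("fluorescence association traces decrease monotonically (noiseless)", {
  tr <- noiseless_trace(frt_eif4f(), rna = 0.5, protein = 0.1,
                        kind = "fluorescence")
  expect_true(all(diff(tr$signal) <= 1e-12))
})

test_that("shot averaging shrinks the noise roughly as 1/sqrt(n)", {
  sys <- one_protein_system()
  m <- signal_model("anisotropy", noise_sd = 0.002)
  clean <- generate_trace(sys, signal_model("anisotropy", noise_sd = 0))
  shots <- lapply(1:7, function(i) generate_trace(sys, m, seed = 1000 + i))
  avg <- average_shots(shots)
  resid_sd <- sd(avg$signal - clean$signal)
  expect_equal(resid_sd, 0.002 / sqrt(7), tolerance = 0.2)
  expect_equal(avg$n_shots, 7L)
  # single trace passes through; noiseless shots average to themselves
  expect_identical(average_shots(list(clean)), clean)
  expect_equal(average_shots(rep(list(clean), 7))$signal, clean$signal)
  # mismatched grids are rejected
  short <- generate_trace(sys, m, n_points = 500, seed = 1)
  expect_error(average_shots(list(clean, short)), "time grids")
})

test_that("titration presets reproduce the published designs", {
  s2 <- generate_titration_series("fig2_frt", seed = 1, noise_sd = 0)
  expect_length(s2, 4)
  expect_equal(vapply(s2, function(x) x$condition$protein_uM, numeric(1)),
               c(0.05, 0.2, 0.5, 1.0))
  expect_true(all(vapply(s2, function(x) x$condition$rna_uM, numeric(1)) == 0.05))

  s7 <- generate_titration_series("fig7_eif4f", seed = 1, noise_sd = 0)
  expect_length(s7, 3)
  expect_equal(vapply(s7, function(x) x$condition$rna_uM, numeric(1)),
               c(0.1, 0.2, 0.5))
  expect_true(all(vapply(s7, `[[`, character(1), "signal_kind") == "fluorescence"))

  s3 <- generate_titration_series("fig3_frt_mn", seed = 1, noise_sd = 0)
  expect_length(s3, 16) # 4 Mn2+ conditions x 4 concentrations
  expect_equal(sort(unique(vapply(s3, function(x) x$condition$mn_uM, numeric(1)))),
               c(0, 5, 25, 50))
  expect_error(design_preset("fig9"), "unknown preset")
})

test_that("titration series are reproducible shot-by-shot from the master seed", {
  a <- generate_titration_series("fig2_frt", seed = 5)
  b <- generate_titration_series("fig2_frt", seed = 5)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
})

test_that("dilution traces relax at the linearised relaxation rate", {
  rate <- frt_irp1()
  # pre-mix 0.1 uM RNA + 2 uM IRP1, diluted 2-fold -> 0.05 + 1.0 final
  pre <- binding_system(0.1, binding_protein("IRP1", 2.0, rate))
  tr <- generate_dilution_trace(pre, dilution_factor = 2,
                                model = signal_model("anisotropy", noise_sd = 0))
  k_fit <- fit_single_exponential(tr)$coefficients[["k_obs"]]
  C_eq <- equilibrium_complex(0.05, 1.0, rate$K_d)
  lam <- rate$k_on * ((0.05 - C_eq) + (1.0 - C_eq)) + rate$k_off
  expect_equal(k_fit, lam, tolerance = 0.02)

  # no dilution, same condition: already at equilibrium, flat trace
  flat <- generate_dilution_trace(pre, dilution_factor = 1,
                                  model = signal_model("anisotropy", noise_sd = 0))
  expect_lt(diff(range(flat$signal)), 1e-6)

  # jumping into 50 uM Mn2+ accelerates loss of the bound fraction
  mn <- generate_dilution_trace(pre, dilution_factor = 2,
                                post_rate = frt_irp1(50),
                                model = signal_model("anisotropy", noise_sd = 0),
                                t_end = 0.2)
  buf <- generate_dilution_trace(pre, dilution_factor = 2,
                                 model = signal_model("anisotropy", noise_sd = 0),
                                 t_end = 0.2)
  expect_lt(mn$signal[length(mn$signal)], buf$signal[length(buf$signal)])
  expect_error(generate_dilution_trace(pre, dilution_factor = 0.5), ">= 1")
})
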