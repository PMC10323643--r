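# Constrained least-squares estimation of the circuit parameters and the
# time-series parameter tracking.

test_that("noiseless spectra are recovered to within 2% with the seal/cell ratio pinned", {
  p <- default_circuit_params()
  f <- default_frequency_grid()
  sp <- impedance_spectrum(f, circuit_impedance(2 * pi * f, p))
  truth <- unclass(p)
  for (s in c(1, 2, 3)) {
    set.seed(s)
    pert <- truth
    pert[1:8] <- pert[1:8] * exp(runif(8, log(0.5), log(2)))
    pert["n"] <- runif(1, 0.55, 1)
    fit <- suppressWarnings(fit_circuit(
      sp, init = structure(pert, class = "circuit_params"),
      fix_seal_cell_ratio = truth[["R_seal"]] / truth[["R_cell"]],
      multistart = FALSE))
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) / truth - 1)), 0.02)
  }
})

test_that("an exact start converges immediately with cost ~ 0", {
  p <- default_circuit_params()
  f <- default_frequency_grid()
  sp <- impedance_spectrum(f, circuit_impedance(2 * pi * f, p))
  fit <- suppressWarnings(fit_circuit(sp, init = p, multistart = FALSE))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2)
  expect_lt(fit$cost, 1e-12 * sum(Mod(sp$z)^2))
  expect_equal(unname(coef(fit)), unname(unclass(p)), tolerance = 1e-8)
})

test_that("the returned cost never exceeds the cost at the initial parameters", {
  p <- default_circuit_params()
  f <- default_frequency_grid()
  series <- simulate_spectra_series(p, noise_sd_rel = 0.02, seed = 11,
                                    times_min = 0)
  init <- unclass(p)
  init[1:8] <- init[1:8] * 1.5
  init <- structure(init, class = "circuit_params")
  fit <- suppressWarnings(fit_circuit(series[[1]], init = init,
                                      multistart = FALSE))
  z <- series[[1]]$z
  cost_init <- sum(Mod(z - circuit_impedance(2 * pi * f, init))^2)
  expect_lte(fit$cost, cost_init * (1 + 1e-12))
  expect_gte(fit$cost, 0)
})

test_that("under-determined and degenerate inputs are rejected or flagged", {
  p <- default_circuit_params()
  f5 <- default_frequency_grid(5)
  sp5 <- impedance_spectrum(f5, circuit_impedance(2 * pi * f5, p))
  expect_error(fit_circuit(sp5), "under-determined")
  # the structural seal/cell degeneracy is reported
  f <- default_frequency_grid()
  sp <- impedance_spectrum(f, circuit_impedance(2 * pi * f, p))
  expect_warning(fit_circuit(sp, init = p, multistart = FALSE),
                 "R_seal and R_cell")
  fit <- suppressWarnings(fit_circuit(sp, init = p, multistart = FALSE))
  expect_true(fit$degenerate_seal_cell)
  expect_true(all(fit$covariance_proxy[c("R_seal", "R_cell")] > 1))
  # pinning the ratio removes the degeneracy flag
  fit2 <- fit_circuit(sp, init = p, fix_seal_cell_ratio = 0.6,
                      multistart = FALSE)
  expect_false(fit2$degenerate_seal_cell)
})

test_that("median noisy recovery matches the information content of the spectra", {
  # at 0.1% relative noise every parameter's median estimate is close to
  # truth; at 1% only well-conditioned quantities remain (the circuit is
  # sloppy: see the methods vignette)
  p <- default_circuit_params()
  truth <- unclass(p)
  est_at <- function(noise, n_rep) {
    sapply(seq_len(n_rep), function(s) {
      sp <- simulate_spectra_series(p, rcell_slope = 0, rseal_slope = 0,
                                    noise_sd_rel = noise, seed = s,
                                    times_min = 0)[[1]]
      fit <- suppressWarnings(fit_circuit(
        sp, init = p, fix_seal_cell_ratio = 0.6,
        weighting = "inv-magnitude", multistart = FALSE))
      coef(fit)
    })
  }
  med_lo <- apply(est_at(0.001, 40), 1, median)
  expect_lt(max(abs(med_lo / truth - 1)), 0.15)
  med_hi <- apply(est_at(0.01, 40), 1, median)
  g_truth <- 1 / truth[["R_seal"]] + 1 / truth[["R_cell"]]
  g_hat <- 1 / med_hi[["R_seal"]] + 1 / med_hi[["R_cell"]]
  expect_lt(abs(g_hat / g_truth - 1), 0.15)
  expect_lt(abs(med_hi[["R_ccm"]] / truth[["R_ccm"]] - 1), 0.15)
  expect_lt(abs(med_hi[["n"]] - truth[["n"]]), 0.1)
})

test_that("parameter tracking recovers a linear R_cell drift and flat R_seal", {
  p <- default_circuit_params()
  series <- simulate_spectra_series(p, rcell_slope = 10, rseal_slope = 0,
                                    noise_sd_rel = 0)
  tr <- track_parameters(series, init = p)
  expect_equal(tr$linear_trends$R_cell[["slope"]], 10, tolerance = 0.05)
  expect_gt(tr$linear_trends$R_cell[["r_squared"]], 0.99)
  expect_lt(abs(tr$linear_trends$R_seal[["slope"]]), 1e-6)
  # the parallel-conductance trend is identifiable irrespective of the split
  g0 <- 1 / 3000 + 1 / 5000
  expect_equal(tr$g_parallel[1], g0, tolerance = 1e-6)
})

test_that("tracking flags constant series and rejects single spectra", {
  p <- default_circuit_params()
  series <- simulate_spectra_series(p, rcell_slope = 0, rseal_slope = 0,
                                    noise_sd_rel = 0)
  tr <- track_parameters(series, init = p)
  expect_lt(abs(tr$linear_trends$R_cell[["slope"]]), 1e-6)
  expect_true(is.na(tr$linear_trends$R_cell[["r_squared"]]))
  expect_error(track_parameters(series[1], init = p), "at least 2")
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  p <- default_circuit_params()
  f <- default_frequency_grid()
  sp <- impedance_spectrum(f, circuit_impedance(2 * pi * f, p))
  fit <- suppressWarnings(fit_circuit(sp, init = p, multistart = FALSE))
  expect_named(coef(fit), c("R_ccm", "R_ECM", "C_ECM", "R_seal", "R_cell",
                            "C_cell", "R_ct", "Q", "n"))
  expect_equal(predict(fit) + residuals(fit), sp$z)
  s <- summary(fit)
  expect_s3_class(s, "summary.circuit_fit")
  expect_equal(nrow(s$table), 9)
})
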