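# Forward equivalent-circuit model: constant-phase element, block structure,
# analytic limits, passivity, and agreement with the admittance oracle.

test_that("constant-phase element reduces to resistor, capacitor, and -45 deg phase", {
  # n = 0: pure resistor 1/Q, at any frequency
  expect_equal(cpa_impedance(123.4, Q = 2, n = 0), 0.5 + 0i)
  # n = 1: ideal capacitor 1/(jwC)
  w <- 2 * pi * 5e4
  expect_equal(cpa_impedance(w, Q = 3e-9, n = 1), 1 / (1i * w * 3e-9))
  # n = 0.5 at w = 1e4, Q = 1e-6: |Z| = 1e4, phase -45 deg
  z <- cpa_impedance(1e4, Q = 1e-6, n = 0.5)
  expect_equal(Mod(z), 1e4)
  expect_equal(Arg(z), -pi / 4)
  # general phase law: -n * 90 deg, frequency independent
  for (n in c(0.2, 0.8)) {
    ph <- Arg(cpa_impedance(10^seq(2, 7, 1), Q = 1e-7, n = n))
    expect_equal(ph, rep(-n * pi / 2, 6))
  }
  expect_error(cpa_impedance(-1, 1e-6, 0.5), "omega")
  expect_error(cpa_impedance(1e4, 0, 0.5), "Q")
  expect_error(cpa_impedance(1e4, 1e-6, 1.2), "n")
})

test_that("circuit impedance matches its analytic DC and high-frequency limits", {
  p <- circuit_params(R_ccm = 500, R_ECM = 2000, C_ECM = 1e-9,
                      R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
                      R_ct = 1e5, Q = 1e-6, n = 0.8)
  # w -> 0: capacitive branches open, CPA diverges so interface -> R_ct
  dc_expect <- 1e5 + 500 + 2000 + 3000 * 5000 / 8000   # 104 375 Ohm
  z_dc <- circuit_impedance(2 * pi * 1e-9, p)
  expect_equal(Re(z_dc), dc_expect, tolerance = 1e-4)
  expect_lt(abs(Im(z_dc)) / Re(z_dc), 1e-3)
  # w -> Inf: every reactive block shorts, Z -> R_ccm
  z_hf <- circuit_impedance(2 * pi * 1e15, p)
  expect_equal(Mod(z_hf), 500, tolerance = 1e-4)
})

test_that("circuit impedance agrees with the frozen block-by-block value at 10 kHz", {
  p <- circuit_params(R_ccm = 500, R_ECM = 2000, C_ECM = 1e-9,
                      R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
                      R_ct = 1e5, Q = 1e-6, n = 0.8)
  z <- circuit_impedance(2 * pi * 1e4, p)
  # computed once with the independent admittance-composition oracle
  expect_equal(Re(z), 4363.2275866203, tolerance = 1e-10)
  expect_equal(Im(z), -603.0970654596, tolerance = 1e-10)
})

test_that("circuit impedance equals the admittance-composition oracle to >= 10 digits", {
  set.seed(42)
  omega <- 2 * pi * 10^seq(1, 7, length.out = 40)   # 6 decades
  for (rep in 1:5) {
    p <- circuit_params(R_ccm = 10^runif(1, 1, 3), R_ECM = 10^runif(1, 2, 4),
                        C_ECM = 10^runif(1, -10, -8),
                        R_seal = 10^runif(1, 3, 4), R_cell = 10^runif(1, 3, 4),
                        C_cell = 10^runif(1, -10, -8),
                        R_ct = 10^runif(1, 4, 6), Q = 10^runif(1, -9, -6),
                        n = runif(1, 0.1, 1))
    z_pkg <- circuit_impedance(omega, p)
    z_orc <- oracle_circuit_impedance(omega, p)
    expect_lt(max(Mod(z_pkg - z_orc) / Mod(z_orc)), 1e-10)
  }
})

test_that("every block is passive with phase in [-90, 0] degrees across 6 decades", {
  set.seed(7)
  omega <- 2 * pi * 10^seq(1, 7, length.out = 60)
  for (rep in 1:5) {
    p <- circuit_params(R_ccm = 10^runif(1, 1, 3), R_ECM = 10^runif(1, 2, 4),
                        C_ECM = 10^runif(1, -10, -8),
                        R_seal = 10^runif(1, 3, 4), R_cell = 10^runif(1, 3, 4),
                        C_cell = 10^runif(1, -10, -8),
                        R_ct = 10^runif(1, 4, 6), Q = 10^runif(1, -9, -6),
                        n = runif(1, 0.05, 1))
    q <- unclass(p)
    blocks <- list(
      1 / (1 / q[["R_ct"]] + q[["Q"]] * (1i * omega)^q[["n"]]),
      1 / (1 / q[["R_ECM"]] + 1i * omega * q[["C_ECM"]]),
      1 / (1 / q[["R_seal"]] + 1 / q[["R_cell"]] + 1i * omega * q[["C_cell"]]))
    for (b in blocks) {
      expect_true(all(Im(b) <= 1e-12))
      expect_true(all(Arg(b) >= -pi / 2 - 1e-12 & Arg(b) <= 1e-12))
      # |R || C|-type block magnitudes never grow with frequency
      expect_true(all(diff(Mod(b)) <= 1e-9 * Mod(b)[-1]))
    }
    # CPA magnitude is non-increasing in omega for n > 0
    expect_true(all(diff(Mod(cpa_impedance(omega, q[["Q"]], q[["n"]]))) <= 0))
  }
})

test_that("parameter and spectrum validation reject invalid input", {
  expect_error(circuit_params(R_ccm = -1, R_ECM = 2000, C_ECM = 1e-9,
                              R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
                              R_ct = 1e5, Q = 1e-6, n = 0.8), "positive")
  expect_error(circuit_params(R_ccm = 500, R_ECM = 2000, C_ECM = 1e-9,
                              R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
                              R_ct = 1e5, Q = 1e-6, n = 1.3), "n must")
  expect_error(impedance_spectrum(c(2e4, 1e4), c(1 + 0i, 2 + 0i)),
               "increasing")
  expect_error(impedance_spectrum(1e4, 1 + 0i), "at least 2")
})
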