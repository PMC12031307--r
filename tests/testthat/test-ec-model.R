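test_that("frequency grid is log-spaced from 50 Hz to 1 MHz with 30 points", {
  f <- freq_grid()
  expect_length(f, 30)
  expect_equal(f[1], 50)
  expect_equal(f[30], 1e6)
  ratios <- f[-1] / f[-length(f)]
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-9)
  expect_true(all(diff(f) > 0))
})

test_that("CPE limits: alpha = 0 is a resistor 1/Q, alpha = 1 an ideal capacitor", {
  expect_equal(cpe_impedance(q = 2, alpha = 0, omega = 123), 0.5 + 0i)
  expect_equal(cpe_impedance(q = 1, alpha = 1, omega = 1), 0 - 1i)
  # phase of a lone CPE is exactly -alpha * 90 degrees at every frequency
  for (alpha in c(0.3, 0.5, 0.8, 1)) {
    z <- cpe_impedance(1e-6, alpha, 2 * pi * freq_grid())
    expect_equal(to_polar(z)$phase_deg, rep(-alpha * 90, 30), tolerance = 1e-12)
  }
})

test_that("CPE matches the complex-log oracle", {
  z <- cpe_impedance(1e-6, 0.8, 2 * pi * 1000)
  zo <- oracle_cpe(1e-6, 0.8, 2 * pi * 1000)
  expect_lt(Mod(z - zo) / Mod(zo), 1e-10)
})

test_that("CPE rejects nonpositive omega and q and out-of-range alpha", {
  expect_error(cpe_impedance(1, 0.5, -1), class = "bisfruit_domain_error")
  expect_error(cpe_impedance(0, 0.5, 1), class = "bisfruit_domain_error")
  expect_error(cpe_impedance(1, 1.2, 1), class = "bisfruit_domain_error")
})

test_that("circuit limits for ideal capacitors: R_e + R_ex at DC, R_ex || R_i at infinity", {
  p <- ec_params(r_e = 100, q_e = 1e-6, alpha_e = 1,
                 r_ex = 1000, r_i = 400, q_m = 1e-8, alpha_m = 1)
  z_lo <- circuit_impedance(p, 1e-6)
  expect_equal(Mod(z_lo), 100 + 1000, tolerance = 1e-3)
  z_hi <- circuit_impedance(p, 1e12)
  expect_equal(Mod(z_hi), 1000 * 400 / 1400, tolerance = 1e-3)
})

test_that("circuit matches an independent complex-arithmetic oracle", {
  p <- ref_ec()
  w <- 2 * pi * 1000
  expect_lt(Mod(circuit_impedance(p, w) - oracle_circuit(p, w)) /
              Mod(oracle_circuit(p, w)), 1e-10)
})

test_that("circuit agrees with the oracle on 1000 random draws", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    p <- ec_params(rlnorm(1, log(100), 1), rlnorm(1, log(1e-6), 1.5),
                   runif(1), rlnorm(1, log(2000), 1), rlnorm(1, log(800), 1),
                   rlnorm(1, log(1e-8), 1.5), runif(1))
    w <- 10^runif(1, log10(2 * pi * 50), log10(2 * pi * 1e6))
    rel <- Mod(circuit_impedance(p, w) - oracle_circuit(p, w)) /
      Mod(oracle_circuit(p, w))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
})

test_that("polar conversion is quadrant-correct and round-trips", {
  expect_equal(to_polar(1 + 0i), list(magnitude = 1, phase_deg = 0))
  p <- to_polar(1 + 1i)
  expect_equal(p$magnitude, sqrt(2))
  expect_equal(p$phase_deg, 45)
  expect_equal(to_polar(1 - 1i)$phase_deg, -45)
  expect_equal(to_polar(-1 + 0i)$phase_deg, 180)  # (-180, 180] convention
  expect_error(to_polar(0 + 0i), class = "bisfruit_domain_error")
  set.seed(3)
  z <- complex(real = rnorm(100), imaginary = rnorm(100))
  pol <- to_polar(z)
  back <- from_polar(pol$magnitude, pol$phase_deg)
  expect_lt(max(Mod(back - z) / Mod(z)), 1e-12)
})

test_that("simulated spectra have one value per grid point and are deterministic", {
  p <- ref_ec()
  s1 <- simulate_spectrum(p)
  s2 <- simulate_spectrum(p)
  expect_equal(nrow(s1), 30)
  expect_identical(s1, s2)
  expect_true(all(Mod(s1$z_real + 1i * s1$z_img) > 0))
})

test_that("magnitude is non-increasing in frequency for ideal-capacitor circuits", {
  set.seed(7)
  for (i in 1:20) {
    p <- ec_params(rlnorm(1, log(100), 0.5), rlnorm(1, log(1e-6), 0.5), 1,
                   rlnorm(1, log(2000), 0.5), rlnorm(1, log(600), 0.5),
                   rlnorm(1, log(1e-8), 0.5), 1)
    s <- simulate_spectrum(p)
    mags <- to_polar(complex(real = s$z_real, imaginary = s$z_img))$magnitude
    expect_true(all(diff(mags) <= 1e-9 * mags[-30]))
  }
})

test_that("canonical labelling leaves the spectrum unchanged and orders dispersions", {
  set.seed(11)
  for (i in 1:20) {
    p <- ec_params(rlnorm(1, log(300), 0.8), rlnorm(1, log(1e-6), 1.2),
                   runif(1, 0.6, 1), rlnorm(1, log(3000), 0.8),
                   rlnorm(1, log(1000), 0.8), rlnorm(1, log(5e-8), 1.2),
                   runif(1, 0.6, 1))
    pc <- canonicalize_ec(p)
    w <- 2 * pi * freq_grid()
    expect_lt(max(Mod(circuit_impedance(p, w) - circuit_impedance(pc, w)) /
                    Mod(circuit_impedance(p, w))), 1e-9)
    # canonical: electrode dispersion at or below tissue characteristic frequency
    w_e <- (pc[["r_e"]] * pc[["q_e"]])^(-1 / pc[["alpha_e"]])
    w_m <- ((pc[["r_ex"]] + pc[["r_i"]]) * pc[["q_m"]])^(-1 / pc[["alpha_m"]])
    expect_lte(w_e, w_m * (1 + 1e-9))
  }
})

test_that("series electrode topology differs from parallel and adds at DC", {
  p <- ref_ec()
  w <- 2 * pi * 100
  expect_gt(Mod(circuit_impedance(p, w, topology = "series_electrode")),
            Mod(circuit_impedance(p, w, topology = "parallel_electrode")))
})
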