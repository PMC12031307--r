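test_that("default design yields the full cohort counts and exact balance", {
  d <- study_design()
  expect_equal(d$n_per_group, 46L)
  expect_equal(d$days, 0:2)
  ch <- draw_cohort(d, cohort_params(), seed = 2)
  expect_equal(nrow(ch$samples), 184)
  expect_equal(sum(ch$samples$size == "small"), 92)
  expect_equal(sum(ch$samples$storage == "room"), 92)
  tab <- table(ch$samples$size, ch$samples$storage)
  expect_true(all(tab == 46))
})

test_that("cohort generation is reproducible under a fixed seed", {
  a <- simulate_cohort(seed = 5, design = study_design(n_per_group = 4))
  b <- simulate_cohort(seed = 5, design = study_design(n_per_group = 4))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$measurements), as.data.frame(b$measurements))
  c2 <- simulate_cohort(seed = 6, design = study_design(n_per_group = 4))
  expect_false(identical(a$truth, c2$truth))
})

test_that("zero cold jitter leaves cold-group parameters exactly at baseline", {
  ch <- draw_cohort(study_design(n_per_group = 4),
                    cohort_params(drift_jitter_cold = 0), seed = 3)
  ch <- apply_drift(ch)
  cold_ids <- ch$samples$sample_id[ch$samples$storage == "cold"]
  t0 <- ch$truth[ch$truth$day == 0 & ch$truth$sample_id %in% cold_ids, ]
  t2 <- ch$truth[ch$truth$day == 2 & ch$truth$sample_id %in% cold_ids, ]
  expect_identical(t0[order(t0$sample_id), bisfruit:::ec_param_names],
                   t2[order(t2$sample_id), bisfruit:::ec_param_names],
                   ignore_attr = TRUE)
})

test_that("room storage raises low-frequency impedance and dominates the deltas", {
  ch <- tiny_cohort(seed = 7, n_per_group = 20)
  m <- ch$measurements
  room2 <- m[m$storage == "room" & m$day == 2, ]
  room0 <- m[m$storage == "room" & m$day == 0, ]
  expect_gt(mean(room2$zmod_001), mean(room0$zmod_001))
  dz <- function(st) {
    d2 <- m[m$day == 2 & m$storage == st, ]
    d0 <- m[m$day == 0 & m$storage == st, ]
    mean(abs(d2$zmod_001 - d0$zmod_001[match(d2$sample_id, d0$sample_id)]))
  }
  expect_gt(dz("room"), dz("cold"))
})

test_that("membrane capacitance couples to diameter: above the membrane relaxation, large fruit show smaller phase magnitude", {
  ch <- simulate_cohort(seed = 7)
  d0 <- ch$measurements[ch$measurements$day == 0, ]
  # frequency point ~46 kHz, above the ~5 kHz membrane dispersion
  k <- which.min(abs(attr(ch$measurements, "freq") - 46e3))
  col <- sprintf("phase_%03d", k)
  small <- abs(d0[[col]][d0$size == "small"])
  large <- abs(d0[[col]][d0$size == "large"])
  expect_lt(mean(large), mean(small))
  expect_lt(t.test(small, large)$p.value, 0.01)
})

test_that("day-0 distributions are exchangeable across storage groups", {
  # labels are assigned after all baseline quantities are drawn; a two-sample
  # test on day-0 low-frequency magnitude should be unremarkable
  ch <- simulate_cohort(seed = 13)
  d0 <- ch$measurements[ch$measurements$day == 0, ]
  p <- t.test(d0$zmod_001[d0$storage == "room"],
              d0$zmod_001[d0$storage == "cold"])$p.value
  expect_gt(p, 0.001)
})

test_that("noise-free measurement equals the forward model and closes the fit loop", {
  ch <- simulate_cohort(seed = 4, design = study_design(n_per_group = 2),
                        params = cohort_params(noise_mag_rel_sd = 0,
                                               noise_phase_sd_deg = 0))
  m <- ch$measurements
  i <- 3
  truth_row <- ch$truth[ch$truth$sample_id == m$sample_id[i] &
                          ch$truth$day == m$day[i], ]
  p <- structure(as.numeric(truth_row[, bisfruit:::ec_param_names]),
                 names = bisfruit:::ec_param_names, class = "ec_params")
  spec <- simulate_spectrum(p, attr(m, "freq"))
  pol <- to_polar(complex(real = spec$z_real, imaginary = spec$z_img))
  nf <- length(attr(m, "freq"))
  expect_equal(as.numeric(m[i, sprintf("zmod_%03d", 1:nf)]), pol$magnitude,
               tolerance = 1e-12)
  expect_equal(as.numeric(m[i, sprintf("phase_%03d", 1:nf)]), pol$phase_deg,
               tolerance = 1e-12)
  # fitting the noiseless measurement recovers the generating parameters
  spec_meas <- bisfruit:::measurements_to_spectra(m)[[i]]
  fit <- suppressWarnings(fit_ec(spec_meas, starts = 6, seed = 1))
  truth_can <- canonicalize_ec(p)
  expect_lt(max(abs(coef(fit) - unclass(truth_can)) / unclass(truth_can)), 0.01)
})

test_that("delta-space separates storage groups better than raw space under a fixed linear probe", {
  ch <- simulate_cohort(seed = 9)
  raw <- assemble_dataset(ch, "bio-raw")
  del <- assemble_dataset(ch, "bio-delta")
  probe_auc <- function(ft) {
    # fixed probe: standardized class-mean difference direction
    x <- suppressWarnings(zscore_normalize(ft$x))$x
    w <- colMeans(x[ft$y == "room", , drop = FALSE]) -
      colMeans(x[ft$y == "cold", , drop = FALSE])
    s <- drop(x %*% w)
    mean(outer(s[ft$y == "room"], s[ft$y == "cold"], ">")) # AUC
  }
  expect_gt(probe_auc(del), probe_auc(raw))
})

test_that("unknown storage labels are rejected", {
  ch <- draw_cohort(study_design(n_per_group = 2), cohort_params(), seed = 1)
  ch$samples$storage[1] <- "tepid"
  expect_error(apply_drift(ch), class = "bisfruit_label_error")
})
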