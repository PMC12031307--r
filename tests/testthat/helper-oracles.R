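# Independent oracles and small fixtures used across the suite.

# CPE impedance via R's complex exponentiation (exp(alpha*log(j*omega))):
# a different code path than the package's cos/sin construction.
oracle_cpe <- function(q, alpha, omega) {
  1 / (q * (complex(real = 0, imaginary = omega))^alpha)
}

# Full circuit by direct complex arithmetic, written independently of
# circuit_impedance (explicit fractions, no shared helpers).
oracle_circuit <- function(p, omega) {
  z_e <- oracle_cpe(p[["q_e"]], p[["alpha_e"]], omega)
  z_m <- oracle_cpe(p[["q_m"]], p[["alpha_m"]], omega)
  block_a <- (p[["r_e"]] * z_e) / (p[["r_e"]] + z_e)
  inner <- p[["r_i"]] + z_m
  block_b <- (p[["r_ex"]] * inner) / (p[["r_ex"]] + inner)
  block_a + block_b
}

# Exact two-sided signed-rank p-value by brute-force enumeration of all
# 2^n sign assignments (requires untied |d|, no zeros).
enum_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# reference parameter set used in several tests
ref_ec <- function() {
  ec_params(r_e = 50, q_e = 1e-7, alpha_e = 0.9,
            r_ex = 2000, r_i = 500, q_m = 1e-8, alpha_m = 0.85)
}

# random valid parameter draw in cohort-like ranges (canonical labelling)
random_ec <- function() {
  canonicalize_ec(ec_params(
    r_e = rlnorm(1, log(300), 0.3), q_e = rlnorm(1, log(1e-5), 0.4),
    alpha_e = runif(1, 0.75, 0.95),
    r_ex = rlnorm(1, log(3000), 0.25), r_i = rlnorm(1, log(1000), 0.25),
    q_m = rlnorm(1, log(5e-8), 0.3), alpha_m = runif(1, 0.7, 0.9)))
}

# tiny cohort for fast end-to-end checks
tiny_cohort <- function(seed = 1, n_per_group = 4, ...) {
  simulate_cohort(seed = seed,
                  design = study_design(n_per_group = n_per_group),
                  params = cohort_params(...))
}

# two well-separated Gaussian blobs (trivially separable)
blob_table <- function(n_per_class = 30, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, -sep / 2, 0.5), n_per_class),
             matrix(rnorm(n_per_class * d, sep / 2, 0.5), n_per_class))
  colnames(x) <- paste0("f", seq_len(d))
  y <- factor(rep(c("room", "cold"), each = n_per_class),
              levels = c("room", "cold"))
  feature_table(x, y,
                data.frame(sample_id = sprintf("B%03d", seq_len(2 * n_per_class)),
                           day = 1L),
                "blobs")
}
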