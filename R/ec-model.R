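#' Logarithmic measurement frequency grid
#'
#' Frequencies at which a spectrum is measured: `n` points log-spaced from
#' `f_min` to `f_max`. The default reproduces the standard sweep used for
#' whole-fruit bioimpedance: 30 points from 50 Hz to 1 MHz.
#'
#' @param n number of frequency points.
#' @param f_min,f_max first and last frequency in Hz.
#' @return numeric vector of frequencies in Hz, strictly increasing.
#' @examples
#' f <- freq_grid()
#' length(f)          # 30
#' range(f)           # 50 Hz to 1 MHz
#' @export
freq_grid <- function(n = 30L, f_min = 50, f_max = 1e6) {
  stopifnot(n >= 2L, f_min > 0, f_max > f_min)
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

#' Constant-phase-element impedance
#'
#' Impedance of a CPE, \eqn{Z_{CPE} = 1 / (Q (j\omega)^\alpha)}, evaluated as
#' \eqn{(j\omega)^\alpha = \omega^\alpha (\cos(\alpha\pi/2) + j \sin(\alpha\pi/2))}.
#' `alpha = 1` is an ideal capacitor (phase \eqn{-90^\circ}), `alpha = 0` a
#' resistor of value `1/q`; a lone CPE has phase exactly
#' \eqn{-\alpha \cdot 90^\circ} at every frequency.
#'
#' @param q non-ideal capacitance magnitude (s^alpha / Ohm), positive.
#' @param alpha ideality factor in \[0, 1\].
#' @param omega angular frequency rad/s (vectorised), positive.
#' @return complex vector, one impedance per `omega`.
#' @export
cpe_impedance <- function(q, alpha, omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop_bisfruit("`omega` must be positive and finite", "bisfruit_domain_error")
  }
  if (!is.finite(q) || q <= 0) {
    stop_bisfruit("CPE `q` must be positive", "bisfruit_domain_error")
  }
  if (alpha < 0 || alpha > 1) {
    stop_bisfruit("CPE `alpha` must lie in [0, 1]", "bisfruit_domain_error")
  }
  1 / (q * omega^alpha * complex(real = cos(alpha * pi / 2),
                                 imaginary = sin(alpha * pi / 2)))
}

#' Equivalent-circuit parameter set
#'
#' The seven free parameters of the modified Hayden circuit: an electrode
#' interface block (contact resistance `r_e` with constant-phase element
#' `q_e`, `alpha_e`) in series with the tissue block (extracellular
#' resistance `r_ex` in parallel with the series pair of intracellular
#' resistance `r_i` and membrane CPE `q_m`, `alpha_m`).
#'
#' @param r_e electrode contact resistance, Ohm.
#' @param q_e,alpha_e electrode CPE parameters.
#' @param r_ex extracellular resistance, Ohm.
#' @param r_i intracellular resistance, Ohm.
#' @param q_m,alpha_m membrane CPE parameters.
#' @return named numeric vector of class `ec_params`.
#' @examples
#' p <- ec_params(r_e = 50, q_e = 1e-7, alpha_e = 0.9,
#'                r_ex = 2000, r_i = 500, q_m = 1e-8, alpha_m = 0.85)
#' @export
ec_params <- function(r_e, q_e, alpha_e, r_ex, r_i, q_m, alpha_m) {
  p <- c(r_e = r_e, q_e = q_e, alpha_e = alpha_e,
         r_ex = r_ex, r_i = r_i, q_m = q_m, alpha_m = alpha_m)
  validate_ec_params(p)
  structure(p, class = "ec_params")
}

ec_param_names <- c("r_e", "q_e", "alpha_e", "r_ex", "r_i", "q_m", "alpha_m")

validate_ec_params <- function(p) {
  if (!all(ec_param_names %in% names(p))) {
    stop_bisfruit("ec_params requires exactly the seven named parameters",
                  "bisfruit_domain_error")
  }
  if (any(!is.finite(unlist(p[ec_param_names])))) {
    stop_bisfruit("ec_params must be finite", "bisfruit_domain_error")
  }
  if (p[["r_e"]] <= 0 || p[["r_ex"]] <= 0 || p[["r_i"]] <= 0 ||
      p[["q_e"]] <= 0 || p[["q_m"]] <= 0) {
    stop_bisfruit("resistances and CPE magnitudes must be positive",
                  "bisfruit_domain_error")
  }
  if (p[["alpha_e"]] < 0 || p[["alpha_e"]] > 1 ||
      p[["alpha_m"]] < 0 || p[["alpha_m"]] > 1) {
    stop_bisfruit("ideality factors must lie in [0, 1]", "bisfruit_domain_error")
  }
  invisible(p)
}

#' @export
print.ec_params <- function(x, digits = 4, ...) {
  cat("Equivalent-circuit parameters (modified Hayden + electrode CPE):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' Canonical labelling of the two circuit dispersions
#'
#' The total impedance of the default topology can be rewritten as
#' \deqn{Z(s) = C + \frac{A_1}{1+\tau_1 s^{\alpha_1}} +
#'   \frac{A_2}{1+\tau_2 s^{\alpha_2}}, \quad s = j\omega,}
#' with \eqn{A_1 = R_e}, \eqn{\tau_1 = R_e Q_e}, \eqn{C = R_{ex} R_i /
#' (R_{ex}+R_i)}, \eqn{A_2 = R_{ex}^2/(R_{ex}+R_i)}, \eqn{\tau_2 =
#' (R_{ex}+R_i) Q_m}. Either dispersion can be realised by either block, so
#' two distinct parameter vectors produce the identical spectrum: the model
#' is identifiable only up to this swap. `canonicalize_ec` resolves the
#' ambiguity by the physical convention that electrode polarisation is the
#' slower process: the dispersion with the lower characteristic frequency
#' \eqn{\omega_c = \tau^{-1/\alpha}} is assigned to the electrode block.
#' The returned parameters generate a spectrum identical to the input's.
#'
#' @param params an [ec_params] object.
#' @return an [ec_params] object in canonical form.
#' @export
canonicalize_ec <- function(params) {
  validate_ec_params(params)
  p <- unclass(params)
  a1 <- p[["r_e"]]
  tau1 <- p[["r_e"]] * p[["q_e"]]
  al1 <- p[["alpha_e"]]
  cc <- p[["r_ex"]] * p[["r_i"]] / (p[["r_ex"]] + p[["r_i"]])
  a2 <- p[["r_ex"]]^2 / (p[["r_ex"]] + p[["r_i"]])
  tau2 <- (p[["r_ex"]] + p[["r_i"]]) * p[["q_m"]]
  al2 <- p[["alpha_m"]]
  w1 <- tau1^(-1 / max(al1, 1e-12))
  w2 <- tau2^(-1 / max(al2, 1e-12))
  if (w1 <= w2) return(params)
  swap_ec_blocks(params)
}

# exact block exchange: dispersion 2 moves to the electrode block,
# dispersion 1 (plus the high-frequency constant C) to the tissue block;
# the generated spectrum is unchanged
swap_ec_blocks <- function(params) {
  p <- unclass(params)
  a1 <- p[["r_e"]]
  tau1 <- p[["r_e"]] * p[["q_e"]]
  cc <- p[["r_ex"]] * p[["r_i"]] / (p[["r_ex"]] + p[["r_i"]])
  a2 <- p[["r_ex"]]^2 / (p[["r_ex"]] + p[["r_i"]])
  tau2 <- (p[["r_ex"]] + p[["r_i"]]) * p[["q_m"]]
  ec_params(r_e = a2, q_e = tau2 / a2, alpha_e = p[["alpha_m"]],
            r_ex = a1 + cc, r_i = (a1 + cc) * cc / a1,
            q_m = tau1 * a1 / (a1 + cc)^2, alpha_m = p[["alpha_e"]])
}

# complex parallel combination a*b/(a+b)
zpar <- function(a, b) {
  s <- a + b
  if (any(Mod(s) == 0)) {
    stop_bisfruit("degenerate parallel combination: |a + b| = 0",
                  "bisfruit_degeneracy_error")
  }
  a * b / s
}

#' Total circuit impedance
#'
#' Impedance of the full equivalent circuit at angular frequency `omega`.
#' The default topology is `"parallel_electrode"`:
#' \deqn{Z(\omega) = [R_e \parallel Z_{CPE,e}] + [R_{ex} \parallel (R_i + Z_{CPE,m})]}
#' The alternative `"series_electrode"` places the electrode contact
#' resistance in series with its CPE instead.
#'
#' @param params an [ec_params] object.
#' @param omega angular frequency rad/s (vectorised), positive.
#' @param topology electrode-block wiring.
#' @return complex vector of impedances, Ohm.
#' @export
circuit_impedance <- function(params, omega,
                              topology = c("parallel_electrode", "series_electrode")) {
  topology <- match.arg(topology)
  validate_ec_params(params)
  z_e <- cpe_impedance(params[["q_e"]], params[["alpha_e"]], omega)
  z_m <- cpe_impedance(params[["q_m"]], params[["alpha_m"]], omega)
  electrode <- switch(topology,
    parallel_electrode = zpar(params[["r_e"]] + 0i, z_e),
    series_electrode   = params[["r_e"]] + z_e)
  tissue <- zpar(params[["r_ex"]] + 0i, params[["r_i"]] + z_m)
  electrode + tissue
}

#' Polar form of a complex impedance
#'
#' @param z complex vector (or anything coercible by `as.complex`).
#' @return list with `magnitude` (Ohm) and `phase_deg` (degrees, quadrant
#'   correct, in (-180, 180]).
#' @export
to_polar <- function(z) {
  z <- as.complex(z)
  if (any(Mod(z) == 0)) {
    stop_bisfruit("phase undefined for a zero impedance", "bisfruit_domain_error")
  }
  list(magnitude = Mod(z), phase_deg = Arg(z) * 180 / pi)
}

#' Cartesian form from magnitude and phase
#'
#' Inverse of [to_polar()].
#'
#' @param magnitude impedance modulus, Ohm.
#' @param phase_deg phase angle in degrees.
#' @return complex vector.
#' @export
from_polar <- function(magnitude, phase_deg) {
  complex(modulus = magnitude, argument = phase_deg * pi / 180)
}

#' Impedance spectrum container
#'
#' A spectrum is a data frame with one row per frequency (`freq` in Hz,
#' `z_real`, `z_img` in Ohm) plus per-measurement metadata carried as
#' attributes: `sample_id`, `day`, `size`, `storage`, `diameter_mm`.
#'
#' @param freq frequency vector, Hz, strictly increasing.
#' @param z complex impedance vector, same length as `freq`.
#' @param sample_id,day,size,storage,diameter_mm optional metadata.
#' @return object of class `impedance_spectrum` (a data frame).
#' @export
impedance_spectrum <- function(freq, z, sample_id = NA_character_,
                               day = NA_integer_, size = NA_character_,
                               storage = NA_character_, diameter_mm = NA_real_) {
  stopifnot(length(freq) == length(z), all(diff(freq) > 0))
  z <- as.complex(z)
  if (any(Mod(z) <= 0)) {
    stop_bisfruit("spectrum magnitudes must be positive", "bisfruit_domain_error")
  }
  structure(
    data.frame(freq = freq, z_real = Re(z), z_img = Im(z)),
    class = c("impedance_spectrum", "data.frame"),
    sample_id = sample_id, day = day, size = size, storage = storage,
    diameter_mm = diameter_mm)
}

spectrum_z <- function(spec) complex(real = spec$z_real, imaginary = spec$z_img)

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.3g Hz to %.3g Hz\n",
              nrow(x), min(x$freq), max(x$freq)))
  meta <- attributes(x)[c("sample_id", "day", "size", "storage", "diameter_mm")]
  if (!is.na(meta$sample_id)) {
    cat(sprintf("  sample %s, day %s, %s / %s, diameter %.1f mm\n",
                meta$sample_id, meta$day, meta$size, meta$storage,
                meta$diameter_mm))
  }
  pol <- to_polar(spectrum_z(x))
  cat(sprintf("  |Z| range %.4g to %.4g Ohm, phase range %.2f to %.2f deg\n",
              min(pol$magnitude), max(pol$magnitude),
              min(pol$phase_deg), max(pol$phase_deg)))
  invisible(x)
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  pol <- to_polar(spectrum_z(x))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$freq, pol$magnitude, log = "xy", type = "b", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "|Z| (Ohm)", ...)
  graphics::plot(x$freq, pol$phase_deg, log = "x", type = "b", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "Phase (deg)", ...)
  invisible(x)
}

#' Simulate a spectrum from circuit parameters
#'
#' Evaluates [circuit_impedance()] at every grid frequency. Deterministic:
#' repeated calls with identical inputs give identical spectra.
#'
#' @param params an [ec_params] object.
#' @param freq frequency grid in Hz (default [freq_grid()]).
#' @param topology passed to [circuit_impedance()].
#' @inheritParams impedance_spectrum
#' @return an [impedance_spectrum].
#' @export
simulate_spectrum <- function(params, freq = freq_grid(),
                              topology = "parallel_electrode",
                              sample_id = NA_character_, day = NA_integer_,
                              size = NA_character_, storage = NA_character_,
                              diameter_mm = NA_real_) {
  z <- circuit_impedance(params, 2 * pi * freq, topology = topology)
  impedance_spectrum(freq, z, sample_id = sample_id, day = day, size = size,
                     storage = storage, diameter_mm = diameter_mm)
}
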