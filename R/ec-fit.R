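#' Chi-square fit-quality statistic
#'
#' Modulus-weighted, per-point-normalised chi-square between a measured and a
#' modelled spectrum:
#' \deqn{\chi^2 = \frac{1}{2N} \sum_k \left[
#'   \left(\frac{Z'_{meas,k} - Z'_{mod,k}}{|Z_{meas,k}|}\right)^2 +
#'   \left(\frac{Z''_{meas,k} - Z''_{mod,k}}{|Z_{meas,k}|}\right)^2 \right]}
#' Weighting by the measured modulus is essential because magnitudes span
#' orders of magnitude between 50 Hz and 1 MHz; the 1/(2N) normalisation
#' makes the statistic comparable across spectra of different length. Fits
#' with \eqn{\chi^2 \le 3\times10^{-4}} are conventionally regarded as
#' accurate for this class of data.
#'
#' @param measured,modeled [impedance_spectrum] objects on the same grid.
#' @return non-negative scalar.
#' @export
chi_square <- function(measured, modeled) {
  if (nrow(measured) != nrow(modeled) ||
      any(abs(measured$freq - modeled$freq) > 1e-9 * measured$freq)) {
    stop_bisfruit("measured and modeled spectra must share one grid",
                  "bisfruit_shape_error")
  }
  w <- Mod(spectrum_z(measured))
  if (any(w == 0)) {
    stop_bisfruit("zero measured magnitude: modulus weighting undefined",
                  "bisfruit_weighting_error")
  }
  n <- nrow(measured)
  sum(((measured$z_real - modeled$z_real) / w)^2 +
      ((measured$z_img - modeled$z_img) / w)^2) / (2 * n)
}

# parameter transforms: log for resistances and CPE magnitudes,
# logit for ideality factors (keeps alpha in (0,1) smoothly)
ec_to_theta <- function(p, free) {
  th <- numeric(length(free))
  for (i in seq_along(free)) {
    nm <- free[i]
    th[i] <- if (nm %in% c("alpha_e", "alpha_m")) {
      stats::qlogis(min(max(p[[nm]], 1e-8), 1 - 1e-8))
    } else {
      log(p[[nm]])
    }
  }
  names(th) <- free
  th
}

theta_to_ec <- function(th, free, fixed) {
  p <- numeric(7)
  names(p) <- ec_param_names
  for (nm in ec_param_names) {
    p[nm] <- if (nm %in% free) {
      if (nm %in% c("alpha_e", "alpha_m")) stats::plogis(th[[nm]]) else exp(th[[nm]])
    } else {
      fixed[[nm]]
    }
  }
  structure(p, class = "ec_params")
}

# data-driven initial guess from the measured spectrum
ec_heuristic_start <- function(spec) {
  pol <- to_polar(spectrum_z(spec))
  r0 <- pol$magnitude[1]                     # low-frequency plateau ~ r_e + r_ex
  rinf <- pol$magnitude[length(pol$magnitude)]  # high-frequency ~ r_ex || r_i
  r_e <- max(0.15 * r0, 1e-3)
  r_ex <- max(r0 - r_e, 2 * rinf, 1e-3)
  r_i <- if (r_ex > 1.05 * rinf) rinf * r_ex / (r_ex - rinf) else 2 * rinf
  alpha0 <- 0.8
  # membrane relaxation: frequency of the phase extremum
  k_c <- which.min(pol$phase_deg)
  w_c <- 2 * pi * spec$freq[k_c]
  q_m <- 1 / ((r_ex + r_i) * w_c^alpha0)
  # electrode CPE sized to be comparable to r_e at the lowest frequency
  w_min <- 2 * pi * spec$freq[1]
  q_e <- 1 / (3 * r_e * w_min^alpha0)
  c(r_e = r_e, q_e = q_e, alpha_e = alpha0, r_ex = r_ex, r_i = r_i,
    q_m = q_m, alpha_m = alpha0)
}

# deterministic multi-start list: the data-driven heuristic, its exact
# block-swapped mirror (the other labelling basin), then seeded log-uniform
# jitters alternating around both
ec_start_list <- function(spec, starts, seed) {
  base <- ec_heuristic_start(spec)
  mirror <- unclass(swap_ec_blocks(structure(base, class = "ec_params")))
  out <- vector("list", starts)
  out[[1]] <- base
  if (starts > 1) out[[2]] <- mirror
  if (starts > 2) {
    with_seed(derive_seed(seed, "ec_fit_starts"), {
      for (k in 3:starts) {
        p <- if (k %% 2 == 1) base else mirror
        for (nm in c("r_e", "r_ex", "r_i")) {
          p[nm] <- p[nm] * exp(stats::runif(1, -log(3), log(3)))
        }
        for (nm in c("q_e", "q_m")) {
          p[nm] <- p[nm] * exp(stats::runif(1, -log(10), log(10)))
        }
        p["alpha_e"] <- stats::runif(1, 0.6, 0.95)
        p["alpha_m"] <- stats::runif(1, 0.6, 0.95)
        out[[k]] <- p
      }
    })
  }
  out
}

#' Fit the equivalent circuit to a measured spectrum
#'
#' Estimates the seven circuit parameters by bounded complex nonlinear least
#' squares. Residuals are the real and imaginary deviations at each
#' frequency, each normalised by the measured modulus, so the minimised sum
#' of squares is \eqn{2N\chi^2} (see [chi_square()]). Resistances and CPE
#' magnitudes are optimised in log space and ideality factors in logit
#' space, which enforces positivity and the \eqn{[0,1]} bounds smoothly.
#' Because least-squares fits of this circuit can depend on the starting
#' point, a deterministic multi-start is used: a data-driven heuristic start
#' plus seeded log-uniform jitters; the start with the lowest final
#' chi-square wins (lowest index on ties).
#'
#' @param spectrum an [impedance_spectrum] to fit.
#' @param topology electrode-block wiring, see [circuit_impedance()].
#' @param starts number of multi-start initialisations.
#' @param seed integer seed for the start jitter.
#' @param fixed optional named vector of parameters to hold fixed, e.g.
#'   `c(alpha_e = 1, alpha_m = 1)` for the ideal-capacitor reduction.
#' @param start_params optional [ec_params] used as the first start.
#' @param ftol,ptol relative cost / step convergence tolerances.
#' @param maxfev maximum residual evaluations per start.
#' @param chi_sq_gate fit-quality gate reported by `summary()`.
#' @param canonical resolve the exact two-fold block-swap ambiguity of the
#'   circuit (see [canonicalize_ec()]) by returning the canonical labelling.
#'   Applied when no parameter is held fixed, or when only the two ideality
#'   factors are fixed to a common value (the swap then preserves them).
#' @return an object of class `ecfit` with components `params`,
#'   `chi_square`, `n_iterations`, `converged`, `start_index`,
#'   `start_chi_squares`, `spectrum`, `topology`.
#' @seealso [fit_ec_batch()] for many spectra.
#' @examples
#' truth <- ec_params(50, 1e-7, 0.9, 2000, 500, 1e-8, 0.85)
#' spec <- simulate_spectrum(truth)
#' fit <- fit_ec(spec, starts = 4, seed = 1)
#' coef(fit)
#' fit$chi_square
#' @export
fit_ec <- function(spectrum, topology = "parallel_electrode", starts = 8L,
                   seed = 1L, fixed = NULL, start_params = NULL,
                   ftol = 1e-10, ptol = 1e-10, maxfev = 2000L,
                   chi_sq_gate = 3e-4, canonical = TRUE) {
  stopifnot(inherits(spectrum, "impedance_spectrum"), starts >= 1L)
  fixed <- fixed %||% numeric(0)
  free <- setdiff(ec_param_names, names(fixed))
  omega <- 2 * pi * spectrum$freq
  w <- Mod(spectrum_z(spectrum))
  zr <- spectrum$z_real
  zi <- spectrum$z_img

  resid_fn <- function(th) {
    names(th) <- free
    p <- theta_to_ec(th, free, fixed)
    z <- circuit_impedance(p, omega, topology = topology)
    c((zr - Re(z)) / w, (zi - Im(z)) / w)
  }

  start_list <- ec_start_list(spectrum, starts, seed)
  if (!is.null(start_params)) start_list[[1]] <- unclass(start_params)
  n <- nrow(spectrum)
  runs <- lapply(start_list, function(p0) {
    th0 <- ec_to_theta(as.list(p0), free)
    out <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = ptol, maxfev = maxfev,
                           maxiter = 1024)),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    list(params = theta_to_ec(stats::setNames(out$par, free), free, fixed),
         chisq = out$deviance / (2 * n),
         start_chisq = sum(resid_fn(th0)^2) / (2 * n),
         niter = out$niter,
         converged = out$info %in% 1:3)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    stop_bisfruit("all multi-start fits failed", "bisfruit_fit_failure")
  }
  runs <- runs[ok]
  idx_map <- which(ok)
  chisqs <- vapply(runs, `[[`, numeric(1), "chisq")
  conv <- vapply(runs, `[[`, logical(1), "converged")
  pick <- if (any(conv)) which(conv)[which.min(chisqs[conv])] else which.min(chisqs)
  best <- runs[[pick]]
  if (!any(conv)) {
    warning("no multi-start run converged; returning best non-converged fit")
  }
  can_ok <- length(fixed) == 0 ||
    (setequal(names(fixed), c("alpha_e", "alpha_m")) &&
       fixed[["alpha_e"]] == fixed[["alpha_m"]])
  best_params <- if (canonical && can_ok && topology == "parallel_electrode") {
    canonicalize_ec(best$params)
  } else best$params
  structure(list(
    params = best_params,
    chi_square = best$chisq,
    n_iterations = best$niter,
    converged = best$converged,
    start_index = idx_map[pick],
    start_chi_squares = chisqs,
    chi_sq_gate = chi_sq_gate,
    spectrum = spectrum,
    topology = topology,
    fixed = fixed,
    call = match.call()), class = "ecfit")
}

#' @export
print.ecfit <- function(x, digits = 4, ...) {
  cat("Equivalent-circuit fit (", x$topology, ")\n", sep = "")
  print(signif(unclass(x$params), digits))
  cat(sprintf("chi-square %.3g (%s gate %.1g), start %d of %d, %s\n",
              x$chi_square,
              if (x$chi_square <= x$chi_sq_gate) "passes" else "FAILS",
              x$chi_sq_gate, x$start_index, length(x$start_chi_squares),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.ecfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ecfit")
}

#' @export
print.summary.ecfit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("iterations: %d; per-start chi-squares: %s\n",
              f$n_iterations, paste(signif(f$start_chi_squares, 3),
                                    collapse = ", ")))
  if (length(f$fixed)) {
    cat("fixed:", paste(names(f$fixed), "=", f$fixed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ecfit <- function(object, ...) unclass(object$params)

#' @rdname fit_ec
#' @param object,x an `ecfit` object.
#' @param freq frequencies (Hz) at which to evaluate the fitted circuit.
#' @param ... unused.
#' @export
predict.ecfit <- function(object, freq = NULL, ...) {
  freq <- freq %||% object$spectrum$freq
  simulate_spectrum(object$params, freq, topology = object$topology)
}

#' @export
fitted.ecfit <- function(object, ...) {
  spectrum_z(predict(object))
}

#' @export
residuals.ecfit <- function(object,
                            type = c("weighted", "complex"), ...) {
  type <- match.arg(type)
  z_meas <- spectrum_z(object$spectrum)
  z_fit <- fitted(object)
  if (type == "complex") return(z_meas - z_fit)
  w <- Mod(z_meas)
  c(Re(z_meas - z_fit) / w, Im(z_meas - z_fit) / w)
}

#' @export
plot.ecfit <- function(x, ...) {
  spec <- x$spectrum
  pol <- to_polar(spectrum_z(spec))
  dense <- 10^seq(log10(min(spec$freq)), log10(max(spec$freq)), length.out = 200)
  fitc <- to_polar(spectrum_z(predict(x, freq = dense)))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(spec$freq, pol$magnitude, log = "xy", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "|Z| (Ohm)", ...)
  graphics::lines(dense, fitc$magnitude)
  graphics::plot(spec$freq, pol$phase_deg, log = "x", pch = 16,
                 xlab = "Frequency (Hz)", ylab = "Phase (deg)", ...)
  graphics::lines(dense, fitc$phase_deg)
  invisible(x)
}

#' Fit the equivalent circuit to a batch of spectra
#'
#' Applies [fit_ec()] to each spectrum in order. Individual failures are
#' recorded and do not abort the batch.
#'
#' @param spectra a nonempty list of [impedance_spectrum] objects, or a
#'   measurements table from [measure_cohort()].
#' @param ... passed to [fit_ec()].
#' @return an `ecfit_batch`: a list of `ecfit` objects (or `NULL` for
#'   failures) with an `as.data.frame` method giving one row per spectrum
#'   (`sample_id, day, r_e, q_e, alpha_e, r_ex, r_i, q_m, alpha_m,
#'   chi_square, converged`).
#' @export
fit_ec_batch <- function(spectra, ...) {
  if (inherits(spectra, "bis_measurements")) {
    spectra <- measurements_to_spectra(spectra)
  }
  if (length(spectra) == 0) {
    stop_bisfruit("empty batch of spectra", "bisfruit_domain_error")
  }
  fits <- lapply(spectra, function(s) {
    tryCatch(fit_ec(s, ...), error = function(e) NULL)
  })
  meta <- lapply(spectra, function(s) {
    a <- attributes(s)
    list(sample_id = a$sample_id, day = a$day)
  })
  structure(list(fits = fits, meta = meta), class = "ecfit_batch")
}

#' @export
as.data.frame.ecfit_batch <- function(x, ...) {
  rows <- mapply(function(f, m) {
    if (is.null(f)) {
      p <- rep(NA_real_, 7)
      names(p) <- ec_param_names
      data.frame(sample_id = m$sample_id, day = m$day, t(p),
                 chi_square = NA_real_, converged = FALSE)
    } else {
      data.frame(sample_id = m$sample_id, day = m$day, t(unclass(f$params)),
                 chi_square = f$chi_square, converged = f$converged)
    }
  }, x$fits, x$meta, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ecfit_batch <- function(x, ...) {
  df <- as.data.frame(x)
  gate <- if (length(x$fits) && !is.null(x$fits[[which(!vapply(x$fits, is.null, logical(1)))[1]]])) {
    x$fits[[which(!vapply(x$fits, is.null, logical(1)))[1]]]$chi_sq_gate
  } else 3e-4
  n_fail <- sum(is.na(df$chi_square))
  cat(sprintf("Equivalent-circuit batch: %d spectra, %d failed\n",
              nrow(df), n_fail))
  ok <- df$chi_square[!is.na(df$chi_square)]
  cat(sprintf("chi-square median %.3g; %.1f%% within gate %.1g\n",
              stats::median(ok), 100 * mean(ok <= gate), gate))
  invisible(x)
}
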