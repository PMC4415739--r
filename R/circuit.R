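# Lumped-element (equivalent-circuit) bioimpedance model: electrode
# resistance R_e in series with [solution branch R_s parallel to double-layer
# capacitance C_d parallel to cell branch (R_c in series with C_c)], and
# deterministic least-squares fitting of spectra to it.

#' Construct a five-element equivalent-circuit model
#'
#' @param R_e Electrode resistance (ohm).
#' @param R_s Solution resistance (ohm).
#' @param C_d Double-layer capacitance (F).
#' @param R_c Cytoplasm resistance (ohm).
#' @param C_c Membrane capacitance (F).
#' @return A `circuit_model` object. All elements must be > 0.
#' @export
circuit_model <- function(R_e, R_s, C_d, R_c, C_c) {
  v <- c(R_e = R_e, R_s = R_s, C_d = C_d, R_c = R_c, C_c = C_c)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all circuit elements must be finite and > 0")
  structure(as.list(v), class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf(
    "circuit_model: R_e=%.4g, R_s=%.4g ohm; C_d=%.4g F; R_c=%.4g ohm; C_c=%.4g F\n",
    x$R_e, x$R_s, x$C_d, x$R_c, x$C_c))
  invisible(x)
}

#' Complex impedance of the equivalent circuit
#'
#' Z(f) = R_e + 1 / (1/R_s + j*w*C_d + 1/(R_c + 1/(j*w*C_c))), w = 2*pi*f.
#' At f = 0 the capacitors are open and Z = R_e + R_s.
#'
#' @param m A `circuit_model`.
#' @param f Frequency in Hz (vectorised, >= 0).
#' @return Complex impedance (ohm), one value per frequency.
#' @export
circuit_impedance <- function(m, f) {
  stopifnot(inherits(m, "circuit_model"), all(f >= 0))
  w <- 2 * pi * f
  Z <- complex(real = rep(NA_real_, length(f)))
  dc <- w == 0
  Z[dc] <- m$R_e + m$R_s
  if (any(!dc)) {
    wa <- w[!dc]
    Zc <- m$R_c + 1 / (1i * wa * m$C_c)           # cell branch
    Y <- 1 / m$R_s + 1i * wa * m$C_d + 1 / Zc     # parallel network
    Z[!dc] <- m$R_e + 1 / Y
  }
  Z
}

#' Magnitude and phase of a complex impedance
#'
#' Magnitude is sqrt(Re(Z)^2 + Im(Z)^2); phase uses the quadrant-aware
#' arctangent (atan2) in degrees, since a literal tan^-1(Im/Re) loses the
#' quadrant (e.g. Z = -1 + 0i is 180 deg, not 0).
#'
#' @param Z Complex vector.
#' @return A data.frame with `magnitude` (ohm) and `phase_deg`. Phase of
#'   Z = 0 is `NA` (flagged with a warning).
#' @export
magnitude_phase <- function(Z) {
  mag <- Mod(Z)
  ph <- atan2(Im(Z), Re(Z)) * 180 / pi
  if (any(mag == 0)) {
    warning("zero impedance: phase undefined")
    ph[mag == 0] <- NA_real_
  }
  data.frame(magnitude = mag, phase_deg = ph)
}

#' Assemble an impedance spectrum container
#'
#' @param shape Electrode-shape tag (or other label).
#' @param V Operating voltage.
#' @param f Frequencies in Hz, strictly increasing.
#' @param Z Complex impedances, same length as `f`.
#' @return An `impedance_spectrum` data.frame with columns `f_hz`, `Z_real`,
#'   `Z_imag`, `magnitude`, `phase_deg`.
#' @export
impedance_spectrum <- function(shape, V, f, Z) {
  stopifnot(length(f) == length(Z))
  if (is.unsorted(f, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  mp <- magnitude_phase(Z)
  structure(data.frame(f_hz = f, Z_real = Re(Z), Z_imag = Im(Z),
                       magnitude = mp$magnitude, phase_deg = mp$phase_deg),
            shape = shape, V = V,
            class = c("impedance_spectrum", "data.frame"))
}

#' Fit the equivalent circuit to an impedance spectrum
#'
#' Deterministic Levenberg-Marquardt least squares on the joint residual of
#' log-magnitude and phase (radians), with a fixed coarse grid of
#' initialisations (no randomness). Elements can be pinned via `fixed`.
#'
#' @param spectrum An `impedance_spectrum` (>= 5 entries).
#' @param fixed Optional named list of elements to hold fixed, e.g.
#'   `list(C_d = 1e-11)`.
#' @return A list with `model` (the fitted `circuit_model`), `residual`
#'   (root-mean-square residual) and `converged`.
#' @export
fit_circuit <- function(spectrum, fixed = list()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  if (nrow(spectrum) < 5L)
    stop("need at least 5 spectrum entries to fit 5 circuit elements")
  f <- spectrum$f_hz
  Z <- complex(real = spectrum$Z_real, imaginary = spectrum$Z_imag)
  obs <- c(log(Mod(Z)), atan2(Im(Z), Re(Z)))
  par_names <- c("R_e", "R_s", "C_d", "R_c", "C_c")
  free_names <- setdiff(par_names, names(fixed))
  resid_fn <- function(logp) {
    p <- as.list(exp(logp))
    names(p) <- free_names
    p <- utils::modifyList(p, fixed)
    m <- circuit_model(p$R_e, p$R_s, p$C_d, p$R_c, p$C_c)
    Zm <- circuit_impedance(m, f)
    c(log(Mod(Zm)), atan2(Im(Zm), Re(Zm))) - obs
  }
  # data-driven anchors: |Z| at the frequency extremes bound R_e and R_e+R_s
  mag_lo <- spectrum$magnitude[1L]
  mag_hi <- spectrum$magnitude[nrow(spectrum)]
  w_mid <- 2 * pi * stats::median(f)
  starts <- expand.grid(
    R_e = mag_hi * c(0.5, 0.05),
    R_s = mag_lo * c(1, 0.3),
    C_d = 1 / (w_mid * mag_lo) * c(1, 10),
    R_c = mag_lo * c(0.1, 0.01),
    C_c = 1 / (w_mid * mag_lo) * c(1, 100))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- log(unlist(starts[s, free_names, drop = FALSE]))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, par = ans$par, info = ans$info)
  }
  if (is.null(best)) stop("circuit fit failed from every initialisation")
  p <- as.list(exp(best$par)); names(p) <- free_names
  p <- utils::modifyList(p, fixed)
  model <- circuit_model(p$R_e, p$R_s, p$C_d, p$R_c, p$C_c)
  converged <- best$rss < 1e-12 || best$info %in% 1:3
  if (!converged)
    warning("circuit fit did not fully converge; best RMS residual ",
            signif(sqrt(best$rss / length(obs)), 3))
  list(model = model, residual = sqrt(best$rss / length(obs)),
       converged = converged)
}

#' Impedance-contrast sensitivity of a detection volume
#'
#' Sensitivity = (|Z_solution| - |Z_cell|) / |Z_solution|: the relative drop
#' in impedance magnitude caused by the cell's presence. 0 when the cell has
#' no contrast, 1 when the cell short-circuits the device.
#'
#' @param Z_solution_mag Impedance magnitude without the cell (ohm, > 0).
#' @param Z_cell_mag Impedance magnitude with the cell (ohm).
#' @param f,V Optional operating-point metadata.
#' @return A `sensitivity_result` list.
#' @export
sensitivity <- function(Z_solution_mag, Z_cell_mag, f = NA_real_,
                        V = NA_real_) {
  stopifnot(is.numeric(Z_solution_mag), is.numeric(Z_cell_mag))
  if (Z_solution_mag <= 0) stop("Z_solution_mag must be > 0")
  structure(list(f = f, V = V,
                 Z_solution_mag = Z_solution_mag,
                 Z_cell_mag = Z_cell_mag,
                 sensitivity = (Z_solution_mag - Z_cell_mag) / Z_solution_mag),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "sensitivity: %.4f  (|Z| %0.4g -> %0.4g ohm at f = %s Hz, V = %s V)\n",
    x$sensitivity, x$Z_solution_mag, x$Z_cell_mag, format(x$f), format(x$V)))
  invisible(x)
}
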