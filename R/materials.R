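# Material model: PBS constants, tabulated cell dielectric properties on a
# (frequency, voltage) grid, interpolation, and conversion to complex admittivity.

#' Vacuum permittivity (F/m)
#' @export
EPS0 <- 8.8541878128e-12

#' Medium properties (conductivity and relative permittivity)
#'
#' @param sigma Conductivity in S/m, must be >= 0.
#' @param eps_r Relative permittivity (dimensionless), must be >= 1.
#' @return An object of class `medium_properties`.
#' @export
medium_properties <- function(sigma, eps_r) {
  stopifnot(is.numeric(sigma), is.numeric(eps_r), length(sigma) == 1L,
            length(eps_r) == 1L)
  if (sigma < 0) stop("sigma must be >= 0 (got ", sigma, ")")
  if (eps_r < 1) stop("eps_r must be >= 1 (got ", eps_r, ")")
  structure(list(sigma = sigma, eps_r = eps_r), class = "medium_properties")
}

#' Phosphate-buffered saline properties used throughout the study
#'
#' The suspension medium between the electrodes. The defaults are the study
#' values (sigma = 2e-6 S/m, eps_r = 136); both are exposed so users can
#' substitute, e.g., physiological saline conductivity.
#'
#' @param sigma PBS conductivity in S/m.
#' @param eps_r PBS relative permittivity.
#' @return A `medium_properties` object.
#' @export
pbs_properties <- function(sigma = 2e-6, eps_r = 136) {
  medium_properties(sigma, eps_r)
}

#' @export
print.medium_properties <- function(x, ...) {
  cat(sprintf("medium: sigma = %g S/m, eps_r = %g\n", x$sigma, x$eps_r))
  invisible(x)
}

new_cell_dielectric_table <- function(freqs, volts, sigma_grid, eps_grid) {
  structure(list(freqs = freqs, volts = volts,
                 sigma_grid = sigma_grid, eps_grid = eps_grid),
            class = "cell_dielectric_table")
}

#' Load a cell dielectric table (conductivity + permittivity CSV pair)
#'
#' Reads the tabulated single-cell conductivity sigma(f, V) and relative
#' permittivity eps_r(f, V). Each CSV has a first column of frequencies in kHz
#' and a header row of operating voltages in V; conductivities are in S/m and
#' permittivities dimensionless. Scientific notation in either `1.06e-02` or
#' `1.06E-02` form is accepted.
#'
#' @param sigma_path Path to the conductivity CSV.
#' @param eps_path Path to the relative-permittivity CSV.
#' @return A validated `cell_dielectric_table` with fields `freqs` (Hz,
#'   ascending), `volts` (V, ascending), `sigma_grid` and `eps_grid`
#'   (matrices indexed `[frequency, voltage]`).
#' @export
load_cell_table <- function(sigma_path, eps_path) {
  sig <- read_material_csv(sigma_path, "conductivity")
  eps <- read_material_csv(eps_path, "permittivity")
  if (!isTRUE(all.equal(sig$freqs, eps$freqs)) ||
      !isTRUE(all.equal(sig$volts, eps$volts)))
    stop("conductivity and permittivity files tabulate different (f, V) grids")
  tab <- new_cell_dielectric_table(sig$freqs, sig$volts, sig$grid, eps$grid)
  validate_cell_table(tab)
  tab
}

read_material_csv <- function(path, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(what, " file ", path, " has no data rows")
  split_row <- function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1L]])
  header <- split_row(lines[1L])
  volts <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(volts))
    stop(what, " header: non-numeric voltage in column ",
         which(is.na(volts))[1L] + 1L)
  ncol_expect <- length(header)
  rows <- lapply(lines[-1L], split_row)
  nf <- length(rows)
  freqs <- numeric(nf)
  grid <- matrix(NA_real_, nf, length(volts))
  for (i in seq_len(nf)) {
    r <- rows[[i]]
    if (length(r) != ncol_expect)
      stop(what, " row ", i + 1L, ": expected ", ncol_expect,
           " fields, found ", length(r), " (missing or extra cell)")
    vals <- suppressWarnings(as.numeric(r))
    if (anyNA(vals))
      stop(what, " row ", i + 1L, ": non-numeric entry in column ",
           which(is.na(vals))[1L])
    freqs[i] <- vals[1L]
    grid[i, ] <- vals[-1L]
  }
  if (is.unsorted(freqs, strictly = TRUE))
    stop(what, ": frequency axis must be strictly increasing")
  if (is.unsorted(volts, strictly = TRUE))
    stop(what, ": voltage axis must be strictly increasing")
  list(freqs = freqs * 1e3, volts = volts, grid = grid)  # kHz -> Hz
}

validate_cell_table <- function(tab) {
  if (anyNA(tab$sigma_grid) || anyNA(tab$eps_grid))
    stop("incomplete grid: missing cells")
  if (any(tab$sigma_grid <= 0)) stop("all conductivities must be > 0")
  if (any(tab$eps_grid < 1)) stop("all relative permittivities must be >= 1")
  invisible(tab)
}

#' Audit the empirical monotonicity of a cell dielectric table
#'
#' The study's tabulated cell conductivity is non-decreasing in voltage at
#' every frequency and non-decreasing in frequency at every voltage. User
#' tables violating this are reported (not silently fixed).
#'
#' @param table A `cell_dielectric_table`.
#' @return A data.frame of violations (zero rows when the table is monotone),
#'   with columns `axis`, `frequency_hz`, `voltage`.
#' @export
audit_monotonicity <- function(table) {
  stopifnot(inherits(table, "cell_dielectric_table"))
  out <- list()
  g <- table$sigma_grid
  for (i in seq_along(table$freqs)) {
    bad <- which(diff(g[i, ]) < 0)
    for (j in bad)
      out[[length(out) + 1L]] <- data.frame(
        axis = "voltage", frequency_hz = table$freqs[i],
        voltage = table$volts[j + 1L])
  }
  for (j in seq_along(table$volts)) {
    bad <- which(diff(g[, j]) < 0)
    for (i in bad)
      out[[length(out) + 1L]] <- data.frame(
        axis = "frequency", frequency_hz = table$freqs[i + 1L],
        voltage = table$volts[j])
  }
  if (!length(out))
    return(data.frame(axis = character(), frequency_hz = numeric(),
                      voltage = numeric()))
  do.call(rbind, out)
}

#' Write a cell dielectric table back to the CSV pair
#'
#' Inverse of [load_cell_table()]; a reload reproduces every grid value
#' bit-exactly (values are serialised with full double precision).
#'
#' @param table A `cell_dielectric_table`.
#' @param sigma_path,eps_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cell_table <- function(table, sigma_path, eps_path) {
  stopifnot(inherits(table, "cell_dielectric_table"))
  wr <- function(grid, path) {
    header <- paste(c("frequency_khz",
                      formatC(table$volts, format = "g", digits = 17)),
                    collapse = ",")
    rows <- vapply(seq_along(table$freqs), function(i) {
      paste(c(formatC(table$freqs[i] / 1e3, format = "g", digits = 17),
              formatC(grid[i, ], format = "g", digits = 17)),
            collapse = ",")
    }, character(1))
    writeLines(c(header, rows), path)
  }
  wr(table$sigma_grid, sigma_path)
  wr(table$eps_grid, eps_path)
  invisible(c(sigma_path, eps_path))
}

#' The packaged single-cell dielectric table
#'
#' Tabulated HeLa-cell conductivity and relative permittivity over
#' 5-100 kHz and 0.1-1.0 V, shipped with the package.
#'
#' @return A `cell_dielectric_table`.
#' @export
hela_cell_table <- function() {
  load_cell_table(
    system.file("extdata", "hela_conductivity.csv", package = "bioimpedfem",
                mustWork = TRUE),
    system.file("extdata", "hela_permittivity.csv", package = "bioimpedfem",
                mustWork = TRUE))
}

#' Look up cell properties at an operating point
#'
#' Exact table value at grid nodes; bilinear interpolation (linear in both f
#' and V) between nodes. Below the tabulated frequency range the double layer
#' at the electrode-electrolyte interface makes the tabulated properties
#' unreliable, so the default policy refuses out-of-range queries; an explicit
#' policy permits clamping to the nearest edge, or log-linear extrapolation in
#' frequency.
#'
#' @param table A `cell_dielectric_table`.
#' @param f Frequency in Hz.
#' @param V Operating voltage in V.
#' @param policy One of `"strict"` (error outside the grid), `"clamp"`
#'   (clamp to the nearest edge), `"extrapolate_f"` (log-linear extrapolation
#'   along frequency; voltage still strict).
#' @return A `medium_properties` object.
#' @export
cell_properties <- function(table, f, V, policy = c("strict", "clamp",
                                                    "extrapolate_f")) {
  stopifnot(inherits(table, "cell_dielectric_table"),
            is.numeric(f), length(f) == 1L, is.numeric(V), length(V) == 1L)
  policy <- match.arg(policy)
  fr <- range(table$freqs); vr <- range(table$volts)
  f_in <- f >= fr[1L] && f <= fr[2L]
  v_in <- V >= vr[1L] && V <= vr[2L]
  if (policy == "strict" && (!f_in || !v_in))
    stop(sprintf(paste0("operating point (f = %g Hz, V = %g V) outside the ",
                        "tabulated range [%g, %g] Hz x [%g, %g] V; ",
                        "choose policy = 'clamp' or 'extrapolate_f'"),
                 f, V, fr[1L], fr[2L], vr[1L], vr[2L]))
  if (policy == "clamp") {
    f <- min(max(f, fr[1L]), fr[2L])
    V <- min(max(V, vr[1L]), vr[2L])
  }
  if (policy == "extrapolate_f") {
    if (!v_in) stop("voltage ", V, " outside tabulated range [",
                    vr[1L], ", ", vr[2L], "]")
    if (!f_in) {
      # log-linear in f from the two nearest tabulated frequencies
      sig <- loglin_extrap_f(table$freqs, table, V, f, "sigma_grid")
      eps <- loglin_extrap_f(table$freqs, table, V, f, "eps_grid")
      return(medium_properties(sig, max(eps, 1)))
    }
  }
  medium_properties(bilinear(table$freqs, table$volts, table$sigma_grid, f, V),
                    bilinear(table$freqs, table$volts, table$eps_grid, f, V))
}

bilinear <- function(xs, ys, grid, x, y) {
  i <- findInterval(x, xs, all.inside = TRUE)
  j <- findInterval(y, ys, all.inside = TRUE)
  x1 <- xs[i]; x2 <- xs[i + 1L]; y1 <- ys[j]; y2 <- ys[j + 1L]
  tx <- if (x2 > x1) (x - x1) / (x2 - x1) else 0
  ty <- if (y2 > y1) (y - y1) / (y2 - y1) else 0
  (1 - tx) * (1 - ty) * grid[i, j]       + tx * (1 - ty) * grid[i + 1L, j] +
  (1 - tx) * ty       * grid[i, j + 1L]  + tx * ty       * grid[i + 1L, j + 1L]
}

loglin_extrap_f <- function(freqs, table, V, f, which_grid) {
  n <- length(freqs)
  idx <- if (f < freqs[1L]) c(1L, 2L) else c(n - 1L, n)
  v1 <- bilinear(freqs, table$volts, table[[which_grid]], freqs[idx[1L]], V)
  v2 <- bilinear(freqs, table$volts, table[[which_grid]], freqs[idx[2L]], V)
  lf <- log(c(freqs[idx[1L]], freqs[idx[2L]]))
  slope <- (log(v2) - log(v1)) / (lf[2L] - lf[1L])
  exp(log(v1) + slope * (log(f) - lf[1L]))
}

#' Complex admittivity of a medium at a frequency
#'
#' kappa = sigma + i * 2*pi*f * eps0 * eps_r, the single material coefficient
#' of the electro-quasistatic equation combining conduction and displacement
#' current.
#'
#' @param props A `medium_properties` object.
#' @param f Frequency in Hz (>= 0).
#' @return A length-1 complex vector in S/m.
#' @export
complex_admittivity <- function(props, f) {
  stopifnot(inherits(props, "medium_properties"), is.numeric(f),
            length(f) == 1L)
  if (f < 0) stop("frequency must be >= 0 (got ", f, ")")
  complex(real = props$sigma, imaginary = 2 * pi * f * EPS0 * props$eps_r)
}
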