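# Study orchestration: sweep the (shape, frequency, voltage) grid with and
# without the cell, collect spectra, field statistics and sensitivities; plus
# analytic and synthetic fixtures so every stage is testable without the
# packaged material tables.

#' Build a sweep configuration
#'
#' Defaults reproduce the study grid: all four shapes, the tabulated
#' frequencies 5-100 kHz, voltages 0.1-1.0 V in 0.1 V steps.
#'
#' @param shapes Subset of `c("cross","circle","parallel","standard")`.
#' @param frequencies Frequencies in Hz.
#' @param voltages Operating voltages in V.
#' @param resolution Mesh edge length in metres.
#' @param cell_table A `cell_dielectric_table` (default: the packaged one).
#' @param pbs PBS `medium_properties`.
#' @param depth Out-of-plane depth in metres used to convert per-unit-depth
#'   impedance to ohms.
#' @param policy Interpolation policy passed to [cell_properties()].
#' @param field_stats Logical: also compute [field_extrema()] per grid point.
#' @param field_window Window (m) passed to [field_extrema()]. The default is
#'   wider than `field_extrema()`'s own because the default layouts press the
#'   electrode faces into the cell footprint: the band must reach past the
#'   metal for the extracellular annulus to contain any medium elements.
#' @param layout_overrides Named list of per-shape override lists.
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(shapes = c("cross", "circle", "parallel", "standard"),
                         frequencies = c(5, 10, 20, 30, 40, 50, 60, 70, 80,
                                         90, 100) * 1e3,
                         voltages = seq(0.1, 1.0, by = 0.1),
                         resolution = 1e-6,
                         cell_table = NULL,
                         pbs = pbs_properties(),
                         depth = 1,
                         policy = "strict",
                         field_stats = FALSE,
                         field_window = 8e-6,
                         layout_overrides = list()) {
  if (!length(shapes)) stop("config must name at least one electrode shape")
  shapes <- vapply(shapes, match.arg,
                   choices = c("cross", "circle", "parallel", "standard"),
                   FUN.VALUE = character(1))
  if (!length(frequencies) || !length(voltages))
    stop("frequency and voltage lists must be non-empty")
  if (is.unsorted(frequencies, strictly = TRUE) ||
      is.unsorted(voltages, strictly = TRUE))
    stop("frequencies and voltages must be strictly increasing")
  if (is.null(cell_table)) cell_table <- hela_cell_table()
  if (policy == "strict") {
    fr <- range(cell_table$freqs); vr <- range(cell_table$volts)
    if (min(frequencies) < fr[1] || max(frequencies) > fr[2] ||
        min(voltages) < vr[1] || max(voltages) > vr[2])
      stop("sweep extends beyond the material table; choose a non-strict policy")
  }
  structure(list(shapes = unname(shapes), frequencies = frequencies,
                 voltages = voltages, resolution = resolution,
                 cell_table = cell_table, pbs = pbs, depth = depth,
                 policy = policy, field_stats = field_stats,
                 field_window = field_window,
                 layout_overrides = layout_overrides),
            class = "sweep_config")
}

#' Run the full simulation study over a sweep configuration
#'
#' For every (shape, f, V) grid point: build the layout, look up the cell
#' dielectric properties, mesh, solve the quasistatic field with the cell and
#' (once per shape, reusing homogeneity) without it, extract the terminal
#' impedance, and form the with/without-cell sensitivity. Deterministic given
#' the configuration; a failing grid point is recorded in `$errors` and
#' marked missing rather than aborting the study.
#'
#' @param cfg A `sweep_config`.
#' @param verbose Print one line per shape.
#' @return A `study_report` list with data.frames `spectra` (with-cell),
#'   `solution_spectra` (without-cell), `sensitivity`, optionally `extrema`,
#'   plus `errors` and a `provenance` block.
#' @export
run_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  spectra <- list(); solspec <- list(); sens <- list(); extrema <- list()
  errors <- list()
  for (shape in cfg$shapes) {
    ov <- cfg$layout_overrides[[shape]]
    if (is.null(ov)) ov <- list()
    layout <- build_layout(shape, ov)
    mesh <- generate_mesh(layout, cfg$resolution)
    if (verbose)
      message("shape ", shape, ": ", nrow(mesh$nodes), " nodes")
    # Without the cell the medium is homogeneous, so the potential is
    # independent of kappa and the terminal current scales linearly with it:
    # one unit-admittivity solve per shape yields Z_solution at every f.
    sol_unit <- solve_field(mesh, list(PBS = 1 + 0i, CELL = 1 + 0i), V = 1)
    I_unit <- boundary_current(sol_unit, "A")
    for (f in cfg$frequencies) {
      kp <- complex_admittivity(cfg$pbs, f)
      Z_sol <- 1 / (kp * I_unit * cfg$depth)
      solspec[[length(solspec) + 1L]] <- data.frame(
        shape = shape, f_hz = f, Z_real = Re(Z_sol), Z_imag = Im(Z_sol),
        magnitude = Mod(Z_sol))
      for (V in cfg$voltages) {
        rec <- tryCatch({
          props <- cell_properties(cfg$cell_table, f, V, cfg$policy)
          kc <- complex_admittivity(props, f)
          lay_v <- layout; lay_v$drive_voltage <- V
          sol <- solve_field(mesh, list(PBS = kp, CELL = kc), V = V, f = f)
          sol$layout <- lay_v
          Z <- fem_impedance(sol, cfg$depth)
          mp <- magnitude_phase(Z)
          if (cfg$field_stats)
            extrema[[length(extrema) + 1L]] <- local({
              fx <- field_extrema(sol, window = cfg$field_window)
              data.frame(shape = shape, f_hz = f, V = V,
                         intra_min = fx$intracellular$min,
                         intra_max = fx$intracellular$max,
                         intra_mean = fx$intracellular$mean,
                         extra_min = fx$extracellular$min,
                         extra_max = fx$extracellular$max,
                         extra_mean = fx$extracellular$mean)
            })
          list(
            spec = data.frame(shape = shape, V = V, f_hz = f,
                              Z_real = Re(Z), Z_imag = Im(Z),
                              magnitude = mp$magnitude,
                              phase_deg = mp$phase_deg),
            sens = data.frame(shape = shape, f_hz = f, V = V,
                              Z_solution_mag = Mod(Z_sol),
                              Z_cell_mag = mp$magnitude,
                              sensitivity = (Mod(Z_sol) - mp$magnitude) /
                                Mod(Z_sol)))
        }, error = function(e) {
          errors[[length(errors) + 1L]] <<- data.frame(
            shape = shape, f_hz = f, V = V, error = conditionMessage(e))
          NULL
        })
        if (!is.null(rec)) {
          spectra[[length(spectra) + 1L]] <- rec$spec
          sens[[length(sens) + 1L]] <- rec$sens
        }
      }
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(
    spectra = bind(spectra),
    solution_spectra = bind(solspec),
    sensitivity = bind(sens),
    extrema = bind(extrema),
    errors = bind(errors),
    provenance = list(
      shapes = cfg$shapes, frequencies = cfg$frequencies,
      voltages = cfg$voltages, resolution = cfg$resolution,
      depth = cfg$depth, policy = cfg$policy,
      package_version = as.character(utils::packageVersion("bioimpedfem")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d with-cell records, %d without-cell, %d errors\n",
              if (is.null(x$spectra)) 0L else nrow(x$spectra),
              if (is.null(x$solution_spectra)) 0L else nrow(x$solution_spectra),
              if (is.null(x$errors)) 0L else nrow(x$errors)))
  invisible(x)
}

#' Generate a verification or synthetic-data fixture
#'
#' * `plate`: homogeneous slab device (electrodes = top/bottom walls) with
#'   the closed-form impedance Z = h / (kappa * w * depth) in the metadata.
#' * `annulus`: concentric-electrode device with closed-form potential
#'   phi(r) = V ln(b/r)/ln(b/a) and current I = 2 pi kappa V / ln(b/a).
#' * `homogeneous_cell`: a layout whose cell admittivity equals the PBS one
#'   (null contrast; sensitivity should vanish).
#' * `synthetic_tables`: (f, V) material grids from the parametric law
#'   sigma(f, V) = sigma0 * (f/f0)^a * exp(b*V), eps_r constant, written in
#'   the packaged CSV dialect.
#'
#' @param kind One of `"plate"`, `"annulus"`, `"homogeneous_cell"`,
#'   `"synthetic_tables"`.
#' @param params Named list of parameters (see details above; all optional).
#' @param dir Directory for fixtures that write files (`synthetic_tables`).
#' @return A list describing the fixture, including closed-form references
#'   where they exist.
#' @export
make_fixture <- function(kind = c("plate", "annulus", "homogeneous_cell",
                                  "synthetic_tables"),
                         params = list(), dir = tempdir()) {
  kind <- match.arg(kind)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]]
                               else default
  switch(kind,
    plate = {
      kappa <- p("kappa", 2e-6 + 0i)
      depth <- p("depth", 1)
      layout <- build_layout("plate", list(
        width = p("width", 100e-6), height = p("height", 100e-6)))
      list(kind = kind, layout = layout, kappa = kappa, depth = depth,
           Z_ref = layout$height / (kappa * layout$width * depth),
           E_ref = layout$drive_voltage / layout$height)
    },
    annulus = {
      a <- p("a", 5e-6); b <- p("b", 40e-6)
      kappa <- p("kappa", 1 + 0i); V <- p("V", 1)
      list(kind = kind, a = a, b = b, kappa = kappa, V = V,
           phi_ref = function(r) V * log(b / r) / log(b / a),
           I_ref = 2 * pi * kappa * V / log(b / a))
    },
    homogeneous_cell = {
      shape <- p("shape", "standard")
      layout <- build_layout(shape, p("overrides", list()))
      pbs <- p("pbs", pbs_properties())
      list(kind = kind, layout = layout, pbs = pbs,
           materials = function(f) {
             k <- complex_admittivity(pbs, f)
             list(PBS = k, CELL = k)
           })
    },
    synthetic_tables = {
      sigma0 <- p("sigma0", 1e-4); f0 <- p("f0", 5e3)
      a <- p("a", 1); b <- p("b", 2); eps0_r <- p("eps_r", 5e3)
      freqs <- p("frequencies", c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90,
                                  100) * 1e3)
      volts <- p("voltages", seq(0.1, 1.0, by = 0.1))
      sig <- outer(freqs, volts, function(f, V) sigma0 * (f / f0)^a * exp(b * V))
      eps <- matrix(eps0_r, length(freqs), length(volts))
      tab <- new_cell_dielectric_table(freqs, volts, sig, eps)
      validate_cell_table(tab)
      sp <- file.path(dir, "synthetic_conductivity.csv")
      ep <- file.path(dir, "synthetic_permittivity.csv")
      write_cell_table(tab, sp, ep)
      list(kind = kind, table = tab, sigma_path = sp, eps_path = ep,
           law = function(f, V) sigma0 * (f / f0)^a * exp(b * V))
    })
}
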