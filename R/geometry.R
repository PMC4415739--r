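# Parametric 2D device layouts: chamber, electrode pair (four shapes plus a
# homogeneous plate test device), trapped cell. All lengths SI metres, origin
# at the chamber centre, x rightward, y upward.

SHAPE_TAGS <- c("cross", "circle", "parallel", "standard", "plate")

default_shape_params <- function(shape) {
  switch(shape,
    # two bars facing each other across the cell along y; bar length matches
    # the cell diameter so the cell dominates the sensed volume
    parallel = list(bar_length = 20e-6, bar_thickness = 10e-6),
    # finger approaching the cell tip-on along x; the tip conforms to the
    # trapped cell (front face overlaps the cell footprint by `bite`)
    standard = list(tip_width = 10e-6, bite = 0.5e-6),
    # standard finger whose tip carries a perpendicular crossbar
    cross    = list(tip_width = 10e-6, bite = 0.5e-6,
                    arm_width = 4e-6, arm_length = 20e-6),
    # tip ends in a circular-arc face concave toward (and conforming to) the
    # cell; the arc is concentric with the cell
    circle   = list(arc_radius = 7e-6),
    plate    = list(),
    stop("unknown electrode shape: ", shape)
  )
}

default_gap <- function(shape, cell_radius, params) {
  switch(shape,
    parallel = 8e-6,
    circle   = 8e-6,
    # tip-to-tip shapes: tip separation set by the trapped cell footprint
    standard = 2 * (cell_radius - params$bite),
    cross    = 2 * (cell_radius - params$bite),
    plate    = NA_real_
  )
}

#' Build a parametric device layout
#'
#' Constructs one of the four electrode geometries (`cross`, `circle`,
#' `parallel`, `standard`) or the homogeneous `plate` validation device
#' (electrodes on the top and bottom chamber walls, no interior metal) in a
#' 100 x 100 um chamber with a 20-um-diameter cell at the origin.
#'
#' Electrode A is driven at `+drive_voltage`, electrode B is grounded. The
#' drive axis is x for `cross`/`circle`/`standard` and y for
#' `parallel`/`plate`. Where electrode metal and the cell footprint overlap,
#' the metal wins (the electrode displaces everything).
#'
#' @param shape One of `"cross"`, `"circle"`, `"parallel"`, `"standard"`,
#'   `"plate"`.
#' @param overrides Named list overriding any of: `width`, `height`, `gap`,
#'   `cell_radius`, `cell_center` (length-2), `drive_voltage`, or shape
#'   parameters (`bar_length`, `bar_thickness`, `tip_width`, `bite`,
#'   `arm_width`, `arm_length`, `arc_radius`).
#' @return A `device_layout` object.
#' @export
build_layout <- function(shape, overrides = list()) {
  shape <- match.arg(shape, SHAPE_TAGS)
  stopifnot(is.list(overrides))
  params <- default_shape_params(shape)
  lay <- list(width = 100e-6, height = 100e-6, shape = shape,
              cell_radius = if (shape == "plate") 0 else 10e-6,
              cell_center = c(0, 0), drive_voltage = 1)
  known <- c(names(lay), "gap", names(params))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    stop("unknown layout parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in intersect(names(overrides), names(lay)))
    lay[[nm]] <- overrides[[nm]]
  for (nm in intersect(names(overrides), names(params)))
    params[[nm]] <- overrides[[nm]]
  if ("gap" %in% names(overrides)) {
    lay$gap <- overrides$gap
    if (shape %in% c("standard", "cross"))
      params$bite <- lay$cell_radius - lay$gap / 2
  } else {
    lay$gap <- default_gap(shape, lay$cell_radius, params)
  }
  lay$shape_params <- params
  lay$drive_axis <- if (shape %in% c("parallel", "plate")) "y" else "x"
  lay <- structure(lay, class = "device_layout")
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  p <- lay$shape_params
  if (lay$width <= 0 || lay$height <= 0) stop("domain dimensions must be > 0")
  if (lay$cell_radius < 0) stop("cell_radius must be >= 0")
  if (lay$cell_radius > 0) {
    hw <- c(lay$width, lay$height) / 2
    if (any(abs(lay$cell_center) + lay$cell_radius > hw))
      stop("cell does not fit inside the domain")
  }
  if (lay$shape != "plate") {
    if (!is.numeric(lay$gap) || lay$gap <= 0)
      stop("geometry error: electrode gap must be > 0 (got ", lay$gap, ")")
  }
  switch(lay$shape,
    parallel = {
      if (lay$gap / 2 + p$bar_thickness > lay$height / 2)
        stop("geometry error: bars extend beyond the domain")
      if (p$bar_length > lay$width) stop("geometry error: bar too long")
    },
    circle = {
      if (lay$gap / 2 >= p$arc_radius)
        stop("geometry error: circle tips (gap/2) must lie inside arc_radius")
    },
    standard = ,
    cross = {
      if (lay$gap / 2 >= lay$width / 2)
        stop("geometry error: electrode faces outside the domain")
    },
    plate = NULL)
  invisible(lay)
}

#' @export
print.device_layout <- function(x, ...) {
  cat(sprintf("device_layout: %s | domain %g x %g um | gap %s um | cell r = %g um\n",
              x$shape, x$width * 1e6, x$height * 1e6,
              if (is.na(x$gap)) "-" else format(x$gap * 1e6),
              x$cell_radius * 1e6))
  invisible(x)
}

# Vectorised membership in electrode A (the driven electrode). Electrode B is
# A mirrored through the origin along the drive axis.
in_electrode_A <- function(lay, x, y) {
  p <- lay$shape_params
  switch(lay$shape,
    parallel = {
      y0 <- lay$gap / 2
      abs(x) <= p$bar_length / 2 & y >= y0 & y <= y0 + p$bar_thickness
    },
    standard = {
      x0 <- lay$gap / 2
      x >= x0 & abs(y) <= p$tip_width / 2
    },
    cross = {
      x0 <- lay$gap / 2
      (x >= x0 & x <= x0 + p$arm_width & abs(y) <= p$arm_length / 2) |
        (x >= x0 + p$arm_width & abs(y) <= p$tip_width / 2)
    },
    circle = {
      x0 <- lay$gap / 2
      ycap <- sqrt(p$arc_radius^2 - x0^2)
      r <- sqrt(x^2 + y^2)
      x >= x0 & abs(y) <= ycap & r >= p$arc_radius
    },
    plate = rep(FALSE, length(x))
  )
}

# Returns "ELECTRODE_A", "ELECTRODE_B" or NA per point.
electrode_label <- function(lay, x, y) {
  lab <- rep(NA_character_, length(x))
  inA <- in_electrode_A(lay, x, y)
  inB <- if (lay$drive_axis == "x") in_electrode_A(lay, -x, y)
         else in_electrode_A(lay, x, -y)
  lab[inB] <- "ELECTRODE_B"
  lab[inA] <- "ELECTRODE_A"   # A wins ties (degenerate overlapping layouts)
  lab
}

#' Classify points into device regions
#'
#' Deterministic region label with precedence ELECTRODE > CELL > PBS; points
#' on a boundary resolve to the higher-precedence region.
#'
#' @param layout A `device_layout`.
#' @param x,y Coordinates in metres (vectorised).
#' @return Character vector in `{"PBS","CELL","ELECTRODE_A","ELECTRODE_B"}`.
#' @export
classify_point <- function(layout, x, y) {
  stopifnot(inherits(layout, "device_layout"), length(x) == length(y))
  eps <- 1e-12
  if (any(abs(x) > layout$width / 2 + eps | abs(y) > layout$height / 2 + eps))
    stop("point outside the domain")
  lab <- rep("PBS", length(x))
  if (layout$cell_radius > 0) {
    r2 <- (x - layout$cell_center[1])^2 + (y - layout$cell_center[2])^2
    lab[r2 <= layout$cell_radius^2] <- "CELL"
  }
  el <- electrode_label(layout, x, y)
  lab[!is.na(el)] <- el[!is.na(el)]
  lab
}

#' Minimum distance between the two electrode regions
#'
#' Computed by dense boundary sampling: the domain is rasterised at pitch
#' `pitch`, boundary pixels of each electrode are extracted, and the minimum
#' cross distance reported (accurate to about one pitch).
#'
#' @param layout A `device_layout` (not `plate`).
#' @param pitch Sampling pitch in metres.
#' @return Minimum distance in metres (0 when the electrodes touch).
#' @export
electrode_gap_distance <- function(layout, pitch = 0.25e-6) {
  stopifnot(inherits(layout, "device_layout"))
  if (layout$shape == "plate")
    return(layout$height)
  xs <- seq(-layout$width / 2, layout$width / 2, by = pitch)
  ys <- seq(-layout$height / 2, layout$height / 2, by = pitch)
  g <- expand.grid(x = xs, y = ys)
  lab <- matrix(electrode_label(layout, g$x, g$y), nrow = length(xs))
  boundary_pts <- function(tag) {
    m <- !is.na(lab) & lab == tag
    # boundary pixel: in region but some 4-neighbour is not
    pad <- function(mm) {
      out <- matrix(FALSE, nrow(mm) + 2L, ncol(mm) + 2L)
      out[2:(nrow(mm) + 1L), 2:(ncol(mm) + 1L)] <- mm
      out
    }
    P <- pad(m)
    nr <- nrow(m); nc <- ncol(m)
    core <- P[2:(nr + 1L), 2:(nc + 1L)]
    nb <- P[1:nr, 2:(nc + 1L)] & P[3:(nr + 2L), 2:(nc + 1L)] &
          P[2:(nr + 1L), 1:nc] & P[2:(nr + 1L), 3:(nc + 2L)]
    idx <- which(core & !nb, arr.ind = TRUE)
    cbind(xs[idx[, 1L]], ys[idx[, 2L]])
  }
  A <- boundary_pts("ELECTRODE_A"); B <- boundary_pts("ELECTRODE_B")
  if (!nrow(A) || !nrow(B)) stop("electrode region(s) empty at this pitch")
  # blockwise min cross distance
  best <- Inf
  step <- 2000L
  for (i0 in seq(1L, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(A))
    dx <- outer(A[ii, 1L], B[, 1L], "-")
    dy <- outer(A[ii, 2L], B[, 2L], "-")
    best <- min(best, sqrt(min(dx * dx + dy * dy)))
  }
  best
}

#' Write a resolved layout (all defaults expanded) to YAML for provenance
#'
#' @param layout A `device_layout`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout_yaml <- function(layout, path) {
  stopifnot(inherits(layout, "device_layout"))
  out <- list(
    shape = layout$shape,
    width_um = layout$width * 1e6, height_um = layout$height * 1e6,
    gap_um = if (is.na(layout$gap)) NULL else layout$gap * 1e6,
    cell_radius_um = layout$cell_radius * 1e6,
    cell_center_um = as.numeric(layout$cell_center) * 1e6,
    drive_voltage_V = layout$drive_voltage,
    drive_axis = layout$drive_axis,
    shape_params_um = lapply(layout$shape_params, function(v) v * 1e6))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a layout from a YAML config written by [write_layout_yaml()] or by hand
#'
#' Recognised keys: `shape`, `gap_um`, `cell_radius_um`, `cell_center_um`,
#' `drive_voltage_V`, `shape_params_um` (a map of shape parameters in um).
#'
#' @param path YAML file path.
#' @return A `device_layout`.
#' @export
read_layout_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$shape)) stop("layout config must name a shape")
  ov <- list()
  if (!is.null(cfg$width_um)) ov$width <- cfg$width_um * 1e-6
  if (!is.null(cfg$height_um)) ov$height <- cfg$height_um * 1e-6
  if (!is.null(cfg$gap_um)) ov$gap <- cfg$gap_um * 1e-6
  if (!is.null(cfg$cell_radius_um)) ov$cell_radius <- cfg$cell_radius_um * 1e-6
  if (!is.null(cfg$cell_center_um)) ov$cell_center <- cfg$cell_center_um * 1e-6
  if (!is.null(cfg$drive_voltage_V)) ov$drive_voltage <- cfg$drive_voltage_V
  if (!is.null(cfg$shape_params_um))
    for (nm in names(cfg$shape_params_um))
      ov[[nm]] <- cfg$shape_params_um[[nm]] * 1e-6
  build_layout(cfg$shape, ov)
}
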