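# Reduction of field solutions to reported quantities: line profiles along
# the coordinate axes and intracellular/extracellular field statistics.

#' Field magnitude profile along an axis through the cell centre
#'
#' Samples the element-constant |E| along the line through the cell centre
#' parallel to `axis` (element-wise constant interpolation via the nearest
#' element centroid within the line's band). Samples falling in electrode
#' metal are masked `NA`.
#'
#' @param sol A `field_solution` on a layout mesh.
#' @param axis `"x"` or `"y"`.
#' @param n Number of samples across the domain (default gives >= 200 across
#'   a 20 um cell on a 100 um domain).
#' @return A `line_profile` data.frame with `position` (m, strictly
#'   increasing), `magnitude` (V/m) and `region`.
#' @export
line_profile <- function(sol, axis = c("x", "y"), n = 1001L) {
  axis <- match.arg(axis)
  lay <- sol$layout
  if (is.null(lay)) stop("line_profile requires a layout-based solution")
  ef <- electric_field(sol)
  half <- if (axis == "x") lay$width / 2 else lay$height / 2
  s <- seq(-half, half, length.out = n)
  ctr <- lay$cell_center
  if (axis == "x") { px <- s; py <- rep(ctr[2], n) }
  else             { py <- s; px <- rep(ctr[1], n) }
  h <- sol$mesh$resolution
  near <- if (axis == "x") abs(ef$y - ctr[2]) <= 1.5 * h
          else abs(ef$x - ctr[1]) <= 1.5 * h
  cand <- which(near)
  if (!length(cand)) stop("no elements near the requested line")
  mag <- numeric(n); regs <- character(n)
  cxy <- if (axis == "x") ef$x[cand] else ef$y[cand]
  perp <- if (axis == "x") ef$y[cand] - ctr[2] else ef$x[cand] - ctr[1]
  for (i in seq_len(n)) {
    d2 <- (cxy - s[i])^2 + perp^2
    e <- cand[which.min(d2)]
    mag[i] <- ef$magnitude[e]
    regs[i] <- as.character(ef$region[e])
  }
  if (all(is.na(mag))) stop("profile line lies entirely inside electrode metal")
  structure(data.frame(position = s, magnitude = mag, region = regs,
                       stringsAsFactors = FALSE),
            axis = axis, class = c("line_profile", "data.frame"))
}

#' Intracellular and extracellular field statistics
#'
#' Area-weighted min/max/mean of |E| over (a) cell elements and (b) PBS
#' elements within `window` of the cell boundary, both restricted to a band
#' of half-width `window` around the drive axis (mirroring how the reported
#' values are read off axis profiles).
#'
#' @param sol A `field_solution` on a layout with a cell.
#' @param window Window length in metres (>= one element size). With the
#'   default contact layouts the electrode metal overlaps the cell footprint
#'   and covers the on-axis annulus out to several micrometres, so a window
#'   of 8e-6 or more is needed for the extracellular set to be non-empty
#'   (an empty set raises an error rather than returning NaN).
#' @return A `field_extrema` list with `intracellular` and `extracellular`
#'   components (each `min`, `max`, `mean` in V/m) plus bookkeeping fields.
#' @export
field_extrema <- function(sol, window = 5e-6) {
  lay <- sol$layout
  if (is.null(lay) || lay$cell_radius <= 0)
    stop("field_extrema requires a layout with a cell")
  if (window < sol$mesh$resolution)
    stop("window must be at least one element size")
  ef <- electric_field(sol)
  ctr <- lay$cell_center
  r <- sqrt((ef$x - ctr[1])^2 + (ef$y - ctr[2])^2)
  perp <- if (lay$drive_axis == "x") abs(ef$y - ctr[2]) else abs(ef$x - ctr[1])
  band <- perp <= window
  intra <- ef$region == "CELL" & band & !is.na(ef$magnitude)
  extra <- ef$region == "PBS" & band & !is.na(ef$magnitude) &
    r > lay$cell_radius & r <= lay$cell_radius + window
  stats_of <- function(sel) {
    if (!any(sel)) stop("empty element set for field statistics")
    w <- sol$mesh$area[sel]; m <- ef$magnitude[sel]
    list(min = min(m), max = max(m), mean = sum(w * m) / sum(w),
         n = sum(sel))
  }
  structure(list(intracellular = stats_of(intra),
                 extracellular = stats_of(extra),
                 window = window, f = sol$f, V = sol$V,
                 shape = lay$shape),
            class = "field_extrema")
}

#' @export
print.field_extrema <- function(x, ...) {
  fmt <- function(s) sprintf("min %.3e  max %.3e  mean %.3e V/m (n=%d)",
                             s$min, s$max, s$mean, s$n)
  cat(sprintf("field_extrema (%s, f = %s Hz, V = %g V, window %g um)\n",
              x$shape, format(x$f), x$V, x$window * 1e6))
  cat("  intracellular:", fmt(x$intracellular), "\n")
  cat("  extracellular:", fmt(x$extracellular), "\n")
  invisible(x)
}

#' Mean intracellular field over all cell elements
#'
#' Area-weighted mean |E| over every element labelled CELL (no axial band).
#'
#' @param sol A `field_solution`.
#' @return Mean field magnitude in V/m.
#' @export
intracellular_mean_field <- function(sol) {
  ef <- electric_field(sol)
  sel <- ef$region == "CELL" & !is.na(ef$magnitude)
  if (!any(sel)) stop("solution has no cell elements")
  w <- sol$mesh$area[sel]
  sum(w * ef$magnitude[sel]) / sum(w)
}

#' Ratio of mean intracellular field between two solutions
#'
#' @param solA,solB `field_solution`s at the same frequency and drive voltage
#'   on comparable meshes.
#' @return Dimensionless ratio mean|E|_A / mean|E|_B.
#' @export
intracellular_ratio <- function(solA, solB) {
  if (!is.na(solA$f) && !is.na(solB$f) && solA$f != solB$f)
    stop("solutions are at different frequencies")
  if (solA$V != solB$V) stop("solutions are at different drive voltages")
  den <- intracellular_mean_field(solB)
  if (den == 0) stop("zero intracellular field in the denominator solution")
  intracellular_mean_field(solA) / den
}
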