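# Structured triangulation of device layouts and polar triangulation of the
# annulus fixture. Elements are P1 triangles; each element carries exactly one
# region label (centroid classification).

new_fem_mesh <- function(nodes, triangles, elem_region, dirichlet_A,
                         dirichlet_B, resolution, layout = NULL) {
  m <- list(nodes = nodes, triangles = triangles, elem_region = elem_region,
            dirichlet_A = as.integer(dirichlet_A),
            dirichlet_B = as.integer(dirichlet_B),
            resolution = resolution, layout = layout)
  geo <- element_geometry(nodes, triangles)
  if (any(geo$area <= 1e-24))
    stop("mesh contains degenerate or inverted elements")
  m$area <- geo$area; m$bmat <- geo$bmat; m$cmat <- geo$cmat
  m$K_unit <- region_stiffness(m)
  class(m) <- "fem_mesh"
  m
}

element_geometry <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  inv2A <- 1 / (2 * area)
  bmat <- cbind((y2 - y3) * inv2A, (y3 - y1) * inv2A, (y1 - y2) * inv2A)
  cmat <- cbind((x3 - x2) * inv2A, (x1 - x3) * inv2A, (x2 - x1) * inv2A)
  list(area = area, bmat = bmat, cmat = cmat)
}

# Unit-admittivity stiffness matrix per conducting region (electrode metal is
# modelled as a Dirichlet boundary, never as meshed material).
region_stiffness <- function(m) {
  n <- nrow(m$nodes)
  regions <- setdiff(unique(m$elem_region), c("ELECTRODE_A", "ELECTRODE_B"))
  out <- list()
  for (reg in regions) {
    e <- which(m$elem_region == reg)
    tri <- m$triangles[e, , drop = FALSE]
    A <- m$area[e]; b <- m$bmat[e, , drop = FALSE]; c_ <- m$cmat[e, , drop = FALSE]
    ii <- jj <- xx <- vector("list", 9L)
    k <- 0L
    for (a in 1:3) for (bb in 1:3) {
      k <- k + 1L
      ii[[k]] <- tri[, a]; jj[[k]] <- tri[, bb]
      xx[[k]] <- A * (b[, a] * b[, bb] + c_[, a] * c_[, bb])
    }
    out[[reg]] <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                       x = unlist(xx), dims = c(n, n))
  }
  out
}

#' Mesh a device layout on a structured, mirror-symmetric triangular grid
#'
#' Squares of side `resolution` are each split into two triangles; the
#' diagonal direction is chosen per quadrant so the triangulation shares the
#' layout's mirror symmetries. Element regions come from classifying element
#' centroids, so region boundaries are resolved within one element.
#'
#' @param layout A `device_layout`.
#' @param resolution Target edge length in metres; must resolve the electrode
#'   gap (`resolution <= gap/4`).
#' @return A `fem_mesh` with nodes, triangles, per-element regions, Dirichlet
#'   node sets for the two electrodes, and cached per-region unit stiffness
#'   matrices.
#' @export
generate_mesh <- function(layout, resolution) {
  stopifnot(inherits(layout, "device_layout"), resolution > 0)
  if (layout$shape != "plate" && resolution > layout$gap / 4 + 1e-15)
    stop(sprintf("resolution %g m too coarse: must be <= gap/4 = %g m",
                 resolution, layout$gap / 4))
  nx <- max(2L, as.integer(round(layout$width / resolution)))
  ny <- max(2L, as.integer(round(layout$height / resolution)))
  xs <- seq(-layout$width / 2, layout$width / 2, length.out = nx + 1L)
  ys <- seq(-layout$height / 2, layout$height / 2, length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i   # i along x, j along y
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  n00 <- idx(i, j); n10 <- idx(i + 1L, j)
  n01 <- idx(i, j + 1L); n11 <- idx(i + 1L, j + 1L)
  xc <- (xs[i] + xs[i + 1L]) / 2
  yc <- (ys[j] + ys[j + 1L]) / 2
  d1 <- xc * yc > 0   # backslash diagonal in quadrants I and III
  tri <- rbind(
    cbind(n00[d1], n10[d1], n11[d1]), cbind(n00[d1], n11[d1], n01[d1]),
    cbind(n00[!d1], n10[!d1], n01[!d1]), cbind(n10[!d1], n11[!d1], n01[!d1]))
  cx <- (nodes[tri[, 1L], 1L] + nodes[tri[, 2L], 1L] + nodes[tri[, 3L], 1L]) / 3
  cy <- (nodes[tri[, 1L], 2L] + nodes[tri[, 2L], 2L] + nodes[tri[, 3L], 2L]) / 3
  reg <- classify_point(layout, cx, cy)
  if (layout$shape == "plate") {
    dirA <- idx(seq_len(nx + 1L), rep(ny + 1L, nx + 1L))  # top wall
    dirB <- idx(seq_len(nx + 1L), rep(1L, nx + 1L))       # bottom wall
  } else {
    dirA <- unique(as.vector(tri[reg == "ELECTRODE_A", , drop = FALSE]))
    dirB <- unique(as.vector(tri[reg == "ELECTRODE_B", , drop = FALSE]))
  }
  if (!length(dirA) || !length(dirB))
    stop("empty electrode node set: resolution too coarse for this layout")
  if (length(intersect(dirA, dirB)))
    stop("electrode node sets overlap: electrodes touch at this resolution")
  new_fem_mesh(nodes, tri, reg, dirA, dirB, resolution, layout)
}

#' Polar mesh of a concentric annulus with electrode rings
#'
#' Analytic verification fixture: inner electrode at radius `a` (driven),
#' outer electrode at radius `b` (grounded), homogeneous medium between. The
#' closed-form potential is phi(r) = V ln(b/r) / ln(b/a) and the terminal
#' current per unit depth is I = 2 pi kappa V / ln(b/a).
#'
#' @param a,b Inner and outer radii in metres (0 < a < b).
#' @param resolution Target edge length in metres.
#' @return A `fem_mesh` whose single region is `"PBS"`.
#' @export
annulus_mesh <- function(a, b, resolution) {
  stopifnot(a > 0, b > a, resolution > 0)
  nr <- max(2L, as.integer(round((b - a) / resolution)))
  nt <- max(8L, as.integer(round(2 * pi * b / resolution)))
  rs <- seq(a, b, length.out = nr + 1L)
  th <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  nodes <- cbind(rep(rs, each = nt) * cos(rep(th, nr + 1L)),
                 rep(rs, each = nt) * sin(rep(th, nr + 1L)))
  idx <- function(k, t) (k - 1L) * nt + ((t - 1L) %% nt) + 1L
  k <- rep(seq_len(nr), each = nt)
  t <- rep(seq_len(nt), times = nr)
  n00 <- idx(k, t); n10 <- idx(k, t + 1L)
  n01 <- idx(k + 1L, t); n11 <- idx(k + 1L, t + 1L)
  tri <- rbind(cbind(n00, n11, n10), cbind(n00, n01, n11))
  reg <- rep("PBS", nrow(tri))
  dirA <- idx(rep(1L, nt), seq_len(nt))
  dirB <- idx(rep(nr + 1L, nt), seq_len(nt))
  new_fem_mesh(nodes, tri, reg, dirA, dirB, resolution, layout = NULL)
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %d nodes, %d triangles, resolution %g um\n",
              nrow(x$nodes), nrow(x$triangles), x$resolution * 1e6))
  tb <- table(x$elem_region)
  cat("  elements by region:",
      paste(names(tb), as.integer(tb), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
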