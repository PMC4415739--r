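# Complex electro-quasistatic solver: piecewise-linear Galerkin discretisation
# of div(kappa grad phi) = 0 with Dirichlet electrodes and insulating outer
# walls, solved by sparse direct factorisation. The complex n x n system is
# solved as the equivalent real 2n x 2n block system
# [[Kr, -Ki], [Ki, Kr]] [phi_r; phi_i] = [b_r; b_i].

#' Solve the electro-quasistatic field problem on a mesh
#'
#' Solves div(kappa grad phi) = 0 with phi = `V` on electrode A, phi = 0 on
#' electrode B, and zero normal flux on the outer boundary. kappa is constant
#' per region (complex admittivity, S/m).
#'
#' @param mesh A `fem_mesh`.
#' @param materials Named list or complex vector mapping every conducting
#'   region of the mesh (e.g. `PBS`, `CELL`) to its complex admittivity.
#' @param V Drive voltage applied to electrode A (electrode B grounded).
#' @param f Frequency in Hz associated with the solve (metadata; the
#'   admittivities already encode it).
#' @return A `field_solution` with complex nodal potential `phi`.
#' @export
solve_field <- function(mesh, materials, V, f = NA_real_) {
  stopifnot(inherits(mesh, "fem_mesh"))
  regions <- names(mesh$K_unit)
  if (!all(regions %in% names(materials)))
    stop("materials must provide an admittivity for region(s): ",
         paste(setdiff(regions, names(materials)), collapse = ", "))
  kap <- vapply(regions, function(r) as.complex(materials[[r]]), complex(1))
  if (any(Re(kap) < 0) || any(Re(kap) == 0 & Im(kap) <= 0))
    stop("every admittivity needs a positive real or imaginary part")
  n <- nrow(mesh$nodes)
  Kr <- Ki <- NULL
  for (r in seq_along(regions)) {
    Kr <- if (is.null(Kr)) Re(kap[r]) * mesh$K_unit[[r]]
          else Kr + Re(kap[r]) * mesh$K_unit[[r]]
    Ki <- if (is.null(Ki)) Im(kap[r]) * mesh$K_unit[[r]]
          else Ki + Im(kap[r]) * mesh$K_unit[[r]]
  }
  dir_nodes <- c(mesh$dirichlet_A, mesh$dirichlet_B)
  phi_d <- c(rep(V, length(mesh$dirichlet_A)),
             rep(0, length(mesh$dirichlet_B)))
  free <- setdiff(seq_len(n), dir_nodes)
  if (!length(free)) stop("no free nodes to solve for")
  Krff <- Kr[free, free]; Krfd <- Kr[free, dir_nodes]
  rhs_r <- as.numeric(-Krfd %*% phi_d)
  phi <- complex(real = numeric(n), imaginary = numeric(n))
  all_real <- all(Im(kap) == 0)
  sol <- tryCatch({
    if (all_real) {
      xr <- as.numeric(Matrix::solve(Krff, rhs_r))
      complex(real = xr, imaginary = 0)
    } else {
      Kiff <- Ki[free, free]; Kifd <- Ki[free, dir_nodes]
      rhs_i <- as.numeric(-Kifd %*% phi_d)
      B <- rbind(cbind(Krff, -Kiff), cbind(Kiff, Krff))
      x <- as.numeric(Matrix::solve(B, c(rhs_r, rhs_i)))
      nf <- length(free)
      complex(real = x[seq_len(nf)], imaginary = x[nf + seq_len(nf)])
    }
  }, error = function(e) {
    stop("linear solve failed (singular system; disconnected domain or ",
         "empty electrode set?): ", conditionMessage(e))
  })
  phi[free] <- sol
  phi[mesh$dirichlet_A] <- V
  phi[mesh$dirichlet_B] <- 0
  structure(list(phi = phi, mesh = mesh, layout = mesh$layout,
                 f = f, V = V,
                 kappa_map = stats::setNames(as.list(kap), regions)),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: V = %g V, f = %s Hz, %d nodes\n",
              x$V, format(x$f), length(x$phi)))
  invisible(x)
}

#' Element-wise electric field of a solution
#'
#' E = -grad(phi), constant per P1 element. The reported magnitude is
#' sqrt(|Ex|^2 + |Ey|^2) using complex moduli. Electrode elements are `NA`.
#'
#' @param sol A `field_solution`.
#' @return A data.frame with element centroids, region, complex `Ex`, `Ey`
#'   and real `magnitude` (V/m).
#' @export
electric_field <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  m <- sol$mesh
  tri <- m$triangles
  p1 <- sol$phi[tri[, 1L]]; p2 <- sol$phi[tri[, 2L]]; p3 <- sol$phi[tri[, 3L]]
  Ex <- -(p1 * m$bmat[, 1L] + p2 * m$bmat[, 2L] + p3 * m$bmat[, 3L])
  Ey <- -(p1 * m$cmat[, 1L] + p2 * m$cmat[, 2L] + p3 * m$cmat[, 3L])
  mag <- sqrt(Mod(Ex)^2 + Mod(Ey)^2)
  metal <- m$elem_region %in% c("ELECTRODE_A", "ELECTRODE_B")
  Ex[metal] <- NA; Ey[metal] <- NA; mag[metal] <- NA
  cx <- (m$nodes[tri[, 1L], 1L] + m$nodes[tri[, 2L], 1L] +
           m$nodes[tri[, 3L], 1L]) / 3
  cy <- (m$nodes[tri[, 1L], 2L] + m$nodes[tri[, 2L], 2L] +
           m$nodes[tri[, 3L], 2L]) / 3
  data.frame(x = cx, y = cy, region = m$elem_region,
             Ex = Ex, Ey = Ey, magnitude = mag)
}

#' Terminal current of an electrode, per unit depth
#'
#' Computed by the weak-form (residual) method: the discrete residual of the
#' unconstrained stiffness matrix at the electrode's Dirichlet nodes equals
#' the boundary integral of kappa dphi/dn. Sign convention: current leaving
#' the electrode into the domain is positive.
#'
#' @param sol A `field_solution`.
#' @param electrode `"A"` (driven) or `"B"` (grounded).
#' @return Complex current per unit depth (A/m).
#' @export
boundary_current <- function(sol, electrode = c("A", "B")) {
  electrode <- match.arg(electrode)
  m <- sol$mesh
  regions <- names(m$K_unit)
  res <- 0
  for (r in regions) {
    kap <- as.complex(sol$kappa_map[[r]])
    Kphi_r <- as.numeric(m$K_unit[[r]] %*% Re(sol$phi))
    Kphi_i <- as.numeric(m$K_unit[[r]] %*% Im(sol$phi))
    res <- res + kap * complex(real = Kphi_r, imaginary = Kphi_i)
  }
  nodes <- if (electrode == "A") m$dirichlet_A else m$dirichlet_B
  sum(res[nodes])
}

#' Impedance of a device from a field solution
#'
#' Z = V / (I * depth), with I the terminal current of electrode A per unit
#' depth. 2D solves give impedance per unit out-of-plane depth; `depth`
#' converts to ohms.
#'
#' @param sol A `field_solution`.
#' @param depth Assumed out-of-plane device depth in metres.
#' @return Complex impedance in ohms.
#' @export
fem_impedance <- function(sol, depth = 1) {
  stopifnot(inherits(sol, "field_solution"), depth > 0)
  I <- boundary_current(sol, "A")
  if (Mod(I) < 1e-300) stop("terminal current is numerically zero")
  sol$V / (I * depth)
}
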