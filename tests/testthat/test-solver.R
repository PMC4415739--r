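# Discretisation and solver checks against closed-form solutions.

test_that("plate solve reproduces the linear potential to round-off", {
  lay <- build_layout("plate")
  mesh <- generate_mesh(lay, 5e-6)
  kap <- 2e-6 + 0i
  sol <- solve_field(mesh, list(PBS = kap), V = 1)
  # phi(y) = (y + h/2) / h lies in the P1 space, so the FEM is nodally exact
  phi_ref <- (mesh$nodes[, 2L] + 50e-6) / 100e-6
  expect_lt(max(Mod(sol$phi - phi_ref)), 1e-10)
  ef <- electric_field(sol)
  expect_lt(max(abs(ef$magnitude - 1e4)), 1e-4)   # |E| = V/h = 1e4 V/m
  expect_lt(max(Mod(ef$Ex)), 1e-6)                # field purely along y
  # slab impedance Z = h / (kappa * w * depth)
  Z <- fem_impedance(sol)
  expect_equal(Z, 100e-6 / (kap * 100e-6), tolerance = 1e-10)
})

test_that("terminal currents balance and scale linearly with drive voltage", {
  sol <- solve_shape("standard", f = 1e5, V = 1)
  IA <- boundary_current(sol, "A")
  IB <- boundary_current(sol, "B")
  # charge conservation: current into B equals current out of A
  expect_lt(Mod(IA + IB) / Mod(IA), 1e-10)
  # linearity of the PDE in the drive voltage
  lay <- build_layout("standard", list(drive_voltage = 0.5))
  mesh <- generate_mesh(lay, 1e-6)
  mats <- list(PBS = sol$kappa_map$PBS, CELL = sol$kappa_map$CELL)
  sol_half <- solve_field(mesh, mats, V = 0.5, f = 1e5)
  expect_equal(boundary_current(sol_half, "A"), IA / 2, tolerance = 1e-9)
  expect_equal(fem_impedance(sol_half), fem_impedance(sol), tolerance = 1e-9)
})

test_that("annulus solve converges at second order to the log potential", {
  a <- 10e-6; b <- 40e-6; V <- 1
  kap <- 2e-6 + 0i
  err <- function(res) {
    mesh <- annulus_mesh(a, b, res)
    sol <- solve_field(mesh, list(PBS = kap), V = V)
    r <- sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2)
    phi_ref <- V * log(b / r) / log(b / a)
    max(Mod(sol$phi - phi_ref))
  }
  e1 <- err(2e-6)
  e2 <- err(1e-6)
  expect_lt(e1, 5e-3)
  expect_gt(e1 / e2, 3)   # O(h^2) nodal convergence
  # terminal current against I = 2 pi kappa V / ln(b/a)
  mesh <- annulus_mesh(a, b, 1e-6)
  sol <- solve_field(mesh, list(PBS = kap), V = V)
  I_ref <- 2 * pi * kap * V / log(b / a)
  expect_lt(Mod(boundary_current(sol, "A") - I_ref) / Mod(I_ref), 5e-3)
})

test_that("complex and real solve paths agree in the conduction limit", {
  lay <- build_layout("parallel")
  mesh <- generate_mesh(lay, 2e-6)
  mats_r <- list(PBS = 2e-6 + 0i, CELL = 8.2e-3 + 0i)
  # a vanishing imaginary part must route through the block solver yet give
  # the same potential as the purely real path
  mats_c <- list(PBS = 2e-6 + 1e-18i, CELL = 8.2e-3 + 1e-18i)
  pr <- solve_field(mesh, mats_r, V = 1)$phi
  pc <- solve_field(mesh, mats_c, V = 1)$phi
  expect_lt(max(Mod(pr - pc)), 1e-8)
})

test_that("potential respects the discrete maximum principle and symmetry", {
  for (shape in c("parallel", "cross")) {
    sol <- solve_shape(shape)
    expect_lte(max(Mod(sol$phi)), 1 + 1e-9)
    m <- sol$mesh
    phiA <- sol$phi[m$dirichlet_A]; phiB <- sol$phi[m$dirichlet_B]
    expect_true(all(phiA == 1) && all(phiB == 0))
    # mirror antisymmetry about the mid-equipotential along the drive axis:
    # phi(mirror(p)) = V - phi(p)
    ax <- sol$layout$drive_axis
    key <- function(x, y) paste(round(x / 1e-9), round(y / 1e-9))
    k0 <- key(m$nodes[, 1L], m$nodes[, 2L])
    km <- if (ax == "x") key(-m$nodes[, 1L], m$nodes[, 2L])
          else key(m$nodes[, 1L], -m$nodes[, 2L])
    mirror <- match(km, k0)
    expect_false(anyNA(mirror))
    expect_lt(max(Mod(sol$phi[mirror] - (sol$V - sol$phi))), 1e-8)
  }
})

test_that("solver input validation catches bad materials and coarse meshes", {
  lay <- build_layout("parallel")
  expect_error(generate_mesh(lay, 5e-6), "too coarse")
  mesh <- generate_mesh(lay, 2e-6)
  expect_error(solve_field(mesh, list(PBS = 2e-6 + 0i), V = 1),
               "admittivity for region")
  expect_error(solve_field(mesh, list(PBS = -1 + 0i, CELL = 1 + 0i), V = 1),
               "positive real or imaginary")
  expect_error(solve_field(mesh, list(PBS = 0 + 0i, CELL = 1 + 0i), V = 1),
               "positive real or imaginary")
})

test_that("a more conductive cell lowers the device impedance magnitude", {
  # dual-route sanity: with-cell versus homogeneous PBS at identical mesh
  sol_cell <- solve_shape("standard", f = 1e5, V = 1, with_cell = TRUE)
  sol_pbs <- solve_shape("standard", f = 1e5, V = 1, with_cell = FALSE)
  Zc <- Mod(fem_impedance(sol_cell))
  Zp <- Mod(fem_impedance(sol_pbs))
  expect_lt(Zc, Zp)
  # and the homogeneous result is independent of which admittivity scales it:
  # Z_hom(kappa) = Z_hom(1) / kappa
  mesh <- sol_pbs$mesh
  s1 <- solve_field(mesh, list(PBS = 1 + 0i, CELL = 1 + 0i), V = 1)
  kap <- sol_pbs$kappa_map$PBS
  expect_equal(fem_impedance(sol_pbs), fem_impedance(s1) / kap,
               tolerance = 1e-9)
})
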