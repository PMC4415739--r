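test_that("packaged tables expose the tabulated values exactly", {
  tab <- hela_tab
  expect_equal(tab$freqs, c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100) * 1e3)
  expect_equal(tab$volts, seq(0.1, 1.0, by = 0.1))
  expect_identical(tab$sigma_grid[1L, 1L], 2.25e-4)     # 5 kHz, 0.1 V
  expect_identical(tab$sigma_grid[11L, 10L], 5.49e-2)   # 100 kHz, 1.0 V
  expect_identical(tab$eps_grid[11L, 10L], 8.5e3)       # 100 kHz, 1.0 V
  expect_identical(tab$sigma_grid[8L, 7L], 1.06e-2)     # the E-notation cell
  expect_identical(nrow(audit_monotonicity(tab)), 0L)
})

test_that("table round-trips bit-exactly through write/load", {
  tab <- hela_tab
  sp <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_cell_table(tab, sp, ep)
  tab2 <- load_cell_table(sp, ep)
  expect_identical(tab2$sigma_grid, tab$sigma_grid)
  expect_identical(tab2$eps_grid, tab$eps_grid)
  expect_identical(tab2$freqs, tab$freqs)
  expect_identical(tab2$volts, tab$volts)
})

test_that("loader rejects ragged, non-numeric and unsorted input", {
  sig <- matrix(c(1e-4, 2e-4, 3e-4, 4e-4), 2, 2)
  eps <- matrix(2e3, 2, 2)
  p <- write_test_tables(c(5, 10), c(0.1, 0.2), sig, eps, tag = "ok")
  expect_s3_class(load_cell_table(p["sigma"], p["eps"]),
                  "cell_dielectric_table")

  # one deleted cell
  lines <- readLines(p["sigma"])
  lines[2] <- sub(",[^,]*$", "", lines[2])
  bad <- tempfile(fileext = ".csv"); writeLines(lines, bad)
  expect_error(load_cell_table(bad, p["eps"]), "row 2.*missing|missing.*row 2")

  # non-numeric entry
  lines <- readLines(p["sigma"]); lines[3] <- sub("4e-04", "oops", lines[3])
  bad2 <- tempfile(fileext = ".csv"); writeLines(lines, bad2)
  expect_error(load_cell_table(bad2, p["eps"]), "non-numeric")

  # unsorted frequency axis
  p2 <- write_test_tables(c(10, 5), c(0.1, 0.2), sig, eps, tag = "unsorted")
  expect_error(load_cell_table(p2["sigma"], p2["eps"]), "increasing")
})

test_that("both scientific-notation dialects parse to the same number", {
  sig1 <- matrix(c("1.06e-02", "2e-2", "3e-2", "4e-2"), 2, 2)
  sig2 <- matrix(c("1.06E-02", "2E-2", "3E-2", "4E-2"), 2, 2)
  eps <- matrix("2e3", 2, 2)
  pa <- write_test_tables(c(5, 10), c(0.1, 0.2), sig1, eps, tag = "lower")
  pb <- write_test_tables(c(5, 10), c(0.1, 0.2), sig2, eps, tag = "upper")
  ta <- load_cell_table(pa["sigma"], pa["eps"])
  tb <- load_cell_table(pb["sigma"], pb["eps"])
  expect_identical(ta$sigma_grid, tb$sigma_grid)
  expect_identical(ta$sigma_grid[1L, 1L], 1.06e-2)
})

test_that("monotonicity audit reports violations without fixing them", {
  sig <- matrix(c(2e-4, 1e-4, 3e-4, 4e-4), 2, 2)  # decreasing in f at V1
  eps <- matrix(2e3, 2, 2)
  p <- write_test_tables(c(5, 10), c(0.1, 0.2), sig, eps, tag = "mono")
  tab <- load_cell_table(p["sigma"], p["eps"])
  v <- audit_monotonicity(tab)
  expect_gt(nrow(v), 0L)
  expect_true("frequency" %in% v$axis)
  expect_identical(tab$sigma_grid[2L, 1L], 1e-4)  # value untouched
})

test_that("lookup is exact at grid nodes and bilinear between them", {
  tab <- hela_tab
  for (i in c(1L, 5L, 11L)) for (j in c(1L, 4L, 10L)) {
    pr <- cell_properties(tab, tab$freqs[i], tab$volts[j])
    expect_identical(pr$sigma, tab$sigma_grid[i, j])
    expect_identical(pr$eps_r, tab$eps_grid[i, j])
  }
  # midpoint of two adjacent voltage cells at 5 kHz
  pr <- cell_properties(tab, 5e3, 0.15)
  expect_equal(pr$sigma, (2.25e-4 + 2.60e-4) / 2, tolerance = 1e-12)
  expect_equal(pr$sigma, 2.425e-4, tolerance = 1e-12)
  # generic bilinear against a direct hand computation
  f <- 7.5e3; V <- 0.35
  t_f <- (f - 5e3) / 5e3; t_v <- 0.5
  hand <- (1 - t_f) * ((1 - t_v) * tab$sigma_grid[1, 3] + t_v * tab$sigma_grid[1, 4]) +
    t_f * ((1 - t_v) * tab$sigma_grid[2, 3] + t_v * tab$sigma_grid[2, 4])
  expect_equal(cell_properties(tab, f, V)$sigma, hand, tolerance = 1e-12)
})

test_that("range policies behave as documented", {
  tab <- hela_tab
  expect_error(cell_properties(tab, 1e3, 0.1), "outside the tabulated range")
  expect_error(cell_properties(tab, 5e3, 1.5), "outside the tabulated range")
  cl <- cell_properties(tab, 1e3, 0.1, policy = "clamp")
  expect_identical(cl$sigma, tab$sigma_grid[1L, 1L])
  # log-linear frequency extrapolation is continuous at the grid edge
  edge <- cell_properties(tab, 5e3, 0.1, policy = "extrapolate_f")
  expect_equal(edge$sigma, 2.25e-4, tolerance = 1e-10)
  lo <- cell_properties(tab, 1e3, 0.1, policy = "extrapolate_f")
  expect_lt(lo$sigma, 2.25e-4)   # sigma rises with f, so below-range is lower
  expect_gt(lo$sigma, 0)
  expect_error(cell_properties(tab, 1e3, 2, policy = "extrapolate_f"),
               "voltage")
})

test_that("complex admittivity matches direct evaluation and is monotone in f", {
  expect_identical(complex_admittivity(medium_properties(2e-6, 136), 0),
                   2e-6 + 0i)
  k <- complex_admittivity(pbs_ref, 1e5)
  expect_equal(Re(k), 2e-6)
  expect_equal(Im(k), 2 * pi * 1e5 * EPS0 * 136, tolerance = 1e-12)
  expect_equal(Im(k), 7.566020377e-4, tolerance = 1e-8)
  # unit-imaginary construction
  k1 <- complex_admittivity(medium_properties(0, 1), 1 / (2 * pi * EPS0))
  expect_equal(k1, 0 + 1i, tolerance = 1e-12)
  # |kappa| strictly increasing in f
  fs <- 10^seq(2, 7, by = 0.5)
  mods <- vapply(fs, function(f) Mod(complex_admittivity(pbs_ref, f)),
                 numeric(1))
  expect_true(all(diff(mods) > 0))
  expect_error(complex_admittivity(pbs_ref, -1), ">= 0")
})

test_that("medium property invariants are enforced", {
  expect_error(medium_properties(-1, 10), "sigma")
  expect_error(medium_properties(1, 0.5), "eps_r")
})
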