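# Shared fixtures: small meshes and material handles reused across test files.

hela_tab <- hela_cell_table()
pbs_ref <- pbs_properties()

# one cached coarse solve per shape at (1 V, 100 kHz), 1 um resolution
solve_shape <- local({
  cache <- new.env(parent = emptyenv())
  function(shape, f = 1e5, V = 1, resolution = 1e-6, with_cell = TRUE) {
    key <- paste(shape, f, V, resolution, with_cell, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    lay <- build_layout(shape, list(drive_voltage = V))
    mesh <- generate_mesh(lay, resolution)
    kp <- complex_admittivity(pbs_ref, f)
    kc <- if (with_cell)
      complex_admittivity(cell_properties(hela_tab, f, V), f) else kp
    sol <- solve_field(mesh, list(PBS = kp, CELL = kc), V = V, f = f)
    cache[[key]] <- sol
    sol
  }
})

# write a small material CSV pair from matrices, returning the two paths
write_test_tables <- function(freqs_khz, volts, sig, eps, dir = tempdir(),
                              tag = "tt") {
  sp <- file.path(dir, paste0(tag, "_sigma.csv"))
  ep <- file.path(dir, paste0(tag, "_eps.csv"))
  hdr <- paste(c("frequency_khz", volts), collapse = ",")
  wr <- function(grid, path) {
    rows <- vapply(seq_along(freqs_khz), function(i)
      paste(c(freqs_khz[i], grid[i, ]), collapse = ","), character(1))
    writeLines(c(hdr, rows), path)
  }
  wr(sig, sp); wr(eps, ep)
  c(sigma = sp, eps = ep)
}
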