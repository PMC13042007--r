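test_that("a circular cut voids the stated area through cells and walls", {
  sp <- small_spec()
  f <- build_honeycomb_map(sp, 0.025)
  fc <- carve_defect(f, defect_spec("cut_circle", diameter = 2))
  void_area <- sum(fc$grid == 0L) * fc$pitch^2
  expect_equal(void_area, pi * 1^2, tolerance = 4 * fc$pitch)
  # transgranular: both labels voided inside the circle
  inside <- outer((f$xs - 3)^2, (f$ys - 1.5)^2, `+`) <= 0.8^2
  expect_true(all(fc$grid[inside] == 0L))
  expect_true(any(f$grid[inside] == 1L) && any(f$grid[inside] == 2L))
  expect_error(carve_defect(f, defect_spec("cut_circle", diameter = 10)),
               "fit")
})

test_that("a ripped wound removes whole cell interiors and spares walls", {
  sp <- small_spec(8, 5)
  f <- build_honeycomb_map(sp, 0.025)
  fr <- carve_defect(f, defect_spec("ripped_units", n_units = 20, seed = 7))
  # intergranular: no collagen pixel voided
  expect_true(all(f$grid[fr$grid == 0L] == 2L))
  # exactly 20 distinct cells lost their interiors
  voided_cells <- unique(fracturelattice:::cell_key(
    fr$cell_m, fr$cell_n)[fr$grid == 0L])
  expect_length(voided_cells, 20L)
  # those cells are fully emptied of lipid
  key <- fracturelattice:::cell_key(f$cell_m, f$cell_n)
  sel <- key %in% voided_cells & f$grid == 2L
  expect_true(all(fr$grid[sel] == 0L))
  # determinism and seed-dependence
  fr2 <- carve_defect(f, defect_spec("ripped_units", n_units = 20, seed = 7))
  expect_identical(fr$grid, fr2$grid)
  fr3 <- carve_defect(f, defect_spec("ripped_units", n_units = 20, seed = 8))
  expect_false(identical(fr$grid, fr3$grid))
})

test_that("degenerate defects behave as documented", {
  sp <- small_spec()
  f <- build_honeycomb_map(sp, 0.025)
  expect_identical(carve_defect(f, defect_spec("none"))$grid, f$grid)
  expect_identical(
    carve_defect(f, defect_spec("ripped_units", n_units = 0))$grid, f$grid)
  expect_error(
    carve_defect(f, defect_spec("ripped_units", n_units = 10000)),
    "exceeds")
})

test_that("material fields round-trip through CSV and export to VTK", {
  sp <- small_spec(3, 2)
  f <- build_honeycomb_map(sp, 0.03)
  tmp <- tempfile(fileext = ".csv")
  write_material_csv(f, tmp)
  f2 <- read_material_csv(tmp)
  expect_identical(f2$grid, f$grid)
  expect_equal(f2$pitch, f$pitch)
  vtk <- tempfile(fileext = ".vtk")
  write_material_vtk(f, vtk)
  head <- readLines(vtk, n = 10)
  expect_true(any(grepl("STRUCTURED_POINTS", head)))
  expect_true(any(grepl(sprintf("CELL_DATA %d", f$nx * f$ny), head)))
})
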