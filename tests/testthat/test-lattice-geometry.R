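test_that("lattice spec validates its invariants and derives edge lengths", {
  sp <- lattice_spec()
  expect_equal(sp$d_long, 0.674)
  expect_equal(sp$d_short, 0.34)
  # one geometric factor maps both diagonals to their edge-class lengths
  f_long <- sp$edge_lengths["long"] / sp$d_long
  f_short <- sp$edge_lengths["short"] / sp$d_short
  expect_equal(unname(f_long), unname(f_short), tolerance = 1e-12)
  # vertices reproduce the diagonals exactly
  g <- sp$geom
  expect_equal(2 * g$c, sp$d_long)
  expect_equal(2 * g$b, sp$d_short)
  expect_error(lattice_spec(d_long = 0.3, d_short = 0.34), "d_long")
  expect_error(lattice_spec(boundary_thickness = 0.2), "boundary_thickness")
  expect_error(lattice_spec(sheet_width = 0.5, sheet_height = 0.5), "larger")
})

test_that("every complete cell has four long and two short boundary segments", {
  sp <- small_spec()
  s1 <- enumerate_boundary_segments(sp, one_cell_window(sp))
  expect_equal(nrow(s1), 6L)
  expect_equal(sum(s1$klass == "long"), 4L)
  expect_equal(sum(s1$klass == "short"), 2L)
  # lengths match the class lengths
  expect_equal(sort(unique(round(s1$length, 6))),
               sort(unique(round(unname(sp$edge_lengths), 6))))
})

test_that("boundary segments are deduplicated across shared cell edges", {
  sp <- small_spec()
  g <- sp$geom; o <- sp$origin_offset
  # 3x3 block of hexagons: brute-force edge list from the 9 centres
  t1 <- g$t1; t2 <- g$t2
  mn <- expand.grid(m = -1:1, n = -1:1)
  keys <- character()
  for (k in seq_len(nrow(mn))) {
    cx <- o[1] + (mn$m[k] + mn$n[k]) * t1[1]
    cy <- o[2] + (mn$m[k] - mn$n[k]) * g$b
    i2 <- c(2:6, 1)
    for (e in 1:6) {
      p <- sort(c(paste(round(cx + g$vx[e], 6), round(cy + g$vy[e], 6)),
                  paste(round(cx + g$vx[i2[e]], 6),
                        round(cy + g$vy[i2[e]], 6))))
      keys <- c(keys, paste(p, collapse = "|"))
    }
  }
  expected_n <- length(unique(keys))
  # restrict the full inventory to the edges of those 9 hexagons
  segs <- enumerate_boundary_segments(sp)
  skey <- paste(paste(round(segs$x1, 6), round(segs$y1, 6)),
                paste(round(segs$x2, 6), round(segs$y2, 6)), sep = "|")
  expect_equal(sum(skey %in% keys), expected_n)
  # junction indices consistent with endpoints
  jt <- attr(segs, "junctions")
  expect_true(all(segs$j1 %in% jt$id) && all(segs$j2 %in% jt$id))
})

test_that("an empty window yields no segments", {
  sp <- small_spec()
  segs <- enumerate_boundary_segments(sp, c(0.01, 0.02, 0.01, 0.02))
  expect_equal(nrow(segs), 0L)
})

test_that("raster honours wall thickness and resolves the stated diagonals", {
  sp <- small_spec()
  f <- build_honeycomb_map(sp, 0.025)
  expect_error(build_honeycomb_map(sp, 0.05), "too coarse")
  expect_setequal(unique(as.vector(f$grid)), c(1L, 2L))
  # suppressed walls: all lipid
  f0 <- build_honeycomb_map(sp, 0.05, suppress_walls = TRUE)
  expect_equal(collagen_area_fraction(f0), 0)
  # the lipid run along a cell-centre row spans the long diagonal minus the
  # slant-wall band intersections
  o <- sp$origin_offset
  g <- sp$geom
  jrow <- which.min(abs(f$ys - o[2]))
  run <- rle(f$grid[, jrow] == 2L)
  off <- (sp$boundary_thickness / 2) / sin(atan2(g$b, g$c - g$a))
  expect_true(any(abs(run$lengths[run$values] * f$pitch -
                        (sp$d_long - 2 * off)) <= 2 * f$pitch))
})

test_that("collagen area fraction matches an independent fine-raster oracle", {
  sp <- lattice_spec(5, 5, d_long = 1, d_short = 0.5,
                     boundary_thickness = 0.1)
  f <- build_honeycomb_map(sp, 0.05)
  # oracle: distance of a fine sample grid to the explicit segment list
  segs <- enumerate_boundary_segments(
    sp, c(-0, sp$sheet_width, 0, sp$sheet_height))
  h <- 0.01
  xs <- seq(h / 2, sp$sheet_width, by = h)
  ys <- seq(h / 2, sp$sheet_height, by = h)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  d2 <- rep(Inf, length(px))
  # include segments just outside the sheet so border pixels see their walls
  segs2 <- enumerate_boundary_segments(
    lattice_spec(7, 7, 1, 0.5, 0.1,
                 origin_offset = sp$origin_offset + 1), NULL)
  for (k in seq_len(nrow(segs2))) {
    x1 <- segs2$x1[k] - 1; y1 <- segs2$y1[k] - 1
    ex <- segs2$x2[k] - 1 - x1; ey <- segs2$y2[k] - 1 - y1
    L2 <- ex^2 + ey^2
    tt <- pmin(1, pmax(0, ((px - x1) * ex + (py - y1) * ey) / L2))
    d2 <- pmin(d2, (px - x1 - tt * ex)^2 + (py - y1 - tt * ey)^2)
  }
  frac_oracle <- mean(sqrt(d2) <= sp$boundary_thickness / 2)
  walls_len <- sum(segs$length)
  tol <- 2 * 0.05 * walls_len / (sp$sheet_width * sp$sheet_height)
  expect_lt(abs(collagen_area_fraction(f) - frac_oracle), tol)
})

test_that("tessellation is periodic on interior windows", {
  sp <- small_spec()
  g <- sp$geom
  pitch <- 2 * g$b / 16     # one vertical lattice period = 16 pixels
  f <- build_honeycomb_map(sp, pitch)
  a <- f$grid[40:80, 30:60]
  b <- f$grid[40:80, 30:60 + 16L]
  expect_gt(mean(a == b), 0.995)
})

test_that("unit cell crack path follows the declared polyline arithmetic", {
  uc <- build_unit_cell(L = 1, w = 0.3, theta = 60, a = 0.2)
  expect_equal(uc$path_length, 1.3)
  expect_equal(uc$ligament, 1.1)
  # polyline length equals the summed segment lengths
  expect_equal(fracturelattice:::polyline_length(uc$crack_path), 1.3)
  # right angle gives a straight interface
  uc90 <- build_unit_cell(L = 1, w = 0.3, theta = 90, a = 0)
  d <- diff(uc90$crack_path)
  expect_equal(d[1, 2], 0)
  expect_equal(d[2, 2], 0, tolerance = 1e-12)
  expect_error(build_unit_cell(1, 0.3, 60, a = 1.5), "pre-crack")
  expect_error(build_unit_cell(1, 1.3, 60), "w")
  expect_error(build_unit_cell(1, 0.3, 190), "theta")
})
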