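test_that("cohesive law encodes the triangular traction-separation curve", {
  law <- cohesive_law(10, 500, 0.1)
  expect_equal(law$fracture_energy, 0.5 * 10 * 0.1)
  expect_equal(law$delta_peak, 0.02)
  # envelope: linear rise, linear softening, zero beyond
  expect_equal(fracturelattice:::law_envelope(law, 0.01), 5)
  expect_equal(fracturelattice:::law_envelope(law, 0.02), 10)
  expect_equal(fracturelattice:::law_envelope(law, 0.06), 5)
  expect_equal(fracturelattice:::law_envelope(law, 0.2), 0)
  # full dissipation equals the fracture energy
  expect_equal(fracturelattice:::law_dissipated(law, 1), law$fracture_energy)
  expect_equal(fracturelattice:::law_dissipated(law, 0.01), 0)
  expect_error(cohesive_law(10, 50, 0.1), "peak")
})

test_that("spring lattice mirrors the boundary-segment inventory", {
  sp <- small_spec()
  lat <- build_spring_lattice(sp)
  segs <- enumerate_boundary_segments(sp)
  walls <- lat$bonds[lat$bonds$klass != "junction", ]
  expect_equal(nrow(walls), nrow(segs))          # shared walls built once
  expect_equal(sort(walls$rest_length), sort(segs$length))
  # wall fracture energy sums as length x thickness x energy density
  G <- lat$laws$wall_long$fracture_energy
  expect_equal(sum(walls$area) * G,
               sum(segs$length) * lat$thickness * G)
  # single-cell lattice: 6 wall bonds and 6 lipid spokes
  win <- one_cell_window(sp)
  lat1 <- build_spring_lattice(sp, region = win)
  expect_equal(sum(lat1$bonds$klass != "junction"), 6L)
  central <- which.max(tabulate(lat1$spokes$cell))
  expect_equal(sum(lat1$spokes$cell == central), 6L)
  expect_error(build_spring_lattice(sp, laws = list(wall_long =
                                                      cohesive_law())),
               "missing cohesive law")
})

test_that("pinch tearing is intergranular, deterministic and energy-consistent", {
  lat <- build_spring_lattice(small_spec())
  res <- simulate_quasistatic(lat, "pinch")
  expect_true(all(res$log$klass %in% c("wall_long", "wall_short",
                                       "junction")))
  expect_true(all(diff(res$log$displacement_mm) >= 0))
  expect_true(all(res$curve$force >= 0))
  aud <- energy_audit(res)
  expect_true(aud$balanced)
  expect_equal(aud$dissipated,
               sum(vapply(seq_len(nrow(res$log)), function(i) {
                 law <- lat$laws[[res$log$klass[i]]]
                 area <- if (res$log$klass[i] == "junction")
                   lat$spec$boundary_thickness * lat$thickness
                 else res$log$rest_length_mm[i] * lat$thickness
                 law$fracture_energy * area
               }, 0)), tolerance = 1e-6)
  # determinism: identical reruns give identical event logs
  res2 <- simulate_quasistatic(lat, "pinch")
  expect_identical(res$log, res2$log)
  expect_identical(res$curve$force, res2$curve$force)
})

test_that("the sawtooth emerges with intervals matching failed wall lengths", {
  lat <- build_spring_lattice(small_spec())
  res <- simulate_quasistatic(lat, "pinch")
  pk <- detect_peaks(res$curve, min_spacing = lat$spec$geom$edge_short / 2)
  expect_gte(length(pk), 3L)
  iv <- extract_intervals(pk, res$curve)
  # each interval matches the summed lengths of walls failing between peaks
  walls <- res$log[res$log$klass != "junction", ]
  pk_u <- res$curve$displacement[pk]
  for (k in seq_along(iv)) {
    in_tooth <- walls$displacement_mm > pk_u[k] &
      walls$displacement_mm <= pk_u[k + 1] + res$increment
    expect_equal(iv[k], sum(walls$rest_length_mm[in_tooth]),
                 tolerance = 2.5 * res$increment)
  }
})

test_that("single-bond pull matches the closed-form cohesive response", {
  # a strip holding exactly one wall past the pre-crack
  sp <- small_spec(2.2, 1.2)
  lat <- build_spring_lattice(sp)
  path <- fracturelattice:::tear_path(lat)
  pb <- lat$bonds[match(path, lat$bonds$id), ]
  precrack <- sum(pb$rest_length) - pb$rest_length[nrow(pb)] + 1e-6
  res <- simulate_quasistatic(lat, "tearing", precrack = precrack)
  law <- lat$laws[[pb$klass[nrow(pb)]]]
  area <- pb$area[nrow(pb)]
  # peak sampled on the displacement grid: allow one rising step of slack
  expect_equal(res$peak_propagation_force,
               law$peak_traction * area / lat$thickness, tolerance = 0.04)
  aud <- energy_audit(res)
  jn_area <- sp$boundary_thickness * lat$thickness
  expect_equal(aud$dissipated,
               law$fracture_energy * area +
                 lat$laws$junction$fracture_energy * jn_area,
               tolerance = 1e-8)
  expect_true(aud$balanced)
})

test_that("opening failure order matches the exhaustive oracle", {
  # parallel ligament with equal grips: junctions (smaller failure
  # separation) must fail first, then walls, each in ascending bond id
  lat <- build_spring_lattice(small_spec(3.5, 1.2))
  res <- simulate_quasistatic(lat, "opening", precrack = 0.5)
  kl <- res$log$klass
  expect_true(all(which(kl == "junction") <
                    min(which(kl != "junction"))))
  walls <- res$log$bond_id[kl != "junction"]
  expect_identical(walls, sort(walls))
  jns <- res$log$bond_id[kl == "junction"]
  expect_identical(jns, sort(jns))
})

test_that("opening-mode strength exceeds tearing-mode strength", {
  lat <- build_spring_lattice(small_spec())
  cm <- compare_modes(lat, precrack = 1)
  expect_true(cm$ordering_ok)
  expect_gt(cm$opening$peak_propagation_force,
            cm$tearing$peak_propagation_force)
  # doubling every peak traction doubles the peak forces (linearity)
  laws2 <- default_cohesive_laws()
  laws2$wall_long <- cohesive_law(20, 1000, 0.1)
  laws2$wall_short <- laws2$wall_long
  laws2$junction <- cohesive_law(20 * 0.15, 1000, 0.1 * 0.15)
  lat2 <- build_spring_lattice(small_spec(), laws = laws2)
  cm2 <- compare_modes(lat2, precrack = 1)
  expect_equal(cm2$tearing$peak_propagation_force,
               2 * cm$tearing$peak_propagation_force, tolerance = 0.03)
  expect_equal(cm2$opening$peak_propagation_force,
               2 * cm$opening$peak_propagation_force, tolerance = 0.03)
})

test_that("zero-ductility limit transmits (almost) no propagation force", {
  laws0 <- default_cohesive_laws()
  laws0$wall_long <- cohesive_law(1e-6, 500, 1e-6 / 500 * 1.5)
  laws0$wall_short <- laws0$wall_long
  laws0$junction <- laws0$wall_long
  lat <- build_spring_lattice(small_spec(), laws = laws0)
  res <- simulate_quasistatic(lat, "tearing", precrack = 1,
                              max_displacement = 3)
  expect_lt(res$peak_propagation_force, 1e-5)
})
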