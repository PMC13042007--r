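# fracturelattice

Spiny mouse (*Acomys*) skin tears on purpose. Its dermis is tessellated
into hexagonal lipid-filled cells bounded by thin collagen walls — a
**fracture lattice** — so that under a predator's pinch the tissue unzips
along cell boundaries instead of rupturing across them. The
force–displacement record of such a tear is a sawtooth whose successive
peak spacings are integer combinations of the two boundary lengths of the
hexagon (four long boundaries of mean length 0.674 mm, two short of
0.340 mm per cell).

`fracturelattice` implements the mechanics behind that observation, for
researchers in tissue biomechanics who want to reproduce or extend the
modelling:

* **Lattice geometry** — periodic honeycomb tessellation with hexagon
  diagonals `d_long`/`d_short`, rasterised collagen/lipid material maps,
  cut (transgranular) and ripped (intergranular) wound defects, and the
  boundary-segment inventory (`lattice_spec()`, `build_honeycomb_map()`,
  `carve_defect()`, `enumerate_boundary_segments()`).
* **Elastic stress analysis** — plane-stress FEM of the heterogeneous
  composite under edge displacement (collagen E = 92.2 kPa, ν = 0.3; fat
  E = 9.4 kPa, ν = 0.48), a heterogeneous thin-plate solver for transverse
  pinch-like loading, von Mises fields
  (σ_vm = √(σxx² − σxx σyy + σyy² + 3σxy²)), line profiles,
  patterned-vs-unpatterned stress-concentration ratios, and nested
  mesh-independence studies (`solve_plane_stress()`, `solve_transverse()`,
  `stress_concentration_ratio()`, `mesh_convergence()`).
* **Cohesive-zone fracture** — a quasi-static spring-lattice simulator
  with bilinear traction–separation laws on walls and junctions and
  non-failing lipid spokes, driven in pinch, opening (mode I) or tearing
  (mode III) kinematics, with deterministic failure cascades, event logs
  and a step-by-step energy audit (`build_spring_lattice()`,
  `simulate_quasistatic()`, `compare_modes()`, `energy_audit()`).
* **Sawtooth curve analysis** — thickness normalisation, prominence-based
  peak calling, interval extraction, decomposition of intervals into
  a·L_long + b·L_short, an exactly calibrated Monte-Carlo discreteness
  test, Marko–Siggia worm-like-chain fitting and sawtooth/smooth
  classification (`detect_peaks()`, `decompose_interval()`,
  `discreteness_test()`, `fit_wlc()`, `classify_curve()`).
* **Synthetic data** — seeded generators for sawtooth and worm-like-chain
  curves with ground truth, and a self-labelling fixture suite
  (`gen_sawtooth_curve()`, `gen_wlc_curve()`, `gen_fixture_suite()`),
  plus a YAML-configured pipeline (`run_pipeline()`) and a thin command
  line front end in `inst/scripts/fracture-lattice.R`.

## Worked example: tearing a lattice and reading the sawtooth

```r
library(fracturelattice)

spec <- lattice_spec(sheet_width = 8, sheet_height = 4)
spec
#> Honeycomb lattice spec
#>   sheet: 8.000 x 4.000 mm
#>   cell diagonals: 0.674 (long, x) / 0.340 (short, y) mm
#>   edge lengths: 0.3097 (long) / 0.1562 (short) mm
#>   collagen wall thickness: 0.075 mm

lat <- build_spring_lattice(spec)
res <- simulate_quasistatic(lat, "pinch")
res
#> mode_result (pinch): peak propagation force 3.096 N/mm, 66 failure events
```

Every failure event is a collagen wall or junction — lipid never fails —
and the curve is a sawtooth whose intervals are wall lengths:

```r
pk <- detect_peaks(res$curve, min_spacing = spec$edge_lengths["short"] / 2)
iv <- extract_intervals(pk, res$curve)
round(head(iv, 5), 4)
#> [1] 0.3125 0.1562 0.3086 0.1562 0.3086

decompose_interval(iv[2], spec$edge_lengths["long"], spec$edge_lengths["short"],
                   tol = res$increment)
#> 0.1562 mm ~ 0 x 0.31 + 1 x 0.156 (residual +0 mm) -> decomposable

discreteness_test(iv, spec$edge_lengths["long"], spec$edge_lengths["short"],
                  seed = 1)
#> Interval discreteness test: mean residual 0.0005528 mm, p = 0.005
#> (199 Monte-Carlo draws, seed 1)
```

The peak force of ~3 N/mm is the calibrated tearing strength scale; the
p-value of 0.005 (the smallest attainable with 199 draws) says the
intervals sit on the combination lattice far more tightly than uniform
spacings would. The energy budget closes and opening-mode propagation
needs far more force than tearing, as in the experiments:

```r
energy_audit(res)
#> work 3.992, dissipated 3.988 N mm; max step imbalance 0.085% of work

cm <- compare_modes(lat, precrack = 1)
#> opening peak 87.21 N/mm vs tearing peak 3.10 N/mm
```

For the stress side, `run_pipeline()` reproduces the transverse
concentration study: with the pattern present, the maximum von Mises
stress sits on a collagen wall and exceeds the maximum of the wall-free
(pattern-ablated) sheet about 5.7-fold — the stress-redirection effect
that primes the walls for crack initiation:

```r
rep <- run_pipeline(stages = "stress")
rep$stress
#> $uniform_stress_check   TRUE
#> $max_vm_patterned_kpa   15.2
#> $max_vm_unpatterned_kpa 2.69
#> $concentration_ratio    5.67
```

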