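# Shared small fixtures. Everything is generated in code; nothing is read
# from disk.

paper_spec <- function(wall = 0.075)
  lattice_spec(59.701, 39.442, 0.674, 0.34, boundary_thickness = wall)

small_spec <- function(w = 6, h = 3, wall = 0.075)
  lattice_spec(w, h, 0.674, 0.34, boundary_thickness = wall)

# single interior cell window around the sheet-centre hexagon
one_cell_window <- function(spec) {
  g <- spec$geom
  o <- spec$origin_offset
  c(o[1] - g$c - 0.01, o[1] + g$c + 0.01,
    o[2] - g$b - 0.01, o[2] + g$b + 0.01)
}

equal_materials <- function(E = 92.2, nu = 0.3)
  list(collagen = material_props(E, nu), lipid = material_props(E, nu))

# independent exhaustive minimiser used as the decomposition oracle
oracle_decompose <- function(delta, L_long, L_short, max_count) {
  best <- c(a = NA, b = NA, resid = Inf)
  for (a in 0:max_count) for (b in 0:max_count) {
    if (a + b < 1) next
    r <- delta - a * L_long - b * L_short
    if (abs(r) < abs(best["resid"])) best <- c(a = a, b = b, resid = r)
  }
  best
}
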