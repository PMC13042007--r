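#' Rasterised collagen/lipid material map of a honeycomb sheet
#'
#' Labels every pixel of the sheet as collagen (wall), lipid (cell interior)
#' or void. A pixel is collagen when its centre lies within half the wall
#' thickness of a wall centreline. Pixel centres sit at `(i - 0.5) * pitch`
#' with the origin at the sheet's lower-left corner.
#'
#' @param spec A [lattice_spec()].
#' @param pitch Pixel size in mm. Must satisfy `pitch <= boundary_thickness/2`
#'   so that walls span at least two pixels (unless `suppress_walls`).
#' @param suppress_walls If `TRUE`, the zero-thickness wall limit: every pixel
#'   is lipid and the wall raster is empty.
#' @return An object of class `material_field`: integer label grid
#'   (`0` void, `1` collagen, `2` lipid) plus per-pixel host-cell lattice
#'   coordinates, pitch and provenance.
#' @export
build_honeycomb_map <- function(spec, pitch, suppress_walls = FALSE) {
  stopifnot(inherits(spec, "lattice_spec"), pitch > 0)
  if (!suppress_walls && pitch > spec$boundary_thickness / 2)
    stop(sprintf(paste0("pitch %.4g mm too coarse to resolve %.4g mm walls; ",
                        "need pitch <= boundary_thickness/2 = %.4g mm"),
                 pitch, spec$boundary_thickness, spec$boundary_thickness / 2))
  nx <- max(1L, round(spec$sheet_width / pitch))
  ny <- max(1L, round(spec$sheet_height / pitch))
  xs <- (seq_len(nx) - 0.5) * pitch
  ys <- (seq_len(ny) - 0.5) * pitch
  grid <- matrix(2L, nx, ny)
  cell_m <- matrix(NA_integer_, nx, ny)
  cell_n <- matrix(NA_integer_, nx, ny)
  half_wall <- if (suppress_walls) -1 else spec$boundary_thickness / 2
  # process in column blocks to bound temporary memory
  block <- max(1L, floor(4e5 / nx))
  j0 <- 1L
  while (j0 <= ny) {
    j1 <- min(ny, j0 + block - 1L)
    jj <- j0:j1
    px <- rep(xs, times = length(jj))
    py <- rep(ys[jj], each = nx)
    loc <- locate_pixels(spec, px, py)
    if (!suppress_walls)
      grid[, jj] <- ifelse(loc$wall_dist <= half_wall, 1L, 2L)
    cell_m[, jj] <- loc$m
    cell_n[, jj] <- loc$n
    j0 <- j1 + 1L
  }
  structure(list(grid = grid, pitch = pitch, nx = nx, ny = ny,
                 xs = xs, ys = ys, spec = spec, defect = NULL,
                 cell_m = cell_m, cell_n = cell_n),
            class = "material_field")
}

# For arbitrary points: host hexagon lattice coordinates (m, n) and distance
# to the nearest wall centreline. Candidate hexagons are the four floor/ceil
# combinations of the real-valued lattice coordinates; the host is always
# among them because |m - m_host| < 1 for points inside a hexagon.
# With track_edges = TRUE also returns a canonical key of the nearest wall
# segment (its rounded global endpoints), used to pool pixels per segment.
locate_pixels <- function(spec, px, py, track_edges = FALSE) {
  g <- spec$geom
  o <- spec$origin_offset
  dx <- px - o[1]; dy <- py - o[2]
  mr <- dx / (2 * g$t1[1]) + dy / (2 * g$b)
  nr <- dx / (2 * g$t1[1]) - dy / (2 * g$b)
  mf <- floor(mr); nf <- floor(nr)
  npt <- length(px)
  best_m <- integer(npt); best_n <- integer(npt)
  found <- logical(npt)
  wall_d2 <- rep(Inf, npt)
  if (track_edges) {
    ex1 <- ey1 <- ex2 <- ey2 <- numeric(npt)
  }
  i1 <- 1:6; i2 <- c(2:6, 1)
  eps <- 1e-9
  for (dm in 0:1) for (dn in 0:1) {
    M <- mf + dm; N <- nf + dn
    cx <- o[1] + (M + N) * g$t1[1]
    cy <- o[2] + (M - N) * g$b
    lx <- px - cx; ly <- py - cy
    inside <- abs(ly) <= g$b + eps &
      g$b * abs(lx) + (g$c - g$a) * abs(ly) <= g$b * g$c + eps
    new <- inside & !found
    best_m[new] <- M[new]; best_n[new] <- N[new]
    found <- found | inside
    for (e in 1:6) {
      p1x <- g$vx[i1[e]]; p1y <- g$vy[i1[e]]
      ex <- g$vx[i2[e]] - p1x; ey <- g$vy[i2[e]] - p1y
      L2 <- ex^2 + ey^2
      tt <- ((lx - p1x) * ex + (ly - p1y) * ey) / L2
      tt <- pmin(1, pmax(0, tt))
      d2 <- (lx - p1x - tt * ex)^2 + (ly - p1y - tt * ey)^2
      if (track_edges) {
        upd <- d2 < wall_d2
        if (any(upd)) {
          ex1[upd] <- cx[upd] + p1x; ey1[upd] <- cy[upd] + p1y
          ex2[upd] <- cx[upd] + g$vx[i2[e]]; ey2[upd] <- cy[upd] + g$vy[i2[e]]
        }
      }
      wall_d2 <- pmin(wall_d2, d2)
    }
  }
  out <- list(m = best_m, n = best_n, wall_dist = sqrt(wall_d2))
  if (track_edges) {
    swap <- (ex1 > ex2) | (ex1 == ex2 & ey1 > ey2)
    t1_ <- ex1[swap]; ex1[swap] <- ex2[swap]; ex2[swap] <- t1_
    t2_ <- ey1[swap]; ey1[swap] <- ey2[swap]; ey2[swap] <- t2_
    out$edge_key <- paste(round(ex1, 6), round(ey1, 6),
                          round(ex2, 6), round(ey2, 6))
  }
  out
}

label_names <- c("void", "collagen", "lipid")
label_code <- c(void = 0L, collagen = 1L, lipid = 2L)

#' Collagen area fraction of a material field
#' @param field A `material_field`.
#' @return Fraction of all pixels labelled collagen.
#' @export
collagen_area_fraction <- function(field) mean(field$grid == label_code["collagen"])

#' @export
print.material_field <- function(x, ...) {
  cat(sprintf("material_field: %d x %d pixels at %.4g mm (%.3f x %.3f mm)\n",
              x$nx, x$ny, x$pitch, x$nx * x$pitch, x$ny * x$pitch))
  tab <- table(factor(label_names[x$grid + 1L], levels = label_names))
  cat("  labels:", paste(sprintf("%s %.1f%%", names(tab),
                                 100 * tab / length(x$grid)), collapse = ", "),
      "\n")
  if (!is.null(x$defect))
    cat(sprintf("  defect: %s\n", x$defect$kind))
  invisible(x)
}

#' @export
plot.material_field <- function(x, ...) {
  graphics::image(x$xs, x$ys, x$grid, asp = 1, useRaster = TRUE,
                  col = c("white", "grey20", "lemonchiffon"),
                  breaks = c(-0.5, 0.5, 1.5, 2.5),
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

# Lattice coordinates of complete cells (hexagon + wall fully inside sheet).
complete_cells <- function(spec) {
  g <- spec$geom
  mar <- spec$boundary_thickness / 2
  ctr <- hex_centers_in(spec, c(0, spec$sheet_width), c(0, spec$sheet_height))
  keep <- ctr$cx - g$c - mar >= 0 & ctr$cx + g$c + mar <= spec$sheet_width &
    ctr$cy - g$b - mar >= 0 & ctr$cy + g$b + mar <= spec$sheet_height
  ctr[keep, , drop = FALSE]
}

cell_key <- function(m, n) (as.numeric(m) + 5e4) * 1e6 + (as.numeric(n) + 5e4)

#' Carve a wound defect into a material field
#'
#' A `cut_circle` defect removes every pixel inside the circle regardless of
#' label (a transgranular cut through cells and walls alike). A
#' `ripped_units` defect removes the lipid interiors of a seeded contiguous
#' set of whole cells, grown cell by cell from the cell containing the defect
#' centre, and never removes a collagen wall pixel (intergranular rupture).
#'
#' @param field A `material_field`.
#' @param defect A [defect_spec()].
#' @return The field with void pixels and the defect recorded in provenance.
#' @export
carve_defect <- function(field, defect) {
  stopifnot(inherits(field, "material_field"), inherits(defect, "defect_spec"))
  spec <- field$spec
  ctr <- defect$center
  if (is.null(ctr)) ctr <- c(spec$sheet_width / 2, spec$sheet_height / 2)
  if (defect$kind == "none") {
    field$defect <- defect
    return(field)
  }
  if (defect$kind == "cut_circle") {
    r <- defect$diameter / 2
    if (ctr[1] - r < 0 || ctr[1] + r > spec$sheet_width ||
        ctr[2] - r < 0 || ctr[2] + r > spec$sheet_height)
      stop("cut_circle defect does not fit inside the sheet")
    d2 <- outer((field$xs - ctr[1])^2, (field$ys - ctr[2])^2, `+`)
    field$grid[d2 <= r^2] <- label_code[["void"]]
  } else { # ripped_units
    if (defect$n_units == 0L) {
      field$defect <- defect
      return(field)
    }
    cells <- complete_cells(spec)
    if (defect$n_units > nrow(cells))
      stop(sprintf("n_units = %d exceeds the %d complete cells available",
                   defect$n_units, nrow(cells)))
    loc <- locate_pixels(spec, ctr[1], ctr[2])
    sel <- grow_cell_region(cells, c(loc$m, loc$n), defect$n_units,
                            defect$seed)
    insel <- matrix(cell_key(field$cell_m, field$cell_n) %in% sel,
                    field$nx, field$ny)
    field$grid[insel & field$grid == label_code[["lipid"]]] <-
      label_code[["void"]]
  }
  field$defect <- defect
  field
}

# Seeded breadth-first-style random growth over the cell adjacency graph
# (6 neighbours per hexagon). Returns keys of the selected cells.
grow_cell_region <- function(cells, start_mn, n_units, seed) {
  avail <- cell_key(cells$m, cells$n)
  start <- cell_key(start_mn[1], start_mn[2])
  if (!(start %in% avail))
    stop("defect centre does not lie in a complete cell")
  nb <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  sel <- start
  selm <- start_mn[1]; seln <- start_mn[2]
  with_seed(seed, {
    while (length(sel) < n_units) {
      fm <- rep(selm, each = 6) + nb[, 1]
      fn <- rep(seln, each = 6) + nb[, 2]
      fk <- cell_key(fm, fn)
      ok <- fk %in% avail & !(fk %in% sel)
      if (!any(ok))
        stop("ripped region cannot grow further; fewer complete cells than n_units")
      cand <- which(ok)
      pick <- cand[sample.int(length(cand), 1L)]
      sel <- c(sel, fk[pick])
      selm <- c(selm, fm[pick]); seln <- c(seln, fn[pick])
    }
  })
  sel
}

#' Write / read a material field as plain-text CSV
#'
#' The format is a commented header (`# key,value` lines holding pitch, grid
#' dimensions and provenance) followed by the integer label grid, one CSV row
#' per y-row from bottom to top.
#'
#' @param field A `material_field`.
#' @param path Output/input file path.
#' @return `read_material_csv` returns a `material_field` (provenance reduced
#'   to what the header stores); `write_material_csv` returns `path`.
#' @export
write_material_csv <- function(field, path) {
  hdr <- c("# fracturelattice material_field v1",
           sprintf("# pitch_mm,%.17g", field$pitch),
           sprintf("# nx,%d", field$nx),
           sprintf("# ny,%d", field$ny),
           sprintf("# labels,%s", paste(label_names, collapse = ";")),
           sprintf("# defect,%s", if (is.null(field$defect)) "none" else
             field$defect$kind))
  rows <- apply(field$grid, 2, paste, collapse = ",")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_material_csv
#' @export
read_material_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ","), hdr, value = TRUE)
    if (length(ln) != 1L) stop("missing header key: ", key)
    sub(paste0("^# ", key, ","), "", ln)
  }
  pitch <- as.numeric(getv("pitch_mm"))
  nx <- as.integer(getv("nx")); ny <- as.integer(getv("ny"))
  if (length(body) != ny) stop("grid row count does not match header ny")
  grid <- matrix(0L, nx, ny)
  for (j in seq_len(ny)) {
    v <- as.integer(strsplit(body[j], ",", fixed = TRUE)[[1]])
    if (length(v) != nx) stop(sprintf("row %d has %d values, expected %d",
                                      j, length(v), nx))
    grid[, j] <- v
  }
  structure(list(grid = grid, pitch = pitch, nx = nx, ny = ny,
                 xs = (seq_len(nx) - 0.5) * pitch,
                 ys = (seq_len(ny) - 0.5) * pitch,
                 spec = NULL, defect = NULL,
                 cell_m = NULL, cell_n = NULL),
            class = "material_field")
}

#' Export a material field as a legacy VTK structured-points file
#'
#' Cell data hold the integer material label; suitable for ParaView.
#' @param field A `material_field`.
#' @param path Output `.vtk` path.
#' @export
write_material_vtk <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fracturelattice material field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", field$nx + 1L, field$ny + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g 1", field$pitch, field$pitch),
               sprintf("CELL_DATA %d", field$nx * field$ny),
               "SCALARS material int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(field$grid), collapse = " "), con)
  invisible(path)
}
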