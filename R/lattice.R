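#' Hexagonal fracture-lattice specification
#'
#' Describes the periodic honeycomb tessellation of skin into lipid-filled
#' hexagonal cells bounded by thin collagen walls. Cells are elongated along
#' the body (x) axis: the long diagonal `d_long` runs along x, the short
#' diagonal `d_short` along y. The free shape parameter of the hexagon is
#' chosen so that the ratio of long to short edge lengths equals
#' `d_long / d_short`; each cell then has four long (slanted) and two short
#' (horizontal) boundary segments, the composition observed in spiny mouse
#' skin.
#'
#' @param sheet_width,sheet_height Sheet dimensions in mm.
#' @param d_long Long diagonal of a hexagonal cell (mm), along x.
#' @param d_short Short diagonal (mm), along y.
#' @param boundary_thickness Collagen wall thickness (mm).
#' @param origin_offset Numeric length-2: position of a hexagon centre (mm).
#'   Defaults to the sheet centre.
#' @return An object of class `lattice_spec`.
#' @examples
#' spec <- lattice_spec()
#' spec$edge_lengths
#' @export
lattice_spec <- function(sheet_width = 59.701, sheet_height = 39.442,
                         d_long = 0.674, d_short = 0.34,
                         boundary_thickness = 0.075,
                         origin_offset = c(sheet_width / 2, sheet_height / 2)) {
  stopifnot(is.numeric(d_long), is.numeric(d_short), length(d_long) == 1L)
  if (!(d_long > d_short && d_short > 0))
    stop("need d_long > d_short > 0")
  if (!(boundary_thickness > 0 && boundary_thickness < d_short / 2))
    stop("need 0 < boundary_thickness < d_short/2")
  if (!(sheet_width > d_long && sheet_height > d_long))
    stop("sheet must be larger than one cell")
  geom <- hex_geometry(d_long, d_short)
  structure(list(
    sheet_width = sheet_width, sheet_height = sheet_height,
    d_long = d_long, d_short = d_short,
    boundary_thickness = boundary_thickness,
    origin_offset = as.numeric(origin_offset),
    geom = geom,
    edge_lengths = c(long = geom$edge_long, short = geom$edge_short)
  ), class = "lattice_spec")
}

# Hexagon with vertices (+-c, 0), (+-a, +-b); c = d_long/2, b = d_short/2.
# The free half-width a of the two horizontal edges is fixed by requiring
# edge_long / edge_short = d_long / d_short, so one geometric factor maps
# diagonals to edge lengths for both classes.
hex_geometry <- function(d_long, d_short) {
  cc <- d_long / 2
  b <- d_short / 2
  rho <- d_long / d_short
  k <- 4 * rho^2 - 1
  a <- (-cc + sqrt(cc^2 + k * (cc^2 + b^2))) / k
  edge_short <- 2 * a
  edge_long <- sqrt((cc - a)^2 + b^2)
  list(a = a, b = b, c = cc,
       t1 = c(a + cc, b), t2 = c(a + cc, -b),
       edge_long = edge_long, edge_short = edge_short,
       # vertices counter-clockwise from (+c, 0)
       vx = c(cc, a, -a, -cc, -a, a),
       vy = c(0, b, b, 0, -b, -b))
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("Honeycomb lattice spec\n")
  cat(sprintf("  sheet: %.3f x %.3f mm\n", x$sheet_width, x$sheet_height))
  cat(sprintf("  cell diagonals: %.3f (long, x) / %.3f (short, y) mm\n",
              x$d_long, x$d_short))
  cat(sprintf("  edge lengths: %.4f (long) / %.4f (short) mm\n",
              x$edge_lengths["long"], x$edge_lengths["short"]))
  cat(sprintf("  collagen wall thickness: %.3f mm\n", x$boundary_thickness))
  invisible(x)
}

#' Wound-defect specification
#'
#' @param kind `"none"`, `"cut_circle"` (smooth circular excision cutting
#'   through cells, transgranular) or `"ripped_units"` (a contiguous set of
#'   whole cells whose lipid interiors are removed while the collagen walls
#'   survive, intergranular).
#' @param center Defect centre (mm).
#' @param diameter Circle diameter in mm (`cut_circle` only).
#' @param n_units Number of whole cells removed (`ripped_units` only).
#' @param seed Integer seed for the contiguous-region growth of a ripped wound.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(kind = c("none", "cut_circle", "ripped_units"),
                        center = NULL, diameter = 15, n_units = 254,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "cut_circle" && !(diameter > 0)) stop("diameter must be > 0")
  if (kind == "ripped_units" && n_units < 0) stop("n_units must be >= 0")
  structure(list(kind = kind, center = center, diameter = diameter,
                 n_units = as.integer(n_units), seed = as.integer(seed)),
            class = "defect_spec")
}

#' Simplified parallelogram unit cell for the crack-propagation model
#'
#' The skin's lipid clusters are idealised as parallelograms of side `L` and
#' internal angle `theta`, separated by lipid-rich seams of width `w`; a crack
#' advances along the collagen-lipid interface. The crack path is one zigzag
#' period: a segment of length `L` along the cluster side followed by a jog of
#' length `w` rotated by `theta - 90` degrees, so that `theta = 90` gives a
#' straight interface.
#'
#' @param L Parallelogram side length (mm).
#' @param w Lipid seam width (mm).
#' @param theta Internal angle of the parallelogram (degrees).
#' @param t Sheet thickness (mm).
#' @param a Initial (pre-)crack length along the path (mm).
#' @return An object of class `unit_cell_spec` with the crack path polyline
#'   and derived `path_length` and `ligament` (= path_length - a).
#' @export
build_unit_cell <- function(L, w, theta, t = 1.02, a = 0) {
  if (!(theta > 0 && theta < 180)) stop("need 0 < theta < 180")
  if (!(w > 0 && w < L)) stop("need 0 < w < L")
  if (a < 0) stop("need a >= 0")
  ang <- (theta - 90) * pi / 180
  path <- rbind(c(0, 0), c(L, 0), c(L + w * cos(ang), w * sin(ang)))
  path_length <- L + w
  if (a >= path_length) stop("pre-crack a exceeds the crack path length")
  structure(list(L = L, w = w, theta = theta, t = t, a = a,
                 crack_path = path, path_length = path_length,
                 ligament = path_length - a),
            class = "unit_cell_spec")
}

polyline_length <- function(p) {
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

# Hexagon centres covering a window, as integer lattice coordinates (m, n):
# centre = origin + m * t1 + n * t2.
hex_centers_in <- function(spec, xlim, ylim, margin = 0) {
  g <- spec$geom
  o <- spec$origin_offset
  span <- function(lim, half) c(lim[1] - half - margin, lim[2] + half + margin)
  # conservative m, n bounds from the corners of the window
  corners <- expand.grid(x = span(xlim, g$c), y = span(ylim, g$b))
  m <- (corners$x - o[1]) / (2 * g$t1[1]) + (corners$y - o[2]) / (2 * g$b)
  n <- (corners$x - o[1]) / (2 * g$t1[1]) - (corners$y - o[2]) / (2 * g$b)
  mn <- expand.grid(m = seq(floor(min(m)) - 1L, ceiling(max(m)) + 1L),
                    n = seq(floor(min(n)) - 1L, ceiling(max(n)) + 1L))
  cx <- o[1] + (mn$m + mn$n) * g$t1[1]
  cy <- o[2] + (mn$m - mn$n) * g$b
  keep <- cx >= xlim[1] - g$c - margin & cx <= xlim[2] + g$c + margin &
    cy >= ylim[1] - g$b - margin & cy <= ylim[2] + g$b + margin
  data.frame(m = mn$m[keep], n = mn$n[keep], cx = cx[keep], cy = cy[keep])
}

#' Enumerate boundary segments of the lattice
#'
#' Lists every collagen wall centreline edge once, classifies it as long or
#' short, and indexes the degree-3 junction vertices. Every complete interior
#' cell touches exactly four long and two short segments.
#'
#' @param spec A [lattice_spec()].
#' @param region Optional window `c(xmin, xmax, ymin, ymax)` (mm); segments are
#'   kept when their midpoint falls inside. Default: the whole sheet.
#' @param class_tol Relative tolerance for class assignment (default 0.15).
#' @return A data.frame of class `boundary_segments` with columns `id`, `x1`,
#'   `y1`, `x2`, `y2`, `length`, `klass`, `j1`, `j2` and an attribute
#'   `junctions` (data.frame of vertex coordinates).
#' @export
enumerate_boundary_segments <- function(spec, region = NULL, class_tol = 0.15) {
  if (is.null(region))
    region <- c(0, spec$sheet_width, 0, spec$sheet_height)
  xlim <- region[1:2]; ylim <- region[3:4]
  if (xlim[1] < 0 || xlim[2] > spec$sheet_width ||
      ylim[1] < 0 || ylim[2] > spec$sheet_height)
    stop("region must lie inside the sheet")
  g <- spec$geom
  ctr <- hex_centers_in(spec, xlim, ylim)
  if (nrow(ctr) == 0L) {
    out <- data.frame(id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), length = numeric(),
                      klass = character(), j1 = integer(), j2 = integer())
    attr(out, "junctions") <- data.frame(id = integer(), x = numeric(),
                                         y = numeric())
    class(out) <- c("boundary_segments", class(out))
    return(out)
  }
  # 6 edges per hexagon, vertices CCW
  i1 <- 1:6; i2 <- c(2:6, 1)
  nh <- nrow(ctr)
  x1 <- rep(ctr$cx, each = 6) + g$vx[i1]
  y1 <- rep(ctr$cy, each = 6) + g$vy[i1]
  x2 <- rep(ctr$cx, each = 6) + g$vx[i2]
  y2 <- rep(ctr$cy, each = 6) + g$vy[i2]
  # canonical orientation, then deduplicate shared edges
  swap <- (x1 > x2) | (x1 == x2 & y1 > y2)
  tx <- x1[swap]; x1[swap] <- x2[swap]; x2[swap] <- tx
  ty <- y1[swap]; y1[swap] <- y2[swap]; y2[swap] <- ty
  key <- paste(round(x1, 6), round(y1, 6), round(x2, 6), round(y2, 6))
  keep <- !duplicated(key)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
  inwin <- mx >= xlim[1] & mx <= xlim[2] & my >= ylim[1] & my <= ylim[2]
  x1 <- x1[inwin]; y1 <- y1[inwin]; x2 <- x2[inwin]; y2 <- y2[inwin]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  klass <- rep("other", length(len))
  klass[abs(len - g$edge_long) <= class_tol * g$edge_long] <- "long"
  klass[abs(len - g$edge_short) <= class_tol * g$edge_short] <- "short"
  # junction vertices
  vkey <- c(paste(round(x1, 6), round(y1, 6)), paste(round(x2, 6), round(y2, 6)))
  vx <- c(x1, x2); vy <- c(y1, y2)
  uidx <- !duplicated(vkey)
  jt <- data.frame(id = seq_len(sum(uidx)), x = vx[uidx], y = vy[uidx])
  jmap <- stats::setNames(jt$id, vkey[uidx])
  n <- length(x1)
  out <- data.frame(id = seq_len(n), x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                    length = len, klass = klass,
                    j1 = unname(jmap[paste(round(x1, 6), round(y1, 6))]),
                    j2 = unname(jmap[paste(round(x2, 6), round(y2, 6))]))
  attr(out, "junctions") <- jt
  class(out) <- c("boundary_segments", class(out))
  out
}
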