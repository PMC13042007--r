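#' Bilinear (triangular) cohesive traction-separation law
#'
#' Traction rises linearly at `initial_slope` to `peak_traction`, then
#' softens linearly to zero at `failure_separation`. The fracture energy per
#' unit interface area is `peak_traction * failure_separation / 2`.
#'
#' Cohesive parameters are not measured quantities here: defaults are a
#' calibration chosen so that a lattice of walls at the measured geometry
#' tears at the few-N/mm normalised forces observed for spiny mouse skin.
#'
#' @param peak_traction Peak traction (N/mm^2).
#' @param initial_slope Rising slope (N/mm^2 per mm of separation).
#' @param failure_separation Separation at complete failure (mm).
#' @return An object of class `cohesive_law`.
#' @export
cohesive_law <- function(peak_traction = 10, initial_slope = 500,
                         failure_separation = 0.1) {
  d1 <- peak_traction / initial_slope
  if (!(d1 < failure_separation))
    stop("peak must be reached before failure_separation ",
         "(peak_traction/initial_slope < failure_separation)")
  structure(list(peak_traction = peak_traction,
                 initial_slope = initial_slope,
                 failure_separation = failure_separation,
                 delta_peak = d1,
                 fracture_energy = 0.5 * peak_traction * failure_separation,
                 shape = "bilinear"),
            class = "cohesive_law")
}

#' @export
print.cohesive_law <- function(x, ...) {
  cat(sprintf(paste0("bilinear cohesive law: peak %.3g N/mm^2 at %.4g mm, ",
                     "failure at %.4g mm, Gc = %.4g N/mm\n"),
              x$peak_traction, x$delta_peak, x$failure_separation,
              x$fracture_energy))
  invisible(x)
}

# traction on the softening envelope at separation d (per unit area)
law_envelope <- function(law, d) {
  ifelse(d <= law$delta_peak, law$initial_slope * d,
         ifelse(d >= law$failure_separation, 0,
                law$peak_traction * (law$failure_separation - d) /
                  (law$failure_separation - law$delta_peak)))
}

# energy per unit area dissipated having reached max separation dmax
law_dissipated <- function(law, dmax) {
  d1 <- law$delta_peak
  if (dmax <= d1) return(0)
  if (dmax >= law$failure_separation) return(law$fracture_energy)
  Tm <- law_envelope(law, dmax)
  # area under envelope up to dmax minus recoverable secant energy
  0.5 * law$peak_traction * d1 +
    0.5 * (law$peak_traction + Tm) * (dmax - d1) - 0.5 * Tm * dmax
}

#' Default cohesive law set for walls and junctions
#'
#' Junctions (where three walls meet, built of perpendicularly arranged,
#' densely packed collagen) get a weaker, more brittle law: both peak
#' traction and failure separation scaled by `junction_factor`, encoding
#' their role as crack initiation points.
#'
#' @param junction_factor Strength/ductility scale for junction bonds
#'   (default 0.15).
#' @return Named list of [cohesive_law()] for classes `wall_long`,
#'   `wall_short`, `junction`.
#' @export
default_cohesive_laws <- function(junction_factor = 0.15) {
  wall <- cohesive_law()
  jn <- cohesive_law(peak_traction = wall$peak_traction * junction_factor,
                     initial_slope = wall$initial_slope,
                     failure_separation =
                       wall$failure_separation * junction_factor)
  list(wall_long = wall, wall_short = wall, junction = jn)
}

#' Build a cohesive spring lattice from the honeycomb geometry
#'
#' Nodes sit at wall junctions and cell centres. Wall segments become
#' cohesive bonds (interface area = segment length x sheet thickness),
#' junction vertices carry their own small cohesive element (area = wall
#' thickness x sheet thickness), and cell centres connect to their six
#' vertices by compliant, non-failing lipid spokes.
#'
#' @param spec A [lattice_spec()].
#' @param laws Cohesive laws per class (see [default_cohesive_laws()]);
#'   must cover `wall_long`, `wall_short` and `junction`.
#' @param materials Material set; lipid stiffness sets the spoke springs.
#' @param thickness Sheet thickness (mm).
#' @param region Optional window passed to [enumerate_boundary_segments()].
#' @return An object of class `spring_lattice`.
#' @export
build_spring_lattice <- function(spec, laws = default_cohesive_laws(),
                                 materials = default_materials(),
                                 thickness = 1.02, region = NULL) {
  for (cl in c("wall_long", "wall_short", "junction"))
    if (is.null(laws[[cl]]))
      stop("missing cohesive law for class ", cl)
  segs <- enumerate_boundary_segments(spec, region)
  if (nrow(segs) == 0L) stop("no boundary segments in region")
  jt <- attr(segs, "junctions")
  bonds <- data.frame(
    id = seq_len(nrow(segs)),
    n1 = segs$j1, n2 = segs$j2,
    klass = ifelse(segs$klass == "long", "wall_long",
                   ifelse(segs$klass == "short", "wall_short", "wall_long")),
    rest_length = segs$length,
    area = segs$length * thickness,
    stringsAsFactors = FALSE)
  # junction elements at interior (degree-3) vertices
  deg <- table(factor(c(segs$j1, segs$j2), levels = jt$id))
  jnodes <- jt$id[deg >= 3]
  if (length(jnodes)) {
    jb <- data.frame(
      id = max(bonds$id) + seq_along(jnodes),
      n1 = jnodes, n2 = jnodes,
      klass = "junction",
      rest_length = 0,
      area = spec$boundary_thickness * thickness,
      stringsAsFactors = FALSE)
    bonds <- rbind(bonds, jb)
  }
  # lipid spokes: cell centres to their 6 vertices
  ctr <- hex_centers_in(spec,
                        if (is.null(region)) c(0, spec$sheet_width)
                        else region[1:2],
                        if (is.null(region)) c(0, spec$sheet_height)
                        else region[3:4])
  g <- spec$geom
  E_lip <- materials$lipid$youngs_modulus / 1000  # kPa -> N/mm^2
  spokes <- NULL
  if (nrow(ctr)) {
    vkey <- paste(round(c(jt$x), 6), round(c(jt$y), 6))
    vmap <- stats::setNames(jt$id, vkey)
    cs <- lapply(seq_len(nrow(ctr)), function(i) {
      vx <- round(ctr$cx[i] + g$vx, 6); vy <- round(ctr$cy[i] + g$vy, 6)
      ids <- vmap[paste(vx, vy)]
      ok <- !is.na(ids)
      if (!any(ok)) return(NULL)
      data.frame(cell = i, vertex = unname(ids[ok]),
                 length = sqrt((ctr$cx[i] - jt$x[ids[ok]])^2 +
                                 (ctr$cy[i] - jt$y[ids[ok]])^2))
    })
    spokes <- do.call(rbind, cs)
    if (!is.null(spokes))
      spokes$stiffness <- E_lip * thickness * spokes$length /
        pmax(spokes$length, 1e-9)   # ~ E' t, breadth ~ length
  }
  structure(list(nodes = jt, bonds = bonds, spokes = spokes,
                 cells = ctr, laws = laws, thickness = thickness,
                 spec = spec),
            class = "spring_lattice")
}

#' @export
print.spring_lattice <- function(x, ...) {
  cat(sprintf("spring_lattice: %d nodes, %d cohesive bonds (%s), %d lipid spokes\n",
              nrow(x$nodes), nrow(x$bonds),
              paste(names(table(x$bonds$klass)),
                    table(x$bonds$klass), collapse = ", ", sep = ":"),
              if (is.null(x$spokes)) 0L else nrow(x$spokes)))
  invisible(x)
}

# Ordered tear path through wall bonds: walk junction-to-junction choosing,
# at each step, the unused wall whose far endpoint advances most in +x
# (ties by lowest bond id). Returns bond ids in tearing order.
tear_path <- function(lattice, start = NULL, min_x_margin = 0.3) {
  segs <- lattice$bonds[lattice$bonds$klass != "junction", ]
  jt <- lattice$nodes
  if (is.null(start)) {
    # start at the junction closest to the left-centre of the covered region
    sx <- min(jt$x); sy <- stats::median(jt$y)
    start <- jt$id[which.min((jt$x - sx)^2 + (jt$y - sy)^2)]
  }
  xmax <- max(jt$x) - min_x_margin
  used <- logical(nrow(segs))
  path <- integer()
  cur <- start
  repeat {
    inc <- which(!used & (segs$n1 == cur | segs$n2 == cur))
    if (!length(inc)) break
    far <- ifelse(segs$n1[inc] == cur, segs$n2[inc], segs$n1[inc])
    adv <- jt$x[far]
    best <- inc[order(-adv, segs$id[inc])][1]
    nxt <- ifelse(segs$n1[best] == cur, segs$n2[best], segs$n1[best])
    if (jt$x[nxt] <= jt$x[cur] - 1e-9) break  # refuse to walk backwards
    used[best] <- TRUE
    path <- c(path, segs$id[best])
    cur <- nxt
    if (jt$x[cur] >= xmax) break
  }
  path
}

#' Quasi-static displacement-controlled fracture simulation
#'
#' Drives the lattice through a displacement-controlled peel (pinch,
#' tearing) or opening-mode test. At each displacement increment the elastic
#' system is re-solved with secant stiffness for cohesive elements on their
#' softening branch; the most-overloaded element beyond its failure
#' separation fails (largest overshoot, ties by lowest bond id) and the
#' system is re-solved until no further state change, giving deterministic
#' cascades.
#'
#' Pinch and tearing are peel kinematics along a tear path: the pulled flap
#' lengthens by each failed wall's length (slack added to the flap springs),
#' so peak-to-peak displacement intervals reproduce wall-length
#' combinations. Junction elements sit at the path vertices and, being
#' weaker and more brittle, fail ahead of their wall -- crack initiation at
#' junctions. Opening loads the intact ligament bonds in parallel between
#' grips.
#'
#' @param lattice A `spring_lattice`.
#' @param loading `"pinch"`, `"opening"` or `"tearing"`.
#' @param precrack Pre-crack length (mm): path walls within this arc length
#'   are removed before loading (default 0 for pinch, 6 for opening/tearing
#'   per the fracture-test protocol).
#' @param max_displacement Control displacement to sweep (mm); default
#'   derived from the path length.
#' @param increment Displacement increment (mm); default one twentieth of
#'   the short edge length.
#' @param flap_stiffness Stiffness of the pulled flap / grip train (N/mm).
#' @param seed Unused placeholder for interface symmetry (the simulation is
#'   deterministic).
#' @return An object of class `mode_result`: the normalised
#'   force-displacement `curve` (`fd_curve`), the failure-event `log`, the
#'   per-step `energy` trace and `peak_propagation_force` (N/mm).
#' @export
simulate_quasistatic <- function(lattice, loading = c("pinch", "opening",
                                                      "tearing"),
                                 precrack = NULL, max_displacement = NULL,
                                 increment = NULL, flap_stiffness = 1e5,
                                 seed = NULL) {
  loading <- match.arg(loading)
  stopifnot(inherits(lattice, "spring_lattice"))
  if (is.null(precrack)) precrack <- if (loading == "pinch") 0 else 6
  g <- lattice$spec$geom
  if (is.null(increment)) increment <- g$edge_short / 40
  if (!(increment > 0)) stop("increment must be > 0")
  t <- lattice$thickness
  path <- tear_path(lattice)
  if (!length(path)) stop("no tear path found in lattice")
  pb <- lattice$bonds[match(path, lattice$bonds$id), ]
  cum <- cumsum(pb$rest_length)
  if (precrack >= sum(pb$rest_length) + 1e-9 &&
      loading != "opening")
    stop("precrack longer than the tear path")
  live <- cum > precrack
  pb <- pb[live, , drop = FALSE]
  if (nrow(pb) == 0L) stop("precrack removed the whole ligament")
  jn_all <- lattice$bonds[lattice$bonds$klass == "junction", ]
  if (loading == "opening") {
    res <- run_opening(lattice, pb, jn_all, increment, max_displacement,
                       flap_stiffness)
  } else {
    res <- run_peel(lattice, pb, jn_all, increment, max_displacement,
                    flap_stiffness)
  }
  curve <- fd_curve(res$u, res$F / t, thickness = t, normalized = TRUE,
                    metadata = list(mode = loading,
                                    increment = increment,
                                    precrack = precrack))
  log <- res$log
  structure(list(mode = loading,
                 peak_propagation_force = max(curve$force),
                 curve = curve, log = log, energy = res$energy,
                 increment = increment,
                 path_classes = pb$klass, path_lengths = pb$rest_length),
            class = "mode_result")
}

#' @export
print.mode_result <- function(x, ...) {
  cat(sprintf("mode_result (%s): peak propagation force %.4g N/mm, %d failure events\n",
              x$mode, x$peak_propagation_force, nrow(x$log)))
  invisible(x)
}

#' @export
plot.mode_result <- function(x, ...) {
  plot(x$curve, main = sprintf("%s mode", x$mode), ...)
  if (nrow(x$log))
    graphics::abline(v = x$log$displacement_mm, col = "grey80", lty = 3)
  invisible(x)
}

# shared bookkeeping for cohesive elements
new_coh_state <- function(ids, klass, lengths, areas, laws) {
  list(id = ids, klass = klass, len = lengths, area = areas,
       law = lapply(klass, function(k) laws[[k]]),
       dmax = numeric(length(ids)), failed = logical(length(ids)))
}

coh_secant <- function(st, i) {
  law <- st$law[[i]]
  if (st$failed[i]) return(0)
  if (st$dmax[i] <= law$delta_peak) return(law$initial_slope * st$area[i])
  Tm <- law_envelope(law, st$dmax[i])
  Tm * st$area[i] / st$dmax[i]
}

coh_dissipated <- function(st) {
  sum(vapply(seq_along(st$id), function(i) {
    law <- st$law[[i]]
    law_dissipated(law, if (st$failed[i]) law$failure_separation else
      st$dmax[i]) * st$area[i]
  }, 0))
}

# Peel model (pinch / tearing): chain nodes 1..N along the tear path; flap
# spring i (stiffness k_f, tension-only: the flap cannot push) connects node
# i-1 to node i and gains slack equal to wall i's length once wall i has
# failed, so the pull must advance by the peeled length before the next wall
# re-tensions -- the geometric origin of the sawtooth intervals. Wall and
# junction cohesive elements anchor node i; weak elastic lipid anchors
# release when the local wall fails. Control displacement at node 0.
run_peel <- function(lattice, pb, jn_all, increment, max_displacement,
                     k_f) {
  N <- nrow(pb)
  laws <- lattice$laws
  wall <- new_coh_state(pb$id, pb$klass, pb$rest_length, pb$area, laws)
  # one junction element per path node (the vertex the crack passes)
  jarea <- lattice$spec$boundary_thickness * lattice$thickness
  jn <- new_coh_state(max(lattice$bonds$id) + seq_len(N),
                      rep("junction", N), rep(0, N), rep(jarea, N), laws)
  k_lip <- if (is.null(lattice$spokes)) 0.01 else
    stats::median(lattice$spokes$stiffness) * 2
  k_reg <- 1e-8         # N/mm; keeps fully-detached nodes well-posed
  lip_on <- rep(TRUE, N)
  slack <- numeric(N)    # on flap spring i (node i-1 -- node i)
  # the flap transmits load only as far as the current tear front (the
  # first intact wall): the fracture process zone is one wall wide
  front <- function() {
    w <- which(!wall$failed)
    if (length(w)) w[1] else N
  }
  eng <- rep(TRUE, N)    # flap spring engagement (taut vs slack)
  if (is.null(max_displacement))
    max_displacement <- sum(pb$rest_length) +
      laws$wall_long$failure_separation * 3 + 0.5
  steps <- seq(increment, max_displacement, by = increment)
  Fout <- numeric(length(steps))
  events <- list()
  energy <- data.frame(step = seq_along(steps), work = NA_real_,
                       stored = NA_real_, dissipated = NA_real_)
  work <- 0
  Fprev <- 0
  p <- numeric(N)
  solve_chain <- function(u) {
    kw <- vapply(seq_len(N), function(i) coh_secant(wall, i), 0)
    kj <- vapply(seq_len(N), function(i) coh_secant(jn, i), 0)
    kanchor <- kw + kj + ifelse(lip_on, k_lip, 0) + k_reg
    ke <- ifelse(eng, k_f, 0)
    K <- matrix(0, N, N)
    f <- numeric(N)
    for (i in seq_len(N)) {
      K[i, i] <- K[i, i] + ke[i] + kanchor[i]
      if (i == 1L) f[i] <- f[i] + ke[1] * (u - slack[1])
      else {
        K[i - 1L, i - 1L] <- K[i - 1L, i - 1L] + ke[i]
        K[i, i - 1L] <- K[i, i - 1L] - ke[i]
        K[i - 1L, i] <- K[i - 1L, i] - ke[i]
        f[i] <- f[i] - ke[i] * slack[i]
        f[i - 1L] <- f[i - 1L] + ke[i] * slack[i]
      }
    }
    solve(K, f)
  }
  stretch_of <- function(u, p) {
    c(u - slack[1] - p[1],
      if (N > 1) p[-N] - p[-1] - slack[-1] else numeric())
  }
  for (si in seq_along(steps)) {
    u <- steps[si]
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 20L * (2L * N + 5L))
        stop("internal equilibration did not converge at step ", si)
      p <- solve_chain(u)
      # flap spring engagement: tension-only, and no load transfer beyond
      # the tear front
      s <- stretch_of(u, p)
      eng_new <- (s > -1e-9) & (seq_len(N) <= front())
      if (any(eng_new != eng)) {
        eng <- eng_new
        next
      }
      # update damage states; fail the single most-overloaded element
      cand_st <- character(); cand_i <- integer(); over <- numeric()
      newdam <- FALSE
      for (st_name in c("jn", "wall")) {
        st <- get(st_name)
        for (i in seq_len(N)) {
          if (st$failed[i]) next
          d <- max(0, p[i])
          law <- st$law[[i]]
          if (d > st$dmax[i] + 1e-12) {
            st$dmax[i] <- d
            newdam <- TRUE
          }
          if (st$dmax[i] >= law$failure_separation - 1e-12) {
            cand_st <- c(cand_st, st_name)
            cand_i <- c(cand_i, i)
            over <- c(over, st$dmax[i] / law$failure_separation)
          }
        }
        assign(st_name, st)
      }
      if (length(cand_i)) {
        ids <- ifelse(cand_st == "wall", wall$id[cand_i], jn$id[cand_i])
        k <- order(-over, ids)[1]
        idx <- cand_i[k]
        if (cand_st[k] == "wall") {
          wall$failed[idx] <- TRUE
          slack[idx] <- slack[idx] + wall$len[idx]
          lip_on[idx] <- FALSE
          ev_id <- wall$id[idx]; ev_k <- wall$klass[idx]
          ev_len <- wall$len[idx]
        } else {
          jn$failed[idx] <- TRUE
          ev_id <- jn$id[idx]; ev_k <- "junction"; ev_len <- 0
        }
        Fnow <- if (eng[1]) k_f * max(0, u - slack[1] - p[1]) else 0
        events[[length(events) + 1L]] <-
          data.frame(step = si, bond_id = ev_id, klass = ev_k,
                     rest_length_mm = ev_len, displacement_mm = u,
                     force_n_per_mm = Fnow / lattice$thickness)
        next
      }
      if (!newdam) break
    }
    s <- stretch_of(u, p)
    Fnow <- if (eng[1]) k_f * max(0, s[1]) else 0
    Fout[si] <- Fnow
    work <- work + 0.5 * (Fprev + Fnow) * increment
    Fprev <- Fnow
    kw <- vapply(seq_len(N), function(i) coh_secant(wall, i), 0)
    kj <- vapply(seq_len(N), function(i) coh_secant(jn, i), 0)
    stored <- 0.5 * k_f * sum(pmax(0, s[eng])^2) +
      0.5 * sum((kw + kj) * pmax(0, p)^2) +
      0.5 * sum((ifelse(lip_on, k_lip, 0) + k_reg) * p^2)
    energy$work[si] <- work
    energy$stored[si] <- stored
    energy$dissipated[si] <- coh_dissipated(wall) + coh_dissipated(jn)
    if (all(wall$failed)) {
      Fout <- Fout[seq_len(si)]
      energy <- energy[seq_len(si), ]
      steps <- steps[seq_len(si)]
      break
    }
  }
  list(u = c(0, steps), F = c(0, Fout),
       log = if (length(events)) do.call(rbind, events) else
         data.frame(step = integer(), bond_id = integer(),
                    klass = character(), rest_length_mm = numeric(),
                    displacement_mm = numeric(),
                    force_n_per_mm = numeric()),
       energy = energy)
}

# Opening mode: ligament bonds load in parallel between grips; a single
# free grip node connects to the control through the grip-train stiffness.
run_opening <- function(lattice, pb, jn_all, increment, max_displacement,
                        k_grip) {
  laws <- lattice$laws
  N <- nrow(pb)
  jarea <- lattice$spec$boundary_thickness * lattice$thickness
  st <- new_coh_state(c(pb$id, max(lattice$bonds$id) + seq_len(N)),
                      c(pb$klass, rep("junction", N)),
                      c(pb$rest_length, rep(0, N)),
                      c(pb$area, rep(jarea, N)), laws)
  M <- length(st$id)
  if (is.null(max_displacement))
    max_displacement <- laws$wall_long$failure_separation * 4
  steps <- seq(increment, max_displacement, by = increment)
  Fout <- numeric(length(steps))
  events <- list()
  energy <- data.frame(step = seq_along(steps), work = NA_real_,
                       stored = NA_real_, dissipated = NA_real_)
  work <- 0; Fprev <- 0
  for (si in seq_along(steps)) {
    u <- steps[si]
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 10L * (M + 5L))
        stop("internal equilibration did not converge at step ", si)
      ks <- vapply(seq_len(M), function(i) coh_secant(st, i), 0)
      ktot <- sum(ks)
      pg <- k_grip * u / (k_grip + ktot)
      newdam <- FALSE
      cand <- c(); ratio <- c()
      for (i in seq_len(M)) {
        if (st$failed[i]) next
        d <- max(0, pg)
        law <- st$law[[i]]
        if (d > st$dmax[i] + 1e-12) { st$dmax[i] <- d; newdam <- TRUE }
        if (st$dmax[i] >= law$failure_separation - 1e-12) {
          cand <- c(cand, i)
          ratio <- c(ratio, st$dmax[i] / law$failure_separation)
        }
      }
      if (length(cand)) {
        pick <- cand[order(-ratio, st$id[cand])][1]
        st$failed[pick] <- TRUE
        Fnow <- k_grip * (u - pg)
        events[[length(events) + 1L]] <-
          data.frame(step = si, bond_id = st$id[pick],
                     klass = st$klass[pick],
                     rest_length_mm = st$len[pick], displacement_mm = u,
                     force_n_per_mm = max(0, Fnow) / lattice$thickness)
        next
      }
      if (!newdam) break
    }
    ks <- vapply(seq_len(M), function(i) coh_secant(st, i), 0)
    ktot <- sum(ks)
    pg <- k_grip * u / (k_grip + ktot)
    Fnow <- k_grip * (u - pg)
    Fout[si] <- Fnow
    work <- work + 0.5 * (Fprev + Fnow) * increment
    Fprev <- Fnow
    energy$work[si] <- work
    energy$stored[si] <- 0.5 * k_grip * (u - pg)^2 + 0.5 * sum(ks) * pg^2
    energy$dissipated[si] <- coh_dissipated(st)
    if (all(st$failed)) {
      Fout <- Fout[seq_len(si)]; energy <- energy[seq_len(si), ]
      steps <- steps[seq_len(si)]
      break
    }
  }
  list(u = c(0, steps), F = c(0, Fout),
       log = if (length(events)) do.call(rbind, events) else
         data.frame(step = integer(), bond_id = integer(),
                    klass = character(), rest_length_mm = numeric(),
                    displacement_mm = numeric(),
                    force_n_per_mm = numeric()),
       energy = energy)
}

#' Compare opening- and tearing-mode strength
#'
#' Runs both crack-propagation modes on the same lattice with identical
#' cohesive parameters except the documented junction-adhesion reduction in
#' tearing (the perpendicular junction fibre arrangement resists opening
#' but shears easily along the crack front).
#'
#' @param lattice A `spring_lattice`.
#' @param junction_factor Junction adhesion scale used in tearing.
#' @param ... Passed to [simulate_quasistatic()].
#' @return List with elements `opening` and `tearing` (`mode_result`s) and
#'   `ordering_ok` (`TRUE` when opening strength strictly exceeds tearing).
#' @export
compare_modes <- function(lattice, junction_factor = 0.15, ...) {
  lat_open <- lattice
  lat_open$laws <- default_cohesive_laws(junction_factor = 1 - 1e-9)
  lat_open$laws$wall_long <- lattice$laws$wall_long
  lat_open$laws$wall_short <- lattice$laws$wall_short
  lat_open$laws$junction <- lattice$laws$wall_long
  lat_tear <- lattice
  lat_tear$laws <- lattice$laws
  lat_tear$laws$junction <- with(lattice$laws$wall_long, cohesive_law(
    peak_traction = peak_traction * junction_factor,
    initial_slope = initial_slope,
    failure_separation = failure_separation * junction_factor))
  opening <- simulate_quasistatic(lat_open, "opening", ...)
  tearing <- simulate_quasistatic(lat_tear, "tearing", ...)
  list(opening = opening, tearing = tearing,
       ordering_ok = opening$peak_propagation_force >
         tearing$peak_propagation_force)
}

#' Energy audit of a fracture simulation
#'
#' Work input (trapezoidal integral of force over displacement), stored
#' elastic energy and cohesive dissipation at the final state, and the
#' largest per-step imbalance of work = stored + dissipated.
#'
#' @param result A `mode_result`.
#' @return List with `work`, `stored`, `dissipated` (N mm per mm thickness
#'   scaled back to N mm), `max_residual_fraction` and `balanced`
#'   (residual < 1% of work at every recorded step).
#' @export
energy_audit <- function(result) {
  stopifnot(inherits(result, "mode_result"))
  en <- result$energy
  en <- en[!is.na(en$work), ]
  resid <- abs(en$work - en$stored - en$dissipated)
  # residual relative to the total work done (early steps have ~zero work)
  mrf <- max(resid) / max(en$work[nrow(en)], 1e-12)
  list(work = en$work[nrow(en)], stored = en$stored[nrow(en)],
       dissipated = en$dissipated[nrow(en)],
       max_residual_fraction = mrf,
       balanced = mrf < 0.01)
}
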