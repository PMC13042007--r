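#' Elastic material properties
#'
#' @param youngs_modulus Young's modulus in kPa.
#' @param poisson_ratio Poisson's ratio (0 <= nu < 0.5).
#' @param density Density in kg/m^3; stored for provenance, unused in the
#'   quasi-static solvers.
#' @return An object of class `material_props`.
#' @export
material_props <- function(youngs_modulus, poisson_ratio, density = NA_real_) {
  if (!(youngs_modulus > 0)) stop("youngs_modulus must be > 0")
  if (!(poisson_ratio >= 0 && poisson_ratio < 0.5))
    stop("poisson_ratio must be in [0, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio, density = density),
            class = "material_props")
}

#' Default material set: collagen walls and fat (lipid) interiors
#'
#' Collagen: E = 92.2 kPa, nu = 0.3, rho = 1120 kg/m^3. Fat: E = 9.4 kPa,
#' nu = 0.48, rho = 900 kg/m^3. The whole-skin tensile modulus preset
#' (644 kPa) is available via `homogeneous_skin_materials()`.
#' @return Named list of [material_props()] for labels `collagen` and `lipid`.
#' @export
default_materials <- function() {
  list(collagen = material_props(92.2, 0.3, 1120),
       lipid = material_props(9.4, 0.48, 900))
}

#' @rdname default_materials
#' @export
homogeneous_skin_materials <- function() {
  m <- material_props(644, 0.3)
  list(collagen = m, lipid = m)
}

#' Von Mises equivalent stress (plane stress)
#'
#' `sqrt(sxx^2 - sxx*syy + syy^2 + 3*sxy^2)`; vectorised.
#' @param sxx,syy,sxy In-plane stress components (kPa).
#' @return Von Mises stress (kPa).
#' @export
von_mises <- function(sxx, syy, sxy) {
  sqrt(pmax(0, sxx^2 - sxx * syy + syy^2 + 3 * sxy^2))
}

#' Triangulate a material field into a constant-strain-triangle mesh
#'
#' Each non-void pixel contributes two right triangles (diagonal from the
#' lower-left to the upper-right corner); void pixels are un-meshed. Nodes
#' shared between pixels are deduplicated and renumbered compactly.
#'
#' @param field A `material_field`.
#' @return An object of class `fem_mesh`: `nodes` (n x 2, mm), `tri`
#'   (m x 3 node indices, counter-clockwise), `mat` (label code per element),
#'   `pixel` (pixel linear index per element), node grid indices and pitch.
#' @export
triangulate <- function(field) {
  stopifnot(inherits(field, "material_field"))
  nx <- field$nx; ny <- field$ny; h <- field$pitch
  solid <- which(field$grid != label_code[["void"]])
  if (length(solid) == 0L) stop("all-void field cannot be meshed")
  pi_ <- ((solid - 1L) %% nx) + 1L    # pixel i (x index)
  pj <- ((solid - 1L) %/% nx) + 1L    # pixel j (y index)
  nxn <- nx + 1L
  bl <- pi_ + nxn * (pj - 1L)
  br <- bl + 1L
  tl <- bl + nxn
  tr <- tl + 1L
  mask <- logical(nxn * (ny + 1L))
  mask[bl] <- TRUE; mask[br] <- TRUE; mask[tl] <- TRUE; mask[tr] <- TRUE
  used <- which(mask)
  renum <- integer(nxn * (ny + 1L))
  renum[used] <- seq_along(used)
  tri <- rbind(cbind(renum[bl], renum[br], renum[tr]),   # orientation 1
               cbind(renum[bl], renum[tr], renum[tl]))   # orientation 2
  orient <- rep(1:2, each = length(solid))
  gi <- ((used - 1L) %% nxn)      # 0-based node grid x index
  gj <- ((used - 1L) %/% nxn)
  nodes <- cbind(gi * h, gj * h)
  structure(list(nodes = nodes, tri = tri, orient = orient,
                 mat = rep(field$grid[solid], 2L),
                 pixel = rep(solid, 2L),
                 node_gi = gi, node_gj = gj,
                 nx = nx, ny = ny, pitch = h),
            class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %d nodes, %d CST elements (pitch %.4g mm)\n",
              nrow(x$nodes), nrow(x$tri), x$pitch))
  invisible(x)
}

# CST shape-function gradient coefficients for the two right-triangle
# orientations on a pixel of side h: strains are
#   exx = sum b_i ux_i, eyy = sum c_i uy_i, gxy = sum (c_i ux_i + b_i uy_i).
cst_coeffs <- function(h) {
  list(list(b = c(-1, 1, 0) / h, c = c(0, -1, 1) / h),   # (bl, br, tr)
       list(b = c(0, 1, -1) / h, c = c(-1, 0, 1) / h))   # (bl, tr, tl)
}

plane_stress_C <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

# 6x6 element stiffness for one orientation/material (thickness 1).
cst_Ke <- function(h, E, nu, orient) {
  co <- cst_coeffs(h)[[orient]]
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- co$b
  B[2, c(2, 4, 6)] <- co$c
  B[3, c(1, 3, 5)] <- co$c
  B[3, c(2, 4, 6)] <- co$b
  (h^2 / 2) * t(B) %*% plane_stress_C(E, nu) %*% B
}

# Geometric nested-dissection elimination order for grid nodes: recursive
# coordinate bisection, children first, separator last. Keeps sparse Cholesky
# fill near-optimal on these structured meshes without external orderings.
nd_node_order <- function(gi, gj, leaf = 32L) {
  n <- length(gi)
  ord <- integer(n)
  pos <- 0L
  rec <- function(idx) {
    if (length(idx) <= leaf) {
      ord[pos + seq_along(idx)] <<- idx
      pos <<- pos + length(idx)
      return(invisible())
    }
    xr <- range(gi[idx]); yr <- range(gj[idx])
    if (diff(xr) >= diff(yr)) {
      mid <- (xr[1] + xr[2]) / 2; v <- gi[idx]
    } else {
      mid <- (yr[1] + yr[2]) / 2; v <- gj[idx]
    }
    sep <- abs(v - mid) < 0.51
    a <- idx[v < mid & !sep]
    b <- idx[v >= mid & !sep]
    s <- idx[sep]
    if (length(a)) rec(a)
    if (length(b)) rec(b)
    ord[pos + seq_along(s)] <<- s
    pos <<- pos + length(s)
    invisible()
  }
  rec(seq_len(n))
  ord
}

# Assemble the global symmetric stiffness matrix. Elements share one of a
# handful of stiffness matrices (orientation x material), so assembly places
# precomputed 6x6 entries at vectorised index patterns, chunked to bound
# transient memory. `node_pos` optionally renumbers nodes (elimination order)
# so the factorisation can run without further permutation.
assemble_K <- function(mesh, materials, node_pos = NULL, chunk = 1000000L) {
  ndof <- 2L * nrow(mesh$nodes)
  labs <- sort(unique(mesh$mat))
  Ke <- list()
  for (lb in labs) {
    mp <- materials[[label_names[lb + 1L]]]
    if (is.null(mp)) stop("no material for label ", label_names[lb + 1L])
    for (or in 1:2)
      Ke[[paste(lb, or)]] <- cst_Ke(mesh$pitch, mp$youngs_modulus,
                                    mp$poisson_ratio, or)
  }
  m <- nrow(mesh$tri)
  m2 <- m %/% 2L    # elements come as pixel-paired orientation blocks
  pair_chunk <- max(1L, chunk %/% 2L)
  nch <- ceiling(m2 / pair_chunk)
  ai <- aj <- ax <- vector("list", nch)
  for (ic in seq_len(nch)) {
    prng <- (((ic - 1L) * pair_chunk + 1L)):min(m2, ic * pair_chunk)
    idx <- c(prng, prng + m2)   # both triangles of each pixel together
    tri <- mesh$tri[idx, , drop = FALSE]
    if (!is.null(node_pos)) tri <- matrix(node_pos[tri], nrow(tri), 3)
    dof <- matrix(0L, length(idx), 6)
    dof[, c(1, 3, 5)] <- 2L * tri - 1L
    dof[, c(2, 4, 6)] <- 2L * tri
    rm(tri)
    gidx <- match(paste(mesh$mat[idx], mesh$orient[idx]), names(Ke))
    ii <- jj <- xx <- vector("list", 21L)
    k <- 1L
    for (a in 1:6) for (b in a:6) {
      if (a == b) {
        ii[[k]] <- dof[, a]; jj[[k]] <- dof[, a]
      } else {
        ii[[k]] <- pmin.int(dof[, a], dof[, b])
        jj[[k]] <- pmax.int(dof[, a], dof[, b])
      }
      xx[[k]] <- vapply(Ke, function(M) M[a, b], 0)[gidx]
      k <- k + 1L
    }
    rm(dof, gidx)
    # aggregate duplicates within the chunk; keep compact triplet arrays
    Kc <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                               dims = c(ndof, ndof), symmetric = TRUE)
    rm(ii, jj, xx)
    ai[[ic]] <- Kc@i + 1L
    aj[[ic]] <- rep.int(seq_len(ndof), diff(Kc@p))
    ax[[ic]] <- Kc@x
    rm(Kc); gc(FALSE)
  }
  # merge all chunk triplets into upper-triangular CSC storage directly:
  # radix sort by (column, row), sum consecutive duplicates, build slots.
  # This stays well below the memory of repeated sparse additions.
  tot <- sum(lengths(ai))
  ui <- integer(tot); uj <- integer(tot); ux <- numeric(tot)
  pos <- 0L
  for (ic in seq_len(nch)) {
    ln <- length(ai[[ic]])
    rng <- pos + seq_len(ln)
    ui[rng] <- ai[[ic]]; ai[[ic]] <- NA
    uj[rng] <- aj[[ic]]; aj[[ic]] <- NA
    ux[rng] <- ax[[ic]]; ax[[ic]] <- NA
    pos <- pos + ln
  }
  rm(ai, aj, ax); gc(FALSE)
  o <- order(uj, ui, method = "radix")
  ui <- ui[o]; gc(FALSE)
  uj <- uj[o]; gc(FALSE)
  ux <- ux[o]
  rm(o); gc(FALSE)
  first <- c(TRUE, diff(uj) != 0L | diff(ui) != 0L)
  # aggregate duplicate entries in blocks aligned to entry boundaries
  nuniq <- sum(first)
  xs <- numeric(nuniq)
  starts <- which(first)
  bs <- 16000000L
  done_u <- 0L
  pos <- 1L
  while (pos <= tot) {
    last_u <- min(nuniq, done_u + bs %/% 2L)
    end <- if (last_u == nuniq) tot else starts[last_u + 1L] - 1L
    rng <- pos:end
    g <- cumsum(first[rng])
    xs[done_u + seq_len(g[length(g)])] <-
      as.numeric(rowsum(ux[rng], g, reorder = FALSE))
    done_u <- done_u + g[length(g)]
    pos <- end + 1L
  }
  rm(ux); gc(FALSE)
  i0 <- ui[first] - 1L
  pj <- uj[first]
  rm(ui, uj, first, starts); gc(FALSE)
  p <- c(0L, cumsum(tabulate(pj, nbins = ndof)))
  rm(pj)
  methods::new("dsCMatrix", i = as.integer(i0), p = as.integer(p), x = xs,
               Dim = c(ndof, ndof), uplo = "U")
}

#' In-plane load cases
#'
#' `load_stretch_biaxial()` prescribes an outward normal displacement on each
#' external edge (the skin's intrinsic tension; the default 0.0674 mm is 10%
#' of the hexagon long diagonal), leaving tangential motion free.
#' `load_uniaxial_x()` prescribes `ux = 0` on the left edge and
#' `ux = strain * width` on the right edge, lateral edges free, with one
#' `uy` pin to remove the rigid-body mode.
#'
#' @param edge_displacement Outward normal displacement (mm) on each edge.
#' @param strain Nominal engineering strain along x.
#' @return An object of class `load_case`.
#' @export
load_stretch_biaxial <- function(edge_displacement = 0.1 * 0.674) {
  structure(list(kind = "in_plane_stretch", subtype = "biaxial",
                 edge_displacement = edge_displacement),
            class = "load_case")
}

#' @rdname load_stretch_biaxial
#' @export
load_uniaxial_x <- function(strain) {
  structure(list(kind = "in_plane_stretch", subtype = "uniaxial_x",
                 strain = strain), class = "load_case")
}

#' Transverse (pinch-like) load case
#'
#' A prescribed out-of-plane deflection on a small central patch with all
#' sheet edges clamped, the idealisation of pressing/pulling the skin
#' transversely at a point.
#'
#' @param center_deflection Imposed deflection at the centre (mm).
#' @param center Patch centre (mm); default sheet centre.
#' @param patch_radius Radius of the loaded patch (mm).
#' @return An object of class `load_case`.
#' @export
load_transverse_center <- function(center_deflection = 1,
                                   center = NULL, patch_radius = 0.15) {
  structure(list(kind = "transverse_center",
                 center_deflection = center_deflection, center = center,
                 patch_radius = patch_radius, clamped_edges = TRUE),
            class = "load_case")
}

# Dirichlet constraints (dof index -> value) for an in-plane load case.
plane_constraints <- function(mesh, load) {
  W <- mesh$nx * mesh$pitch; H <- mesh$ny * mesh$pitch
  left <- which(mesh$node_gi == 0L)
  right <- which(mesh$node_gi == mesh$nx)
  bottom <- which(mesh$node_gj == 0L)
  top <- which(mesh$node_gj == mesh$ny)
  if (load$subtype == "biaxial") {
    d <- load$edge_displacement
    dofs <- c(2 * left - 1, 2 * right - 1, 2 * bottom, 2 * top)
    vals <- c(rep(-d, length(left)), rep(d, length(right)),
              rep(-d, length(bottom)), rep(d, length(top)))
  } else if (load$subtype == "uniaxial_x") {
    pin <- left[which.min(mesh$node_gj[left])]
    dofs <- c(2 * left - 1, 2 * right - 1, 2 * pin)
    vals <- c(rep(0, length(left)), rep(load$strain * W, length(right)), 0)
  } else stop("unknown in-plane load subtype")
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], vals = vals[keep])
}

#' Solve static linear plane-stress elasticity on a triangulated field
#'
#' Assembles the constant-strain-triangle stiffness matrix, eliminates the
#' prescribed displacement constraints, solves the symmetric positive
#' definite system by sparse Cholesky factorisation, and post-processes
#' per-element stresses and the von Mises scalar.
#'
#' @param mesh A `fem_mesh` from [triangulate()].
#' @param materials Named list of [material_props()] keyed by label
#'   (see [default_materials()]).
#' @param load A `load_case` of kind `in_plane_stretch`.
#' @return An object of class `stress_field`: per-element `sigma_xx`,
#'   `sigma_yy`, `sigma_xy`, `von_mises` (kPa), per-node `displacement`
#'   (n x 2, mm), element centroids and labels, and the reaction forces at
#'   constrained dofs (kPa mm, per unit thickness).
#' @export
solve_plane_stress <- function(mesh, materials = default_materials(), load) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(load, "load_case"))
  if (load$kind != "in_plane_stretch")
    stop("solve_plane_stress handles in_plane_stretch load cases")
  con <- plane_constraints(mesh, load)
  out <- solve_fem(mesh, materials, con)
  post_stress(mesh, materials, out$u, con, out$reactions)
}

# Shared constrained solve: nested-dissection renumbering, permuted assembly,
# sparse Cholesky, displacement recovery and reactions. Reactions require
# keeping the assembled matrix through the factorisation; skipping them
# (want_reactions = FALSE) lowers the memory high-water mark on large models.
solve_fem <- function(mesh, materials, con, want_reactions = TRUE,
                      keep_factor = FALSE) {
  ndof <- 2L * nrow(mesh$nodes)
  nx_con <- sum(con$dofs %% 2 == 1)
  ny_con <- sum(con$dofs %% 2 == 0)
  if (nx_con == 0 || ny_con == 0 || (nx_con + ny_con) < 3)
    stop(sprintf("rigid-body modes unconstrained (%d constraint(s) given)",
                 length(con$dofs)))
  ordn <- nd_node_order(mesh$node_gi, mesh$node_gj)
  node_pos <- integer(length(ordn))
  node_pos[ordn] <- seq_along(ordn)
  K <- assemble_K(mesh, materials, node_pos = node_pos)
  pdof <- function(d) {
    node <- (d + 1) %/% 2          # never 0, so no silent index dropping
    2 * node_pos[node] - (d %% 2)
  }
  cdof <- pdof(con$dofs)
  u <- numeric(ndof)
  u[cdof] <- con$vals
  free <- which(!(seq_len(ndof) %in% cdof))
  rhs <- -as.numeric(K %*% u)[free]
  Kff <- Matrix::forceSymmetric(K[free, free], uplo = "U")
  if (!want_reactions) rm(K)
  gc(FALSE)
  ch <- tryCatch(Matrix::Cholesky(Kff, perm = FALSE, LDL = FALSE,
                                  super = TRUE),
                 error = function(e)
                   stop("singular system after constraint elimination: ",
                        conditionMessage(e)))
  rm(Kff); gc(FALSE)
  u[free] <- as.numeric(Matrix::solve(ch, rhs))
  reac <- if (want_reactions) as.numeric(K %*% u)[cdof] else
    rep(NA_real_, length(cdof))
  if (want_reactions) rm(K)
  gc(FALSE)
  # back to original node numbering
  uo <- numeric(ndof)
  uo[2 * seq_along(ordn) - 1] <- u[2 * node_pos - 1]
  uo[2 * seq_along(ordn)] <- u[2 * node_pos]
  out <- list(u = uo, reactions = reac)
  if (keep_factor) {
    # solve Kff x = b with b, x indexed by the original (unpermuted) free
    # dof order; used as a coarse-grid correction by the multilevel solver
    free_orig <- sort(setdiff(seq_len(ndof), con$dofs))
    pd <- pdof(free_orig)
    rk <- match(pd, sort(pd))
    force(ch)
    out$free_dofs <- free_orig
    out$solve_free <- function(b) {
      bp <- numeric(length(b))
      bp[rk] <- b
      as.numeric(Matrix::solve(ch, bp))[rk]
    }
  } else rm(ch)
  gc(FALSE)
  out
}

post_stress <- function(mesh, materials, u, con, reactions) {
  m <- nrow(mesh$tri)
  co <- cst_coeffs(mesh$pitch)
  sxx <- syy <- sxy <- numeric(m)
  for (or in 1:2) {
    sel <- which(mesh$orient == or)
    tri <- mesh$tri[sel, , drop = FALSE]
    ux <- matrix(u[2 * tri - 1], length(sel), 3)
    uy <- matrix(u[2 * tri], length(sel), 3)
    rm(tri)
    b <- co[[or]]$b; cc <- co[[or]]$c
    exx <- ux %*% b
    eyy <- uy %*% cc
    gxy <- ux %*% cc + uy %*% b
    rm(ux, uy)
    msel <- mesh$mat[sel]
    for (lb in unique(msel)) {
      mp <- materials[[label_names[lb + 1L]]]
      sub <- msel == lb
      sel2 <- sel[sub]
      C <- plane_stress_C(mp$youngs_modulus, mp$poisson_ratio)
      sxx[sel2] <- C[1, 1] * exx[sub] + C[1, 2] * eyy[sub]
      syy[sel2] <- C[2, 1] * exx[sub] + C[2, 2] * eyy[sub]
      sxy[sel2] <- C[3, 3] * gxy[sub]
    }
    rm(exx, eyy, gxy)
  }
  pi_ <- ((mesh$pixel - 1L) %% mesh$nx) + 1L
  pj <- ((mesh$pixel - 1L) %/% mesh$nx) + 1L
  h <- mesh$pitch
  cx <- (pi_ - 1L) * h + ifelse(mesh$orient == 1L, 2 * h / 3, h / 3)
  cy <- (pj - 1L) * h + ifelse(mesh$orient == 1L, h / 3, 2 * h / 3)
  structure(list(sigma_xx = sxx, sigma_yy = syy, sigma_xy = sxy,
                 von_mises = von_mises(sxx, syy, sxy),
                 displacement = cbind(u[seq(1, length(u), 2)],
                                      u[seq(2, length(u), 2)]),
                 centroid = cbind(cx, cy),
                 label = label_names[mesh$mat + 1L],
                 pixel = mesh$pixel, orient = mesh$orient,
                 nx = mesh$nx, ny = mesh$ny, pitch = h,
                 constrained_dofs = con$dofs, reactions = reactions,
                 solver = "plane_stress"),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("stress_field (%s): %d elements, pitch %.4g mm\n",
              x$solver, length(x$von_mises), x$pitch))
  cat(sprintf("  max von Mises: %.4g kPa (%s)\n", max(x$von_mises),
              x$label[which.max(x$von_mises)]))
  invisible(x)
}
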