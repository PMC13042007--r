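# Multilevel solver for large plane-stress systems: conjugate gradients
# preconditioned by a symmetrised two-grid V-cycle (damped-Jacobi smoothing
# plus a direct coarse-grid correction on a label-coarsened auxiliary field).
# Bounded memory: no fine-level factorisation is ever formed.

# Coarsen a material field by an integer factor: a coarse pixel is void only
# when all of its children are void; otherwise it takes the majority
# non-void label (ties resolved to collagen). Used only to build the
# auxiliary coarse operator of the multilevel solver.
coarsen_field <- function(field, factor = 4L) {
  f <- as.integer(factor)
  nxc <- as.integer(ceiling(field$nx / f))
  nyc <- as.integer(ceiling(field$ny / f))
  bi <- ((seq_len(field$nx) - 1L) %/% f) + 1L
  bj <- ((seq_len(field$ny) - 1L) %/% f) + 1L
  key <- rep(bi, times = field$ny) + nxc * (rep(bj, each = field$nx) - 1L)
  g <- as.vector(field$grid)
  ncol_ <- rowsum((g == 1L) + 0, key)
  nlip <- rowsum((g == 2L) + 0, key)
  lab <- ifelse(ncol_ + nlip == 0, 0L, ifelse(ncol_ >= nlip, 1L, 2L))
  out <- field
  out$grid <- matrix(as.integer(lab), nxc, nyc)
  out$nx <- nxc; out$ny <- nyc
  out$pitch <- field$pitch * f
  out$xs <- (seq_len(nxc) - 0.5) * out$pitch
  out$ys <- (seq_len(nyc) - 0.5) * out$pitch
  out$cell_m <- out$cell_n <- NULL
  out
}

# Node-level bilinear prolongation from a coarse node grid (spacing `f` fine
# cells) to the fine node grid. Both meshes come from nested/aligned rasters,
# so every fine node's parents exist on the coarse mesh.
build_prolongation <- function(mesh_f, mesh_c, f) {
  lookup_c <- integer((mesh_c$nx + 1L) * (mesh_c$ny + 1L))
  lookup_c[mesh_c$node_gi + (mesh_c$nx + 1L) * mesh_c$node_gj + 1L] <-
    seq_len(nrow(mesh_c$nodes))
  gi <- mesh_f$node_gi; gj <- mesh_f$node_gj
  n <- length(gi)
  ii <- jj <- xx <- vector("list", 4L)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) {
    px <- gi %/% f + dx
    py <- gj %/% f + dy
    wx <- if (dx == 0) 1 - (gi %% f) / f else (gi %% f) / f
    wy <- if (dy == 0) 1 - (gj %% f) / f else (gj %% f) / f
    w <- wx * wy
    sel <- which(w > 0 & px <= mesh_c$nx & py <= mesh_c$ny)
    cid <- lookup_c[px[sel] + (mesh_c$nx + 1L) * py[sel] + 1L]
    ok <- cid > 0L
    k <- k + 1L
    ii[[k]] <- sel[ok]; jj[[k]] <- cid[ok]; xx[[k]] <- w[sel][ok]
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, nrow(mesh_c$nodes)))
  # renormalise rows whose parents were partially absent (void regions,
  # partial edge blocks) by a cheap diagonal scaling
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-12 & rs > 0))
    P <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% P
  P
}

# Conjugate-gradient solve of the biaxial/quadrant stretch problem on a
# large field. `quadrant_bc` as in solve_biaxial(). Relative residual
# tolerance 1e-10; errors out if not reached.
pcg_solve_biaxial <- function(field, materials, edge_displacement,
                              quadrant_bc = FALSE, coarsen = 8L,
                              tol = 1e-10, maxit = 2000L, quiet = TRUE) {
  note <- function(...) if (!quiet)
    message(sprintf("  [pcg] %s (mem %.0f MB)", sprintf(...), sum(gc(FALSE)[, 2])))
  mesh <- triangulate(field)
  con <- biaxial_constraints(mesh, edge_displacement, quadrant_bc)
  ndof <- 2L * nrow(mesh$nodes)
  note("mesh %d dof", ndof)
  K <- assemble_K(mesh, materials)
  note("assembled")
  u <- numeric(ndof)
  u[con$dofs] <- con$vals
  isfree <- rep(TRUE, ndof); isfree[con$dofs] <- FALSE
  free <- which(isfree)
  rhs <- -as.numeric(K %*% u)[free]
  # auxiliary coarse level: same loading, direct solve with kept factor
  fc <- coarsen_field(field, coarsen)
  mesh_c <- triangulate(fc)
  con_c <- biaxial_constraints(mesh_c, edge_displacement, quadrant_bc)
  sol_c <- solve_fem(mesh_c, materials, con_c, want_reactions = FALSE,
                     keep_factor = TRUE)
  note("coarse factor ready")
  P <- build_prolongation(mesh, mesh_c, coarsen)
  note("prolongation built")
  nnode_c <- nrow(mesh_c$nodes)
  isfree_c <- rep(TRUE, 2L * nnode_c); isfree_c[con_c$dofs] <- FALSE
  # initial guess: prolongated coarse solution (constrained dofs exact)
  ucx <- sol_c$u[seq(1, 2 * nnode_c, 2)]
  ucy <- sol_c$u[seq(2, 2 * nnode_c, 2)]
  u0 <- numeric(ndof)
  u0[seq(1, ndof, 2)] <- as.numeric(P %*% ucx)
  u0[seq(2, ndof, 2)] <- as.numeric(P %*% ucy)
  x <- u0[free]
  coarse_corr <- function(r_free) {
    rf <- numeric(ndof); rf[free] <- r_free
    rx <- as.numeric(Matrix::crossprod(P, rf[seq(1, ndof, 2)]))
    ry <- as.numeric(Matrix::crossprod(P, rf[seq(2, ndof, 2)]))
    bc <- numeric(2L * nnode_c)
    bc[seq(1, 2 * nnode_c, 2)] <- rx
    bc[seq(2, 2 * nnode_c, 2)] <- ry
    xc <- numeric(2L * nnode_c)
    xc[isfree_c] <- sol_c$solve_free(bc[isfree_c])
    vx <- as.numeric(P %*% xc[seq(1, 2 * nnode_c, 2)])
    vy <- as.numeric(P %*% xc[seq(2, 2 * nnode_c, 2)])
    vf <- numeric(ndof)
    vf[seq(1, ndof, 2)] <- vx
    vf[seq(2, ndof, 2)] <- vy
    vf[free]
  }
  dK <- Matrix::diag(K)[free]
  omega <- 0.6
  Kmul <- function(v) {
    vf <- numeric(ndof); vf[free] <- v
    as.numeric(K %*% vf)[free]
  }
  prec <- function(r) {
    v <- omega * r / dK
    r2 <- r - Kmul(v)
    v <- v + coarse_corr(r2)
    r3 <- r - Kmul(v)
    v + omega * r3 / dK
  }
  bnorm <- sqrt(sum(rhs^2))
  r <- rhs - Kmul(x)
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Ap <- Kmul(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2))
    if (!quiet && it %% 10 == 0)
      message(sprintf("  pcg iter %d rel resid %.3e", it, rn / bnorm))
    if (rn / bnorm <= tol) break
    if (it >= maxit)
      stop(sprintf("pcg failed to reach %.1e (got %.2e in %d iterations)",
                   tol, rn / bnorm, it))
    z <- prec(r)
    rz2 <- sum(r * z)
    beta <- rz2 / rz
    rz <- rz2
    p <- z + beta * p
  }
  u[free] <- x
  rm(K, P, sol_c, mesh_c, x, r, z, p, rhs, dK); gc(FALSE)
  sf <- post_stress(mesh, materials, u, con,
                    rep(NA_real_, length(con$dofs)))
  attr(sf, "pcg_iterations") <- it
  sf
}

# Dirichlet constraints for the biaxial stretch on the full sheet or the
# symmetric quadrant.
biaxial_constraints <- function(mesh, d, quadrant_bc) {
  left <- which(mesh$node_gi == 0L)
  right <- which(mesh$node_gi == mesh$nx)
  bottom <- which(mesh$node_gj == 0L)
  top <- which(mesh$node_gj == mesh$ny)
  dofs <- c(2 * left - 1, 2 * right - 1, 2 * bottom, 2 * top)
  if (quadrant_bc) {
    vals <- c(rep(0, length(left)), rep(d, length(right)),
              rep(0, length(bottom)), rep(d, length(top)))
  } else {
    vals <- c(rep(-d, length(left)), rep(d, length(right)),
              rep(-d, length(bottom)), rep(d, length(top)))
  }
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], vals = vals[keep])
}
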