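#' Transverse (pinch-like) loading of a heterogeneous sheet
#'
#' Solves Kirchhoff-Love thin-plate bending with spatially varying flexural
#' rigidity `D = E t^3 / (12 (1 - nu^2))` on the pixel grid by finite
#' differences, with all sheet edges clamped and a prescribed deflection on a
#' small central patch -- the idealisation of pressing or pulling the skin
#' out of plane at a point, as in a pinch load. Surface bending stresses at
#' `z = t/2` and their von Mises scalar are reported per grid node.
#'
#' The discrete operator is assembled from the plate strain energy
#' `U = 1/2 D [w_xx^2 + w_yy^2 + 2 nu w_xx w_yy + 2 (1 - nu) w_xy^2]`
#' evaluated with central differences at every interior node, which yields a
#' symmetric positive semi-definite stiffness; clamping (two boundary node
#' rings at w = 0) removes the kernel.
#'
#' @param field A `material_field` (voids are allowed but carry no stiffness;
#'   the loaded centre must not be void).
#' @param materials Named list of [material_props()] per label.
#' @param load A [load_transverse_center()] load case.
#' @param thickness Plate thickness in mm (default 1.02, the mean measured
#'   skin thickness).
#' @return A `stress_field` (solver `"plate"`) with per-node surface
#'   stresses, von Mises scalar, deflection and material label.
#' @export
solve_transverse <- function(field, materials = default_materials(), load,
                             thickness = 1.02) {
  stopifnot(inherits(field, "material_field"), inherits(load, "load_case"))
  if (load$kind != "transverse_center")
    stop("solve_transverse handles transverse_center load cases")
  if (!isTRUE(load$clamped_edges))
    stop("the transverse model requires clamped edges")
  nx <- field$nx; ny <- field$ny; h <- field$pitch
  n <- nx * ny
  ctr <- load$center
  if (is.null(ctr)) ctr <- c(nx * h / 2, ny * h / 2)
  ci <- pmin(nx, pmax(1L, ceiling(ctr[1] / h)))
  cj <- pmin(ny, pmax(1L, ceiling(ctr[2] / h)))
  if (field$grid[ci, cj] == label_code[["void"]])
    stop("load centre lies on a void pixel")
  lab <- as.vector(field$grid)
  E <- nu <- numeric(n)
  for (lb in unique(lab)) {
    nm <- label_names[lb + 1L]
    if (nm == "void") next
    mp <- materials[[nm]]
    if (is.null(mp)) stop("no material for label ", nm)
    E[lab == lb] <- mp$youngs_modulus
    nu[lab == lb] <- mp$poisson_ratio
  }
  D <- E * thickness^3 / (12 * (1 - nu^2))
  # second-derivative operators on the node grid (zero rows at the frame)
  Txx <- band_op(nx, c(1, -2, 1) / h^2, half = 1L)
  Tyy <- band_op(ny, c(1, -2, 1) / h^2, half = 1L)
  Tx1 <- band_op(nx, c(-1, 0, 1) / (2 * h), half = 1L)
  Ty1 <- band_op(ny, c(-1, 0, 1) / (2 * h), half = 1L)
  Ix <- Matrix::Diagonal(nx); Iy <- Matrix::Diagonal(ny)
  Axx <- Matrix::kronecker(Iy, Txx)
  Ayy <- Matrix::kronecker(Tyy, Ix)
  Axy <- Matrix::kronecker(Ty1, Tx1)
  w1 <- D * h^2
  wn <- nu * D * h^2
  wg <- 2 * (1 - nu) * D * h^2
  K <- Matrix::t(Axx) %*% (w1 * Axx) + Matrix::t(Ayy) %*% (w1 * Ayy) +
    Matrix::t(Axx) %*% (wn * Ayy) + Matrix::t(Ayy) %*% (wn * Axx) +
    Matrix::t(Axy) %*% (wg * Axy)
  # constraints: two clamped boundary rings, the loaded patch, void nodes
  gi <- rep(seq_len(nx), times = ny)
  gj <- rep(seq_len(ny), each = nx)
  ring <- gi <= 2L | gi >= nx - 1L | gj <= 2L | gj >= ny - 1L
  xs <- (gi - 0.5) * h; ys <- (gj - 0.5) * h
  patch <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= load$patch_radius^2
  if (!any(patch)) patch[ci + nx * (cj - 1L)] <- TRUE
  void <- lab == label_code[["void"]]
  fixed <- ring | patch | void
  wvals <- numeric(n)
  wvals[patch & !ring & !void] <- load$center_deflection
  free <- which(!fixed)
  w <- wvals
  rhs <- -as.numeric(K %*% w)[free]
  Kff <- Matrix::forceSymmetric(K[free, free], uplo = "U")
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("singular plate operator: ", conditionMessage(e)))
  w[free] <- as.numeric(Matrix::solve(ch, rhs))
  rm(Kff, ch); gc(FALSE)
  # surface bending stresses (magnitude at z = t/2), kPa
  wxx <- as.numeric(Axx %*% w)
  wyy <- as.numeric(Ayy %*% w)
  wxy <- as.numeric(Axy %*% w)
  fac <- E * thickness / (2 * (1 - nu^2))
  sxx <- fac * (wxx + nu * wyy)
  syy <- fac * (wyy + nu * wxx)
  sxy <- E * thickness / (2 * (1 + nu)) * wxy
  vm <- von_mises(sxx, syy, sxy)
  vm[void] <- 0
  structure(list(sigma_xx = sxx, sigma_yy = syy, sigma_xy = sxy,
                 von_mises = vm,
                 displacement = cbind(w, 0),
                 deflection = w,
                 centroid = cbind(xs, ys),
                 label = label_names[lab + 1L],
                 pixel = seq_len(n), orient = rep(1L, n),
                 nx = nx, ny = ny, pitch = h,
                 constrained_dofs = which(fixed), reactions = NULL,
                 solver = "plate"),
            class = "stress_field")
}

# nxn banded operator with the given 3-point stencil on rows
# (half+1)..(n-half); frame rows are zero.
band_op <- function(n, stencil, half = 1L) {
  rows <- (half + 1L):(n - half)
  i <- rep(rows, each = 3L)
  j <- as.vector(vapply(rows, function(r) r + (-1:1), numeric(3)))
  x <- rep(stencil, times = length(rows))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}
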