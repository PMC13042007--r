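#' Force-displacement curve
#'
#' The fundamental record of a skin fracture test: displacement (mm,
#' non-decreasing) against measured force. Forces are normalised by the
#' sample thickness (N/mm) for cross-sample comparison, the convention used
#' throughout for strength values.
#'
#' @param displacement Numeric vector (mm), non-decreasing, length >= 2.
#' @param force Numeric vector, same length. N if `normalized = FALSE`,
#'   N/mm otherwise.
#' @param thickness Sample thickness (mm).
#' @param normalized Whether `force` is already per unit thickness.
#' @param metadata Optional named list (species, mode, sample id, ...).
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(displacement, force, thickness = 1.02,
                     normalized = FALSE, metadata = list()) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) < 2 || length(displacement) != length(force))
    stop("displacement and force must have equal length >= 2")
  if (any(diff(displacement) < -1e-12))
    stop("displacement must be non-decreasing")
  if (!(thickness > 0)) stop("thickness must be > 0")
  structure(list(displacement = displacement, force = force,
                 thickness = thickness, normalized = isTRUE(normalized),
                 metadata = metadata),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("fd_curve: %d points, displacement %.3g..%.3g mm, %s\n",
              length(x$force), min(x$displacement), max(x$displacement),
              if (x$normalized) "normalized (N/mm)" else "raw (N)"))
  cat(sprintf("  thickness %.3g mm, max force %.4g %s\n", x$thickness,
              max(x$force), if (x$normalized) "N/mm" else "N"))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ...) {
  graphics::plot(x$displacement, x$force, type = "l",
                 xlab = "displacement (mm)",
                 ylab = if (x$normalized) "force / thickness (N/mm)"
                 else "force (N)", ...)
  invisible(x)
}

#' Normalise a curve by its sample thickness
#'
#' @param curve An `fd_curve`.
#' @return The curve with `force` divided by thickness and the flag set.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  if (curve$normalized) stop("curve is already normalized")
  if (!(curve$thickness > 0)) stop("thickness must be > 0")
  curve$force <- curve$force / curve$thickness
  curve$normalized <- TRUE
  curve
}

#' Detect sawtooth force peaks
#'
#' Local maxima filtered by topographic prominence and a minimum peak
#' spacing, ordered by displacement. Defaults follow the package convention:
#' prominence 5% of the curve maximum and spacing of half the short boundary
#' length.
#'
#' @param curve A normalised `fd_curve`.
#' @param min_prominence Minimum prominence (N/mm). Default 5% of max force.
#' @param min_spacing Minimum displacement between accepted peaks (mm).
#' @param smooth Odd running-median window (samples) applied before peak
#'   finding; 1 (default) disables smoothing. Useful for noisy records.
#' @return Integer indices of peaks into the curve arrays.
#' @export
detect_peaks <- function(curve, min_prominence = NULL,
                         min_spacing = 0.340 / 2, smooth = 1L) {
  stopifnot(inherits(curve, "fd_curve"))
  if (!curve$normalized) stop("detect_peaks expects a normalized curve")
  f <- curve$force
  if (smooth > 1L) f <- as.numeric(stats::runmed(f, smooth))
  x <- curve$displacement
  n <- length(f)
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(f)
  cand <- which(diff(sign(diff(f))) < 0) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- f[i]
    # walk left/right to the first higher point; prominence = h - max(min L, min R)
    lmin <- h; k <- i
    while (k > 1L) {
      k <- k - 1L
      if (f[k] > h) break
      if (f[k] < lmin) lmin <- f[k]
    }
    if (k == 1L && f[k] <= h) lmin <- min(lmin, f[1L])
    rmin <- h; k <- i
    while (k < n) {
      k <- k + 1L
      if (f[k] > h) break
      if (f[k] < rmin) rmin <- f[k]
    }
    if (k == n && f[k] <= h) rmin <- min(rmin, f[n])
    h - max(lmin, rmin)
  }, 0)
  cand <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (!length(cand)) return(integer())
  # enforce spacing, keeping the more prominent peak
  ord <- order(-prom)
  keep <- logical(length(cand))
  for (k in ord) {
    if (!any(keep & abs(x[cand] - x[cand[k]]) < min_spacing)) keep[k] <- TRUE
  }
  sort(cand[keep])
}

#' Displacement intervals between successive peaks
#'
#' @param peaks Peak indices from [detect_peaks()].
#' @param curve The `fd_curve` the indices refer to.
#' @return Numeric vector of successive peak-to-peak displacements (mm);
#'   empty when fewer than two peaks.
#' @export
extract_intervals <- function(peaks, curve) {
  if (length(peaks) < 2) return(numeric())
  diff(curve$displacement[peaks])
}

#' Decompose a displacement interval into boundary-length combinations
#'
#' Searches integer counts `(a, b)` with `a + b >= 1`, `a, b <= max_count`,
#' minimising `|delta - (a L_long + b L_short)|`; the interval is
#' decomposable when the best residual is within `tol`. This is the
#' arithmetic behind reading sawtooth tearing increments as "one long
#' boundary", "a long plus a short", and so on.
#'
#' @param delta Interval (mm), > 0.
#' @param L_long,L_short Boundary lengths (mm), defaults the measured
#'   0.674 and 0.340 mm.
#' @param tol Decomposability tolerance (mm), default 0.05.
#' @param max_count Largest count per class searched (default 6).
#' @return An object of class `interval_decomposition`: list with `delta`,
#'   `a`, `b`, `residual`, `decomposable`.
#' @export
decompose_interval <- function(delta, L_long = 0.674, L_short = 0.340,
                               tol = 0.05, max_count = 6L) {
  if (!(delta > 0)) stop("delta must be > 0")
  if (!(L_long > L_short && L_short > 0)) stop("need L_long > L_short > 0")
  if (tol < 0) stop("tol must be >= 0")
  ab <- expand.grid(a = 0:max_count, b = 0:max_count)
  ab <- ab[ab$a + ab$b >= 1L, ]
  resid <- delta - (ab$a * L_long + ab$b * L_short)
  best <- which.min(abs(resid))
  structure(list(delta = delta, a = ab$a[best], b = ab$b[best],
                 residual = resid[best],
                 decomposable = abs(resid[best]) <= tol,
                 L_long = L_long, L_short = L_short, tol = tol),
            class = "interval_decomposition")
}

#' @export
print.interval_decomposition <- function(x, ...) {
  cat(sprintf("%.4g mm ~ %d x %.3g + %d x %.3g (residual %+.4g mm) -> %s\n",
              x$delta, x$a, x$L_long, x$b, x$L_short, x$residual,
              if (x$decomposable) "decomposable" else "not decomposable"))
  invisible(x)
}

#' Monte-Carlo test for discreteness of sawtooth intervals
#'
#' Statistic: mean over the observed intervals of the minimal residual
#' against the `(a, b)` combination lattice. Null: intervals drawn uniformly
#' on the observed range, conditioned on the observed extremes (each null
#' replicate keeps the observed minimum and maximum and redraws the interior
#' values), which makes observed and null statistics exchangeable under the
#' uniform null and the Monte-Carlo p-value exactly calibrated. The p-value
#' is `(1 + #[null <= observed]) / (n_mc + 1)`, seeded and reproducible.
#'
#' @param deltas Observed intervals (mm), length >= 3.
#' @param L_long,L_short,tol,max_count As in [decompose_interval()].
#' @param n_mc Number of Monte-Carlo draws (>= 99).
#' @param seed Integer seed.
#' @return An object of class `discreteness_test`: `statistic` (mm),
#'   `p_value`, `n_mc`, `seed`, `null_stats`.
#' @export
discreteness_test <- function(deltas, L_long = 0.674, L_short = 0.340,
                              tol = 0.05, max_count = 6L, n_mc = 199L,
                              seed = 1L) {
  if (length(deltas) < 3) stop("need at least 3 intervals")
  if (n_mc < 99) stop("n_mc must be >= 99")
  combos <- combo_lengths(L_long, L_short, max_count)
  stat <- function(d) mean(vapply(d, function(x) min(abs(x - combos)), 0))
  obs <- stat(deltas)
  lo <- min(deltas); hi <- max(deltas)
  nin <- length(deltas) - 2L
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_mc), function(k)
      stat(c(lo, hi, stats::runif(nin, lo, hi))), 0)
  })
  p <- (1 + sum(null_stats <= obs)) / (n_mc + 1)
  structure(list(statistic = obs, p_value = p, n_mc = as.integer(n_mc),
                 seed = as.integer(seed), null_stats = null_stats,
                 tol = tol),
            class = "discreteness_test")
}

combo_lengths <- function(L_long, L_short, max_count) {
  ab <- expand.grid(a = 0:max_count, b = 0:max_count)
  ab <- ab[ab$a + ab$b >= 1L, ]
  ab$a * L_long + ab$b * L_short
}

#' @export
print.discreteness_test <- function(x, ...) {
  cat(sprintf(paste0("Interval discreteness test: mean residual %.4g mm, ",
                     "p = %.4g (%d Monte-Carlo draws, seed %d)\n"),
              x$statistic, x$p_value, x$n_mc, x$seed))
  invisible(x)
}

# Marko-Siggia worm-like-chain interpolation, amplitude A and contour
# length Lc: F(x) = A * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)
wlc_force <- function(x, A, Lc) {
  s <- x / Lc
  A * (1 / (4 * (1 - s)^2) - 0.25 + s)
}

#' Fit the worm-like-chain force-extension model
#'
#' Least-squares fit of the Marko-Siggia interpolation with amplitude `A`
#' (N/mm, phenomenological thermal-force scale per unit thickness) and
#' contour length `Lc` (mm, constrained above the largest observed
#' displacement). For fixed `Lc` the model is linear in `A`, so the fit
#' profiles `A` out analytically and optimises `Lc` on one dimension --
#' robust without starting values.
#'
#' @param curve A normalised `fd_curve` with >= 10 points.
#' @param Lc_max_factor Upper search bound for `Lc` as a multiple of the
#'   maximum displacement.
#' @return An object of class `wlc_fit` with `amplitude`, `contour_length`,
#'   `rss`, `fitted`, and the data; supports `coef`, `predict`, `print`.
#' @export
fit_wlc <- function(curve, Lc_max_factor = 100) {
  stopifnot(inherits(curve, "fd_curve"))
  if (!curve$normalized) stop("fit_wlc expects a normalized curve")
  x <- curve$displacement
  f <- curve$force
  if (length(x) < 10) stop("need >= 10 points")
  xm <- max(x)
  if (all(f == 0)) {
    fit <- structure(list(amplitude = 0, contour_length = Inf, rss = 0,
                          fitted = rep(0, length(x)), displacement = x,
                          force = f, degenerate = TRUE), class = "wlc_fit")
    return(fit)
  }
  prof <- function(Lc) {
    g <- wlc_force(x, 1, Lc)
    A <- sum(f * g) / sum(g * g)
    sum((f - A * g)^2)
  }
  opt <- stats::optimize(prof, c(xm * 1.0001, xm * Lc_max_factor))
  Lc <- opt$minimum
  g <- wlc_force(x, 1, Lc)
  A <- sum(f * g) / sum(g * g)
  if (!(A > 0))
    stop("worm-like-chain fit failed: non-positive amplitude ",
         "(force trend not increasing?)")
  structure(list(amplitude = A, contour_length = Lc, rss = opt$objective,
                 fitted = A * g, displacement = x, force = f,
                 degenerate = FALSE),
            class = "wlc_fit")
}

#' @export
coef.wlc_fit <- function(object, ...) {
  c(amplitude = object$amplitude, contour_length = object$contour_length)
}

#' @export
predict.wlc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$displacement else
    if (is.list(newdata)) newdata$displacement else as.numeric(newdata)
  wlc_force(x, object$amplitude, object$contour_length)
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(paste0("Worm-like-chain fit: amplitude %.4g N/mm, contour ",
                     "length %.4g mm, RSS %.4g\n"),
              x$amplitude, x$contour_length, x$rss))
  invisible(x)
}

#' @export
residuals.wlc_fit <- function(object, ...) object$force - object$fitted

#' Classify a fracture curve as sawtooth or smooth
#'
#' Sawtooth when at least two qualifying force peaks precede final failure
#' (the lattice-unzipping signature); otherwise smooth when the worm-like-
#' chain fit explains the curve to within `wlc_threshold` (relative RSS);
#' otherwise `"ambiguous"`. An all-zero curve classifies as smooth with a
#' degenerate-flag warning attribute.
#'
#' @param curve A normalised `fd_curve`.
#' @param min_prominence,min_spacing Passed to [detect_peaks()].
#' @param wlc_threshold Maximum relative RSS (RSS / sum(force^2)) for the
#'   smooth class (default 0.05).
#' @return `"sawtooth"`, `"smooth"` or `"ambiguous"`, with attributes
#'   `n_peaks` and `wlc_rel_rss`.
#' @export
classify_curve <- function(curve, min_prominence = NULL,
                           min_spacing = 0.340 / 2, wlc_threshold = 0.05) {
  stopifnot(inherits(curve, "fd_curve"))
  if (!curve$normalized) stop("classify_curve expects a normalized curve")
  if (all(curve$force == 0)) {
    out <- "smooth"
    attr(out, "warning") <- "degenerate all-zero curve"
    attr(out, "n_peaks") <- 0L
    return(out)
  }
  pk <- detect_peaks(curve, min_prominence, min_spacing)
  # peaks before final failure: exclude a terminal maximum at the very end
  pk <- pk[curve$displacement[pk] < max(curve$displacement)]
  if (length(pk) >= 2) {
    out <- "sawtooth"
    attr(out, "n_peaks") <- length(pk)
    return(out)
  }
  rel <- tryCatch({
    fit <- fit_wlc(curve)
    fit$rss / sum(curve$force^2)
  }, error = function(e) Inf)
  out <- if (rel <= wlc_threshold) "smooth" else "ambiguous"
  attr(out, "n_peaks") <- length(pk)
  attr(out, "wlc_rel_rss") <- rel
  out
}

#' Maximum normalised strength of a curve
#'
#' @param curve A normalised `fd_curve`.
#' @return Max of the normalised force (N/mm).
#' @export
max_normalized_strength <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  if (!curve$normalized) stop("expects a normalized curve")
  max(curve$force)
}
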