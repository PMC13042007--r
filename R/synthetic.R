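#' Generate a synthetic sawtooth force-displacement curve
#'
#' Builds a tearing-style curve from a tooth plan: each tooth spans
#' `a * L_long + b * L_short` of displacement, rising linearly to
#' `peak_force` and dropping, with seeded Gaussian force noise. Ground-truth
#' peak positions are attached, so peak-calling and interval decomposition
#' can be scored without external data.
#'
#' @param teeth Two-column matrix or data.frame of non-negative integer
#'   counts `(a, b)` per tooth, each row with `a + b >= 1`.
#' @param peak_force Tooth peak (N/mm).
#' @param L_long,L_short Basis lengths (mm); defaults the measured boundary
#'   lengths 0.674 and 0.340 mm.
#' @param noise_sd Gaussian noise SD (N/mm); default 2% of `peak_force`.
#' @param sample_pitch Sampling pitch (mm); must be < `L_short`/10.
#' @param seed Integer seed.
#' @param thickness Thickness metadata (mm).
#' @return A normalised `fd_curve` with attribute `true_peaks` (displacement
#'   of each tooth peak, mm) and `plan`.
#' @export
gen_sawtooth_curve <- function(teeth, peak_force = 3, L_long = 0.674,
                               L_short = 0.340, noise_sd = 0.02 * peak_force,
                               sample_pitch = L_short / 40, seed = 1L,
                               thickness = 1.02) {
  teeth <- as.matrix(teeth)
  if (ncol(teeth) != 2 || any(teeth < 0) || any(rowSums(teeth) < 1))
    stop("teeth must be rows of counts (a, b) with a + b >= 1")
  if (!(sample_pitch < L_short / 10))
    stop("sample_pitch must be < L_short / 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  widths <- teeth[, 1] * L_long + teeth[, 2] * L_short
  ends <- cumsum(widths)
  starts <- c(0, ends[-length(ends)])
  x <- seq(0, ends[length(ends)] + 2 * sample_pitch, by = sample_pitch)
  idx <- pmin(findInterval(x, c(0, ends), rightmost.closed = TRUE),
              length(widths))
  frac <- (x - starts[idx]) / widths[idx]
  f <- peak_force * frac
  # final rupture: force drops to zero after the last tooth
  f[x > ends[length(ends)]] <- 0
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  cv <- fd_curve(x, f, thickness = thickness, normalized = TRUE,
                 metadata = list(generator = "sawtooth", seed = seed))
  attr(cv, "true_peaks") <- ends
  attr(cv, "plan") <- teeth
  cv
}

#' Generate a synthetic worm-like-chain curve
#'
#' Marko-Siggia force-extension evaluated on a displacement grid, plus
#' seeded Gaussian noise: the smooth divergent profile typical of ordinary
#' (non-lattice) skin fracture.
#'
#' @param amplitude `A` (N/mm).
#' @param contour_length `Lc` (mm); must exceed `max_displacement`.
#' @param max_displacement Largest displacement sampled (mm).
#' @param noise_sd Gaussian noise SD (N/mm).
#' @param sample_pitch Sampling pitch (mm).
#' @param seed Integer seed.
#' @param thickness Thickness metadata (mm).
#' @return A normalised `fd_curve` with attribute `true_params`.
#' @export
gen_wlc_curve <- function(amplitude = 2, contour_length = 30,
                          max_displacement = 20, noise_sd = 0,
                          sample_pitch = 0.05, seed = 1L, thickness = 1.02) {
  if (!(max_displacement < contour_length))
    stop("max_displacement must be below the contour length")
  x <- seq(0, max_displacement, by = sample_pitch)
  f <- wlc_force(x, amplitude, contour_length)
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  cv <- fd_curve(x, f, thickness = thickness, normalized = TRUE,
                 metadata = list(generator = "wlc", seed = seed))
  attr(cv, "true_params") <- c(amplitude = amplitude,
                               contour_length = contour_length)
  cv
}

#' Write the self-contained fixture suite
#'
#' Writes three sawtooth curves, three worm-like-chain curves, a lattice
#' configuration at the measured skin geometry, and cut / ripped wound
#' defect configurations, plus a JSON manifest with generator parameters,
#' seeds and ground-truth labels. Regeneration from the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @return The manifest (invisibly also written as `manifest.json`).
#' @export
gen_fixture_suite <- function(out_dir, seed = 1L) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to ", out_dir)
  plans <- list(
    s1 = cbind(a = c(1, 1, 0, 1, 0, 1), b = c(0, 0, 1, 1, 1, 0)),
    s2 = cbind(a = c(0, 1, 2, 0, 1, 0, 1), b = c(1, 1, 0, 1, 0, 2, 0)),
    s3 = cbind(a = c(1, 0, 1, 1, 0, 2), b = c(1, 1, 0, 0, 1, 0)))
  wlcs <- list(w1 = c(2, 30, 20), w2 = c(1.5, 25, 16), w3 = c(3, 40, 28))
  entries <- list()
  for (nm in names(plans)) {
    sd_i <- seed + match(nm, names(plans))
    cv <- gen_sawtooth_curve(plans[[nm]], seed = sd_i)
    fn <- file.path(out_dir, paste0(nm, "_sawtooth.csv"))
    write_curve_csv(cv, fn)
    entries[[length(entries) + 1L]] <- list(
      file = basename(fn), generator = "gen_sawtooth_curve",
      seed = sd_i, label = "sawtooth",
      teeth = apply(plans[[nm]], 1, paste, collapse = ","),
      true_peaks = as.numeric(attr(cv, "true_peaks")))
  }
  for (nm in names(wlcs)) {
    p <- wlcs[[nm]]
    sd_i <- seed + 10L + match(nm, names(wlcs))
    cv <- gen_wlc_curve(amplitude = p[1], contour_length = p[2],
                        max_displacement = p[3], noise_sd = 0.02 * p[1],
                        seed = sd_i)
    fn <- file.path(out_dir, paste0(nm, "_wlc.csv"))
    write_curve_csv(cv, fn)
    entries[[length(entries) + 1L]] <- list(
      file = basename(fn), generator = "gen_wlc_curve", seed = sd_i,
      label = "smooth", amplitude = p[1], contour_length = p[2])
  }
  cfgs <- list(
    lattice = list(file = "lattice.yaml",
                   config = default_config()),
    cut = list(file = "defect_cut.yaml",
               config = utils::modifyList(default_config(), list(
                 defect = list(kind = "cut_circle", diameter_mm = 15)))),
    ripped = list(file = "defect_ripped.yaml",
                  config = utils::modifyList(default_config(), list(
                    defect = list(kind = "ripped_units", n_units = 254,
                                  seed = seed)))))
  for (nm in names(cfgs)) {
    fn <- file.path(out_dir, cfgs[[nm]]$file)
    save_config(cfgs[[nm]]$config, fn)
    entries[[length(entries) + 1L]] <- list(
      file = cfgs[[nm]]$file, generator = "save_config", seed = seed,
      label = "config")
  }
  manifest <- list(seed = seed, n_files = length(entries),
                   entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
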