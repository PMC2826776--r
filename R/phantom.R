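# Synthetic thorax phantom: low-uptake background, hypermetabolic
# ellipsoidal tumour(s) with radially decaying uptake, scanner PSF blur,
# additive noise, and an optional respiratory-motion-averaged mode.

#' Describe one ellipsoidal tumour component
#'
#' Uptake inside the component decays smoothly from `peak_uptake` at the
#' centre towards the ellipsoid boundary:
#' `uptake = background + (peak - background) * (1 - (1 - edge_fraction) *
#' rho^exponent)`, with `rho` the normalized ellipsoidal radius. At the
#' boundary the uptake is still `edge_fraction` of the peak-to-background
#' contrast above background — hypermetabolic tumours present a contrast
#' step at their rim (this is what makes threshold-based delineation
#' clinically viable), while the radial decay plus partial-volume blurring
#' make the per-slice optimal threshold depend on the cross-section, which
#' is precisely the slice-to-slice variation the learner must cope with.
#'
#' @param centre Tumour centre in mm (x, y, z), in voxel-centre
#'   coordinates (voxel i is centred at `(i - 0.5) * voxel_size`).
#' @param semi_axes Ellipsoid semi-axes in mm (x, y, z).
#' @param peak_uptake Peak SUV at the centre (must exceed background).
#' @param profile_exponent Radial decay exponent (default 2, paraboloid).
#' @param edge_fraction Fraction of the peak-to-background contrast
#'   remaining at the ellipsoid boundary, in `[0, 1)` (default 0.3; 0
#'   fades the tumour into the background, which makes the rim invisible).
#' @return A `tumour_component` list.
#' @export
tumour_component <- function(centre, semi_axes, peak_uptake = 10,
                             profile_exponent = 2, edge_fraction = 0.3) {
  stopifnot(length(centre) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0), peak_uptake > 0, profile_exponent > 0,
            edge_fraction >= 0, edge_fraction < 1)
  structure(list(centre = as.numeric(centre),
                 semi_axes = as.numeric(semi_axes),
                 peak_uptake = peak_uptake,
                 profile_exponent = profile_exponent,
                 edge_fraction = edge_fraction),
            class = "tumour_component")
}

#' Phantom specification
#'
#' Defaults emulate a single-bed thorax acquisition: a 64 x 64 x 48 grid of
#' 4 mm isotropic voxels, background uptake 1 SUV, one elongated ellipsoid
#' tumour peaking at 10 SUV, a 7 mm FWHM isotropic Gaussian PSF, and
#' additive Gaussian noise of 0.05 SUV. In `free_breathing` mode the
#' activity is averaged over sinusoidally sampled axial displacements from
#' the end-exhale reference position (default 8 mm amplitude over 8 phase
#' samples) before blurring, emulating respiratory motion blur relative to
#' the phase the GTV is defined at; `gated` mode skips the averaging.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size Voxel dimensions in mm.
#' @param background_uptake Background SUV.
#' @param tumour List of [tumour_component()]s.
#' @param psf_fwhm Scanner point-spread FWHM in mm (0 disables blur).
#' @param noise_sd Additive Gaussian noise SD in SUV (0 disables noise).
#' @param mode `"gated"` or `"free_breathing"`.
#' @param motion_amplitude Axial peak-to-peak respiratory displacement, mm.
#' @param motion_samples Number of respiratory phase samples averaged.
#' @param n_free_slices Adjacent tumour-free slices required (default 8).
#' @param seed Integer seed for the noise draws.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_size = c(4, 4, 4),
                         background_uptake = 1.0,
                         tumour = list(tumour_component(
                           centre = c(126, 126, 94),
                           semi_axes = c(22, 22, 64))),
                         psf_fwhm = 7,
                         noise_sd = 0.05,
                         mode = c("gated", "free_breathing"),
                         motion_amplitude = 8,
                         motion_samples = 8L,
                         n_free_slices = 8L,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2),
            length(voxel_size) == 3L, all(voxel_size > 0),
            background_uptake >= 0, psf_fwhm >= 0, noise_sd >= 0,
            motion_amplitude >= 0, motion_samples >= 1L,
            length(tumour) >= 1L)
  for (tc in tumour) {
    stopifnot(inherits(tc, "tumour_component"))
    if (tc$peak_uptake <= background_uptake)
      stop("tumour peak uptake must exceed the background uptake")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 background_uptake = background_uptake,
                 tumour = tumour, psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 mode = mode, motion_amplitude = motion_amplitude,
                 motion_samples = as.integer(motion_samples),
                 n_free_slices = as.integer(n_free_slices),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate vectors (mm) along each axis
.axis_coords <- function(spec) {
  lapply(1:3, function(d)
    (seq_len(spec$grid_shape[d]) - 0.5) * spec$voxel_size[d])
}

# pre-blur activity field and GTV mask (centre-inclusion rasterization)
.activity_and_gtv <- function(spec) {
  cc <- .axis_coords(spec)
  d <- spec$grid_shape
  act <- array(spec$background_uptake, d)
  gtv <- array(FALSE, d)
  for (tc in spec$tumour) {
    dx2 <- ((cc[[1]] - tc$centre[1]) / tc$semi_axes[1])^2
    dy2 <- ((cc[[2]] - tc$centre[2]) / tc$semi_axes[2])^2
    dz2 <- ((cc[[3]] - tc$centre[3]) / tc$semi_axes[3])^2
    q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside <- q <= 1
    gtv <- gtv | inside
    rho <- sqrt(pmin(q, 1))
    act <- act + inside * (tc$peak_uptake - spec$background_uptake) *
      (1 - (1 - tc$edge_fraction) * rho^tc$profile_exponent)
  }
  list(activity = act, gtv = gtv)
}

# separable Gaussian blur with renormalized (edge-aware) truncated kernel
.gaussian_blur <- function(arr, fwhm, voxel_size) {
  if (fwhm <= 0) return(arr)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sigma <- sigma_mm / voxel_size[axis]
    r <- max(1L, ceiling(3 * sigma))
    w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    num <- array(0, dim(arr))
    den <- array(0, dim(arr))
    n <- dim(arr)[axis]
    for (j in seq(-r, r)) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)
      inb <- (seq_len(n) + j >= 1L) & (seq_len(n) + j <= n)
      wj <- w[j + r + 1L]
      idx <- switch(axis,
                    quote(arr[src, , , drop = FALSE]),
                    quote(arr[, src, , drop = FALSE]),
                    quote(arr[, , src, drop = FALSE]))
      shifted <- eval(idx)
      mask <- switch(axis, inb[slice.index(arr, 1)],
                     inb[slice.index(arr, 2)],
                     inb[slice.index(arr, 3)])
      num <- num + wj * shifted * mask
      den <- den + wj * mask
    }
    arr <- num / den
  }
  arr
}

# shift along the axial axis by a fractional number of voxels
# (linear interpolation, edge replication)
.shift_axial <- function(arr, shift_vox) {
  n <- dim(arr)[3]
  src <- seq_len(n) - shift_vox
  i0 <- floor(src)
  frac <- src - i0
  lo <- pmin(pmax(i0, 1L), n)
  hi <- pmin(pmax(i0 + 1L, 1L), n)
  nxy <- prod(dim(arr)[1:2])
  a <- arr[, , lo, drop = FALSE]
  b <- arr[, , hi, drop = FALSE]
  fr <- array(rep(frac, each = nxy), dim(arr))
  a * (1 - fr) + b * fr
}

# 6-neighbour binary dilation iterated 'times' times (city-block distance)
.dilate6 <- function(mask, times = 1L) {
  d <- dim(mask)
  for (t in seq_len(times)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
    mask <- out
  }
  mask
}

# shared generator: optional externally supplied noise array so paired
# modes can reuse identical draws
.generate_study_impl <- function(spec, noise = NULL, study_id = "phantom") {
  ag <- .activity_and_gtv(spec)
  act <- ag$activity
  gtv <- ag$gtv
  if (!any(gtv)) stop("tumour lies outside the grid")
  tum_slices <- which(apply(gtv, 3, any))
  clear_inf <- min(tum_slices) - 1L
  clear_sup <- spec$grid_shape[3] - max(tum_slices)
  if (clear_inf + clear_sup < spec$n_free_slices)
    stop("insufficient tumour-free slices adjacent to the tumour")
  if (max(clear_inf, clear_sup) < spec$n_free_slices %/% 2L)
    stop("tumour leaves fewer than ", spec$n_free_slices %/% 2L,
         " clear slices on both axial sides")

  if (spec$mode == "free_breathing" && spec$motion_amplitude > 0) {
    # Displacement from the end-exhale reference position (the phase the
    # gated acquisition selects and the GTV is defined at), sinusoidally
    # sampled over the respiratory cycle: offsets span [0, amplitude],
    # dwelling near the exhale extreme as real breathing does.
    k <- seq_len(spec$motion_samples)
    offsets_mm <- (spec$motion_amplitude / 2) *
      (1 - cos(2 * pi * (k - 1) / spec$motion_samples))
    acc <- array(0, dim(act))
    for (o in offsets_mm)
      acc <- acc + .shift_axial(act, o / spec$voxel_size[3])
    act <- acc / spec$motion_samples
  }
  img <- .gaussian_blur(act, spec$psf_fwhm, spec$voxel_size)
  if (is.null(noise) && spec$noise_sd > 0)
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(prod(spec$grid_shape),
                                          sd = spec$noise_sd),
                             spec$grid_shape))
  if (!is.null(noise)) img <- img + noise
  img <- pmax(img, 0)

  background <- .dilate6(gtv, 4L) & !.dilate6(gtv, 1L)
  study_fixture(suv_volume(img, spec$voxel_size), gtv, background,
                mode = spec$mode, study_id = study_id, truth = unclass(spec))
}

#' Generate a synthetic PET study
#'
#' Builds the pre-blur activity field (background plus radially decaying
#' tumour components), rasterizes the GTV as the union of the pre-blur
#' ellipsoid supports (the anatomic tumour, not its blurred image, is the
#' delineation target), applies respiratory-motion averaging in
#' free-breathing mode, convolves with the scanner PSF, adds seeded
#' Gaussian noise (clipped at zero), and derives a peritumoral background
#' shell (city-block distance 2-4 voxels outside the GTV) for the
#' contrast-oriented baseline.
#'
#' @param spec A [phantom_spec()].
#' @param study_id Study identifier for the returned fixture.
#' @return A [study_fixture()] with `truth` set to the generation
#'   parameters.
#' @export
generate_study <- function(spec, study_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  .generate_study_impl(spec, study_id = study_id)
}

#' Generate a gated / free-breathing study pair
#'
#' The two studies share tumour geometry, seed and noise draws, and differ
#' only in the respiratory-motion averaging: the pair isolates the effect
#' of motion blur on the threshold statistics.
#'
#' @param spec A [phantom_spec()] (its `mode` field is ignored).
#' @param study_id Base study identifier; `_gated` / `_free_breathing` is
#'   appended.
#' @return List with elements `gated` and `free_breathing`.
#' @export
paired_modes <- function(spec, study_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, array(stats::rnorm(prod(spec$grid_shape),
                                            sd = spec$noise_sd),
                               spec$grid_shape))
  sg <- spec; sg$mode <- "gated"
  sf <- spec; sf$mode <- "free_breathing"
  list(gated = .generate_study_impl(sg, noise = noise,
                                    study_id = paste0(study_id, "_gated")),
       free_breathing = .generate_study_impl(
         sf, noise = noise,
         study_id = paste0(study_id, "_free_breathing")))
}

#' Default four-study phantom suite
#'
#' Two tumour geometries - a smaller ellipsoid spanning 24 axial slices and
#' a larger one spanning 33 slices at 4 mm spacing - each generated in both
#' gated and free-breathing modes: four studies in total (two "patients",
#' two acquisition modes each), deterministic given the seed.
#'
#' @param seed Integer master seed.
#' @return List of four [study_fixture()]s named
#'   `patient1_gated`, `patient1_free_breathing`, `patient2_gated`,
#'   `patient2_free_breathing`.
#' @export
default_patient_suite <- function(seed = 1L) {
  small <- phantom_spec(
    tumour = list(tumour_component(centre = c(126, 126, 96),
                                   semi_axes = c(16, 16, 46))),
    seed = seed)
  large <- phantom_spec(seed = seed + 1L)
  p1 <- paired_modes(small, study_id = "patient1")
  p2 <- paired_modes(large, study_id = "patient2")
  list(patient1_gated = p1$gated,
       patient1_free_breathing = p1$free_breathing,
       patient2_gated = p2$gated,
       patient2_free_breathing = p2$free_breathing)
}
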