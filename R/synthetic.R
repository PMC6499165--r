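# Synthetic head phantoms and motor-map datasets with known ground truth,
# so the whole pipeline can be exercised and validated without any
# downloaded data.

#' Build an ellipsoidal head phantom
#'
#' A solid triaxial ellipsoid of constant foreground intensity in a zero
#' background, with optional additive Gaussian noise, plus its ground-truth
#' mask for segmentation oracles. Default geometry approximates an adult
#' head (radii 80 x 95 x 70 mm).
#'
#' @param shape voxel grid dimensions (default `c(64, 64, 64)`).
#' @param spacing voxel size in mm (default 3.5 mm isotropic).
#' @param center ellipsoid centre in mm; defaults to the volume centre.
#' @param radii semi-axes (a, b, c) in mm.
#' @param intensity foreground intensity (default 100).
#' @param noise_sd additive Gaussian noise standard deviation (default 0).
#' @param seed optional integer seed for the noise.
#' @return List with `scan` (a [head_scan]), `mask` (ground-truth
#'   `head_mask`), `center` and `radii` (mm).
#' @export
make_head_phantom <- function(shape = c(64L, 64L, 64L), spacing = c(3.5, 3.5, 3.5),
                              center = NULL, radii = c(80, 95, 70),
                              intensity = 100, noise_sd = 0, seed = NULL) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (any(radii <= 0)) stop_mm("value_error", "radii must be > 0")
  extent <- (shape - 1L) * spacing
  if (is.null(center)) center <- extent / 2
  if (any(center - radii < 0) || any(center + radii > extent)) {
    stop_mm("value_error", "ellipsoid exceeds the volume")
  }
  ax <- ((0:(shape[1] - 1L)) * spacing[1] - center[1]) / radii[1]
  ay <- ((0:(shape[2] - 1L)) * spacing[2] - center[2]) / radii[2]
  az <- ((0:(shape[3] - 1L)) * spacing[3] - center[3]) / radii[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- r2 <= 1
  vol <- array(0, shape)
  vol[mask] <- intensity
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sd), shape)
  }
  list(scan = head_scan(vol, spacing),
       mask = structure(list(mask = mask, spacing = spacing), class = "head_mask"),
       center = center, radii = radii)
}

#' Simulate a grid-sampled Gaussian motor map on a modelled scalp
#'
#' Emulates a TMS mapping session: stimulation sites on a regular grid
#' conforming to the scalp surface (default 5 mm spacing, the common
#' 0.5 x 0.5 cm protocol), an underlying MEP field that falls off as a
#' Gaussian of the angular distance from a hotspot, and `repeats` noisy
#' samples per site (multiplicative log-normal noise of coefficient of
#' variation `noise_cv`, plus an additive Gaussian floor), clipped at 0.
#' Ground-truth map features are computed from the noiseless field.
#'
#' @param model a `scalp_ellipsoid` (e.g. fitted to a phantom).
#' @param center hotspot centre `c(theta, phi)` in radians (default
#'   `c(pi/2, 0)`, on the equator).
#' @param amplitude hotspot peak amplitude in microvolt (default 2000).
#' @param width_mm Gaussian width (sd) on the scalp in mm (default 15, a
#'   typical hand-muscle hotspot extent, and comfortably above the 5 mm
#'   sampling grid); converted to radians through the local scalp radius.
#' @param grid_spacing_mm grid step on the scalp in mm (default 5).
#' @param extent_mm half-width of the sampled square patch in mm (default
#'   25, i.e. an 11 x 11 grid at 5 mm).
#' @param repeats stimulations per site (default 3).
#' @param noise_cv multiplicative noise coefficient of variation (default
#'   0.1).
#' @param noise_sd additive noise floor sd in microvolt (default 10).
#' @param seed optional integer seed.
#' @return List with `map` (a [motor_map]), `sites` (per-site angular
#'   coordinates and noiseless expected values), and `ground_truth`
#'   (`cog` mm, `peak` position mm + value, field function, and the angular
#'   hotspot centre).
#' @export
make_gaussian_map <- function(model, center = c(pi / 2, 0), amplitude = 2000,
                              width_mm = 15, grid_spacing_mm = 5, extent_mm = 25,
                              repeats = 3L, noise_cv = 0.1, noise_sd = 10,
                              seed = NULL) {
  stopifnot(inherits(model, "scalp_ellipsoid"))
  if (amplitude < 0) stop_mm("value_error", "amplitude must be >= 0")
  if (repeats < 1L) stop_mm("value_error", "repeats must be >= 1")
  c3d <- predict(model, center[1], center[2])
  r_local <- sqrt(sum((c3d - model$centroid)^2))
  if (!is.finite(r_local) || r_local <= 0) {
    stop_mm("value_error", "hotspot centre is not on the modelled surface")
  }
  s_ang <- grid_spacing_mm / r_local           # angular grid step
  width <- width_mm / r_local                  # angular hotspot width
  n_half <- floor(extent_mm / grid_spacing_mm)
  offs <- (-n_half:n_half) * s_ang
  sites <- expand.grid(theta = center[1] + offs, phi = center[2] + offs)
  pos <- predict(model, sites$theta, sites$phi)
  # the model is not purely radial, so the angular coordinates recovered from
  # the 3D site positions differ slightly from the generating lattice; the
  # field is defined on the recovered (analysis) coordinates so that ground
  # truth and pipeline live in the same coordinate system
  ang_eff <- cartesian_to_angular(pos, model$centroid)
  sites$theta <- ang_eff$theta
  sites$phi <- ang_eff$phi

  field <- function(theta, phi) {
    d2 <- (theta - center[1])^2 + (phi - center[2])^2
    amplitude * exp(-d2 / (2 * width^2))
  }
  sites$expected <- field(sites$theta, sites$phi)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n_sites <- nrow(sites)
  idx <- rep(seq_len(n_sites), each = repeats)
  expected <- sites$expected[idx]
  if (noise_cv > 0 || noise_sd > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- if (noise_cv > 0) {
      stats::rlnorm(length(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(idx))
    add <- if (noise_sd > 0) stats::rnorm(length(idx), 0, noise_sd) else 0
    values <- pmax(0, expected * mult + add)
  } else {
    values <- expected
  }
  map <- motor_map(pos[idx, 1], pos[idx, 2], pos[idx, 3], values,
                   session_label = "synthetic gaussian map")

  w <- sites$expected / sum(sites$expected)
  true_cog <- c(x = sum(pos[, 1] * w), y = sum(pos[, 2] * w), z = sum(pos[, 3] * w))
  list(
    map = map,
    sites = cbind(sites, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    ground_truth = list(
      cog = true_cog,
      peak = list(position = c(x = c3d[1, 1], y = c3d[1, 2], z = c3d[1, 3]),
                  value = amplitude, theta = center[1], phi = center[2]),
      field = field,
      center = center, width = width, amplitude = amplitude,
      grid_angular_spacing = s_ang
    )
  )
}
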