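# Scalp head model: centroid, angular coordinates, and the least-squares
# polynomial ellipsoid that maps (theta, phi) back to 3D scanner mm.
#
# Angular convention (followed throughout the package):
#   theta = inclination from +z, in [0, pi]:  theta = acos((z - z_o)/r)
#   phi   = azimuth, in (-pi, pi]:            phi   = atan2(y - y_o, x - x_o)
# measured about the head centroid (x_o, y_o, z_o).

#' Centroid of a point cloud
#'
#' Coordinate-wise arithmetic mean of the cloud, used as the origin of the
#' angular coordinate system (it approximates the centre of curvature of the
#' scalp).
#'
#' @param points numeric matrix with columns x, y, z (mm).
#' @return Named numeric vector `c(x, y, z)`.
#' @export
compute_centroid <- function(points) {
  points <- as_points3(points)
  if (nrow(points) < 1L) stop_mm("value_error", "point cloud is empty")
  out <- colMeans(points)
  names(out) <- c("x", "y", "z")
  out
}

as_points3 <- function(points) {
  if (inherits(points, "motor_map")) {
    points <- cbind(points$x, points$y, points$z)
  }
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L) {
    stop_mm("value_error", "points must be an N x 3 matrix")
  }
  storage.mode(points) <- "double"
  assert_finite(points, "points")
  points
}

#' Convert 3D Cartesian points to angular coordinates
#'
#' Strips the radial dimension: each point is described by its inclination
#' `theta` (radians from +z) and azimuth `phi` (quadrant-aware, radians)
#' about the centroid. Points coincident with the centroid have no direction
#' and raise an error.
#'
#' @param points N x 3 matrix (mm) or a [motor_map].
#' @param centroid length-3 numeric, the angular origin (mm).
#' @return data.frame with columns `theta` (in `[0, pi]`) and `phi`
#'   (in `(-pi, pi]`).
#' @export
cartesian_to_angular <- function(points, centroid) {
  pts <- as_points3(points)
  centroid <- as.numeric(centroid)
  d <- sweep(pts, 2L, centroid)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) {
    stop_mm("degenerate_point_error", "point coincides with the centroid")
  }
  theta <- acos(pmin(1, pmax(-1, d[, 3] / r)))
  phi <- atan2(d[, 2], d[, 1])
  data.frame(theta = theta, phi = phi)
}

# Polynomial design for the radial term: 1, th, ph, th^2, ph^2, th^3, ph^3,
# th^4, ph^4 (a fourth-order polynomial in each angle, no cross terms).
radial_basis <- function(theta, phi) {
  cbind(1, theta, phi, theta^2, phi^2, theta^3, phi^3, theta^4, phi^4)
}

# Full 10-column per-axis design: a constant offset plus the radial
# polynomial modulated by the spherical direction cosines of the axis.
ellipsoid_design <- function(theta, phi) {
  B <- radial_basis(theta, phi)
  list(
    x = cbind(1, B * (sin(theta) * cos(phi))),
    y = cbind(1, B * (sin(theta) * sin(phi))),
    z = cbind(1, B * cos(theta))
  )
}

#' Construct a scalp ellipsoid model from known weights
#'
#' Low-level constructor; see [fit_scalp_ellipsoid()] for fitting. An exact
#' sphere of radius R about the centroid corresponds to weight vectors with
#' `w2 = R` and all other entries 0 on every axis.
#'
#' @param weights numeric k x 3 matrix (k <= 10) of per-axis weights
#'   (columns x, y, z).
#' @param centroid length-3 numeric (mm).
#' @return An object of class `scalp_ellipsoid`.
#' @export
scalp_ellipsoid <- function(weights, centroid) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 3L || nrow(weights) < 1L || nrow(weights) > 10L) {
    stop_mm("value_error", "weights must be a k x 3 matrix with 1 <= k <= 10")
  }
  assert_finite(weights, "weights")
  colnames(weights) <- c("x", "y", "z")
  structure(list(weights = weights, centroid = as.numeric(centroid),
                 n_terms = nrow(weights), residuals = NULL),
            class = "scalp_ellipsoid")
}

#' Fit the polynomial scalp ellipsoid
#'
#' Least-squares fit, per axis, of an ellipsoid whose radial term is a
#' fourth-order polynomial in the two angles: for each axis the centred
#' coordinate is modelled as
#' `w1 + (w2 + w3*theta + w4*phi + ... + w10*phi^4) * direction_cosine`,
#' 10 weights per axis (30 in total). The solved model maps any angular
#' coordinate back to a 3D point on the modelled scalp surface.
#'
#' @param points N x 3 point cloud (mm), typically from [sample_point_cloud()].
#' @param centroid angular origin; defaults to [compute_centroid()] of
#'   `points`.
#' @param n_terms number of design columns to use per axis (1-10); the
#'   default 10 is the full model.
#' @return A `scalp_ellipsoid` with components `weights` (n_terms x 3),
#'   `centroid`, `residuals` (N x 3, observed minus fitted mm).
#' @export
fit_scalp_ellipsoid <- function(points, centroid = NULL, n_terms = 10L) {
  pts <- as_points3(points)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L || n_terms > 10L) stop_mm("value_error", "n_terms must be in 1..10")
  if (nrow(pts) < n_terms) {
    stop_mm("insufficient_points_error",
            sprintf("need at least %d points, got %d", n_terms, nrow(pts)))
  }
  if (is.null(centroid)) centroid <- compute_centroid(pts)
  ang <- cartesian_to_angular(pts, centroid)
  design <- ellipsoid_design(ang$theta, ang$phi)
  centred <- sweep(pts, 2L, as.numeric(centroid))
  weights <- matrix(0, n_terms, 3L, dimnames = list(NULL, c("x", "y", "z")))
  resid <- matrix(0, nrow(pts), 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (k in 1:3) {
    A <- design[[k]][, seq_len(n_terms), drop = FALSE]
    qrA <- qr(A)
    if (qrA$rank < n_terms) {
      stop_mm("singular_design_error",
              sprintf("rank-deficient design on axis %s (rank %d < %d)",
                      c("x", "y", "z")[k], qrA$rank, n_terms))
    }
    w <- qr.coef(qrA, centred[, k])
    weights[, k] <- w
    resid[, k] <- centred[, k] - A %*% w
  }
  out <- scalp_ellipsoid(weights, centroid)
  out$residuals <- resid
  out
}

#' Evaluate the scalp ellipsoid at angular coordinates
#'
#' Maps `(theta, phi)` back to 3D scanner mm by evaluating the fitted
#' per-axis polynomials and adding the centroid offset.
#'
#' @param object a `scalp_ellipsoid`.
#' @param theta,phi numeric vectors of equal length (radians); alternatively
#'   `theta` may be a data.frame with columns `theta` and `phi`.
#' @param ... unused.
#' @return N x 3 matrix of Cartesian coordinates (mm).
#' @export
predict.scalp_ellipsoid <- function(object, theta, phi = NULL, ...) {
  if (is.data.frame(theta)) { phi <- theta$phi; theta <- theta$theta }
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  if (length(theta) != length(phi)) stop_mm("value_error", "theta and phi lengths differ")
  design <- ellipsoid_design(theta, phi)
  k <- object$n_terms
  out <- vapply(1:3, function(ax) {
    as.numeric(design[[ax]][, seq_len(k), drop = FALSE] %*% object$weights[, ax])
  }, numeric(length(theta)))
  out <- matrix(out, ncol = 3L)
  out <- sweep(out, 2L, object$centroid, `+`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
coef.scalp_ellipsoid <- function(object, ...) object$weights

#' @export
residuals.scalp_ellipsoid <- function(object, ...) object$residuals

#' @export
print.scalp_ellipsoid <- function(x, ...) {
  cat(sprintf("<scalp_ellipsoid> %d weights per axis, centroid (%.1f, %.1f, %.1f) mm\n",
              x$n_terms, x$centroid[1], x$centroid[2], x$centroid[3]))
  if (!is.null(x$residuals)) {
    cat(sprintf("  fit RMS residual: %.3f mm over %d cloud points\n",
                sqrt(mean(x$residuals^2)), nrow(x$residuals)))
  }
  invisible(x)
}

#' Render the topographic ("globe-like") projection of a scan
#'
#' Samples the scan's voxel intensity at every angular grid position on the
#' modelled scalp surface (nearest-voxel lookup; positions falling outside
#' the volume read as the background value), producing the 2D topographic
#' image on which motor maps are displayed.
#'
#' @param scan a [head_scan].
#' @param model a `scalp_ellipsoid`.
#' @param spacing angular pixel spacing in radians (default `pi/512`,
#'   a 512 x 1024 image over the full sphere).
#' @param theta_range,phi_range angular extents (radians).
#' @param background intensity for out-of-volume pixels (default 0).
#' @return An object of class `topographic_grid`: list with `image`
#'   (theta x phi matrix), axis vectors `theta`, `phi`, and `spacing`.
#' @export
render_topographic <- function(scan, model, spacing = pi / 512,
                               theta_range = c(0, pi),
                               phi_range = c(-pi, pi),
                               background = 0) {
  stopifnot(inherits(scan, "head_scan"), inherits(model, "scalp_ellipsoid"))
  if (spacing <= 0) stop_mm("value_error", "pixel spacing must be > 0")
  theta <- seq(theta_range[1], theta_range[2], by = spacing)
  phi <- seq(phi_range[1], phi_range[2], by = spacing)
  grid <- expand.grid(theta = theta, phi = phi)
  p <- predict(model, grid$theta, grid$phi)
  ijk <- round(sweep(p, 2L, scan$spacing, `/`)) + 1L
  d <- dim(scan$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  vals <- rep(background, nrow(ijk))
  if (any(ok)) {
    vals[ok] <- scan$data[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
  }
  structure(list(image = matrix(vals, nrow = length(theta)),
                 theta = theta, phi = phi, spacing = spacing),
            class = "topographic_grid")
}

#' @export
print.topographic_grid <- function(x, ...) {
  cat(sprintf("<topographic_grid> %d x %d pixels, spacing %.4g rad\n",
              length(x$theta), length(x$phi), x$spacing))
  invisible(x)
}

#' @export
plot.topographic_grid <- function(x, ...) {
  graphics::image(x$theta, x$phi, x$image, col = grDevices::gray.colors(256),
                  xlab = "theta (rad)", ylab = "phi (rad)", useRaster = TRUE, ...)
  invisible(x)
}

# Rodrigues rotation matrix about unit axis `u` by angle `ang`.
rotation_about <- function(u, ang) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Rotate a map so its centre of gravity sits on the equator
#'
#' The angular projection distorts distances most near the poles; snapping
#' the data's centre of gravity to inclination pi/2 keeps the map in the
#' least-distorted band. One rigid rotation about the head centroid takes the
#' COG direction to the equator by the minimal angle; the same rotation is
#' applied to the data and the head point cloud so the ellipsoid can be
#' refitted consistently.
#'
#' @param map a [motor_map].
#' @param centroid head centroid (mm) defining the rotation centre.
#' @param cloud optional N x 3 point cloud rotated alongside the data.
#' @return List with `map` (rotated [motor_map]), `cloud` (rotated matrix or
#'   `NULL`) and `rotation` (3 x 3 matrix).
#' @export
snap_cog_to_equator <- function(map, centroid, cloud = NULL) {
  stopifnot(inherits(map, "motor_map"))
  centroid <- as.numeric(centroid)
  cog <- center_of_gravity(map)
  u <- cog - centroid
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop_mm("degenerate_cog_error", "data COG coincides with the centroid")
  u <- u / nu
  v <- c(u[1], u[2], 0)
  nv <- sqrt(sum(v^2))
  if (nv == 0) v <- c(1, 0, 0) else v <- v / nv   # COG on the polar axis: send it to +x
  cosang <- pmin(1, pmax(-1, sum(u * v)))
  ang <- acos(cosang)
  if (ang < 1e-15) {
    R <- diag(3)
  } else {
    axis <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
    na <- sqrt(sum(axis^2))
    if (na == 0) {           # antipodal: rotate by pi about any horizontal axis
      axis <- c(-u[2], u[1], 0)
      na <- sqrt(sum(axis^2))
      if (na == 0) axis <- c(0, 1, 0) else axis <- axis / na
      R <- rotation_about(axis, pi)
    } else {
      R <- rotation_about(axis / na, ang)
    }
  }
  rot <- function(p) sweep(sweep(p, 2L, centroid) %*% t(R), 2L, centroid, `+`)
  pts <- rot(cbind(map$x, map$y, map$z))
  out_map <- motor_map(pts[, 1], pts[, 2], pts[, 3], map$value,
                       reference_point = attr(map, "reference_point"),
                       reference_source = attr(map, "reference_source") %||% "imported",
                       session_label = attr(map, "session_label"))
  out_cloud <- if (is.null(cloud)) NULL else rot(as_points3(cloud))
  list(map = out_map, cloud = out_cloud, rotation = R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
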