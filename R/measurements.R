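# Map feature measurements: centre of gravity, peak, thresholded surface
# area and volume integral by discrete patch integration on the scalp
# ellipsoid, reference-relative position reporting, and peak discretization.

#' Centre of gravity of a motor map
#'
#' The MEP-amplitude-weighted mean of the 3D stimulation positions. Computed
#' from the raw (pre-fit) data; no fitted surface is required. With
#' non-negative weights the COG always lies inside the convex hull of the
#' stimulation sites.
#'
#' @param map a [motor_map] (positions mm, values microvolt).
#' @return Named numeric vector `c(x, y, z)` in mm.
#' @export
center_of_gravity <- function(map) {
  stopifnot(inherits(map, "motor_map"))
  w <- map$value
  total <- sum(w)
  if (total <= 0) stop_mm("zero_mass_error", "all MEP values are zero; COG undefined")
  out <- c(sum(map$x * w), sum(map$y * w), sum(map$z * w)) / total
  names(out) <- c("x", "y", "z")
  out
}

#' Peak of a motor map or fitted surface
#'
#' The absolute maximum measurement (for raw data) or the argmax over a dense
#' evaluation grid (for a fitted surface). Ties go to the lowest event index.
#'
#' @param x a [motor_map] or `motor_surface`.
#' @param ... further arguments; for surfaces: `model` (a `scalp_ellipsoid`,
#'   optional, to report the 3D position), `spacing` (grid spacing, radians).
#' @return List with `value` and `position` (mm for raw maps or when `model`
#'   is given; for surfaces also `theta`, `phi`).
#' @export
map_peak <- function(x, ...) UseMethod("map_peak")

#' @export
map_peak.motor_map <- function(x, ...) {
  i <- which.max(x$value)   # which.max takes the first (lowest index) on ties
  list(position = c(x = x$x[i], y = x$y[i], z = x$z[i]), value = x$value[i])
}

#' @rdname map_peak
#' @param model optional `scalp_ellipsoid` used to map the angular argmax to
#'   3D mm.
#' @param spacing evaluation grid spacing in radians (default `pi/512`).
#' @export
map_peak.motor_surface <- function(x, model = NULL, spacing = pi / 512, ...) {
  g <- surface_cells(x, spacing)
  v <- g$values
  if (all(is.na(v))) stop_mm("no_peak_error", "surface is undefined on the whole grid")
  i <- which.max(v)          # NA cells never win; first index on ties
  ij <- arrayInd(i, dim(v))
  th <- g$theta_centers[ij[1]]; ph <- g$phi_centers[ij[2]]
  out <- list(theta = th, phi = ph, value = v[i])
  if (!is.null(model)) {
    p <- predict(model, th, ph)
    out$position <- c(x = p[1, 1], y = p[1, 2], z = p[1, 3])
  }
  out
}

# Dense cell-grid evaluation shared by SA/VI/peak/discretization.
# Cells are indexed by their lower corner (theta_j, phi_k); the map value is
# sampled at the cell centre (midpoint rule), while patch vectors p, q run
# between the corners (theta,phi) -> (theta+s,phi) and (theta,phi) -> (theta,phi+s).
surface_cells <- function(surface, spacing, theta_range = NULL, phi_range = NULL) {
  if (spacing <= 0) stop_mm("value_error", "grid spacing must be > 0")
  if (inherits(surface, "motor_surface")) {
    if (is.null(theta_range)) theta_range <- range(surface$theta)
    if (is.null(phi_range)) phi_range <- range(surface$phi)
    value_fn <- function(th, ph) predict(surface, th, ph)
  } else if (is.function(surface)) {
    if (is.null(theta_range) || is.null(phi_range)) {
      stop_mm("value_error", "theta_range and phi_range are required for a function surface")
    }
    value_fn <- surface
  } else {
    stop_mm("value_error", "surface must be a motor_surface or a function(theta, phi)")
  }
  n_th <- max(1L, ceiling((theta_range[2] - theta_range[1]) / spacing))
  n_ph <- max(1L, ceiling((phi_range[2] - phi_range[1]) / spacing))
  th0 <- theta_range[1] + (0:(n_th - 1L)) * spacing   # lower corners
  ph0 <- phi_range[1] + (0:(n_ph - 1L)) * spacing
  centers <- expand.grid(theta = th0 + spacing / 2, phi = ph0 + spacing / 2)
  values <- matrix(value_fn(centers$theta, centers$phi), nrow = n_th)
  list(theta_corners = c(th0, th0[n_th] + spacing),
       phi_corners = c(ph0, ph0[n_ph] + spacing),
       theta_centers = th0 + spacing / 2,
       phi_centers = ph0 + spacing / 2,
       values = values, spacing = spacing)
}

# Areas of all grid patches on the ellipsoid: ||p x q|| per cell, where p and
# q join the cell corner to its theta- and phi-neighbouring corners.
patch_areas <- function(model, cells) {
  thc <- cells$theta_corners; phc <- cells$phi_corners
  n_th <- length(thc); n_ph <- length(phc)
  corner_grid <- expand.grid(theta = thc, phi = phc)
  P <- predict(model, corner_grid$theta, corner_grid$phi)
  Px <- matrix(P[, 1], n_th); Py <- matrix(P[, 2], n_th); Pz <- matrix(P[, 3], n_th)
  i <- 1:(n_th - 1L); j <- 1:(n_ph - 1L)
  px <- Px[i + 1L, j, drop = FALSE] - Px[i, j, drop = FALSE]
  py <- Py[i + 1L, j, drop = FALSE] - Py[i, j, drop = FALSE]
  pz <- Pz[i + 1L, j, drop = FALSE] - Pz[i, j, drop = FALSE]
  qx <- Px[i, j + 1L, drop = FALSE] - Px[i, j, drop = FALSE]
  qy <- Py[i, j + 1L, drop = FALSE] - Py[i, j, drop = FALSE]
  qz <- Pz[i, j + 1L, drop = FALSE] - Pz[i, j, drop = FALSE]
  cx <- py * qz - pz * qy
  cy <- pz * qx - px * qz
  cz <- px * qy - py * qx
  sqrt(cx^2 + cy^2 + cz^2)
}

patch_integrals <- function(surface, model, spacing = pi / 512, threshold = 0,
                            theta_range = NULL, phi_range = NULL,
                            region = NULL) {
  stopifnot(inherits(model, "scalp_ellipsoid"))
  cells <- surface_cells(surface, spacing, theta_range, phi_range)
  areas <- patch_areas(model, cells)
  qualifies <- !is.na(cells$values) & cells$values > threshold
  if (!is.null(region)) qualifies <- qualifies & region
  sa <- sum(areas[qualifies])
  vi <- sum(areas[qualifies] * cells$values[qualifies])
  list(surface_area = sa, volume_integral = vi, cells = cells,
       areas = areas, qualifies = qualifies)
}

#' Thresholded surface area of a motor map
#'
#' Discrete patch integration on the scalp ellipsoid: every angular grid cell
#' whose map value is strictly above the threshold contributes the area of
#' its surface patch, `||p x q||`, where `p` and `q` are the 3D edge vectors
#' of the cell obtained by mapping the corners `(theta, phi)`,
#' `(theta + s, phi)` and `(theta, phi + s)` through the ellipsoid. Cells
#' where the surface is undefined (outside the training hull) are excluded.
#'
#' @param surface a `motor_surface` (or a `function(theta, phi)` returning
#'   map values, mainly for testing against closed forms).
#' @param model a `scalp_ellipsoid`.
#' @param spacing grid pixel spacing in radians (default `pi/512`).
#' @param threshold inclusion threshold in map units (default 0).
#' @param theta_range,phi_range integration extents; default the training
#'   hull's bounding box.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(surface, model, spacing = pi / 512, threshold = 0,
                         theta_range = NULL, phi_range = NULL) {
  patch_integrals(surface, model, spacing, threshold,
                  theta_range, phi_range)$surface_area
}

#' Volume integral of a motor map
#'
#' As [surface_area()], but each qualifying patch is weighted by its map
#' value: `VI = sum ||p x q|| * v`. A proxy for overall corticospinal
#' excitability: doubling every map value doubles VI while leaving the COG
#' unchanged.
#'
#' @inheritParams surface_area
#' @return Volume integral in map-units times mm^2 (microvolt mm^2 for
#'   amplitude maps).
#' @export
volume_integral <- function(surface, model, spacing = pi / 512, threshold = 0,
                            theta_range = NULL, phi_range = NULL) {
  patch_integrals(surface, model, spacing, threshold,
                  theta_range, phi_range)$volume_integral
}

#' Position of a point relative to a reference point
#'
#' Signed per-axis components (right-left, posterior-anterior,
#' inferior-superior, i.e. point minus reference in the scanner frame) and
#' the Euclidean distance, all in mm.
#'
#' @param point,reference length-3 numeric positions in mm.
#' @return Named list `x`, `y`, `z`, `euclidean`.
#' @export
position_report <- function(point, reference) {
  point <- as.numeric(point); reference <- as.numeric(reference)
  assert_finite(c(point, reference), "positions")
  d <- point - reference
  list(x = d[1], y = d[2], z = d[3], euclidean = sqrt(sum(d^2)))
}

#' Discretize a motor map into individual peaks
#'
#' Maps from subjects with neurologic conditions (e.g. cerebral palsy) can
#' show several distinct hotspots. This splits the above-threshold part of
#' the fitted surface into one region per prominent local maximum using a
#' persistence-gated watershed: grid cells are flooded in order of
#' decreasing value; a new region starts at each unclaimed local maximum,
#' and when two regions meet, the shallower one is merged into the deeper
#' unless its prominence (peak value minus meeting level) reaches
#' `min_prominence` times the global maximum. Per-region COG, peak, surface
#' area and volume integral are computed from the region's cells only.
#'
#' @param surface a `motor_surface`.
#' @param model a `scalp_ellipsoid`.
#' @param spacing grid spacing in radians (default `pi/256`).
#' @param threshold inclusion threshold in map units (default 0).
#' @param min_prominence fraction of the global maximum a local peak must
#'   rise above its saddle to count as a separate region (default 0.1).
#' @return List of `peak_region` objects, ordered by decreasing peak value;
#'   each has `peak` (theta, phi, value, position mm), `cog` (mm),
#'   `surface_area`, `volume_integral`, `n_cells` and a logical `mask` on the
#'   cell grid (with `theta`/`phi` centre attributes).
#' @export
discretize_peaks <- function(surface, model, spacing = pi / 256, threshold = 0,
                             min_prominence = 0.1) {
  pi_ <- patch_integrals(surface, model, spacing, threshold)
  V <- pi_$cells$values
  Q <- pi_$qualifies
  if (!any(Q)) stop_mm("no_peak_error", "no grid cell above threshold")
  gmax <- max(V[Q])
  prom_limit <- min_prominence * gmax
  d <- dim(V)
  labels <- matrix(0L, d[1], d[2])
  peak_value <- numeric(0)      # per-label peak height
  parent <- integer(0)          # union-find
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  ord <- order(V[Q], decreasing = TRUE)
  cells_idx <- which(Q)[ord]
  for (ci in cells_idx) {
    ij <- arrayInd(ci, d)
    i <- ij[1]; j <- ij[2]
    nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2], , drop = FALSE]
    nb_lab <- labels[nb]
    nb_roots <- unique(vapply(nb_lab[nb_lab > 0L], find, integer(1)))
    if (length(nb_roots) == 0L) {
      new_lab <- length(parent) + 1L
      parent[new_lab] <- new_lab
      peak_value[new_lab] <- V[ci]
      labels[ci] <- new_lab
    } else if (length(nb_roots) == 1L) {
      labels[ci] <- nb_roots
    } else {
      keep <- nb_roots[which.max(peak_value[nb_roots])]
      for (r in setdiff(nb_roots, keep)) {
        if (peak_value[r] - V[ci] < prom_limit) {
          parent[r] <- keep          # not prominent enough: merge basins
        }
      }
      labels[ci] <- keep
    }
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  final <- matrix(0L, d[1], d[2])
  final[Q] <- roots[labels[Q]]
  region_ids <- sort(unique(final[final > 0L]))
  region_ids <- region_ids[order(peak_value[region_ids], decreasing = TRUE)]

  th_c <- pi_$cells$theta_centers; ph_c <- pi_$cells$phi_centers
  regions <- lapply(region_ids, function(id) {
    mask <- final == id
    idx <- which(mask)
    ij <- arrayInd(idx, d)
    th <- th_c[ij[, 1]]; ph <- ph_c[ij[, 2]]
    v <- V[idx]; a <- pi_$areas[idx]
    pos <- predict(model, th, ph)
    w <- v / sum(v)
    imax <- which.max(v)
    structure(list(
      peak = list(theta = th[imax], phi = ph[imax], value = v[imax],
                  position = c(x = pos[imax, 1], y = pos[imax, 2], z = pos[imax, 3])),
      cog = c(x = sum(pos[, 1] * w), y = sum(pos[, 2] * w), z = sum(pos[, 3] * w)),
      surface_area = sum(a),
      volume_integral = sum(a * v),
      n_cells = length(idx),
      mask = structure(mask, theta = th_c, phi = ph_c)
    ), class = "peak_region")
  })
  regions
}

#' @export
print.peak_region <- function(x, ...) {
  cat(sprintf("<peak_region> peak %.1f at (theta %.3f, phi %.3f), %d cells\n",
              x$peak$value, x$peak$theta, x$peak$phi, x$n_cells))
  cat(sprintf("  SA %.1f mm^2, VI %.4g uV mm^2\n", x$surface_area, x$volume_integral))
  invisible(x)
}

#' Measure all features of one motor map
#'
#' Runs the single-map measurement stage: COG and peak from the raw events,
#' surface area and volume integral from a surface fitted to the
#' (consolidated) events in angular space, and position reports of COG and
#' peak relative to the reference point (the map's imported reference point,
#' or the head centroid by default).
#'
#' @param map a [motor_map] (already consolidated if it held repeats).
#' @param model a `scalp_ellipsoid`.
#' @param algorithm surface fitting algorithm (see [fit_surface()]).
#' @param spacing integration grid spacing in radians.
#' @param sa_threshold inclusion threshold for SA/VI (map units, default 0).
#' @param reference optional length-3 reference point (mm); overrides the
#'   map's own.
#' @return An object of class `map_measurements`.
#' @export
measure_map <- function(map, model, algorithm = "cubic", spacing = pi / 512,
                        sa_threshold = 0, reference = NULL) {
  stopifnot(inherits(map, "motor_map"), inherits(model, "scalp_ellipsoid"))
  ref_src <- "user_set"
  if (is.null(reference)) {
    reference <- attr(map, "reference_point")
    ref_src <- "imported"
  }
  if (is.null(reference)) {
    reference <- model$centroid
    ref_src <- "centroid_default"
  }
  cog <- center_of_gravity(map)
  peak <- map_peak(map)
  surf <- fit_surface(project_events(map, model), algorithm = algorithm)
  ints <- patch_integrals(surf, model, spacing, sa_threshold)
  structure(list(
    cog = cog,
    peak = peak,
    surface_area = ints$surface_area,
    volume_integral = ints$volume_integral,
    sa_threshold = sa_threshold,
    algorithm = algorithm,
    reference_point = stats::setNames(as.numeric(reference), c("x", "y", "z")),
    reference_source = ref_src,
    cog_to_reference = position_report(cog, reference),
    peak_to_reference = position_report(peak$position, reference),
    surface = surf
  ), class = "map_measurements")
}

#' @export
print.map_measurements <- function(x, ...) {
  cat("Motor map measurements\n")
  cat(sprintf("  COG:  (%.2f, %.2f, %.2f) mm  [%.2f mm from reference]\n",
              x$cog[1], x$cog[2], x$cog[3], x$cog_to_reference$euclidean))
  cat(sprintf("  Peak: %.1f uV at (%.2f, %.2f, %.2f) mm  [%.2f mm from reference]\n",
              x$peak$value, x$peak$position[1], x$peak$position[2],
              x$peak$position[3], x$peak_to_reference$euclidean))
  cat(sprintf("  SA (> %.4g uV): %.2f mm^2\n", x$sa_threshold, x$surface_area))
  cat(sprintf("  VI: %.6g uV mm^2   [%s fit]\n", x$volume_integral, x$algorithm))
  cat(sprintf("  reference (%s): (%.2f, %.2f, %.2f) mm\n", x$reference_source,
              x$reference_point[1], x$reference_point[2], x$reference_point[3]))
  invisible(x)
}
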