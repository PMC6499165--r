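# Non-parametric surface fitting in angular space: z = S(theta, phi).
#
# Four algorithms, all evaluable at arbitrary angular coordinates inside the
# convex hull of the training sites (outside the hull the surface is
# undefined and predictions are NA -- the map was never sampled there):
#   piecewise linear  -- barycentric interpolation on a Delaunay
#                        triangulation (interp package)
#   piecewise cubic   -- C1 piecewise-cubic spline on the same triangulation
#                        (interp package; Akima-style patches)
#   biharmonic        -- biharmonic ("v4") spline: one Green's-function
#                        basis g(r) = r^2 (log r - 1) per data point
#   lowess            -- locally weighted first-order regression over the
#                        nearest span*N points, tricube weights

SURFACE_ALGORITHMS <- c("cubic", "linear", "biharmonic", "lowess")

biharmonic_green <- function(r) ifelse(r > 0, r^2 * (log(r) - 1), 0)

#' Project a motor map into angular coordinates
#'
#' Convenience wrapper attaching `(theta, phi)` from [cartesian_to_angular()]
#' to the event table, ready for [fit_surface()].
#'
#' @param map a [motor_map].
#' @param model a `scalp_ellipsoid` (its centroid is the angular origin), or
#'   a length-3 centroid vector.
#' @return data.frame with columns `theta`, `phi`, `value`.
#' @export
project_events <- function(map, model) {
  stopifnot(inherits(map, "motor_map"))
  centroid <- if (inherits(model, "scalp_ellipsoid")) model$centroid else as.numeric(model)
  ang <- cartesian_to_angular(map, centroid)
  data.frame(theta = ang$theta, phi = ang$phi, value = map$value)
}

#' Fit a continuous surface to an angular motor map
#'
#' Fits `value = S(theta, phi)` to consolidated (or raw) angular data with
#' one of four non-parametric algorithms. `"cubic"`, `"linear"` and
#' `"biharmonic"` interpolate: they return the training value at every
#' training site. `"lowess"` smooths (span fixed at 0.25 of the data by
#' default) and is exempt from the interpolation property.
#'
#' @param data data.frame with columns `theta`, `phi`, `value` (radians,
#'   microvolt or consolidated units), e.g. from [project_events()].
#' @param algorithm one of `"cubic"`, `"linear"`, `"biharmonic"`, `"lowess"`.
#' @param span lowess smoothing ratio in (0, 1]; fraction of points entering
#'   each local regression (default 0.25).
#' @return An object of class `motor_surface` with a [predict][predict.motor_surface]
#'   method.
#' @export
fit_surface <- function(data, algorithm = c("cubic", "linear", "biharmonic", "lowess"),
                        span = 0.25) {
  if (length(algorithm) == 1L && !algorithm %in% SURFACE_ALGORITHMS) {
    stop_mm("method_error", sprintf("unknown surface algorithm '%s'", algorithm))
  }
  algorithm <- match.arg(algorithm)
  if (!all(c("theta", "phi", "value") %in% names(data))) {
    stop_mm("schema_error", "data must have columns theta, phi, value")
  }
  th <- as.numeric(data$theta); ph <- as.numeric(data$phi)
  v <- as.numeric(data$value)
  assert_finite(cbind(th, ph, v), "training data")
  n <- length(v)
  dup <- duplicated(cbind(th, ph))
  if (algorithm %in% c("cubic", "linear")) {
    if (any(dup)) {
      stop_mm("degenerate_geometry_error", "duplicate training sites")
    }
    if (n < 3L) {
      stop_mm("degenerate_geometry_error",
              "piecewise fits need at least 3 non-collinear sites")
    }
  }
  if (algorithm == "biharmonic" && any(dup)) {
    # collapse duplicates by averaging before solving the dense system
    key <- paste(th, ph)
    th <- tapply(th, key, mean); ph <- tapply(ph, key, mean)
    v <- tapply(v, key, mean)
    th <- as.numeric(th); ph <- as.numeric(ph); v <- as.numeric(v)
    n <- length(v)
  }
  tri <- NULL
  if (n >= 3L) {
    tri <- tryCatch(interp::tri.mesh(th, ph), error = function(e) NULL)
    if (is.null(tri) && algorithm %in% c("cubic", "linear")) {
      stop_mm("degenerate_geometry_error",
              "training sites are collinear; no triangulation exists")
    }
  } else if (algorithm %in% c("cubic", "linear")) {
    stop_mm("degenerate_geometry_error", "too few sites for a triangulation")
  }

  fit <- list(algorithm = algorithm, theta = th, phi = ph, value = v,
              span = span, tri = tri)
  if (algorithm == "biharmonic") {
    if (n == 1L) {
      fit$coefficients <- 0   # single site: surface defined only there
      fit$intercept <- v
    } else {
      # Green's-function system augmented with a constant trend subject to
      # sum(alpha) = 0, so constant data reproduce exactly and adding c to
      # all values shifts every prediction by exactly c.
      D <- as.matrix(stats::dist(cbind(th, ph)))
      G <- biharmonic_green(D)
      A <- rbind(cbind(G, 1), c(rep(1, n), 0))
      sol <- tryCatch(solve(A, c(v, 0)), error = function(e) {
        stop_mm("singular_system_error",
                paste("biharmonic system is singular:", conditionMessage(e)))
      })
      fit$coefficients <- sol[seq_len(n)]
      fit$intercept <- sol[n + 1L]
    }
  }
  if (algorithm == "cubic") {
    fit$gradients <- ct_gradients(tri, v)
  }
  if (algorithm == "lowess") {
    k <- ceiling(span * n)
    fit$k <- k
    # global first-order fit, used when fewer than 3 points fall in span
    fit$global_fit <- stats::lm.fit(cbind(1, th, ph), v)$coefficients
  }
  class(fit) <- "motor_surface"
  fit
}

in_hull <- function(object, theta, phi) {
  if (!is.null(object$tri)) {
    interp::in.convex.hull(object$tri, theta, phi, strict = FALSE)
  } else {
    # degenerate geometry (1-2 sites or collinear): defined only at sites
    vapply(seq_along(theta), function(i) {
      any(abs(theta[i] - object$theta) < 1e-12 & abs(phi[i] - object$phi) < 1e-12)
    }, logical(1))
  }
}

#' Evaluate a fitted motor-map surface
#'
#' Predicts the surface value at arbitrary angular coordinates. Coordinates
#' outside the convex hull of the training sites return `NA` (the surface is
#' undefined where the map was not sampled; no extrapolation is performed).
#'
#' @param object a `motor_surface`.
#' @param theta,phi numeric vectors (radians) of equal length; `theta` may be
#'   a data.frame with columns `theta`, `phi`.
#' @param ... unused.
#' @return Numeric vector of predicted values (`NA` outside the hull).
#' @export
predict.motor_surface <- function(object, theta, phi = NULL, ...) {
  if (is.data.frame(theta)) { phi <- theta$phi; theta <- theta$theta }
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  stopifnot(length(theta) == length(phi))
  if (length(theta) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(theta))
  ok <- in_hull(object, theta, phi) & is.finite(theta) & is.finite(phi)
  if (!any(ok)) return(out)
  tq <- theta[ok]; pq <- phi[ok]
  out[ok] <- switch(object$algorithm,
    linear = interp_delaunay(object, tq, pq),
    cubic = ct_interpolate(object, tq, pq),
    biharmonic = {
      if (length(object$value) == 1L) {
        rep(object$value, length(tq))
      } else {
        r <- sqrt(outer(tq, object$theta, `-`)^2 + outer(pq, object$phi, `-`)^2)
        as.numeric(biharmonic_green(r) %*% object$coefficients) + object$intercept
      }
    },
    lowess = lowess_predict(object, tq, pq)
  )
  out
}

interp_delaunay <- function(object, tq, pq) {
  # interpp retries with jitter on near-degenerate (gridded) site layouts;
  # the retry warning is informational only
  res <- withCallingHandlers(
    interp::interpp(object$theta, object$phi, object$value,
                    xo = tq, yo = pq, linear = TRUE,
                    extrap = FALSE, duplicate = "error"),
    warning = function(w) {
      if (grepl("shull", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  snap_site_misses(object, tq, pq, res$z)
}

ct_interpolate <- function(object, tq, pq) {
  vals <- ct_evaluate(object$tri, object$value, object$gradients, tq, pq)
  snap_site_misses(object, tq, pq, vals)
}

# boundary queries occasionally miss by floating-point; snap exact site hits
snap_site_misses <- function(object, tq, pq, vals) {
  miss <- is.na(vals)
  if (any(miss)) {
    for (i in which(miss)) {
      hit <- which(abs(tq[i] - object$theta) < 1e-12 &
                   abs(pq[i] - object$phi) < 1e-12)
      if (length(hit)) vals[i] <- object$value[hit[1]]
    }
  }
  vals
}

lowess_predict <- function(object, tq, pq) {
  n <- length(object$value)
  k <- object$k
  if (k < 3L) {
    return(cbind(1, tq, pq) %*% object$global_fit)
  }
  vapply(seq_along(tq), function(i) {
    d <- sqrt((object$theta - tq[i])^2 + (object$phi - pq[i])^2)
    ord <- order(d)[seq_len(k)]
    h <- max(d[ord])
    if (h == 0) return(mean(object$value[ord]))
    w <- (1 - pmin(d[ord] / h, 1)^3)^3
    w[w <= 0] <- 1e-9          # keep the furthest neighbour barely weighted
    A <- cbind(1, object$theta[ord], object$phi[ord])
    fit <- tryCatch(stats::lm.wfit(A, object$value[ord], w)$coefficients,
                    error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit))) {
      # collinear neighbourhood: weighted mean fallback
      return(sum(w * object$value[ord]) / sum(w))
    }
    sum(c(1, tq[i], pq[i]) * fit)
  }, numeric(1))
}

#' Evaluate a surface on a dense angular grid
#'
#' @param object a `motor_surface`.
#' @param theta,phi numeric axis vectors (radians).
#' @return A `length(theta)` x `length(phi)` matrix of predictions (`NA`
#'   outside the training hull).
#' @export
evaluate_surface <- function(object, theta, phi) {
  grid <- expand.grid(theta = theta, phi = phi)
  matrix(predict(object, grid$theta, grid$phi), nrow = length(theta))
}

#' @export
print.motor_surface <- function(x, ...) {
  cat(sprintf("<motor_surface> algorithm = %s, %d training sites\n",
              x$algorithm, length(x$value)))
  cat(sprintf("  theta in [%.3f, %.3f], phi in [%.3f, %.3f] rad\n",
              min(x$theta), max(x$theta), min(x$phi), max(x$phi)))
  if (x$algorithm == "lowess") cat(sprintf("  span = %.2f (%d points per fit)\n", x$span, x$k))
  invisible(x)
}

#' @export
residuals.motor_surface <- function(object, ...) {
  object$value - predict(object, object$theta, object$phi)
}

#' @export
plot.motor_surface <- function(x, spacing = diff(range(x$theta)) / 100, ...) {
  th <- seq(min(x$theta), max(x$theta), by = spacing)
  ph <- seq(min(x$phi), max(x$phi), by = spacing)
  z <- evaluate_surface(x, th, ph)
  graphics::image(th, ph, z, xlab = "theta (rad)", ylab = "phi (rad)",
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  graphics::points(x$theta, x$phi, pch = 20, cex = 0.4)
  invisible(x)
}
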