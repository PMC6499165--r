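# Shared fixtures and independent oracles. Heavyweight objects (the head
# phantom and the head model fitted to it) are built once per test run and
# cached.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(.fixtures$phantom)) .fixtures$phantom <- make_head_phantom()
  .fixtures$phantom
}

fixture_head_model <- function() {
  if (is.null(.fixtures$model)) {
    ph <- fixture_phantom()
    mask <- segment_head(ph$scan)
    cloud <- sample_point_cloud(mask)
    .fixtures$model <- fit_scalp_ellipsoid(cloud)
  }
  .fixtures$model
}

# Exact-sphere scalp model: radius R about `centroid` (w2 = R, rest 0).
sphere_model <- function(R, centroid = c(0, 0, 0)) {
  w <- matrix(0, 10, 3)
  w[2, ] <- R
  scalp_ellipsoid(w, centroid)
}

# Surface point cloud of an axis-aligned ellipsoid (not a solid volume).
ellipsoid_surface_cloud <- function(radii, centroid = c(0, 0, 0), n = 2000) {
  # uniform-on-sphere directions scaled per axis
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(sweep(u, 2, radii, `*`), 2, centroid, `+`)
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_motor_map <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  motor_map(runif(n, 0, 200), runif(n, 0, 200), runif(n, 0, 200),
            runif(n, 0, 5000))
}

# --- independent oracles -------------------------------------------------

# Eq-1 style centroid by naive scalar accumulation.
oracle_centroid <- function(points) {
  sx <- 0; sy <- 0; sz <- 0
  for (i in seq_len(nrow(points))) {
    sx <- sx + points[i, 1]; sy <- sy + points[i, 2]; sz <- sz + points[i, 3]
  }
  c(sx, sy, sz) / nrow(points)
}

# Term-by-term evaluation of the per-axis polynomial ellipsoid.
oracle_angular_to_cartesian <- function(weights, centroid, theta, phi) {
  out <- matrix(0, length(theta), 3)
  for (i in seq_along(theta)) {
    th <- theta[i]; ph <- phi[i]
    trig <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    for (ax in 1:3) {
      w <- weights[, ax]
      poly <- w[2] + w[3] * th + w[4] * ph + w[5] * th^2 + w[6] * ph^2 +
        w[7] * th^3 + w[8] * ph^3 + w[9] * th^4 + w[10] * ph^4
      out[i, ax] <- w[1] + poly * trig[ax] + centroid[ax]
    }
  }
  out
}

# Exhaustive quality-threshold clustering on a handful of points: the
# candidate cluster for each seed is found by checking every subset.
oracle_qt_cluster <- function(points, threshold) {
  n <- nrow(points)
  stopifnot(n <= 10)
  D <- as.matrix(stats::dist(points))
  limit <- threshold * max(D)
  remaining <- seq_len(n)
  labels <- integer(n)
  lab <- 0L
  while (length(remaining)) {
    best <- integer(0)
    for (seed in remaining) {
      m <- length(remaining)
      for (bits in 0:(2^m - 1)) {
        subset <- remaining[bitwAnd(bits, 2^(seq_len(m) - 1)) > 0]
        if (!(seed %in% subset)) next
        if (length(subset) <= length(best)) next
        if (length(subset) == 1 || max(D[subset, subset]) <= limit) best <- subset
      }
    }
    lab <- lab + 1L
    labels[best] <- lab
    remaining <- setdiff(remaining, best)
  }
  labels
}

# Rank-based AUC (Mann-Whitney with tie correction).
oracle_auc <- function(predictions, labels) {
  r <- rank(predictions)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Partition equality up to relabelling.
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}
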