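test_that("head segmentation recovers the phantom mask", {
  ph <- fixture_phantom()
  seg <- segment_head(ph$scan)
  expect_gte(dice_coefficient(seg$mask, ph$mask$mask), 0.99)

  noisy <- make_head_phantom(noise_sd = 5, seed = 21)   # 5% of foreground 100
  seg_n <- segment_head(noisy$scan)
  expect_gte(dice_coefficient(seg_n$mask, noisy$mask$mask), 0.98)

  blank <- head_scan(array(0, c(8, 8, 8)))
  expect_error(segment_head(blank), class = "no_foreground_error")
})

test_that("point-cloud sampling takes every stride-th foreground voxel", {
  mask <- array(FALSE, c(10, 10, 1))
  mask[1:10, 1:10, 1] <- TRUE
  hm <- structure(list(mask = mask, spacing = c(2, 2, 2)), class = "head_mask")
  expect_equal(nrow(sample_point_cloud(hm, stride = 1)), 100L)
  expect_equal(nrow(sample_point_cloud(hm, stride = 25)), ceiling(100 / 25))
  for (k in c(37, 99, 100)) {
    mask_k <- array(FALSE, c(10, 10, 1)); mask_k[seq_len(k)] <- TRUE
    hm_k <- structure(list(mask = mask_k, spacing = c(1, 1, 1)), class = "head_mask")
    expect_equal(nrow(sample_point_cloud(hm_k, stride = 25)), ceiling(k / 25))
  }
  expect_equal(formals(sample_point_cloud)$stride, 25L)
  # coordinates are 0-based voxel index times spacing
  pts <- sample_point_cloud(hm, stride = 1)
  expect_equal(pts[1, ], c(x = 0, y = 0, z = 0))
  small <- structure(list(mask = array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                          spacing = c(1, 1, 1)), class = "head_mask")
  expect_error(sample_point_cloud(small, stride = 25),
               class = "insufficient_foreground_error")
})

test_that("centroid is the coordinate-wise mean", {
  expect_equal(compute_centroid(matrix(c(3, 4, 5), 1)), c(x = 3, y = 4, z = 5))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(unname(compute_centroid(cube)), c(0.5, 0.5, 0.5))
  set.seed(5)
  pts <- matrix(runif(3000, -50, 50), ncol = 3)
  expect_equal(unname(compute_centroid(pts)), oracle_centroid(pts),
               tolerance = 1e-12)
})

test_that("cartesian/angular conversion follows the inclination-azimuth convention", {
  o <- c(10, 20, 30)
  a <- cartesian_to_angular(matrix(c(10, 20, 45), 1), o)   # straight above
  expect_equal(a$theta, 0)
  a2 <- cartesian_to_angular(matrix(c(25, 20, 30), 1), o)  # +x direction
  expect_equal(a2$theta, pi / 2)
  expect_equal(a2$phi, 0)
  expect_error(cartesian_to_angular(matrix(o, 1), o),
               class = "degenerate_point_error")

  # round-trip through an exact-sphere model
  set.seed(6)
  R <- 80
  dirs <- matrix(rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * R, 2, o, `+`)
  mod <- sphere_model(R, o)
  ang <- cartesian_to_angular(pts, o)
  back <- predict(mod, ang$theta, ang$phi)
  expect_lt(max(abs(back - pts)) / R, 1e-9)
})

test_that("ellipsoid fit is exact on a sphere and accurate on an ellipsoid", {
  set.seed(7)
  o <- c(100, 120, 90); R <- 85
  cloud <- ellipsoid_surface_cloud(c(R, R, R), o, n = 1500)
  fit <- fit_scalp_ellipsoid(cloud, o)
  ang <- data.frame(theta = acos(runif(1000, -1, 1)), phi = runif(1000, -pi, pi))
  pred <- predict(fit, ang)
  radii <- sqrt(rowSums(sweep(pred, 2, o)^2))
  expect_lt(max(abs(radii - R)), 1e-6 * R)
  expect_equal(unname(coef(fit)[2, ]), c(R, R, R), tolerance = 1e-6)

  # triaxial ellipsoid: held-out surface points within 2% RMS radial error
  radii3 <- c(90, 110, 80)
  train <- ellipsoid_surface_cloud(radii3, o, n = 3000)
  test <- ellipsoid_surface_cloud(radii3, o, n = 500)
  fit3 <- fit_scalp_ellipsoid(train, o)
  ang_t <- cartesian_to_angular(test, o)
  pred_t <- predict(fit3, ang_t)
  r_pred <- sqrt(rowSums(sweep(pred_t, 2, o)^2))
  r_true <- sqrt(rowSums(sweep(test, 2, o)^2))
  rms <- sqrt(mean((r_pred - r_true)^2))
  expect_lt(rms, 0.02 * mean(r_true))

  expect_error(fit_scalp_ellipsoid(cloud[1:9, ], o),
               class = "insufficient_points_error")
  # all points along one ray: rank-deficient design
  ray <- cbind(seq(1, 20), seq(1, 20), seq(1, 20))
  expect_error(fit_scalp_ellipsoid(sweep(ray, 2, o, `+`), o),
               class = "singular_design_error")
})

test_that("model evaluation matches independent term-by-term expansion", {
  o <- c(5, -3, 12)
  mod <- sphere_model(70, o)
  p <- predict(mod, 0, 0)
  expect_equal(unname(p[1, ]), o + c(0, 0, 70), tolerance = 1e-12)
  p2 <- predict(mod, pi / 2, 0)
  expect_equal(unname(p2[1, ]), o + c(70, 0, 0), tolerance = 1e-12)

  set.seed(8)
  w <- matrix(rnorm(30, 0, 5), 10, 3)
  m <- scalp_ellipsoid(w, o)
  theta <- runif(50, 0, pi); phi <- runif(50, -pi, pi)
  expect_equal(unname(predict(m, theta, phi)),
               oracle_angular_to_cartesian(w, o, theta, phi),
               tolerance = 1e-12)
})

test_that("fit residual is non-increasing as polynomial terms are added", {
  set.seed(9)
  cloud <- ellipsoid_surface_cloud(c(90, 110, 80), c(0, 0, 0), n = 800)
  rms <- vapply(1:10, function(k) {
    sqrt(mean(residuals(fit_scalp_ellipsoid(cloud, c(0, 0, 0), n_terms = k))^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
})

test_that("topographic rendering samples the scan on the model surface", {
  ph <- fixture_phantom()
  R <- 60                                       # inside the phantom everywhere
  mod <- sphere_model(R, ph$center)
  topo <- render_topographic(ph$scan, mod, spacing = pi / 64)
  expect_true(all(topo$image == 100))           # uniform interior intensity

  # a bright marker at a known angular position shows up at that pixel
  s <- pi / 64
  th_star <- 20 * s; ph_star <- 10 * s
  scan2 <- ph$scan
  p <- predict(mod, th_star, -pi + ph_star)
  ijk <- round(p / ph$scan$spacing) + 1
  scan2$data[ijk[1], ijk[2], ijk[3]] <- 999
  topo2 <- render_topographic(scan2, mod, spacing = s)
  expect_equal(topo2$image[21, 11], 999)

  # halving the pixel spacing leaves shared angular coordinates unchanged
  topo_h <- render_topographic(scan2, mod, spacing = s / 2)
  expect_equal(topo_h$image[seq(1, nrow(topo_h$image), by = 2),
                            seq(1, ncol(topo_h$image), by = 2)],
               topo2$image)
})

test_that("equator snapping is a rigid rotation taking the COG to inclination pi/2", {
  o <- c(0, 0, 0); R <- 90
  # already equatorial: identity
  m_eq <- motor_map(c(R, R), c(5, -5), c(0, 0), c(100, 100))
  out <- snap_cog_to_equator(m_eq, o)
  expect_equal(cbind(out$map$x, out$map$y, out$map$z),
               cbind(m_eq$x, m_eq$y, m_eq$z), tolerance = 1e-12)

  # cluster near the pole
  set.seed(10)
  th <- runif(40, 0, 0.2); phv <- runif(40, -pi, pi)
  pts <- cbind(R * sin(th) * cos(phv), R * sin(th) * sin(phv), R * cos(th))
  m <- motor_map(pts[, 1], pts[, 2], pts[, 3], runif(40, 10, 500))
  cloud <- ellipsoid_surface_cloud(c(R, R, R), o, n = 200)
  out2 <- snap_cog_to_equator(m, o, cloud)
  cog2 <- center_of_gravity(out2$map)
  incl <- acos(cog2[3] / sqrt(sum(cog2^2)))
  expect_equal(unname(incl), pi / 2, tolerance = 1e-9)
  # pairwise 3D distances preserved (data and cloud)
  expect_equal(as.matrix(dist(cbind(out2$map$x, out2$map$y, out2$map$z))),
               as.matrix(dist(pts)), tolerance = 1e-9)
  expect_equal(as.matrix(dist(out2$cloud)), as.matrix(dist(cloud)),
               tolerance = 1e-9)

  m_deg <- motor_map(0, 0, 0, 100)   # COG at the centroid
  expect_error(snap_cog_to_equator(m_deg, o), class = "degenerate_cog_error")
})

test_that("rigid motions of data and reference leave distance reports unchanged", {
  set.seed(12)
  m <- random_motor_map(30)
  ref <- c(90, 110, 100)
  rep1 <- position_report(center_of_gravity(m), ref)
  ang <- 0.7
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  shift <- c(12, -7, 33)
  pts <- cbind(m$x, m$y, m$z) %*% t(Rz)
  m2 <- motor_map(pts[, 1] + shift[1], pts[, 2] + shift[2], pts[, 3] + shift[3],
                  m$value)
  ref2 <- as.numeric(Rz %*% ref + shift)
  rep2 <- position_report(center_of_gravity(m2), ref2)
  expect_equal(rep2$euclidean, rep1$euclidean, tolerance = 1e-6)
})
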