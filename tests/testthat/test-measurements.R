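test_that("COG is the value-weighted mean of positions", {
  m_eq <- motor_map(c(0, 10, 20), c(0, 0, 30), c(5, 5, 5), c(7, 7, 7))
  expect_equal(unname(center_of_gravity(m_eq)), c(10, 10, 5))
  m_one <- motor_map(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(0, 100, 0))
  expect_equal(unname(center_of_gravity(m_one)), c(2, 5, 8))

  set.seed(50)
  m <- random_motor_map(50)
  naive <- c(0, 0, 0); tot <- 0
  for (i in 1:50) {
    naive <- naive + c(m$x[i], m$y[i], m$z[i]) * m$value[i]
    tot <- tot + m$value[i]
  }
  expect_equal(unname(center_of_gravity(m)), naive / tot, tolerance = 1e-12)

  m_zero <- motor_map(1:3, 1:3, 1:3, c(0, 0, 0))
  expect_error(center_of_gravity(m_zero), class = "zero_mass_error")
})

test_that("peak takes the absolute maximum, ties to the lowest event index", {
  m <- motor_map(c(0, 10, 20), c(0, 0, 0), c(0, 0, 0), c(10, 500, 20))
  pk <- map_peak(m)
  expect_equal(unname(pk$position), c(10, 0, 0))
  expect_equal(pk$value, 500)
  m_tie <- motor_map(c(0, 10), c(0, 0), c(0, 0), c(500, 500))
  expect_equal(unname(map_peak(m_tie)$position), c(0, 0, 0))

  # surface peak equals exhaustive grid argmax
  g <- expand.grid(theta = seq(1.2, 1.8, length.out = 9),
                   phi = seq(-0.5, 0.5, length.out = 9))
  g$value <- 1000 * exp(-((g$theta - 1.45)^2 + (g$phi - 0.1)^2) / 0.02)
  s <- suppressWarnings(fit_surface(g, "cubic"))
  sp <- map_peak(s, spacing = 0.01)
  cells <- motormap:::surface_cells(s, 0.01)
  idx <- which.max(cells$values)
  ij <- arrayInd(idx, dim(cells$values))
  expect_equal(sp$theta, cells$theta_centers[ij[1]])
  expect_equal(sp$phi, cells$phi_centers[ij[2]])
  expect_equal(sp$value, max(cells$values, na.rm = TRUE))
})

test_that("surface area converges to the closed-form spherical cap", {
  R <- 90
  mod <- sphere_model(R)
  for (alpha in c(0.5, 0.8)) {
    sa <- surface_area(function(th, ph) as.numeric(th <= alpha), mod,
                       spacing = 0.005, threshold = 0,
                       theta_range = c(0, pi), phi_range = c(-pi, pi))
    truth <- 2 * pi * R^2 * (1 - cos(alpha))
    expect_lt(abs(sa - truth) / truth, 0.01, label = sprintf("alpha=%.1f", alpha))
  }
  # nothing above threshold -> zero area
  expect_equal(surface_area(function(th, ph) rep(0, length(th)), mod,
                            spacing = 0.05, threshold = 0,
                            theta_range = c(0, pi), phi_range = c(-pi, pi)), 0)
})

test_that("halving the pixel spacing changes SA by under 0.5% on a smooth map", {
  mod <- sphere_model(85, c(10, 10, 10))
  f <- function(th, ph) 100 + 50 * sin(th) * cos(ph)
  sa1 <- surface_area(f, mod, spacing = 0.02, threshold = 120,
                      theta_range = c(0.3, 2.8), phi_range = c(-3, 3))
  sa2 <- surface_area(f, mod, spacing = 0.01, threshold = 120,
                      theta_range = c(0.3, 2.8), phi_range = c(-3, 3))
  expect_lt(abs(sa2 - sa1) / sa2, 0.005)
})

test_that("volume integral is the value-weighted patch sum", {
  R <- 75
  mod <- sphere_model(R)
  alpha <- 0.9
  vconst <- 42
  f <- function(th, ph) ifelse(th <= alpha, vconst, 0)
  sa <- surface_area(f, mod, spacing = 0.01, threshold = 0,
                     theta_range = c(0, pi), phi_range = c(-pi, pi))
  vi <- volume_integral(f, mod, spacing = 0.01, threshold = 0,
                        theta_range = c(0, pi), phi_range = c(-pi, pi))
  expect_equal(vi, vconst * sa, tolerance = 1e-9)

  # doubling values doubles VI and leaves COG unchanged
  set.seed(51)
  m <- random_motor_map(20)
  m2 <- motor_map(m$x, m$y, m$z, 2 * m$value)
  expect_equal(center_of_gravity(m2), center_of_gravity(m), tolerance = 1e-12)
  f2 <- function(th, ph) 2 * f(th, ph)
  vi2 <- volume_integral(f2, mod, spacing = 0.01, threshold = 0,
                         theta_range = c(0, pi), phi_range = c(-pi, pi))
  expect_equal(vi2, 2 * vi, tolerance = 1e-12)

  # independent Riemann-sum oracle with explicit loops on a coarse grid
  g <- function(th, ph) 10 + th + ph^2
  s <- 0.1
  th0 <- seq(0.5, 1.5 - s, by = s); ph0 <- seq(-0.5, 0.5 - s, by = s)
  acc_sa <- 0; acc_vi <- 0
  for (i in seq_along(th0)) for (j in seq_along(ph0)) {
    v <- g(th0[i] + s / 2, ph0[j] + s / 2)
    if (v > 11) {
      p0 <- predict(mod, th0[i], ph0[j])
      p1 <- predict(mod, th0[i] + s, ph0[j])
      p2 <- predict(mod, th0[i], ph0[j] + s)
      pv <- p1 - p0; qv <- p2 - p0
      cr <- c(pv[2] * qv[3] - pv[3] * qv[2],
              pv[3] * qv[1] - pv[1] * qv[3],
              pv[1] * qv[2] - pv[2] * qv[1])
      a <- sqrt(sum(cr^2))
      acc_sa <- acc_sa + a
      acc_vi <- acc_vi + a * v
    }
  }
  sa_pkg <- surface_area(g, mod, spacing = s, threshold = 11,
                         theta_range = c(0.5, 1.5), phi_range = c(-0.5, 0.5))
  vi_pkg <- volume_integral(g, mod, spacing = s, threshold = 11,
                            theta_range = c(0.5, 1.5), phi_range = c(-0.5, 0.5))
  expect_equal(sa_pkg, acc_sa, tolerance = 1e-9)
  expect_equal(vi_pkg, acc_vi, tolerance = 1e-9)
})

test_that("SA and VI are non-increasing in the threshold and scale as expected", {
  mod <- sphere_model(80)
  f <- function(th, ph) 1000 * exp(-((th - 1.5)^2 + ph^2) / 0.1)
  thr <- c(0, 50, 200, 500, 900)
  sa <- vapply(thr, function(t) surface_area(f, mod, spacing = 0.02, threshold = t,
               theta_range = c(1, 2), phi_range = c(-1, 1)), numeric(1))
  vi <- vapply(thr, function(t) volume_integral(f, mod, spacing = 0.02, threshold = t,
               theta_range = c(1, 2), phi_range = c(-1, 1)), numeric(1))
  expect_true(all(diff(sa) <= 0))
  expect_true(all(diff(vi) <= 0))
  # scale equivariance at threshold 0
  fk <- function(th, ph) 3.5 * f(th, ph)
  expect_equal(surface_area(fk, mod, spacing = 0.02, threshold = 0,
                            theta_range = c(1, 2), phi_range = c(-1, 1)),
               sa[1], tolerance = 1e-12)
  expect_equal(volume_integral(fk, mod, spacing = 0.02, threshold = 0,
                               theta_range = c(1, 2), phi_range = c(-1, 1)),
               3.5 * vi[1], tolerance = 1e-12)
})

test_that("position reports decompose into axis components and Euclidean norm", {
  r <- position_report(c(5, 5, 5), c(5, 5, 5))
  expect_equal(unlist(r), c(x = 0, y = 0, z = 0, euclidean = 0))
  r2 <- position_report(c(3, 4, 0), c(0, 0, 0))
  expect_equal(r2$euclidean, 5)
  set.seed(52)
  for (i in 1:10) {
    p <- rnorm(3, 0, 50); q <- rnorm(3, 0, 50)
    rr <- position_report(p, q)
    expect_equal(rr$euclidean, sqrt(rr$x^2 + rr$y^2 + rr$z^2), tolerance = 1e-12)
  }
})

test_that("COG of non-negative data lies in the convex hull of positions", {
  set.seed(53)
  for (i in 1:5) {
    m <- random_motor_map(15)
    cog <- center_of_gravity(m)
    expect_gte(cog[1], min(m$x)); expect_lte(cog[1], max(m$x))
    expect_gte(cog[2], min(m$y)); expect_lte(cog[2], max(m$y))
    expect_gte(cog[3], min(m$z)); expect_lte(cog[3], max(m$z))
  }
})

test_that("peak discretization separates two Gaussian bumps", {
  mod <- sphere_model(90)
  set.seed(54)
  g <- expand.grid(theta = seq(1.1, 2.1, length.out = 25),
                   phi = seq(-0.8, 0.8, length.out = 25))
  g$theta <- g$theta + runif(nrow(g), -0.005, 0.005)
  g$phi <- g$phi + runif(nrow(g), -0.005, 0.005)
  c1 <- c(1.35, -0.4); c2 <- c(1.85, 0.4)
  g$value <- 1000 * exp(-((g$theta - c1[1])^2 + (g$phi - c1[2])^2) / (2 * 0.015)) +
             800 * exp(-((g$theta - c2[1])^2 + (g$phi - c2[2])^2) / (2 * 0.015))
  s <- suppressWarnings(fit_surface(g, "cubic"))
  spacing <- 0.02
  regions <- discretize_peaks(s, mod, spacing = spacing, threshold = 20,
                              min_prominence = 0.1)
  expect_equal(length(regions), 2L)
  expect_lt(abs(regions[[1]]$peak$theta - c1[1]), spacing + 1e-9)
  expect_lt(abs(regions[[1]]$peak$phi - c1[2]), spacing + 1e-9)
  expect_lt(abs(regions[[2]]$peak$theta - c2[1]), spacing + 1e-9)
  expect_lt(abs(regions[[2]]$peak$phi - c2[2]), spacing + 1e-9)

  # regions are disjoint subsets of the above-threshold set
  total <- motormap:::patch_integrals(s, mod, spacing, 20)
  sa_total <- total$surface_area; vi_total <- total$volume_integral
  expect_lte(sum(vapply(regions, `[[`, numeric(1), "surface_area")), sa_total + 1e-9)
  expect_lte(sum(vapply(regions, `[[`, numeric(1), "volume_integral")), vi_total + 1e-9)

  # a single bump gives a single region no larger than the whole map
  g1 <- g; g1$value <- 1000 * exp(-((g$theta - 1.6)^2 + g$phi^2) / (2 * 0.02))
  s1 <- suppressWarnings(fit_surface(g1, "cubic"))
  reg1 <- discretize_peaks(s1, mod, spacing = spacing, threshold = 20)
  expect_equal(length(reg1), 1L)
  expect_lte(reg1[[1]]$surface_area,
             surface_area(s1, mod, spacing = spacing, threshold = 20) + 1e-9)

  flat <- g; flat$value <- rep(1, nrow(g))
  s_flat <- suppressWarnings(fit_surface(flat, "linear"))
  expect_error(discretize_peaks(s_flat, mod, spacing = spacing, threshold = 10),
               class = "no_peak_error")
})

test_that("measure_map assembles a coherent single-map report", {
  mod <- fixture_head_model()
  sim <- make_gaussian_map(mod, seed = 55)
  cons <- consolidate(sim$map, as.integer(qt_cluster(sim$map, 0.02)), "average")
  rep_ <- measure_map(cons, mod, algorithm = "linear")
  expect_s3_class(rep_, "map_measurements")
  expect_equal(unname(rep_$cog), unname(center_of_gravity(cons)))
  expect_gt(rep_$surface_area, 0)
  expect_gt(rep_$volume_integral, 0)
  expect_equal(rep_$reference_source, "centroid_default")
  expect_equal(rep_$cog_to_reference$euclidean,
               sqrt(sum((rep_$cog - mod$centroid)^2)), tolerance = 1e-9)
})
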