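# Clough-Tocher C1 piecewise-cubic interpolation on a Delaunay
# triangulation.
#
# Each triangle is split at its barycentre into three cubic Bezier
# mini-patches. Vertex values and estimated gradients fix the corner and
# edge control points; the control point across each exterior edge is set by
# requiring the derivative normal to the edge to vary linearly along it
# (the same condition on both sides of the edge, hence global C1); the
# interior ring and centre follow from the C1 conditions across the
# interior edges:
#   w_i = (r_i + s_ij + s_ki) / 3,   c = (w_1 + w_2 + w_3) / 3.
# With exact vertex gradients the scheme reproduces quadratic fields
# exactly; gradients are estimated by a local least-squares quadratic over
# the one-ring (two-ring when the one-ring is too small), which recovers
# quadratic fields exactly as well.

# Per-vertex gradient estimates from local least-squares polynomial fits.
ct_gradients <- function(tri, values) {
  x <- tri$x; y <- tri$y
  nb <- interp::neighbours(tri)
  n <- length(x)
  grads <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    ring <- nb[[i]]
    if (length(ring) < 5L) {
      ring <- setdiff(unique(c(ring, unlist(nb[ring]))), i)
    }
    dx <- x[ring] - x[i]; dy <- y[ring] - y[i]
    dv <- values[ring] - values[i]
    A <- if (length(ring) >= 5L) cbind(dx, dy, dx^2, dx * dy, dy^2)
         else cbind(dx, dy)
    qrA <- qr(A)
    if (qrA$rank < 2L) next                     # isolated/degenerate: flat
    if (qrA$rank < ncol(A)) {
      A <- cbind(dx, dy)
      qrA <- qr(A)
      if (qrA$rank < 2L) next
    }
    coefs <- qr.coef(qrA, dv)
    grads[i, ] <- coefs[1:2]
  }
  grads
}

# Vectorised evaluation. `tri` is the triangulation of the training sites,
# `values` and `grads` the per-site data. Queries outside the triangulation
# give NA.
ct_evaluate <- function(tri, values, grads, tq, pq) {
  out <- rep(NA_real_, length(tq))
  loc <- interp::tri.find(tri, tq, pq)
  ok <- loc$tr > 0
  if (!any(ok)) return(out)
  i1 <- loc$i1[ok]; i2 <- loc$i2[ok]; i3 <- loc$i3[ok]
  bc <- loc$bc[ok, , drop = FALSE]
  x <- tri$x; y <- tri$y

  x1 <- x[i1]; y1 <- y[i1]; x2 <- x[i2]; y2 <- y[i2]; x3 <- x[i3]; y3 <- y[i3]
  f1 <- values[i1]; f2 <- values[i2]; f3 <- values[i3]
  g1x <- grads[i1, 1]; g1y <- grads[i1, 2]
  g2x <- grads[i2, 1]; g2y <- grads[i2, 2]
  g3x <- grads[i3, 1]; g3y <- grads[i3, 2]
  xc <- (x1 + x2 + x3) / 3; yc <- (y1 + y2 + y3) / 3

  D12 <- g1x * (x2 - x1) + g1y * (y2 - y1)
  D13 <- g1x * (x3 - x1) + g1y * (y3 - y1)
  D21 <- g2x * (x1 - x2) + g2y * (y1 - y2)
  D23 <- g2x * (x3 - x2) + g2y * (y3 - y2)
  D31 <- g3x * (x1 - x3) + g3y * (y1 - y3)
  D32 <- g3x * (x2 - x3) + g3y * (y2 - y3)

  q12 <- f1 + D12 / 3; q13 <- f1 + D13 / 3
  q21 <- f2 + D21 / 3; q23 <- f2 + D23 / 3
  q31 <- f3 + D31 / 3; q32 <- f3 + D32 / 3
  r1 <- f1 + (D12 + D13) / 9
  r2 <- f2 + (D21 + D23) / 9
  r3 <- f3 + (D31 + D32) / 9

  # cross-edge control: normal derivative linear along the exterior edge
  s_edge <- function(xi, yi, xj, yj, fi, fj, qij, qji, ri, rj) {
    nx <- -(yj - yi); ny <- xj - xi            # edge perpendicular
    a11 <- xi - xc; a12 <- xj - xc
    a21 <- yi - yc; a22 <- yj - yc
    det <- a11 * a22 - a12 * a21
    du <- (nx * a22 - a12 * ny) / det
    dv <- (a11 * ny - nx * a21) / det
    dw <- -du - dv
    (0.5 * (du * (fi + qji) + dv * (qij + fj) + dw * (ri + rj)) -
       du * qij - dv * qji) / dw
  }
  s12 <- s_edge(x1, y1, x2, y2, f1, f2, q12, q21, r1, r2)
  s23 <- s_edge(x2, y2, x3, y3, f2, f3, q23, q32, r2, r3)
  s31 <- s_edge(x3, y3, x1, y1, f3, f1, q31, q13, r3, r1)

  w1 <- (r1 + s12 + s31) / 3
  w2 <- (r2 + s23 + s12) / 3
  w3 <- (r3 + s31 + s23) / 3
  cc <- (w1 + w2 + w3) / 3

  # mini-triangle: the one opposite the smallest barycentric coordinate
  k <- max.col(-bc, ties.method = "first")
  a <- (k %% 3L) + 1L                          # cyclic successor of k
  b <- (a %% 3L) + 1L
  m <- length(k); rows <- seq_len(m)
  u <- bc[cbind(rows, a)] - bc[cbind(rows, k)]
  v <- bc[cbind(rows, b)] - bc[cbind(rows, k)]
  w <- 3 * bc[cbind(rows, k)]

  Fm <- cbind(f1, f2, f3)
  Qab <- cbind(q12, q23, q31)                  # q_{a -> b} for a = 1, 2, 3
  Qba <- cbind(q21, q32, q13)
  Rm <- cbind(r1, r2, r3)
  Sm <- cbind(s12, s23, s31)                   # s on edge (a, b)
  Wm <- cbind(w1, w2, w3)

  fa <- Fm[cbind(rows, a)]; fb <- Fm[cbind(rows, b)]
  qab <- Qab[cbind(rows, a)]; qba <- Qba[cbind(rows, a)]
  ra <- Rm[cbind(rows, a)]; rb <- Rm[cbind(rows, b)]
  sab <- Sm[cbind(rows, a)]
  wa <- Wm[cbind(rows, a)]; wb <- Wm[cbind(rows, b)]

  out[ok] <- u^3 * fa + v^3 * fb + w^3 * cc +
    3 * u^2 * v * qab + 3 * u * v^2 * qba +
    3 * u^2 * w * ra + 3 * v^2 * w * rb +
    6 * u * v * w * sab +
    3 * u * w^2 * wa + 3 * v * w^2 * wb
  out
}
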