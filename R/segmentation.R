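# Head segmentation: Otsu threshold, 6-connectivity morphological closing,
# largest connected component, interior hole filling.  All operations are
# vectorised array shifts; no external image-processing package is required.

# Shift a 3D logical array by one voxel along `axis` (+1/-1), padding FALSE.
shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L); idx_src[[axis]] <- 2:n
  }
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
}

dilate6 <- function(a) {
  out <- a
  for (axis in 1:3) for (dir in c(-1L, 1L)) out <- out | shift3(a, axis, dir)
  out
}

erode6 <- function(a) !dilate6(!a)

# Flood fill: grow `seed` through `allowed` by 6-connectivity until stable.
flood_fill <- function(seed, allowed) {
  cur <- seed & allowed
  repeat {
    grown <- (cur | dilate6(cur)) & allowed
    if (sum(grown) == sum(cur)) return(cur)
    cur <- grown
  }
}

largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood_fill(seed, remaining)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best
}

fill_holes <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood_fill(border & !mask, !mask)
  mask | (!mask & !outside)
}

# Otsu's threshold on a 256-bin histogram: maximise between-class variance.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

#' Segment the head from a structural scan
#'
#' Produces a binary head-vs-background mask: Otsu intensity threshold,
#' one-step morphological closing (6-connectivity), retention of the largest
#' connected component, and filling of interior holes. The result is a single
#' connected foreground component without cavities.
#'
#' @param scan a [head_scan].
#' @return An object of class `head_mask`: list with logical 3D `mask` and
#'   `spacing` (mm).
#' @export
segment_head <- function(scan) {
  stopifnot(inherits(scan, "head_scan"))
  vol <- scan$data
  th <- otsu_threshold(as.numeric(vol))
  fg <- vol > th
  if (!any(fg)) stop_mm("no_foreground_error", "segmentation found no foreground voxels")
  fg <- erode6(dilate6(fg))          # closing: seal small surface gaps
  if (!any(fg)) stop_mm("no_foreground_error", "no foreground after morphological closing")
  fg <- largest_component(fg)
  fg <- fill_holes(fg)
  structure(list(mask = fg, spacing = scan$spacing), class = "head_mask")
}

#' @export
print.head_mask <- function(x, ...) {
  cat(sprintf("<head_mask> %s voxels, %d foreground (%.1f%%)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Sample a point cloud from a head mask
#'
#' Takes every `stride`-th foreground voxel in fixed raster (column-major)
#' order and converts voxel indices to scanner mm (0-based index times voxel
#' spacing). The default stride of 25 thins a typical head segmentation to a
#' tractable cloud while preserving its shape.
#'
#' @param mask a `head_mask` from [segment_head()].
#' @param stride positive integer sampling stride (default 25).
#' @return Numeric matrix with columns `x`, `y`, `z` (mm).
#' @export
sample_point_cloud <- function(mask, stride = 25L) {
  stopifnot(inherits(mask, "head_mask"))
  stride <- as.integer(stride)
  if (stride < 1L) stop_mm("value_error", "stride must be >= 1")
  idx <- which(mask$mask)
  if (length(idx) < stride) {
    stop_mm("insufficient_foreground_error",
            sprintf("mask has %d foreground voxels, need >= %d", length(idx), stride))
  }
  sel <- idx[seq(1L, length(idx), by = stride)]
  ijk <- arrayInd(sel, dim(mask$mask))
  pts <- sweep(ijk - 1L, 2L, mask$spacing, `*`)
  colnames(pts) <- c("x", "y", "z")
  pts
}
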