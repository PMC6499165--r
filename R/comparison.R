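# Within-subject map comparison: continuous feature deltas with RMSE, and
# categorical map-stability analysis via ROC/AUC of a probability map.

#' Root mean square error between a raw map and a fitted surface
#'
#' `sqrt(mean((P_i - O_i)^2))` where `O_i` are the raw values of the
#' observation map and `P_i` the other session's surface predictions at the
#' same angular locations. Points falling outside the surface's training
#' hull carry no prediction and are dropped; if none remain the two maps do
#' not overlap spatially and RMSE is meaningless.
#'
#' @param surface a `motor_surface` (fitted to the predicting session).
#' @param data data.frame with `theta`, `phi`, `value`: the raw observations.
#' @return RMSE in map units, with attribute `n_used` (points inside the
#'   hull).
#' @export
rmse <- function(surface, data) {
  stopifnot(inherits(surface, "motor_surface"))
  p <- predict(surface, data$theta, data$phi)
  ok <- !is.na(p)
  if (!any(ok)) {
    stop_mm("no_overlap_error",
            "no observation lies inside the surface's sampled region")
  }
  out <- sqrt(mean((p[ok] - data$value[ok])^2))
  attr(out, "n_used") <- sum(ok)
  out
}

#' Continuous comparison of two motor maps
#'
#' Fits both maps with the same algorithm and reports feature differences
#' (B minus A): COG and peak shifts (signed per axis plus Euclidean), surface
#' area and volume integral differences, the difference grid `S_B - S_A`
#' over the overlap of the two training hulls, and the RMSE of map A's raw
#' values against map B's surface. Both maps must be expressed in the same
#' scanner frame (same registration/reference point).
#'
#' @param map_a,map_b [motor_map] objects (consolidated if they held
#'   repeats).
#' @param model a `scalp_ellipsoid` shared by both sessions.
#' @param algorithm surface fitting algorithm applied to both maps.
#' @param spacing integration/difference grid spacing in radians.
#' @param sa_threshold SA/VI inclusion threshold (map units).
#' @return An object of class `map_comparison`; `rmse` is `NA` with
#'   `rmse_overlap = FALSE` when the maps share no sampled region.
#' @export
compare_maps <- function(map_a, map_b, model, algorithm = "cubic",
                         spacing = pi / 512, sa_threshold = 0) {
  stopifnot(inherits(map_a, "motor_map"), inherits(map_b, "motor_map"),
            inherits(model, "scalp_ellipsoid"))
  ra <- attr(map_a, "reference_point"); rb <- attr(map_b, "reference_point")
  if (!is.null(ra) && !is.null(rb) && any(ra != rb)) {
    stop_mm("frame_mismatch_error",
            "maps declare different reference points; align sessions first")
  }
  ma <- measure_map(map_a, model, algorithm, spacing, sa_threshold)
  mb <- measure_map(map_b, model, algorithm, spacing, sa_threshold)

  ang_a <- project_events(map_a, model)
  rmse_val <- tryCatch(rmse(mb$surface, ang_a), motormap_error = function(e) NA_real_)

  th_rng <- c(max(min(ma$surface$theta), min(mb$surface$theta)),
              min(max(ma$surface$theta), max(mb$surface$theta)))
  ph_rng <- c(max(min(ma$surface$phi), min(mb$surface$phi)),
              min(max(ma$surface$phi), max(mb$surface$phi)))
  diff_grid <- NULL
  if (th_rng[1] < th_rng[2] && ph_rng[1] < ph_rng[2]) {
    th <- seq(th_rng[1], th_rng[2], by = spacing)
    ph <- seq(ph_rng[1], ph_rng[2], by = spacing)
    za <- evaluate_surface(ma$surface, th, ph)
    zb <- evaluate_surface(mb$surface, th, ph)
    diff_grid <- list(theta = th, phi = ph, difference = zb - za)
  }
  structure(list(
    measurements_a = ma, measurements_b = mb,
    delta_cog = position_report(mb$cog, ma$cog),
    delta_peak = position_report(mb$peak$position, ma$peak$position),
    delta_surface_area = mb$surface_area - ma$surface_area,
    delta_volume_integral = mb$volume_integral - ma$volume_integral,
    rmse = as.numeric(rmse_val),
    rmse_n_used = attr(rmse_val, "n_used"),
    rmse_overlap = !is.na(rmse_val),
    difference_grid = diff_grid,
    algorithm = algorithm
  ), class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Motor map comparison (%s fit, B - A)\n", x$algorithm))
  cat(sprintf("  dCOG:  (%.2f, %.2f, %.2f) mm, |d| = %.2f mm\n",
              x$delta_cog$x, x$delta_cog$y, x$delta_cog$z, x$delta_cog$euclidean))
  cat(sprintf("  dPeak: (%.2f, %.2f, %.2f) mm, |d| = %.2f mm\n",
              x$delta_peak$x, x$delta_peak$y, x$delta_peak$z, x$delta_peak$euclidean))
  cat(sprintf("  dSA: %.2f mm^2   dVI: %.6g uV mm^2\n",
              x$delta_surface_area, x$delta_volume_integral))
  if (x$rmse_overlap) {
    cat(sprintf("  RMSE: %.3f uV (%d overlapping points)\n",
                x$rmse, x$rmse_n_used))
  } else {
    cat("  RMSE: not defined (maps do not overlap spatially)\n")
  }
  invisible(x)
}

#' ROC curve and AUC of a probability map against a testing session
#'
#' Quantifies map stability over time. The training session, consolidated
#' with the probability method and fitted to a surface, predicts at every
#' location the probability (0-100%) of evoking an MEP above the
#' binarization threshold. Testing events are binarized at the same
#' microvolt threshold (strictly above = 1). For each cutoff in an even
#' sweep of `n_cutoffs` percentages over 0-100, model predictions at the
#' testing locations are binarized (predicted positive iff probability >=
#' cutoff), tallied into true/false positives A, B and negatives D, C, and
#' `TPR = A/(A+C)`, `FPR = 1 - D/(D+B)` computed. The curve is forced
#' through (0,0) and (1,1) and AUC obtained by trapezoidal integration of
#' TPR over FPR. AUC 1 means the model always predicts the testing labels at
#' some cutoff, 0 means it always predicts their complement, and 0.5 is
#' chance.
#'
#' @param surface a `motor_surface` fitted to probability-consolidated data
#'   (values 0-100).
#' @param test data.frame with `theta`, `phi`, `value` (raw microvolt) or
#'   `label` (already-binarized 0/1).
#' @param binarization_threshold microvolt cutoff for the testing values
#'   (default 40, matching the probability consolidation default).
#' @param n_cutoffs number of evenly spaced percentage cutoffs (default
#'   1001).
#' @return An object of class `roc_result`: `curve` (data.frame cutoff, FPR,
#'   TPR), `auc`, `n_used`, `n_dropped` (testing points outside the training
#'   hull).
#' @export
roc_auc <- function(surface, test, binarization_threshold = 40,
                    n_cutoffs = 1001L) {
  stopifnot(inherits(surface, "motor_surface"))
  if ("label" %in% names(test)) {
    labels <- as.integer(test$label)
    if (!all(labels %in% c(0L, 1L))) stop_mm("value_error", "labels must be 0/1")
  } else {
    labels <- binarize(test$value, binarization_threshold)
  }
  p <- predict(surface, test$theta, test$phi)
  keep <- !is.na(p)
  n_dropped <- sum(!keep)
  p <- p[keep]; labels <- labels[keep]
  if (length(p) == 0L) {
    stop_mm("no_overlap_error", "no testing point lies inside the training hull")
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_mm("degenerate_test_error",
            sprintf("testing set is all-%s; TPR or FPR is undefined",
                    if (n_pos == 0L) "negative" else "positive"))
  }
  cutoffs <- seq(0, 100, length.out = n_cutoffs)
  tpr <- numeric(n_cutoffs); fpr <- numeric(n_cutoffs)
  for (i in seq_len(n_cutoffs)) {
    pred <- p >= cutoffs[i]
    a <- sum(pred & labels == 1L)          # true positives
    b <- sum(pred & labels == 0L)          # false positives
    c_ <- n_pos - a                        # false negatives
    d <- n_neg - b                         # true negatives
    tpr[i] <- a / (a + c_)
    fpr[i] <- 1 - d / (d + b)
  }
  curve <- data.frame(cutoff = c(cutoffs, NA), FPR = c(fpr, 0), TPR = c(tpr, 0))
  curve <- curve[order(curve$FPR, curve$TPR), ]
  if (curve$FPR[nrow(curve)] < 1 || curve$TPR[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(cutoff = NA, FPR = 1, TPR = 1))
  }
  auc <- sum(diff(curve$FPR) * (utils::head(curve$TPR, -1) + utils::tail(curve$TPR, -1)) / 2)
  structure(list(curve = curve, auc = auc,
                 binarization_threshold = binarization_threshold,
                 n_used = length(p), n_dropped = n_dropped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d testing points, %d dropped outside hull)\n",
              x$auc, x$n_used, x$n_dropped))
  cat(sprintf("  binarization threshold: %g uV\n", x$binarization_threshold))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$FPR, x$curve$TPR, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}
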