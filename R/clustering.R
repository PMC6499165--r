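# Quality-threshold clustering of repeated stimulations and cluster
# consolidation into single representative points.

#' Quality-threshold clustering of stimulation events
#'
#' Groups repeated stimulations delivered at (approximately) the same scalp
#' site. Pairwise 3D Euclidean distances are normalized by the dataset's
#' maximum pairwise distance, so the threshold is a unitless fraction in
#' `[0, 1]`: 0 keeps every event separate, 1 merges everything into one
#' cluster. For each seed event a candidate cluster is grown greedily,
#' adding the point that least increases the cluster diameter while the
#' normalized diameter stays within the threshold; the largest candidate is
#' extracted and the procedure repeats on the remainder (ties broken by the
#' lowest seed index, for determinism).
#'
#' @param map a [motor_map] (or N x 3 matrix of positions).
#' @param threshold normalized diameter bound in `[0, 1]`.
#' @return Integer vector of cluster labels (contiguous, starting at 1),
#'   one per event, with attribute `qt_threshold`.
#' @export
qt_cluster <- function(map, threshold) {
  pts <- as_points3(map)
  n <- nrow(pts)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop_mm("value_error", "qt threshold must be a single number in [0, 1]")
  }
  labels <- integer(n)
  if (threshold == 0 || n == 1L) {
    labels <- seq_len(n)
    attr(labels, "qt_threshold") <- threshold
    return(labels)
  }
  D <- as.matrix(stats::dist(pts))
  dmax <- max(D)
  if (dmax == 0) {            # all events coincident: one cluster
    labels <- rep(1L, n)
    attr(labels, "qt_threshold") <- threshold
    return(labels)
  }
  limit <- threshold * dmax
  remaining <- seq_len(n)
  next_label <- 1L
  while (length(remaining) > 0L) {
    best <- integer(0)
    for (seed in remaining) {
      cand <- qt_candidate(seed, remaining, D, limit)
      if (length(cand) > length(best)) best <- cand
    }
    labels[best] <- next_label
    next_label <- next_label + 1L
    remaining <- setdiff(remaining, best)
  }
  attr(labels, "qt_threshold") <- threshold
  labels
}

# Greedy candidate cluster for one seed: repeatedly add the point whose
# inclusion gives the smallest new diameter, while diameter <= limit.
qt_candidate <- function(seed, remaining, D, limit) {
  members <- seed
  pool <- setdiff(remaining, seed)
  # max distance from each pool point to current members
  dmax_to_members <- D[pool, seed, drop = TRUE]
  while (length(pool) > 0L) {
    i <- which.min(dmax_to_members)
    if (dmax_to_members[i] > limit) break
    newpt <- pool[i]
    members <- c(members, newpt)
    pool <- pool[-i]
    dmax_to_members <- dmax_to_members[-i]
    if (length(pool) > 0L) {
      dmax_to_members <- pmax(dmax_to_members, D[pool, newpt])
    }
  }
  members
}

#' Binarize MEP values at a threshold
#'
#' Values strictly above the threshold map to 1, all others (including values
#' exactly at the threshold) to 0.
#'
#' @param values numeric MEP amplitudes (microvolt).
#' @param threshold binarization threshold in microvolt (default 40).
#' @param strict if `FALSE`, values equal to the threshold also map to 1.
#' @return Integer vector of 0/1 labels.
#' @export
binarize <- function(values, threshold = 40, strict = TRUE) {
  if (threshold < 0) stop_mm("value_error", "binarization threshold must be >= 0")
  if (strict) as.integer(values > threshold) else as.integer(values >= threshold)
}

CONSOLIDATION_METHODS <- c("average", "maximum", "minimum", "variance", "probability")

#' Consolidate clustered events into single representative points
#'
#' Each cluster collapses to one point at the unweighted mean of its member
#' positions, with a representative value per `method`:
#' \describe{
#'   \item{average / maximum / minimum}{mean / max / min of member MEPs
#'     (microvolt).}
#'   \item{variance}{population variance (divide by N) of member MEPs
#'     (microvolt squared).}
#'   \item{probability}{percentage of members whose MEP is strictly above the
#'     binarization threshold (0-100, unitless); for single-measurement data
#'     this is always 0 or 100.}
#' }
#'
#' @param map a [motor_map].
#' @param labels cluster labels from [qt_cluster()] (defaults to singletons).
#' @param method one of `"average"`, `"maximum"`, `"minimum"`, `"variance"`,
#'   `"probability"`.
#' @param binarization_threshold microvolt cutoff for the probability method
#'   (default 40).
#' @return A [motor_map] with one event per cluster, extra columns
#'   `cluster_id` and `n_members`, and attributes `method` and (for
#'   probability) `binarization_threshold`. Clusters are ordered by label.
#' @export
consolidate <- function(map, labels = seq_len(nrow(map)),
                        method = c("average", "maximum", "minimum",
                                   "variance", "probability"),
                        binarization_threshold = 40) {
  stopifnot(inherits(map, "motor_map"))
  if (length(method) == 1L && !method %in% CONSOLIDATION_METHODS) {
    stop_mm("method_error", sprintf("unknown consolidation method '%s'", method))
  }
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(labels) != nrow(map)) {
    stop_mm("value_error", "one cluster label per event is required")
  }
  ids <- sort(unique(labels))
  agg <- function(v) switch(method,
    average = mean(v),
    maximum = max(v),
    minimum = min(v),
    variance = mean((v - mean(v))^2),
    probability = 100 * mean(binarize(v, binarization_threshold))
  )
  pos <- t(vapply(ids, function(id) {
    sel <- labels == id
    c(mean(map$x[sel]), mean(map$y[sel]), mean(map$z[sel]),
      agg(map$value[sel]), sum(sel))
  }, numeric(5)))
  out <- motor_map(pos[, 1], pos[, 2], pos[, 3], pos[, 4],
                   reference_point = attr(map, "reference_point"),
                   reference_source = attr(map, "reference_source") %||% "imported",
                   session_label = attr(map, "session_label"))
  out$cluster_id <- ids
  out$n_members <- as.integer(pos[, 5])
  attr(out, "method") <- method
  if (method == "probability") {
    attr(out, "binarization_threshold") <- binarization_threshold
  }
  out
}
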