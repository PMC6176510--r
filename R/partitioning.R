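#' Affinity-propagation configuration
#'
#' Settings for exemplar-based clustering of a channel window's amplitude
#' values.  The preference (the "reference degree" placed on the diagonal of
#' the similarity matrix) controls how many partitions emerge; the string
#' `"median"` resolves to the median of the off-diagonal similarities, the
#' standard default.
#'
#' @param preference Either the string `"median"` or a numeric value in
#'   similarity units (negated squared amplitude difference, so typically
#'   negative).
#' @param damping Message damping factor in `[0.5, 1)`, default 0.5.  When
#'   the deterministic (noise-free) message passing fails to converge at the
#'   configured damping — typical for dense amplitude data, where undamped
#'   messages oscillate — [ap_cluster()] automatically retries at higher
#'   damping (0.7, 0.9, 0.95) and reports the value actually used.
#' @param max_iter Maximum number of message-passing sweeps.
#' @param convergence_iter Number of consecutive sweeps with an unchanged
#'   exemplar set required to declare convergence.
#' @param max_points Optional cap on the number of points clustered; when set
#'   and exceeded, evenly spaced order statistics are clustered and all points
#'   are assigned to the learned boundaries.  `NULL` (the default) clusters
#'   every point.
#' @return An object of class `ap_config`.
#' @export
ap_config <- function(preference = "median", damping = 0.5, max_iter = 200L,
                      convergence_iter = 15L, max_points = NULL) {
  if (is.character(preference)) {
    if (!identical(preference, "median"))
      stop("preference must be numeric or the string \"median\"")
  } else {
    stopifnot(is.numeric(preference), length(preference) == 1L,
              is.finite(preference))
  }
  stopifnot(is.numeric(damping), length(damping) == 1L,
            damping >= 0.5, damping < 1)
  max_iter <- as.integer(max_iter)
  convergence_iter <- as.integer(convergence_iter)
  stopifnot(convergence_iter >= 1L, max_iter >= convergence_iter)
  if (!is.null(max_points)) {
    max_points <- as.integer(max_points)
    stopifnot(max_points >= 2L)
  }
  structure(list(preference = preference, damping = damping,
                 max_iter = max_iter, convergence_iter = convergence_iter,
                 max_points = max_points),
            class = "ap_config")
}

#' Pairwise similarity matrix for affinity propagation
#'
#' Off-diagonal entries are negated squared Euclidean distances between
#' amplitude values (larger = more similar); the diagonal carries the resolved
#' preference.
#'
#' @param values Numeric vector of amplitudes, sorted ascending.
#' @param config An [ap_config()].
#' @return Square symmetric similarity matrix.
#' @export
compute_similarity <- function(values, config = ap_config()) {
  if (length(values) == 0L) stop("empty window")
  if (any(!is.finite(values))) stop("non-finite values in window")
  d <- outer(values, values, "-")
  s <- -(d * d)
  diag(s) <- resolve_preference(s, config$preference)
  s
}

# preference = "median" -> median of off-diagonal similarities
resolve_preference <- function(similarity, preference) {
  if (is.numeric(preference)) return(preference)
  n <- nrow(similarity)
  if (n == 1L) return(0)
  stats::median(similarity[row(similarity) != col(similarity)])
}

#' Affinity-propagation clustering of amplitude values
#'
#' Alternates the responsibility and availability updates with damping until
#' the exemplar set is stable or `max_iter` is reached.  Deterministic: no
#' random restarts, ties break toward the lower sample index.  Exemplars are
#' always actual data points.  If the messages have not converged at the
#' configured damping, the pass is rerun at progressively higher damping
#' (0.7, 0.9, 0.95); only if every rung fails is `converged = FALSE`
#' returned (not an error).
#'
#' @inheritParams compute_similarity
#' @return An object of class `ap_result` with fields `labels` (cluster index
#'   per sample, `1..K`), `exemplars` (the exemplar sample values),
#'   `exemplar_index` (their positions in `values`), `n_iter`, `converged`,
#'   `damping_used`.
#' @export
ap_cluster <- function(values, config = ap_config()) {
  if (length(values) == 0L) stop("empty window")
  if (any(!is.finite(values))) stop("non-finite values in window")
  if (values[1L] == values[length(values)]) {
    # all values identical: one cluster, trivially converged (the message
    # passing has no gradient to work with when every similarity is zero)
    return(structure(list(labels = rep(1L, length(values)),
                          exemplars = values[1L], exemplar_index = 1L,
                          n_iter = 0L, converged = TRUE,
                          damping_used = config$damping),
                     class = "ap_result"))
  }
  s <- compute_similarity(values, config)
  ladder <- unique(c(config$damping,
                     c(0.7, 0.9, 0.95)[c(0.7, 0.9, 0.95) > config$damping]))
  for (damping in ladder) {
    res <- .ap_messages(s, damping, config$max_iter, config$convergence_iter)
    if (res$converged) break
  }
  ex <- res$exemplars
  if (length(ex) == 0L) {
    # degenerate case (e.g. all values identical): fall back to the single
    # best-evidence point, lowest index on ties
    ex <- which.max(res$evidence)
  }
  # assign every point to the most similar exemplar; exemplars to themselves
  sim_ex <- s[, ex, drop = FALSE]
  labels <- max.col(sim_ex, ties.method = "first")
  labels[ex] <- seq_along(ex)
  structure(list(labels = labels,
                 exemplars = values[ex],
                 exemplar_index = ex,
                 n_iter = res$n_iter,
                 converged = res$converged,
                 damping_used = damping),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("ap_result: %d clusters over %d points (%d sweeps, %s)\n",
              length(x$exemplars), length(x$labels), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

new_partition_scheme <- function(partitions, boundaries) {
  k <- nrow(partitions)
  stopifnot(k >= 1L, length(boundaries) == k - 1L)
  if (k > 1L) {
    if (any(diff(partitions$center) < 0))
      stop("partitions must be sorted by center")
    if (any(diff(boundaries) <= 0))
      stop("boundaries must be strictly increasing")
    # each boundary separates the extents of its neighbours
    if (any(boundaries <= partitions$z_max[-k] - 1e-12) ||
        any(boundaries > partitions$z_min[-1L] + 1e-12))
      stop("non-separable clusters")
  }
  structure(list(partitions = partitions, boundaries = as.numeric(boundaries),
                 count = k),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition_scheme: %d partition(s)\n", x$count))
  print(x$partitions, ...)
  invisible(x)
}

#' Amplitude partitions from cluster labels
#'
#' Turns an AP clustering of a channel window into ordered, non-overlapping
#' amplitude partitions.  Each cluster becomes a partition with center
#' `C = (z_max + z_min)/2` and radius `R = |z_max - z_min|/2`; the dividing
#' point between consecutive partitions is placed at the upper edge of the
#' lower partition plus the half-gap, i.e. the midpoint of the empty interval
#' between them.
#'
#' @param values Numeric amplitudes (the clustered samples).
#' @param labels Cluster index per sample, as produced by [ap_cluster()].
#' @return A `partition_scheme`: a data frame of partitions (`z_min`, `z_max`,
#'   `center`, `radius`), the cut points `boundaries`, and `count`.
#' @export
partitions_from_labels <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 1L)
  zmin <- tapply(values, labels, min)
  zmax <- tapply(values, labels, max)
  center <- (zmax + zmin) / 2
  radius <- abs(zmax - zmin) / 2
  ord <- order(center)
  parts <- data.frame(z_min = as.numeric(zmin[ord]),
                      z_max = as.numeric(zmax[ord]),
                      center = as.numeric(center[ord]),
                      radius = as.numeric(radius[ord]))
  k <- nrow(parts)
  if (k > 1L && any(parts$z_min[-1L] <= parts$z_max[-k]))
    stop("non-separable clusters")
  boundaries <- if (k > 1L) {
    upper <- parts$center[-k] + parts$radius[-k]       # z_max of partition i
    lower <- parts$center[-1L] - parts$radius[-1L]     # z_min of partition i+1
    half_gap <- (lower - upper) / 2
    upper + half_gap
  } else numeric(0)
  new_partition_scheme(parts, boundaries)
}

#' Merge partitions until two schemes have equal counts
#'
#' The scheme with the larger count has its closest adjacent partitions merged
#' (smallest center-to-center gap first, lower pair on ties) until both counts
#' agree; the smaller scheme is returned unchanged.
#'
#' @param scheme_x,scheme_y `partition_scheme` objects.
#' @return List with elements `x` and `y`, both `partition_scheme`s of equal
#'   count.
#' @export
equalize_partition_counts <- function(scheme_x, scheme_y) {
  k <- min(scheme_x$count, scheme_y$count)
  list(x = merge_to_count(scheme_x, k), y = merge_to_count(scheme_y, k))
}

merge_to_count <- function(scheme, k) {
  stopifnot(k >= 1L)
  while (scheme$count > k) {
    p <- scheme$partitions
    gaps <- diff(p$center)
    i <- which.min(gaps)             # lowest index on ties
    merged <- data.frame(z_min = p$z_min[i], z_max = p$z_max[i + 1L])
    merged$center <- (merged$z_max + merged$z_min) / 2
    merged$radius <- abs(merged$z_max - merged$z_min) / 2
    p <- rbind(if (i > 1L) p[seq_len(i - 1L), ], merged,
               if (i + 1L < nrow(p)) p[seq(i + 2L, nrow(p)), ])
    rownames(p) <- NULL
    b <- scheme$boundaries[-i]
    scheme <- new_partition_scheme(p, b)
  }
  scheme
}

#' Equal-probability amplitude partitions
#'
#' Baseline partitioner: boundaries at the empirical quantiles `i/k`, so each
#' bin holds (up to rounding) the same number of samples when values are
#' distinct.  Used for the uniform-partition mutual-information baseline.
#'
#' @param values Numeric amplitudes.
#' @param k Number of bins, `k >= 1`.
#' @return A `partition_scheme` with `k` partitions.
#' @export
uniform_partition <- function(values, k) {
  stopifnot(length(values) >= 1L, k >= 1L)
  k <- as.integer(k)
  if (any(!is.finite(values))) stop("non-finite values in window")
  if (k > length(unique(values))) stop("too many bins")
  if (k == 1L) {
    parts <- data.frame(z_min = min(values), z_max = max(values),
                        center = (max(values) + min(values)) / 2,
                        radius = (max(values) - min(values)) / 2)
    return(new_partition_scheme(parts, numeric(0)))
  }
  boundaries <- stats::quantile(values, probs = seq_len(k - 1L) / k,
                                names = FALSE, type = 7)
  if (any(diff(boundaries) <= 0)) {
    # heavy ties collapsed some quantiles; fall back to distinct-value cuts
    u <- sort(unique(values))
    idx <- round(seq(1, length(u) - 1L, length.out = k - 1L))
    boundaries <- (u[idx] + u[idx + 1L]) / 2
    if (any(diff(boundaries) <= 0)) stop("too many bins")
  }
  sym <- findInterval(values, boundaries) + 1L   # boundary hit -> upper bin
  parts <- do.call(rbind, lapply(seq_len(k), function(i) {
    v <- values[sym == i]
    if (length(v) == 0L) {
      # empty bin: degenerate partition strictly inside its boundary interval
      lo <- if (i == 1L) min(values) - 1 else boundaries[i - 1L]
      hi <- if (i == k) max(values) + 1 else boundaries[i]
      mid <- (lo + hi) / 2
      data.frame(z_min = mid, z_max = mid, center = mid, radius = 0)
    } else {
      data.frame(z_min = min(v), z_max = max(v),
                 center = (max(v) + min(v)) / 2,
                 radius = (max(v) - min(v)) / 2)
    }
  }))
  structure(list(partitions = parts, boundaries = as.numeric(boundaries),
                 count = k),
            class = "partition_scheme")
}

#' Adaptive partition scheme for one channel window
#'
#' Sorts the window's amplitudes, clusters them with affinity propagation and
#' converts the clusters to ordered amplitude partitions.  With
#' `config$max_points` set, clustering runs on evenly spaced order statistics
#' and all samples are then assigned to the learned boundaries.
#'
#' @param values Numeric amplitudes (any order).
#' @param config An [ap_config()].
#' @return A `partition_scheme`.
#' @export
channel_scheme <- function(values, config = ap_config()) {
  v <- sort(values)
  if (v[1L] == v[length(v)]) {  # constant channel: a single partition
    parts <- data.frame(z_min = v[1L], z_max = v[1L], center = v[1L],
                        radius = 0)
    return(new_partition_scheme(parts, numeric(0)))
  }
  if (!is.null(config$max_points) && length(v) > config$max_points) {
    idx <- unique(round(seq(1L, length(v), length.out = config$max_points)))
    v <- v[idx]
  }
  cl <- ap_cluster(v, config)
  partitions_from_labels(v, cl$labels)
}
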