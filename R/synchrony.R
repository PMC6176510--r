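#' Discretize amplitudes against a partition scheme
#'
#' Half-open, lower-inclusive bins: the symbol is one plus the number of
#' boundaries at or below the value, so a value exactly on a boundary falls in
#' the upper bin.  Out-of-range values clamp to the first/last bin.
#'
#' @param values Numeric amplitudes.
#' @param scheme A `partition_scheme`.
#' @return Integer symbols in `1..scheme$count`.
#' @export
discretize <- function(values, scheme) {
  findInterval(values, scheme$boundaries) + 1L
}

#' Empirical joint distribution of two symbol sequences
#'
#' @param symbols_x,symbols_y Equal-length integer symbol sequences
#'   (`1..kX`, `1..kY`).
#' @param k_x,k_y Alphabet sizes; default the observed maximum.
#' @return A `joint_distribution`: probability `table` (kX rows, kY columns)
#'   with `marginal_x` and `marginal_y`.
#' @export
estimate_joint <- function(symbols_x, symbols_y,
                           k_x = max(symbols_x), k_y = max(symbols_y)) {
  if (length(symbols_x) != length(symbols_y))
    stop("symbol sequences differ in length")
  n <- length(symbols_x)
  stopifnot(n >= 1L)
  counts <- tabulate((symbols_y - 1L) * k_x + symbols_x, nbins = k_x * k_y)
  tab <- matrix(counts / n, nrow = k_x, ncol = k_y)
  structure(list(table = tab,
                 marginal_x = rowSums(tab),
                 marginal_y = colSums(tab)),
            class = "joint_distribution")
}

# -sum p log2 p with 0*log(0) := 0
shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Marginal and joint entropies of a joint distribution
#'
#' Base-2 Shannon entropies with the `0 * log 0 = 0` convention.
#'
#' @param joint A `joint_distribution`.
#' @return Named numeric vector `c(h_x, h_y, h_xy)` in bits.
#' @export
entropies <- function(joint) {
  c(h_x = shannon_bits(joint$marginal_x),
    h_y = shannon_bits(joint$marginal_y),
    h_xy = shannon_bits(joint$table))
}

#' Mutual information of a joint distribution
#'
#' `I(X, Y) = H(X) + H(Y) - H(X, Y)` in bits, clipped at zero against
#' floating-point round-off.
#'
#' @param joint A `joint_distribution`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(joint) {
  h <- entropies(joint)
  max(0, h[["h_x"]] + h[["h_y"]] - h[["h_xy"]])
}

#' Adaptive-partition mutual information between two channels
#'
#' The APCPMI of a channel pair: the two schemes (each from its own channel's
#' affinity-propagation clustering) are first merged to a common partition
#' count, both channels are discretized, and the mutual information of the
#' empirical joint distribution is returned.
#'
#' @param x,y Equal-length amplitude vectors.
#' @param scheme_x,scheme_y `partition_scheme`s for `x` and `y`.
#' @return Mutual information in bits.
#' @export
apcpmi_pair <- function(x, y, scheme_x, scheme_y) {
  stopifnot(length(x) == length(y))
  eq <- equalize_partition_counts(scheme_x, scheme_y)
  sx <- discretize(x, eq$x)
  sy <- discretize(y, eq$y)
  mutual_information(estimate_joint(sx, sy, eq$x$count, eq$y$count))
}

#' Equal-probability-partition mutual information baseline
#'
#' Both channels are cut into `k` equal-probability bins by their own
#' empirical quantiles before the mutual information is computed.
#'
#' @param x,y Equal-length amplitude vectors.
#' @param k Number of bins per channel.
#' @return Mutual information in bits.
#' @export
uniform_mi_pair <- function(x, y, k) {
  stopifnot(length(x) == length(y))
  if (k == 1L) return(0)
  sx <- discretize(x, uniform_partition(x, k))
  sy <- discretize(y, uniform_partition(y, k))
  mutual_information(estimate_joint(sx, sy, k, k))
}

#' Global synchronization matrix of a multichannel window
#'
#' Computes the adaptive partition scheme once per channel, then the APCPMI
#' for every channel pair (CMAPCPMI).  The matrix is symmetric; the diagonal
#' holds each channel's self-entropy under its own scheme (the self-mutual
#' information).  A constant channel yields a single partition and zero mutual
#' information with every other channel.
#'
#' @param window Numeric matrix, channels x samples.
#' @param config An [ap_config()].
#' @param channel_names Optional channel labels; defaults to rownames or
#'   `ch1..chn`.
#' @return A `sync_matrix` with fields `values` (n x n, bits),
#'   `channel_names`, `n`.
#' @export
build_cmapcpmi <- function(window, config = ap_config(),
                           channel_names = NULL) {
  stopifnot(is.matrix(window), nrow(window) >= 2L)
  n <- nrow(window)
  if (is.null(channel_names))
    channel_names <- rownames(window)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(n))
  schemes <- lapply(seq_len(n), function(i) channel_scheme(window[i, ], config))
  values <- matrix(0, n, n, dimnames = list(channel_names, channel_names))
  for (i in seq_len(n)) {
    si <- discretize(window[i, ], schemes[[i]])
    values[i, i] <- shannon_bits(tabulate(si, schemes[[i]]$count) / ncol(window))
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      mi <- apcpmi_pair(window[i, ], window[j, ], schemes[[i]], schemes[[j]])
      values[i, j] <- mi
      values[j, i] <- mi
    }
  }
  structure(list(values = values, n = n, channel_names = channel_names),
            class = "sync_matrix")
}

#' @export
print.sync_matrix <- function(x, ...) {
  cat(sprintf("sync_matrix: %d channels, mean off-diagonal MI %.4f bits\n",
              x$n, mean_offdiag(x)))
  invisible(x)
}

#' Mean off-diagonal entry of a synchronization matrix
#'
#' @param sync A `sync_matrix`.
#' @return Mean of the off-diagonal mutual-information values, in bits.
#' @export
mean_offdiag <- function(sync) {
  v <- sync$values
  mean(v[row(v) != col(v)])
}

#' Flatten a synchronization matrix to a feature vector
#'
#' Row-major flattening, so an n-channel window yields `n^2` features
#' (23 channels -> 529).
#'
#' @param sync A `sync_matrix`.
#' @return Numeric vector of length `n^2`.
#' @export
flatten_sync <- function(sync) {
  as.vector(t(sync$values))
}

#' Partition-number sweep of the uniform-partition MI baseline
#'
#' For each bin count `k`, computes the uniform-partition MI matrix of every
#' window and reports the element-wise mean matrix and the average (over
#' matrix elements) standard deviation across windows — the diagnostic that
#' shows how strongly MI estimates depend on the partition number.
#'
#' @param windows List of channels x samples matrices.
#' @param k_list Integer vector of bin counts.
#' @return List with `summary` (data frame of `k` and `avg_sd`) and
#'   `mean_matrices` (one mean MI matrix per `k`).
#' @export
partition_sweep <- function(windows, k_list) {
  stopifnot(length(windows) >= 1L)
  n <- nrow(windows[[1L]])
  res <- lapply(k_list, function(k) {
    mats <- lapply(windows, function(w) {
      m <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i < j) {
            m[i, j] <- uniform_mi_pair(w[i, ], w[j, ], k)
            m[j, i] <- m[i, j]
          } else if (i == j) {
            m[i, i] <- uniform_mi_pair(w[i, ], w[i, ], k)
          }
        }
      }
      m
    })
    arr <- simplify2array(mats)
    mean_mat <- apply(arr, c(1, 2), mean)
    sd_mat <- if (length(mats) > 1L) apply(arr, c(1, 2), stats::sd)
              else matrix(0, n, n)
    list(k = k, mean = mean_mat, avg_sd = mean(sd_mat))
  })
  list(summary = data.frame(k = k_list,
                            avg_sd = vapply(res, `[[`, numeric(1), "avg_sd")),
       mean_matrices = lapply(res, `[[`, "mean"))
}
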