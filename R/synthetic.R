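#' Synthetic multichannel window specification
#'
#' The generator emulates windowed multichannel EEG with controllable
#' inter-channel statistical dependence: a shared oscillatory latent source
#' (an order-2 autoregressive process with spectral mass near 3-12 Hz at
#' 256 Hz) mixed into each channel against independent Gaussian noise.  The
#' mixing weight is the coupling `rho`: high coupling stands in for the
#' hypersynchronous seizure state, low coupling for the non-seizure state.
#'
#' @param n_channels Number of channels (clinical montage convention: 23).
#' @param samples_per_window Samples per window (2,048 = 8 s at 256 Hz).
#' @param sampling_rate Hz.
#' @param coupling_high Coupling for seizure-labelled windows.
#' @param coupling_low Coupling for non-seizure windows.
#' @param noise_sd Per-channel noise standard deviation.
#' @param n_windows_per_class Windows generated per label.
#' @param seed Integer seed; every window is deterministic given
#'   `(seed, index, label)`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 23L, samples_per_window = 2048L,
                           sampling_rate = 256, coupling_high = 0.8,
                           coupling_low = 0.2, noise_sd = 1.0,
                           n_windows_per_class = 20L, seed = 1L) {
  stopifnot(n_channels >= 1L, samples_per_window >= 2L, sampling_rate > 0,
            coupling_high >= 0, coupling_high <= 1,
            coupling_low >= 0, coupling_low <= 1,
            noise_sd >= 0, n_windows_per_class >= 1L)
  structure(list(n_channels = as.integer(n_channels),
                 samples_per_window = as.integer(samples_per_window),
                 sampling_rate = sampling_rate,
                 coupling_high = coupling_high, coupling_low = coupling_low,
                 noise_sd = noise_sd,
                 n_windows_per_class = as.integer(n_windows_per_class),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Fast test profile of the synthetic generator
#'
#' 8 channels and 512 samples per window: small enough for unit tests and the
#' desk-scale pipeline while keeping the coupling structure intact.
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_fast <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 8L, samples_per_window = 512L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# AR(2) latent with complex poles: modulus r, centre frequency f0 Hz
ar2_latent <- function(n, sampling_rate, f0 = 6, r = 0.95) {
  a1 <- 2 * r * cos(2 * pi * f0 / sampling_rate)
  a2 <- -r^2
  burn <- 200L
  e <- stats::rnorm(n + burn)
  s <- numeric(n + burn)
  s[1:2] <- e[1:2]
  for (t in 3:(n + burn)) s[t] <- a1 * s[t - 1L] + a2 * s[t - 2L] + e[t]
  s <- s[(burn + 1L):(burn + n)]
  s / stats::sd(s)
}

# per-dataset channel gains, seeded independently of the window streams
channel_gains <- function(spec) {
  set.seed(spec$seed + 777L)
  stats::runif(spec$n_channels, 0.8, 1.2)
}

window_seed <- function(spec, index, label) {
  as.integer((spec$seed * 7919 + index * 104729 + label * 15485863) %%
               2147483647)
}

#' Generate one synthetic multichannel window
#'
#' Channel `c` is `rho * g_c * s(t) + (1 - rho) * eta_c(t)` with a shared
#' autoregressive latent `s`, per-channel gain `g_c` and independent Gaussian
#' noise; `rho` is `coupling_high` for a seizure window and `coupling_low`
#' otherwise.  Bit-reproducible given `(seed, index, label)`.
#'
#' @param spec A [synthetic_spec()].
#' @param label 1 for seizure, 0 for non-seizure.
#' @param index Window index (for the per-window random stream).
#' @param coupling Optional explicit coupling override of the label's rho.
#' @return Channels x samples numeric matrix.
#' @export
generate_window <- function(spec, label, index = 1L, coupling = NULL) {
  stopifnot(label %in% c(0, 1))
  rho <- if (!is.null(coupling)) coupling
         else if (label == 1) spec$coupling_high else spec$coupling_low
  g <- channel_gains(spec)
  set.seed(window_seed(spec, index, label))
  s <- ar2_latent(spec$samples_per_window, spec$sampling_rate)
  noise <- matrix(stats::rnorm(spec$n_channels * spec$samples_per_window,
                               sd = spec$noise_sd),
                  spec$n_channels, spec$samples_per_window)
  rho * g * matrix(s, spec$n_channels, spec$samples_per_window,
                   byrow = TRUE) * 1 + (1 - rho) * noise
}

#' Generate a balanced labelled synchronization-feature dataset
#'
#' Generates `n_windows_per_class` windows per label, passes each through
#' [build_cmapcpmi()] and returns the flattened synchronization matrices as a
#' feature matrix with labels.
#'
#' @param spec A [synthetic_spec()].
#' @param config An [ap_config()] for the partitioning stage.
#' @param progress Print a dot per window?
#' @return List with `features` (windows x n_channels^2 matrix), `labels`
#'   (0/1), and `matrices` (list of `sync_matrix` objects).
#' @export
generate_labeled_dataset <- function(spec, config = ap_config(),
                                     progress = FALSE) {
  per <- spec$n_windows_per_class
  labels <- rep(c(1L, 0L), each = per)
  indices <- rep(seq_len(per), 2L)
  mats <- vector("list", 2L * per)
  for (i in seq_along(labels)) {
    w <- generate_window(spec, labels[i], indices[i])
    mats[[i]] <- build_cmapcpmi(w, config)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  features <- do.call(rbind, lapply(mats, flatten_sync))
  list(features = features, labels = labels, matrices = mats)
}
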