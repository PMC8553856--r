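#' SPM-style double-gamma hemodynamic response function
#'
#' Canonical HRF: a gamma density peaking near 5-6 s minus a later gamma
#' undershoot (peak near 15-16 s) scaled by \code{undershoot_ratio}.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,undershoot_shape gamma shape parameters (scale 1 s).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return HRF values at \code{t}, normalized to unit peak.
#' @export
doubleGammaHRF <- function(t, peak_shape = 6, undershoot_shape = 16,
                           undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape)
  h / max(h)
}

# Convolve trial boxcars with the HRF on an oversampled grid, sampled back
# at frame times.  Returns frames x trials.
.convolveTrials <- function(onsets, durations, n_frames, TR, oversample = 16,
                            hrf_args = list()) {
  dt <- TR / oversample
  n_fine <- n_frames * oversample
  tfine <- (seq_len(n_fine) - 1) * dt
  hrf <- do.call(doubleGammaHRF,
                 c(list(t = seq(0, 32, by = dt)), hrf_args))
  X <- matrix(0, n_frames, length(onsets))
  for (i in seq_along(onsets)) {
    box <- as.numeric(tfine >= onsets[i] & tfine < onsets[i] + durations[i])
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)]
    X[, i] <- conv[seq(1, n_fine, by = oversample)]
  }
  X * dt
}

#' Simulate BOLD time series from single-trial patterns
#'
#' For each run, builds voxel time series as HRF-convolved trial boxcars
#' scaled by that trial's pattern value per voxel, on a constant baseline,
#' plus AR(1) Gaussian noise.  A framewise-displacement (FD) trace with
#' configurable spike probability is simulated per run; trials overlapping
#' any frame with FD above \code{fd_threshold} are flagged censored.
#'
#' @param schedule trial schedule (all runs) aligned with \code{amplitudes}.
#' @param amplitudes trials x voxels matrix (or \linkS4class{PatternSet}) of
#'   per-trial response amplitudes.
#' @param TR repetition time in seconds (default 2.59 s).
#' @param baseline constant signal level added to every voxel.
#' @param noise_sd marginal SD of the AR(1) noise; scalar or per voxel.
#'   Supply \code{tsnr} instead to set \code{noise_sd = baseline / tsnr}.
#' @param tsnr optional per-voxel target tSNR overriding \code{noise_sd}.
#' @param ar_phi AR(1) coefficient of the noise.
#' @param fd_spike_p per-frame probability of a motion spike (FD drawn
#'   uniformly in 0.5-1.5 mm); non-spike frames draw FD uniformly in
#'   0-0.3 mm.
#' @param fd_threshold censoring threshold in mm.
#' @param seed integer seed.
#' @param pad_s extra seconds of acquisition after the last trial.
#' @return list of class \code{"BoldSim"}: \code{runs} (per run: \code{Y}
#'   frames x voxels, \code{fd}, \code{frame_times}), \code{schedule} (input
#'   schedule with refreshed \code{censored} flags), \code{TR}.
#' @export
simulateBold <- function(schedule, amplitudes, TR = 2.59, baseline = 100,
                         noise_sd = 1, tsnr = NULL, ar_phi = 0.3,
                         fd_spike_p = 0.02, fd_threshold = 0.5, seed = 1,
                         pad_s = 16) {
  if (is(amplitudes, "PatternSet")) amplitudes <- patterns(amplitudes)
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(amplitudes) == nrow(schedule))
  n_vox <- ncol(amplitudes)
  if (!is.null(tsnr)) noise_sd <- baseline / tsnr
  noise_sd <- rep(noise_sd, length.out = n_vox)
  .withSeed(.substream(seed, "bold"), {
    runs <- list()
    censored <- schedule$censored
    for (r in sort(unique(schedule$run))) {
      idx <- which(schedule$run == r)
      on <- schedule$onset[idx]; du <- schedule$duration[idx]
      n_frames <- ceiling((max(on + du) + pad_s) / TR)
      X <- .convolveTrials(on, du, n_frames, TR)
      Y <- X %*% amplitudes[idx, , drop = FALSE] + baseline
      if (any(noise_sd > 0)) {
        innov_sd <- noise_sd * sqrt(1 - ar_phi^2)
        E <- matrix(stats::rnorm(n_frames * n_vox), n_frames, n_vox)
        E <- sweep(E, 2, innov_sd, "*")
        for (tt in 2:n_frames) E[tt, ] <- E[tt, ] + ar_phi * E[tt - 1, ]
        Y <- Y + E
      }
      spikes <- stats::runif(n_frames) < fd_spike_p
      fd <- ifelse(spikes, stats::runif(n_frames, fd_threshold, 1.5),
                   stats::runif(n_frames, 0, 0.3))
      frame_times <- (seq_len(n_frames) - 1) * TR
      for (k in seq_along(idx)) {
        hit <- frame_times >= on[k] & frame_times < on[k] + du[k]
        censored[idx[k]] <- any(fd[hit] > fd_threshold)
      }
      runs[[as.character(r)]] <- list(Y = Y, fd = fd,
                                      frame_times = frame_times)
    }
    schedule$censored <- censored
    structure(list(runs = runs, schedule = schedule, TR = TR),
              class = "BoldSim")
  })
}
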