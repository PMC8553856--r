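# Discrete-cosine high-pass basis (GLM equivalent of a 100 s cutoff
# high-pass filter); k = 1 .. floor(2 * T / cutoff) regressors.
.dctBasis <- function(n_frames, TR, cutoff = 100) {
  K <- floor(2 * n_frames * TR / cutoff)
  if (K < 1) return(NULL)
  tt <- seq_len(n_frames) - 0.5
  X <- vapply(seq_len(K),
              function(k) cos(pi * k * tt / n_frames), numeric(n_frames))
  colnames(X) <- paste0("dct", seq_len(K))
  X
}

# Nuisance block shared by the single-trial and run GLMs: optional motion
# parameters, unit-impulse spike columns for flagged outlier frames, DCT
# high-pass set, intercept.
.nuisanceBlock <- function(n_frames, TR, motion, outlier_frames, highpass) {
  blocks <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_frames)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    blocks$motion <- motion
  }
  if (length(outlier_frames)) {
    S <- matrix(0, n_frames, length(outlier_frames))
    S[cbind(outlier_frames, seq_along(outlier_frames))] <- 1
    colnames(S) <- paste0("spike", outlier_frames)
    blocks$spikes <- S
  }
  dct <- .dctBasis(n_frames, TR, highpass)
  if (!is.null(dct)) blocks$dct <- dct
  blocks$intercept <- matrix(1, n_frames, 1,
                             dimnames = list(NULL, "intercept"))
  do.call(cbind, blocks)
}

# OLS t-statistics of the first column's coefficient for every voxel.
# Errors on rank-deficient designs, naming the collinear columns.
.olsT <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  XtXinv11 <- chol2inv(qr.R(qx))[1, 1]
  se <- sqrt(sigma2 * XtXinv11)
  tval <- ifelse(se > 0, B[1, ] / se, NaN)
  list(beta = B[1, ], t = tval, df = dfres)
}

#' Least-squares-separate single-trial estimation for one run
#'
#' Fits one GLM per trial: the trial of interest as its own regressor and
#' all other trials of the run collapsed into a second regressor, both
#' convolved with the canonical double-gamma HRF; optional event regressors
#' (e.g. outline stage, fixation, incorrect-baseline events), motion
#' parameters, outlier-frame spike columns and a DCT high-pass set complete
#' the model.  Correct active-baseline periods are left unmodeled (implicit
#' baseline).  The per-voxel t-statistic of the trial regressor
#' (\code{beta / SE}) is the trial's activation pattern.
#'
#' @param Y frames x voxels time-series matrix for one run.
#' @param schedule_run schedule rows for this run (onsets in run time).
#' @param TR repetition time (s).
#' @param motion optional frames x 6 motion-parameter matrix.
#' @param nuisance_events optional data.frame (onset, duration) of extra
#'   events modeled as one shared regressor.
#' @param outlier_frames integer frame indices flagged as outliers.
#' @param highpass high-pass cutoff in seconds for the DCT set.
#' @param statistic \code{"t"} (default) or \code{"beta"}: which per-voxel
#'   value to return.
#' @return trials x voxels matrix of single-trial estimates; attribute
#'   \code{"df"} holds the residual degrees of freedom.
#' @export
fitLSS <- function(Y, schedule_run, TR = 2.59, motion = NULL,
                   nuisance_events = NULL, outlier_frames = integer(0),
                   highpass = 100, statistic = c("t", "beta")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  n_frames <- nrow(Y)
  n_trials <- nrow(schedule_run)
  if (any(schedule_run$onset + schedule_run$duration > n_frames * TR)) {
    stop("trial onsets extend past the end of the run time series")
  }
  Xtrial <- .convolveTrials(schedule_run$onset, schedule_run$duration,
                            n_frames, TR)
  nuis <- .nuisanceBlock(n_frames, TR, motion, outlier_frames, highpass)
  if (!is.null(nuisance_events)) {
    xe <- rowSums(.convolveTrials(nuisance_events$onset,
                                  nuisance_events$duration, n_frames, TR))
    nuis <- cbind(extra_events = xe, nuis)
  }
  out <- matrix(NA_real_, n_trials, ncol(Y))
  df <- NA_integer_
  for (i in seq_len(n_trials)) {
    cols <- list(trial_of_interest = Xtrial[, i])
    if (n_trials > 1L) {
      cols$all_other_trials <- rowSums(Xtrial[, -i, drop = FALSE])
    }
    X <- cbind(do.call(cbind, cols), nuis)
    colnames(X)[seq_along(cols)] <- names(cols)
    fit <- .olsT(X, Y)
    out[i, ] <- if (statistic == "t") fit$t else fit$beta
    df <- fit$df
  }
  if (statistic == "t" && any(!is.finite(out))) {
    warning("undefined t-statistics (zero residual variance) returned as NaN")
  }
  attr(out, "df") <- df
  out
}

#' Run-level GLM for remembered trials
#'
#' Fits one GLM per run with separate regressors for remembered (correct)
#' and forgotten (incorrect) trials plus the same nuisance structure as
#' [fitLSS()], and returns the per-voxel t-map of the remembered-trials
#' regressor.
#'
#' @inheritParams fitLSS
#' @return numeric vector (one value per voxel); attribute \code{"df"}.
#' @export
fitRunGLM <- function(Y, schedule_run, TR = 2.59, motion = NULL,
                      nuisance_events = NULL, outlier_frames = integer(0),
                      highpass = 100, statistic = c("t", "beta")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  n_frames <- nrow(Y)
  rem <- schedule_run$correct
  if (!any(rem)) stop("run has no remembered trials")
  Xall <- .convolveTrials(schedule_run$onset, schedule_run$duration,
                          n_frames, TR)
  cols <- list(remembered = rowSums(Xall[, rem, drop = FALSE]))
  if (any(!rem)) cols$forgotten <- rowSums(Xall[, !rem, drop = FALSE])
  nuis <- .nuisanceBlock(n_frames, TR, motion, outlier_frames, highpass)
  if (!is.null(nuisance_events)) {
    xe <- rowSums(.convolveTrials(nuisance_events$onset,
                                  nuisance_events$duration, n_frames, TR))
    nuis <- cbind(extra_events = xe, nuis)
  }
  X <- cbind(do.call(cbind, cols), nuis)
  colnames(X)[seq_along(cols)] <- names(cols)
  fit <- .olsT(X, Y)
  out <- if (statistic == "t") fit$t else fit$beta
  attr(out, "df") <- fit$df
  out
}

#' Estimate trial or run patterns from a simulated BOLD session
#'
#' Convenience wrappers applying [fitLSS()] / [fitRunGLM()] run by run to a
#' \code{BoldSim} object, assembling a \linkS4class{PatternSet} of
#' single-trial t-maps or a matrix of run-level t-maps (one row per run).
#'
#' @param bold a \code{BoldSim} from [simulateBold()].
#' @param ... passed to [fitLSS()] / [fitRunGLM()].
#' @param roiName region label for the resulting PatternSet.
#' @return \code{estimateTrialPatterns}: a \linkS4class{PatternSet};
#'   \code{estimateRunPatterns}: a \linkS4class{PatternSet} with one row per
#'   run.
#' @export
estimateTrialPatterns <- function(bold, ..., roiName = "ROI") {
  sched <- bold$schedule
  mats <- list()
  for (r in names(bold$runs)) {
    idx <- sched$run == as.integer(r)
    mats[[r]] <- fitLSS(bold$runs[[r]]$Y, sched[idx, ], TR = bold$TR, ...)
  }
  pat <- do.call(rbind, mats)
  tsnr <- computeTSNR(do.call(rbind, lapply(bold$runs, `[[`, "Y")))
  PatternSet(pat, sched[order(sched$run, sched$run_trial), ],
             voxelTSNR = tsnr, roiName = roiName)
}

#' @rdname estimateTrialPatterns
#' @export
estimateRunPatterns <- function(bold, ..., roiName = "run-maps") {
  sched <- bold$schedule
  rows <- list(); meta <- list()
  for (r in names(bold$runs)) {
    idx <- sched$run == as.integer(r)
    rows[[r]] <- fitRunGLM(bold$runs[[r]]$Y, sched[idx, ], TR = bold$TR, ...)
    meta[[r]] <- data.frame(run = as.integer(r),
                            city = sched$city[idx][1],
                            task = sched$task[idx][1],
                            correct = TRUE, censored = FALSE)
  }
  tsnr <- computeTSNR(do.call(rbind, lapply(bold$runs, `[[`, "Y")))
  PatternSet(do.call(rbind, rows), do.call(rbind, meta),
             voxelTSNR = tsnr, roiName = roiName)
}
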