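# Hemodynamic lag mapping by lagged cross-correlation, with the 1-second
# affected-hemisphere QC exclusion rule.

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth-magnitude band-pass (default order 4, 0.009-0.09
#' Hz) in the frequency domain, giving an exactly zero-phase realization.
#' The DC component is removed (the mean is zeroed).
#'
#' @param x numeric vector, T x V matrix (time in rows), or 4D
#'   [volume_image].
#' @param tr_s sampling interval (taken from the volume when omitted).
#' @param low_hz,high_hz band edges; `high_hz` must be below Nyquist.
#' @param order Butterworth order of the magnitude response.
#' @return Filtered object of the same type (volumes keep affine/TR).
#' @export
bandpass <- function(x, tr_s = NULL, low_hz = 0.009, high_hz = 0.09,
                     order = 4L) {
  if (is_volume(x)) {
    d <- dim(x$data)
    if (length(d) != 4L) stop("bandpass needs a 4D volume")
    mat <- t(matrix(x$data, prod(d[1:3]), d[4L]))
    filt <- bandpass(mat, tr_s = x$tr_s, low_hz = low_hz, high_hz = high_hz,
                     order = order)
    out <- x
    out$data <- array(t(filt), dim = d)
    return(out)
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (is.null(tr_s)) stop("tr_s required for matrix/vector input")
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for TR %g s (Nyquist %g Hz)",
                 low_hz, high_hz, tr_s, nyq))
  f <- abs(fft_freqs(n, tr_s))
  gain <- 1 / sqrt(1 + (f / high_hz)^(2 * order))
  gain <- gain * ifelse(f == 0, 0, 1 / sqrt(1 + (low_hz / f)^(2 * order)))
  xf <- stats::mvfft(x)
  y <- Re(stats::mvfft(xf * gain, inverse = TRUE)) / n
  if (vec) y[, 1L] else y
}

#' Gray-matter reference signal
#'
#' Unweighted mean time series over voxels with `gm_prob >= gm_thresh` and
#' outside the lesion mask.
#'
#' @param bold_filtered 4D [volume_image] (band-passed).
#' @param gm_prob GM probability [volume_image].
#' @param lesion_mask binary [volume_image].
#' @param gm_thresh GM probability threshold (default 0.5).
#' @return length-T numeric vector.
#' @export
gm_reference <- function(bold_filtered, gm_prob, lesion_mask, gm_thresh = 0.5) {
  assert_same_grid(bold = bold_filtered, gm_prob = gm_prob,
                   lesion_mask = lesion_mask)
  sel <- gm_prob$data >= gm_thresh & !as.logical(lesion_mask$data)
  if (!any(sel)) stop("empty gray-matter compartment (GM minus lesion)")
  colMeans(mask_matrix(bold_filtered, sel))
}

# Correlations of `ts` against `ref` at integer shifts -max..+max; positive
# shift means ts is delayed relative to ref. Overlapping-sample Pearson.
shift_correlations <- function(ts, ref, max_shift) {
  n <- length(ts)
  vapply(-max_shift:max_shift, function(s) {
    if (s >= 0) suppressWarnings(stats::cor(ts[(1 + s):n], ref[1:(n - s)]))
    else suppressWarnings(stats::cor(ts[1:(n + s)], ref[(1 - s):n]))
  }, numeric(1))
}

#' Voxel lag by lagged cross-correlation
#'
#' Pearson correlation between `ts` and `ref` at every integer shift within
#' `+/- max_shift_trs` TRs (overlapping samples, re-normalized per shift).
#' The lag is the shift maximizing the correlation, positive when `ts` is
#' delayed. With `subsample = TRUE` the search runs on a dense sub-TR grid
#' (`tr_s/4` steps) using Fourier-shifted references, clamped to the
#' search window.
#'
#' @param ts,ref numeric vectors of equal length `T > 2*max_shift + 2`.
#' @param tr_s repetition time, seconds.
#' @param max_shift_trs search half-width in TRs (default 4).
#' @param subsample sub-TR refinement by dense-grid cross-correlation
#'   against Fourier-shifted references, grid step `tr_s/4` (default
#'   `TRUE`; `FALSE` gives integer-TR resolution).
#' @return list with `lag_s` and `peak_r` (both `NaN` for zero-variance
#'   input).
#' @export
voxel_lag <- function(ts, ref, tr_s, max_shift_trs = 4L, subsample = TRUE) {
  n <- length(ts)
  if (length(ref) != n) stop("ts and ref lengths differ")
  if (n <= 2L * max_shift_trs + 2L) stop("series too short for the search window")
  if (stats::sd(ts) == 0 || stats::sd(ref) == 0)
    return(list(lag_s = NaN, peak_r = NaN))
  deltas <- if (subsample) c(0, 0.25, 0.5, 0.75) else 0
  best <- list(lag_s = NaN, peak_r = -Inf)
  for (dl in deltas) {
    refs <- if (dl == 0) ref else fourier_shift(ref, dl * tr_s, tr_s)
    r <- shift_correlations(ts, refs, max_shift_trs)
    if (all(is.na(r))) next
    i <- which.max(r)
    lag <- (i - max_shift_trs - 1L + dl) * tr_s
    if (is.finite(r[i]) && r[i] > best$peak_r)
      best <- list(lag_s = lag, peak_r = r[i])
  }
  if (!is.finite(best$peak_r)) return(list(lag_s = NaN, peak_r = NaN))
  best$lag_s <- max(-max_shift_trs * tr_s, min(max_shift_trs * tr_s,
                                               best$lag_s))
  best
}

#' Compute a hemodynamic lag map with hemispheric QC
#'
#' Band-passes the BOLD run, builds the gray-matter reference (excluding the
#' lesion), estimates a per-voxel lag over the analysis mask (default: GM
#' minus lesion), and summarizes the signed (and absolute) mean lag per
#' hemisphere. The split uses world x from the affine (x < 0 = left). A
#' subject whose affected-hemisphere mean lag exceeds the unaffected
#' hemisphere's by more than `exclusion_thresh_s` is marked `excluded`
#' (the unaffected hemisphere anchors lag zero, since only relative lags
#' are identifiable against a global reference).
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param analysis_mask optional binary [volume_image]; default GM >=
#'   `gm_thresh` minus lesion.
#' @param max_shift_trs search half-width (default 4 TRs).
#' @param exclusion_thresh_s QC threshold on the affected-hemisphere mean
#'   lag, seconds (default 1).
#' @param subsample sub-TR dense-grid search, step `tr_s/4` (default
#'   `TRUE`).
#' @param gm_thresh GM threshold for the default mask and reference.
#' @param mean_type `"signed"` (default) or `"abs"`: which voxel lags enter
#'   the hemispheric means used by the QC rule (both are reported).
#' @param low_hz,high_hz band-pass edges.
#' @param n_passes reference passes; values above 1 realign GM voxels by
#'   their estimated lag before re-averaging the reference (default 1).
#' @return Object of class `lag_map`: `lag_s` and `peak_r` (3D
#'   [volume_image]s, `NaN` outside the mask), `mean_lag_affected_s`,
#'   `mean_lag_unaffected_s`, `mean_abs_lag_affected_s`,
#'   `mean_abs_lag_unaffected_s`, `affected_lag_excess_s`, `excluded`,
#'   `max_shift_trs`.
#' @export
compute_lagmap <- function(bold, ctx, analysis_mask = NULL, max_shift_trs = 4L,
                           exclusion_thresh_s = 1.0, subsample = TRUE,
                           gm_thresh = 0.5, mean_type = c("signed", "abs"),
                           low_hz = 0.009, high_hz = 0.09, n_passes = 1L) {
  mean_type <- match.arg(mean_type)
  assert_same_grid(bold = bold, brain = ctx$brain_mask)
  d <- dim(bold$data)
  if (is.null(analysis_mask)) {
    sel <- ctx$gm_prob$data >= gm_thresh & !as.logical(ctx$lesion_mask$data)
  } else {
    assert_same_grid(bold = bold, analysis_mask = analysis_mask)
    sel <- as.logical(analysis_mask$data)
  }
  if (!any(sel)) stop("empty lag analysis mask")
  filt <- bandpass(bold, low_hz = low_hz, high_hz = high_hz)
  gm_sel <- ctx$gm_prob$data >= gm_thresh & !as.logical(ctx$lesion_mask$data)
  if (!any(gm_sel)) stop("empty gray-matter compartment (GM minus lesion)")
  Yref <- mask_matrix(filt, gm_sel)                 # GM voxels for the ref
  Y <- mask_matrix(filt, sel)                       # V x T analysis voxels
  tr <- bold$tr_s
  shifts <- -max_shift_trs:max_shift_trs
  n <- ncol(Y)
  deltas <- if (subsample) c(0, 0.25, 0.5, 0.75) else 0
  estimate <- function(Ymat, ref) {
    # dense-grid lagged correlation, vectorized over voxels: integer-TR
    # windows against (optionally Fourier-shifted) references
    nv <- nrow(Ymat)
    best_lag <- rep(NA_real_, nv)
    best_r <- rep(-Inf, nv)
    for (dl in deltas) {
      refs <- if (dl == 0) ref else fourier_shift(ref, dl * tr, tr)
      for (s in shifts) {
        ts_idx <- if (s >= 0) (1 + s):n else 1:(n + s)
        rf_idx <- if (s >= 0) 1:(n - s) else (1 - s):n
        Ys <- Ymat[, ts_idx, drop = FALSE]
        rs <- refs[rf_idx]
        Yc <- Ys - rowMeans(Ys)
        rc <- rs - mean(rs)
        den <- sqrt(rowSums(Yc^2) * sum(rc^2))
        r <- ifelse(den > 0, as.numeric(Yc %*% rc) / den, NA_real_)
        upd <- !is.na(r) & r > best_r
        best_lag[upd] <- (s + dl) * tr
        best_r[upd] <- r[upd]
      }
    }
    best_r[!is.finite(best_r)] <- NA_real_
    best_lag <- pmax(-max_shift_trs * tr, pmin(max_shift_trs * tr, best_lag))
    list(lag = best_lag, peak_r = best_r)
  }
  ref <- colMeans(Yref)
  if (n_passes > 1L) {
    # Iterative reference refinement: realign GM voxels by their estimated
    # lag before averaging, removing the merge bias a mixed-lag reference
    # induces; lags from the final pass are reported.
    f <- fft_freqs(n, tr)
    for (pass in seq_len(n_passes - 1L)) {
      lag_gm <- estimate(Yref, ref)$lag
      lag_gm[!is.finite(lag_gm)] <- 0
      Yf <- stats::mvfft(t(Yref))
      Yf <- Yf * exp(2i * pi * outer(f, lag_gm))    # shift by -lag
      Yal <- Re(stats::mvfft(Yf, inverse = TRUE)) / n
      ref <- rowMeans(Yal)
    }
  }
  est <- estimate(Y, ref)
  lag <- est$lag; peak_r <- est$peak_r
  novar <- apply(Y, 1L, function(r) stats::sd(r) == 0)
  lag[novar] <- NaN; peak_r[novar] <- NaN

  lag_full <- rep(NaN, prod(d[1:3])); lag_full[sel] <- lag
  r_full <- rep(NaN, prod(d[1:3])); r_full[sel] <- peak_r
  wx <- voxel_world_x(ctx$brain_mask)
  left <- wx < 0
  affected <- if (ctx$affected_side == "left") left else !left
  sel_idx <- which(sel)
  in_aff <- affected[sel_idx]
  if (!any(in_aff) || all(in_aff)) stop("empty hemisphere in analysis mask")
  mean_lag <- function(v) mean(v[is.finite(v)])
  m_aff <- mean_lag(lag[in_aff]); m_unaff <- mean_lag(lag[!in_aff])
  ma_aff <- mean_lag(abs(lag[in_aff])); ma_unaff <- mean_lag(abs(lag[!in_aff]))
  # Only relative lags are identifiable: the global reference absorbs part
  # of any widespread delay. The unaffected hemisphere anchors lag zero
  # (in real cohorts its mean is ~0), so the QC gate uses the affected
  # hemisphere's excess over it.
  excess <- if (mean_type == "signed") m_aff - m_unaff else ma_aff - ma_unaff
  structure(list(
    lag_s = volume_image(array(lag_full, d[1:3]), bold$affine),
    peak_r = volume_image(array(r_full, d[1:3]), bold$affine),
    mean_lag_affected_s = m_aff, mean_lag_unaffected_s = m_unaff,
    mean_abs_lag_affected_s = ma_aff, mean_abs_lag_unaffected_s = ma_unaff,
    affected_lag_excess_s = excess,
    excluded = excess > exclusion_thresh_s,
    exclusion_thresh_s = exclusion_thresh_s,
    max_shift_trs = as.integer(max_shift_trs)), class = "lag_map")
}

#' @export
print.lag_map <- function(x, ...) {
  cat(sprintf("<lag_map> mean lag affected %.3fs / unaffected %.3fs; excluded: %s\n",
              x$mean_lag_affected_s, x$mean_lag_unaffected_s, x$excluded))
  invisible(x)
}

#' Write lag-map outputs
#'
#' Lag and peak-correlation NIfTIs plus a QC JSON with the hemispheric
#' means and the exclusion verdict.
#'
#' @param lm_res a `lag_map`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_lagmap <- function(lm_res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(lm_res$lag_s, file.path(dir, "lag_s.nii.gz"))
  write_volume(lm_res$peak_r, file.path(dir, "peak_r.nii.gz"))
  jsonlite::write_json(
    list(mean_lag_affected_s = lm_res$mean_lag_affected_s,
         mean_lag_unaffected_s = lm_res$mean_lag_unaffected_s,
         mean_abs_lag_affected_s = lm_res$mean_abs_lag_affected_s,
         mean_abs_lag_unaffected_s = lm_res$mean_abs_lag_unaffected_s,
         excluded = lm_res$excluded),
    file.path(dir, "lag_qc.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
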