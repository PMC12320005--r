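# Nuisance-regressor computation: motion expansion, framewise displacement
# (Power and Jenkinson), DVARS, motion-outlier flags, lesion-adjusted tissue
# noise masks, tissue/global mean signals, discrete-cosine drift basis, and
# anatomical CompCor.

#' Expand regressors with derivatives and quadratic terms
#'
#' For each input column `x` adds its backward-difference temporal derivative
#' (first row imputed to 0), its square, and the squared derivative, yielding
#' the conventional 4k expansion (24 regressors from 6 motion parameters).
#'
#' @param cols T x k data.frame or matrix.
#' @return T x 4k data.frame with columns grouped as
#'   `x, x_derivative1, x_power2, x_derivative1_power2`.
#' @export
expand_regressors <- function(cols) {
  cols <- as.data.frame(cols)
  if (nrow(cols) < 2L) stop("need at least 2 time points to differentiate")
  out <- list()
  for (nm in names(cols)) {
    x <- cols[[nm]]
    dx <- c(0, diff(x))
    out[[nm]] <- x
    out[[paste0(nm, "_derivative1")]] <- dx
    out[[paste0(nm, "_power2")]] <- x^2
    out[[paste0(nm, "_derivative1_power2")]] <- dx^2
  }
  grp <- names(cols)
  ord <- c(grp, paste0(grp, "_derivative1"), paste0(grp, "_power2"),
           paste0(grp, "_derivative1_power2"))
  as.data.frame(out)[, ord]
}

check_motion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have 6 columns (3 translations mm, 3 rotations rad)")
  motion
}

#' Framewise displacement, Power formulation
#'
#' Absolute sum of frame-to-frame parameter differences, with rotations
#' converted to arc length on a sphere of `head_radius_mm`. First frame is 0.
#'
#' @param motion T x 6 (trans mm, rot rad).
#' @param head_radius_mm head radius for the rotation arc, default 50 mm.
#' @return length-T numeric vector.
#' @export
fd_power <- function(motion, head_radius_mm = 50) {
  m <- check_motion(motion)
  dm <- abs(diff(m))
  c(0, rowSums(dm[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(dm[, 4:6, drop = FALSE]))
}

# Rigid-body affine from one motion row (rotations applied as Rx Ry Rz,
# then translation).
rigid_affine <- function(par) {
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  A <- diag(4)
  A[1:3, 1:3] <- Rx %*% Ry %*% Rz
  A[1:3, 4] <- par[1:3]
  A
}

#' Framewise displacement, Jenkinson formulation
#'
#' Root-mean-square displacement between consecutive rigid-body affines over
#' a solid sphere of `head_radius_mm` centred at the origin:
#' `sqrt(R^2/5 * tr((M-I)'(M-I)) + |t|^2)` for the relative transform
#' `(M, t)`. First frame is 0.
#'
#' @inheritParams fd_power
#' @return length-T numeric vector.
#' @export
fd_jenkinson <- function(motion, head_radius_mm = 50) {
  m <- check_motion(motion)
  n <- nrow(m)
  affs <- lapply(seq_len(n), function(t) rigid_affine(m[t, ]))
  fd <- numeric(n)
  for (t in 2:n) {
    rel <- affs[[t]] %*% solve(affs[[t - 1]])
    M <- rel[1:3, 1:3] - diag(3)
    tt <- rel[1:3, 4]
    fd[t] <- sqrt(head_radius_mm^2 / 5 * sum(M^2) + sum(tt^2))
  }
  fd
}

#' DVARS
#'
#' Raw DVARS is the RMS over brain-mask voxels of the temporal difference
#' signal (first frame 0). Standardized DVARS divides by the within-run
#' median of the nonzero raw values, so a value of 1.5 means 1.5 times the
#' typical frame-to-frame change.
#'
#' @param bold 4D [volume_image].
#' @param brain_mask binary [volume_image].
#' @return list with `raw` and `standardized`, both length T.
#' @export
dvars <- function(bold, brain_mask) {
  assert_same_grid(bold = bold, brain_mask = brain_mask)
  if (sum(brain_mask$data) == 0) stop("empty brain mask")
  Y <- mask_matrix(bold, brain_mask$data)
  dY <- Y[, -1L, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]
  raw <- c(0, sqrt(colMeans(dY^2)))
  med <- stats::median(raw[-1L])
  std <- if (med > 0) raw / med else raw
  list(raw = raw, standardized = std)
}

#' Flag motion-outlier frames
#'
#' A frame is an outlier when FD strictly exceeds `fd_thresh` (mm) or
#' standardized DVARS strictly exceeds `dvars_thresh`.
#'
#' @param fd length-T framewise displacement.
#' @param dvars_std length-T standardized DVARS.
#' @param fd_thresh,dvars_thresh thresholds (defaults 0.5 mm, 1.5).
#' @return logical vector of length T.
#' @export
flag_motion_outliers <- function(fd, dvars_std, fd_thresh = 0.5,
                                 dvars_thresh = 1.5) {
  if (length(fd) != length(dvars_std))
    stop("fd and dvars_std lengths differ")
  fd > fd_thresh | dvars_std > dvars_thresh
}

# 6-connectivity binary dilation, `iter` voxel layers.
dilate6 <- function(mask3d, iter = 1L) {
  m <- mask3d
  d <- dim(m)
  for (i in seq_len(iter)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

#' Build CompCor noise masks (standard or lesion-adjusted)
#'
#' Standard variant: CSF and WM probability maps are binarized at
#' `prob_thresh` and voxels in a dilated gray-matter mask are subtracted, so
#' components are not extracted from voxels with any GM fraction.
#' Lesion-adjusted variant: lesion voxels are forced into the CSF mask,
#' removed from the WM mask, and removed from the GM exclusion.
#'
#' @param ctx a [subject_context].
#' @param variant `"standard"` or `"lesion_adjusted"`.
#' @param prob_thresh binarization threshold on the probability maps.
#' @param gm_thresh threshold defining the GM mask to dilate.
#' @param gm_dilation_vox dilation radius in voxels (6-connectivity).
#' @return list of class `noise_masks` with binary `csf_mask`, `wm_mask`,
#'   `combined_mask`, `whole_brain_mask` and the `variant`.
#' @export
make_noise_masks <- function(ctx, variant = c("standard", "lesion_adjusted"),
                             prob_thresh = 0.99, gm_thresh = 0.5,
                             gm_dilation_vox = 1L) {
  variant <- match.arg(variant)
  lesion <- as.logical(ctx$lesion_mask$data)
  gm <- ctx$gm_prob$data >= gm_thresh
  if (variant == "lesion_adjusted") gm <- gm & !lesion
  gm_ex <- dilate6(gm, gm_dilation_vox)
  csf <- ctx$csf_prob$data >= prob_thresh & !gm_ex
  wm <- ctx$wm_prob$data >= prob_thresh & !gm_ex
  if (variant == "lesion_adjusted") {
    csf <- csf | lesion
    wm <- wm & !lesion
  }
  if (!any(csf) || !any(wm))
    stop(paste("empty CSF or WM noise mask; relax `prob_thresh` or check",
               "the probability maps"))
  vol <- function(v) volume_image(array(as.numeric(v), dim = dim(ctx$brain_mask$data)),
                                  affine = ctx$brain_mask$affine)
  structure(list(csf_mask = vol(csf), wm_mask = vol(wm),
                 combined_mask = vol(csf | wm),
                 whole_brain_mask = ctx$brain_mask, variant = variant),
            class = "noise_masks")
}

#' Mean tissue/global signals
#'
#' Unweighted voxel-mean time series over the whole brain (`global_signal`)
#' and the variant's CSF and WM noise masks. With `lesion_aware = TRUE` and a
#' nonempty lesion, also emits the within-lesion mean (`lesion_signal`) and
#' the global mean excluding the lesion (`global_signal_excl_lesion`); the
#' plain `global_signal` is the including-lesion column.
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param masks [make_noise_masks()] output (built from `ctx` if `NULL`).
#' @param lesion_aware emit the lesion-split columns.
#' @return data.frame of mean-signal columns.
#' @export
mean_signals <- function(bold, ctx, masks = NULL, lesion_aware = FALSE) {
  if (is.null(masks)) masks <- make_noise_masks(ctx)
  mean_ts <- function(maskvol) {
    if (sum(maskvol$data) == 0) stop("empty mask in mean_signals")
    colMeans(mask_matrix(bold, maskvol$data))
  }
  out <- data.frame(global_signal = mean_ts(ctx$brain_mask),
                    csf = mean_ts(masks$csf_mask),
                    wm = mean_ts(masks$wm_mask))
  if (lesion_aware && sum(ctx$lesion_mask$data) > 0) {
    lesion <- as.logical(ctx$lesion_mask$data)
    brain <- as.logical(ctx$brain_mask$data)
    excl <- brain & !lesion
    d <- dim(ctx$brain_mask$data)
    va <- function(v) volume_image(array(as.numeric(v), dim = d),
                                   affine = ctx$brain_mask$affine)
    out$lesion_signal <- mean_ts(va(lesion))
    out$global_signal_excl_lesion <- mean_ts(va(excl))
  }
  out
}

#' Discrete-cosine drift basis
#'
#' Unit-norm DCT-II basis functions with periods at or above `cutoff_s`
#' (high-pass regressors for the 128 s CompCor filter). The number of
#' columns is `floor(2 * T * tr_s / cutoff_s)`; a run shorter than the
#' cutoff yields zero columns with a warning.
#'
#' @param n_t number of time points.
#' @param tr_s repetition time, seconds.
#' @param cutoff_s high-pass cutoff period, seconds.
#' @return T x k matrix (possibly 0 columns) with names `cosine_XX`.
#' @export
cosine_drift <- function(n_t, tr_s, cutoff_s = 128) {
  dur <- n_t * tr_s
  order <- floor(2 * dur / cutoff_s)
  if (dur <= cutoff_s) order <- 0L       # run shorter than the cutoff period
  if (order < 1L) {
    warning(sprintf("run (%.4gs) shorter than the %.4gs cutoff: no cosine drift columns",
                    dur, cutoff_s), call. = FALSE)
    return(matrix(numeric(0), n_t, 0))
  }
  t0 <- seq_len(n_t) - 1L
  basis <- sapply(seq_len(order), function(k)
    sqrt(2 / n_t) * cos(pi * (2 * t0 + 1) * k / (2 * n_t)))
  basis <- matrix(basis, n_t, order)
  colnames(basis) <- sprintf("cosine_%02d", seq_len(order) - 1L)
  basis
}

#' Anatomical CompCor
#'
#' Voxel time series inside the noise mask are high-pass filtered by
#' regressing out a discrete-cosine basis (with intercept), variance
#' normalized, and decomposed by SVD. The smallest number of leading
#' components whose cumulative explained variance reaches `var_explained`
#' is retained; component time series are unit variance, in singular-value
#' order.
#'
#' @param bold 4D [volume_image].
#' @param mask binary [volume_image] (typically the combined CSF+WM mask).
#' @param highpass_cutoff_s cosine high-pass cutoff (seconds).
#' @param var_explained cumulative variance fraction to retain (default 0.5).
#' @return T x k matrix with names `a_comp_cor_XX`; attributes
#'   `"explained_variance"` (per component, full spectrum) and `"k"`.
#' @export
acompcor <- function(bold, mask, highpass_cutoff_s = 128, var_explained = 0.5) {
  assert_same_grid(bold = bold, mask = mask)
  if (sum(mask$data) == 0) stop("empty CompCor mask")
  Y <- t(mask_matrix(bold, mask$data))               # T x V
  n_t <- nrow(Y)
  dct <- cosine_drift(n_t, bold$tr_s, highpass_cutoff_s)
  X <- cbind(1, dct)
  if (ncol(X) >= n_t) stop("run too short for the cosine high-pass basis")
  scale0 <- mean(abs(Y))
  Y <- stats::lm.fit(X, Y)$residuals
  sds <- apply(Y, 2L, stats::sd)
  keep <- sds > 1e-12 * max(scale0, .Machine$double.eps)
  if (!any(keep)) stop("all mask voxels are constant after filtering")
  Y <- sweep(Y[, keep, drop = FALSE], 2L, sds[keep], "/")
  sv <- svd(Y, nu = min(dim(Y)), nv = 0)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(ev) >= var_explained)[1L]
  comp <- sv$u[, seq_len(k), drop = FALSE]
  comp <- sweep(comp, 2L, apply(comp, 2L, stats::sd), "/")
  colnames(comp) <- sprintf("a_comp_cor_%02d", seq_len(k) - 1L)
  attr(comp, "explained_variance") <- ev
  attr(comp, "k") <- k
  comp
}
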