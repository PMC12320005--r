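# Pipeline presets, full confound computation, design-matrix assembly, and
# confound regression.
#
# Three presets mirror the evaluated pipelines:
#   CompCorGS          standard tissue masks, no ICA regressors
#   CompCorLesionGS    lesion-adjusted masks (lesion -> CSF, out of WM/GM)
#   ICLesionCompCorGS  lesion-adjusted masks + lesion-overlap ICA regressors

#' Pipeline specification
#'
#' @param name `"CompCorGS"`, `"CompCorLesionGS"` or `"ICLesionCompCorGS"`
#'   (case-insensitive).
#' @param include_gsr include the global-signal group (default `TRUE`; the
#'   no-GSR variants support sensitivity analyses).
#' @param expand_tissue apply the derivative/quadratic expansion to the WM
#'   and CSF signals as well as motion and GS (default `TRUE`).
#' @param spike_regressors add one indicator column per motion-outlier frame
#'   (default `FALSE`; outliers are annotated, not scrubbed).
#' @return Object of class `pipeline_spec` with the mask `variant` and
#'   `use_ica` resolved from the preset.
#' @export
pipeline_spec <- function(name, include_gsr = TRUE, expand_tissue = TRUE,
                          spike_regressors = FALSE) {
  presets <- c(compcorgs = "CompCorGS", compcorlesiongs = "CompCorLesionGS",
               iclesioncompcorgs = "ICLesionCompCorGS")
  key <- tolower(name)
  if (!key %in% names(presets))
    stop(sprintf("unknown pipeline '%s' (use %s)", name,
                 paste(presets, collapse = ", ")))
  name <- presets[[key]]
  structure(list(
    name = name,
    variant = if (name == "CompCorGS") "standard" else "lesion_adjusted",
    use_ica = name == "ICLesionCompCorGS",
    include_gsr = include_gsr, expand_tissue = expand_tissue,
    spike_regressors = spike_regressors), class = "pipeline_spec")
}

#' Compute the full confounds table for one subject
#'
#' Runs every confound generator the pipelines consume: 24-parameter motion
#' expansion, FD (Power and Jenkinson), DVARS, motion-outlier flags, noise
#' masks of the requested variant, global/tissue mean signals with their
#' expansions, the cosine drift basis, anatomical CompCor on the combined
#' CSF+WM mask, and (for lesion-aware variants with `ica = TRUE`) the
#' lesion-ICA regressors.
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param variant `"standard"` or `"lesion_adjusted"` noise masks.
#' @param ica compute lesion-ICA regressors (default `FALSE`).
#' @param ica_result reuse a precomputed [lesion_ica()] result (the ICA is
#'   variant-independent, so one fit can serve several pipelines).
#' @param seed RNG seed forwarded to the ICA.
#' @param n_ica_components forwarded to [lesion_ica()].
#' @param acompcor_var_explained retained cumulative variance (default 0.5).
#' @param highpass_cutoff_s cosine/CompCor high-pass cutoff (default 128 s).
#' @return Object of class `confounds_table`: data.frame `data`, list
#'   `groups` (column names per group), `masks`, `ica` (or `NULL`), `meta`.
#' @export
compute_confounds <- function(bold, ctx,
                              variant = c("standard", "lesion_adjusted"),
                              ica = FALSE, ica_result = NULL, seed = 1L,
                              n_ica_components = NULL,
                              acompcor_var_explained = 0.5,
                              highpass_cutoff_s = 128) {
  variant <- match.arg(variant)
  n_t <- n_timepoints(bold)
  stopifnot(nrow(ctx$motion) == n_t)

  motion24 <- expand_regressors(ctx$motion)
  fdp <- fd_power(ctx$motion)
  fdj <- fd_jenkinson(ctx$motion)
  dv <- dvars(bold, ctx$brain_mask)
  outliers <- flag_motion_outliers(fdp, dv$standardized)

  masks <- make_noise_masks(ctx, variant)
  sig <- mean_signals(bold, ctx, masks,
                      lesion_aware = variant == "lesion_adjusted")
  gs4 <- expand_regressors(sig["global_signal"])
  wm4 <- expand_regressors(sig["wm"])
  csf4 <- expand_regressors(sig["csf"])
  cosine <- cosine_drift(n_t, bold$tr_s, highpass_cutoff_s)
  cc <- acompcor(bold, masks$combined_mask,
                 highpass_cutoff_s = highpass_cutoff_s,
                 var_explained = acompcor_var_explained)

  ica_res <- ica_result
  if (ica && is.null(ica_res))
    ica_res <- lesion_ica(bold, ctx$brain_mask, ctx$lesion_mask,
                          n_components = n_ica_components, seed = seed)
  ica_cols <- if (!is.null(ica_res)) as.data.frame(ica_res$regressors)
              else data.frame(row.names = seq_len(n_t))

  df <- cbind(motion24, gs4, wm4, csf4, as.data.frame(cosine),
              as.data.frame(cc))
  if (ncol(ica_cols)) df <- cbind(df, ica_cols)
  df$framewise_displacement <- fdp
  df$framewise_displacement_jenkinson <- fdj
  df$dvars <- dv$raw
  df$std_dvars <- dv$standardized
  df$motion_outlier <- as.numeric(outliers)
  extra <- names(sig)[!names(sig) %in% c("global_signal", "wm", "csf")]
  for (nm in extra) df[[nm]] <- sig[[nm]]

  groups <- list(
    motion24 = names(motion24),
    gs4 = names(gs4), wm = names(wm4), csf = names(csf4),
    compcor = colnames(cc), cosine = colnames(cosine),
    ica_lesion = names(ica_cols),
    fd = c("framewise_displacement", "framewise_displacement_jenkinson"),
    dvars = c("dvars", "std_dvars"),
    outliers = "motion_outlier")
  structure(list(data = df, groups = groups, masks = masks, ica = ica_res,
                 meta = list(variant = variant, seed = seed,
                             acompcor_k = attr(cc, "k"), tr_s = bold$tr_s)),
            class = "confounds_table")
}

#' @export
print.confounds_table <- function(x, ...) {
  cat(sprintf("<confounds_table> %d frames x %d columns (%s masks, %d ICA)\n",
              nrow(x$data), ncol(x$data), x$meta$variant,
              length(x$groups$ica_lesion)))
  invisible(x)
}

#' Assemble the design matrix for a pipeline
#'
#' Columns: intercept, cosine drift, 24 motion regressors, the expanded
#' global signal (when GSR is on), expanded WM and CSF signals, aCompCor
#' components, and the ICA-lesion group for the ICLesion preset. An empty
#' ICA group under the ICLesion preset is allowed (the model then equals
#' CompCorLesionGS) and is logged as a message. Collinear columns are
#' dropped with a warning so the matrix has full column rank.
#'
#' @param spec a [pipeline_spec()].
#' @param confounds a [compute_confounds()] result whose variant matches
#'   `spec`.
#' @return Object of class `design_matrix`: numeric matrix `X` (T x p),
#'   `provenance` (group of each column), `spec`.
#' @export
build_design <- function(spec, confounds) {
  stopifnot(inherits(spec, "pipeline_spec"),
            inherits(confounds, "confounds_table"))
  if (confounds$meta$variant != spec$variant)
    stop(sprintf("confounds were computed with %s masks but %s requires %s",
                 confounds$meta$variant, spec$name, spec$variant))
  df <- confounds$data
  g <- confounds$groups
  take <- function(cols) as.matrix(df[, cols, drop = FALSE])
  parts <- list(intercept = matrix(1, nrow(df), 1,
                                   dimnames = list(NULL, "intercept")))
  if (length(g$cosine)) parts$cosine <- take(g$cosine)
  parts$motion24 <- take(g$motion24)
  if (spec$include_gsr) parts$gs4 <- take(g$gs4)
  tissue_cols <- function(cols4) if (spec$expand_tissue) cols4 else cols4[1L]
  parts$wm <- take(tissue_cols(g$wm))
  parts$csf <- take(tissue_cols(g$csf))
  parts$compcor <- take(g$compcor)
  if (spec$use_ica) {
    if (length(g$ica_lesion)) {
      parts$ica_lesion <- take(g$ica_lesion)
    } else {
      message("no ICA component met the lesion-overlap criterion; ",
              "design equals CompCorLesionGS")
    }
  }
  if (spec$spike_regressors) {
    out <- which(df$motion_outlier > 0)
    if (length(out)) {
      sp <- matrix(0, nrow(df), length(out),
                   dimnames = list(NULL, sprintf("motion_outlier_%02d",
                                                 seq_along(out) - 1L)))
      sp[cbind(out, seq_along(out))] <- 1
      parts$spikes <- sp
    }
  }
  X <- do.call(cbind, parts)
  prov <- rep(names(parts), vapply(parts, ncol, integer(1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning(sprintf("dropping %d collinear design column(s): %s",
                    ncol(X) - qrX$rank,
                    paste(colnames(X)[-keep], collapse = ", ")),
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
    prov <- prov[keep]
  }
  structure(list(X = X, provenance = prov, spec = spec),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s: %d frames x %d regressors\n",
              x$spec$name, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Residualize signals against a design matrix
#'
#' One simultaneous least-squares regression of every signal column on all
#' design columns; returns the residuals.
#'
#' @param signals T x m numeric matrix (or vector).
#' @param design a `design_matrix` (or plain numeric matrix).
#' @return T x m matrix of residuals.
#' @export
regress_out <- function(signals, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(signals)
  if (nrow(Y) != nrow(X)) stop("signal and design lengths differ")
  if (ncol(X) >= nrow(X)) stop("design has p >= T")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  qr.resid(qrX, Y)
}

#' Denoise a BOLD run (or ROI series) by confound regression
#'
#' Applies [regress_out()] voxelwise inside the brain mask; voxels outside
#' are `NaN`. Because regression and spatial averaging commute, denoising
#' region means with the same design is numerically identical to averaging
#' denoised voxels.
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param spec a [pipeline_spec()].
#' @param confounds matching [compute_confounds()] result.
#' @return 4D [volume_image] of residuals, with the design matrix attached
#'   as attribute `"design"`.
#' @export
denoise_bold <- function(bold, ctx, spec, confounds) {
  assert_same_grid(bold = bold, brain = ctx$brain_mask)
  design <- build_design(spec, confounds)
  d <- dim(bold$data)
  inb <- as.logical(ctx$brain_mask$data)
  Y <- t(mask_matrix(bold, ctx$brain_mask$data))
  res <- regress_out(Y, design)
  full <- matrix(NaN, prod(d[1:3]), d[4L])
  full[inb, ] <- t(res)
  out <- volume_image(array(full, d), affine = bold$affine, tr_s = bold$tr_s)
  attr(out, "design") <- design
  out
}

#' Denoised region time series for one pipeline
#'
#' Convenience wrapper: extracts region means and residualizes them against
#' the pipeline design (equivalent to voxelwise denoising then averaging).
#'
#' @inheritParams denoise_bold
#' @param atlas an [atlas_spec].
#' @return T x R matrix of denoised region series with attributes `"atlas"`
#'   and `"design"`.
#' @export
denoise_roi_series <- function(bold, ctx, spec, confounds, atlas) {
  series <- extract_roi_series(bold, atlas, brain_mask = ctx$brain_mask)
  design <- build_design(spec, confounds)
  res <- regress_out(series, design)
  attr(res, "atlas") <- attr(series, "atlas")
  attr(res, "design") <- design
  res
}
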