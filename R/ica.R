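# Spatial ICA for lesion-driven artifact detection.
#
# FastICA (logcosh contrast, symmetric decorrelation) is implemented
# in-package. Spatial ICA convention: the T x V in-brain data matrix is
# reduced to k whitened spatial principal components (unit variance across
# voxels); FastICA rotates them into maximally non-Gaussian spatial maps,
# and mixing time courses are obtained by projecting the data onto the maps.

fastica_symm <- function(Z, max_iter = 200L, tol = 1e-6) {
  # Z: k x V, rows uncorrelated with unit variance (whitened)
  k <- nrow(Z); V <- ncol(Z)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorr <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% W
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z                       # k x V
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / V - diag(rowMeans(Gp)) %*% W
    W_new <- sym_decorr(W_new)
    conv <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (conv < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

#' Spatial ICA with lesion-overlap noise flagging
#'
#' Runs spatial FastICA on the in-brain BOLD data, z-scores each component's
#' spatial map, binarizes it at `|z| >= zmap_threshold`, and computes the
#' lesion overlap of each component. With the default component-referenced
#' denominator, overlap is the fraction of the component's suprathreshold
#' voxels that fall inside the lesion; `overlap_ref = "lesion"` divides by
#' the lesion size instead. Components with overlap at or above
#' `overlap_threshold` are flagged as noise and their mixing time courses
#' become the "ICA lesion" confound columns; the empty set is allowed (no
#' ICA regressors are then added to the model).
#'
#' @param bold 4D [volume_image].
#' @param brain_mask,lesion_mask binary [volume_image]s; lesion must be
#'   nonempty.
#' @param n_components number of components; default `min(8, T %/% 5)`.
#'   Small deliberately: every retained component should capture structured
#'   signal, because components dominated by unstructured noise have
#'   spatially uniform suprathreshold sets whose lesion overlap fluctuates
#'   around the lesion's brain fraction, producing chance flags. Raise it
#'   for longer, richer runs.
#' @param overlap_threshold flag threshold on the overlap fraction
#'   (inclusive; default 0.05).
#' @param zmap_threshold |z| threshold binarizing spatial maps (default 2).
#' @param overlap_ref `"component"` (default) or `"lesion"` denominator.
#' @param seed RNG seed; on non-convergence the fit is retried with a new
#'   derived seed up to 3 times, then errors.
#' @return Object of class `ica_result`: `n_components`, `maps` (V x k
#'   z-scored spatial maps, V = in-brain voxels), `mask` (logical in-brain
#'   selector), `time_courses` (T x k, unit variance), `lesion_overlap`
#'   (length k), `noise_flags` (logical), `regressors` (T x n_flagged,
#'   named `ica_lesion_XX`), `seed`.
#' @export
lesion_ica <- function(bold, brain_mask, lesion_mask, n_components = NULL,
                       overlap_threshold = 0.05, zmap_threshold = 2.0,
                       overlap_ref = c("component", "lesion"), seed = 1L) {
  assert_same_grid(bold = bold, brain_mask = brain_mask,
                   lesion_mask = lesion_mask)
  overlap_ref <- match.arg(overlap_ref)
  if (sum(lesion_mask$data) == 0) stop("empty lesion mask")
  n_t <- n_timepoints(bold)
  if (is.null(n_components)) n_components <- min(8L, n_t %/% 5L)
  if (n_components > n_t / 2)
    stop("n_components must be at most T/2")
  inb <- as.logical(brain_mask$data)
  Y <- t(mask_matrix(bold, brain_mask$data))        # T x V
  Y <- Y - rowMeans(Y)                              # remove spatial mean
  Y <- sweep(Y, 2L, colMeans(Y))                    # centre voxel series
  sv <- svd(Y, nu = 0, nv = n_components)
  k <- sum(sv$d[seq_len(n_components)] > 1e-10 * sv$d[1L])
  if (k < n_components) n_components <- k
  V <- ncol(Y)
  Z <- t(sv$v[, seq_len(n_components), drop = FALSE]) * sqrt(V)  # k x V whitened

  fit <- NULL
  for (attempt in 0:2) {
    set.seed(as.integer(seed) + attempt * 101L)
    fit <- fastica_symm(Z)
    if (fit$converged) break
  }
  if (!fit$converged) stop("FastICA failed to converge after 3 seeded retries")

  S <- fit$W %*% Z                                  # k x V spatial sources
  maps <- t(S)                                      # V x k
  maps <- scale(maps)                               # z-score across voxels
  # mixing time courses by least squares on the maps (dual-regression
  # convention; reduces cross-talk between spatially overlapping maps)
  tc <- t(solve(crossprod(maps), crossprod(maps, t(Y))))
  tc_sd <- apply(tc, 2L, stats::sd)
  tc <- sweep(tc, 2L, ifelse(tc_sd > 0, tc_sd, 1), "/")

  lesion_in <- as.logical(lesion_mask$data)[inb]
  supra <- abs(maps) >= zmap_threshold
  overlap <- vapply(seq_len(n_components), function(j) {
    s <- supra[, j]
    denom <- if (overlap_ref == "component") sum(s) else sum(lesion_in)
    if (denom == 0) 0 else sum(s & lesion_in) / denom
  }, numeric(1))
  flags <- overlap >= overlap_threshold
  reg <- tc[, flags, drop = FALSE]
  if (ncol(reg))
    colnames(reg) <- sprintf("ica_lesion_%02d", seq_len(ncol(reg)) - 1L)
  structure(list(n_components = n_components, maps = maps, mask = inb,
                 time_courses = tc, lesion_overlap = overlap,
                 noise_flags = flags, regressors = reg, seed = seed),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %d components, %d flagged as lesion noise\n",
              x$n_components, sum(x$noise_flags)))
  invisible(x)
}

#' Write an ICA result directory
#'
#' Component spatial maps as one 4D NIfTI, mixing matrix as TSV, overlap
#' report (per-component overlap fraction, flags, seed) as JSON.
#'
#' @param ica an `ica_result`.
#' @param template 3D or 4D [volume_image] providing grid/affine.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ica_result <- function(ica, template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(template$data)[1:3]
  arr <- array(NA_real_, dim = c(d, ica$n_components))
  flat <- matrix(NA_real_, prod(d), ica$n_components)
  flat[ica$mask, ] <- ica$maps
  arr[] <- flat
  write_volume(volume_image(arr, template$affine, tr_s = 1),
               file.path(dir, "ica_maps.nii.gz"))
  tcs <- as.data.frame(ica$time_courses)
  names(tcs) <- sprintf("ica_%02d", seq_len(ica$n_components) - 1L)
  write_confounds(tcs, file.path(dir, "ica_mixing.tsv"))
  jsonlite::write_json(
    list(seed = ica$seed, n_components = ica$n_components,
         lesion_overlap = ica$lesion_overlap,
         noise_flags = ica$noise_flags),
    file.path(dir, "ica_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
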