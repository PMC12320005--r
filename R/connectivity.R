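# Parcellation, Ledoit-Wolf shrinkage correlation, seed-to-voxel maps.

#' Atlas specification
#'
#' Binds an integer label image (0 = background) to a region-to-network
#' lookup. Every nonzero label must have a network entry.
#'
#' @param labels integer-valued 3D [volume_image].
#' @param networks data.frame with columns `region` (integer label) and
#'   `network` (character).
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(labels, networks) {
  stopifnot(is_volume(labels))
  v <- labels$data
  if (max(abs(v - round(v))) > 1e-6) stop("atlas labels must be integers")
  networks <- as.data.frame(networks)
  if (!all(c("region", "network") %in% names(networks)))
    stop("`networks` needs columns `region` and `network`")
  ids <- sort(unique(as.integer(v[v > 0])))
  missing <- setdiff(ids, networks$region)
  if (length(missing))
    stop(sprintf("labels without a network entry: %s",
                 paste(missing, collapse = ", ")))
  counts <- as.integer(table(factor(as.integer(v[v > 0]), levels = ids)))
  structure(list(labels = labels, region_ids = ids,
                 networks = networks[match(ids, networks$region), ,
                                     drop = FALSE],
                 voxel_counts = stats::setNames(counts, ids)),
            class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("<atlas_spec> %d regions, %d networks\n",
              length(x$region_ids), length(unique(x$networks$network))))
  invisible(x)
}

#' Extract region-mean time series
#'
#' Column `r` is the unweighted mean over voxels labelled `r`. Regions wholly
#' outside `brain_mask` are dropped with a warning; regions empty on the grid
#' are an error.
#'
#' @param bold 4D [volume_image].
#' @param atlas an [atlas_spec] on the same grid.
#' @param brain_mask optional binary [volume_image] restricting voxels.
#' @return T x R matrix with region ids as column names and the (possibly
#'   reduced) atlas attached as attribute `"atlas"`.
#' @export
extract_roi_series <- function(bold, atlas, brain_mask = NULL) {
  assert_same_grid(bold = bold, atlas = atlas$labels)
  lab <- as.integer(round(atlas$labels$data))
  if (!is.null(brain_mask)) {
    assert_same_grid(bold = bold, brain_mask = brain_mask)
    lab[!as.logical(brain_mask$data)] <- 0L
  }
  ids <- atlas$region_ids
  empty <- ids[!ids %in% lab]
  if (length(empty)) {
    if (is.null(brain_mask))
      stop(sprintf("empty atlas region(s): %s", paste(empty, collapse = ", ")))
    warning(sprintf("dropping region(s) outside brain mask: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    ids <- setdiff(ids, empty)
    if (!length(ids)) stop("no atlas regions inside the brain mask")
  }
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4L])
  out <- vapply(ids, function(r) colMeans(mat[lab == r, , drop = FALSE]),
                numeric(d[4L]))
  colnames(out) <- as.character(ids)
  keep <- match(ids, atlas$region_ids)
  red <- atlas
  red$region_ids <- ids
  red$networks <- atlas$networks[keep, , drop = FALSE]
  red$voxel_counts <- atlas$voxel_counts[keep]
  attr(out, "atlas") <- red
  out
}

# Ledoit-Wolf (2004) shrinkage of the sample covariance toward a scaled
# identity; returns the shrunk covariance of the centered data matrix X
# (rows = observations) and the shrinkage intensity.
ledoit_wolf_cov <- function(X) {
  n <- nrow(X); p <- ncol(X)
  X <- sweep(X, 2L, colMeans(X))
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - diag(mu, p))^2) / p
  if (delta2 < .Machine$double.eps)
    return(list(cov = S, shrinkage = 0))
  # sum_t ||x_t x_t' - S||_F^2 = sum_t (x_t'x_t)^2 - n ||S||_F^2
  sq_norms <- rowSums(X^2)
  beta2 <- (sum(sq_norms^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(beta2, delta2)
  shrink <- b2 / delta2
  list(cov = shrink * diag(mu, p) + (1 - shrink) * S, shrinkage = shrink)
}

#' Functional connectivity matrix
#'
#' Pearson correlation of region time series with the Ledoit-Wolf shrinkage
#' covariance estimator: columns are standardized, the shrunk covariance is
#' computed, and its diagonal renormalized to 1. `estimator = "sample"` gives
#' the plain sample correlation (the oracle route).
#'
#' @param series T x R matrix from [extract_roi_series()] (or any numeric
#'   matrix; network labels are taken from its `"atlas"` attribute when
#'   present, else from `networks`).
#' @param estimator `"ledoit_wolf"` (default) or `"sample"`.
#' @param networks optional character vector of network labels per column.
#' @return Object of class `connectivity_matrix`: list with `mat` (R x R,
#'   unit diagonal, symmetric), `region_ids`, `networks`, `estimator`,
#'   `shrinkage`.
#' @export
fc_matrix <- function(series, estimator = c("ledoit_wolf", "sample"),
                      networks = NULL) {
  estimator <- match.arg(estimator)
  series <- as.matrix(series)
  if (nrow(series) < 3L) stop("need at least 3 time points")
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant region time series: %s", paste(bad, collapse = ", ")))
  }
  atl <- attr(series, "atlas")
  if (is.null(networks) && !is.null(atl)) networks <- atl$networks$network
  ids <- colnames(series)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(series)))
  Z <- scale(series)
  shrink <- NA_real_
  if (estimator == "ledoit_wolf") {
    lw <- ledoit_wolf_cov(Z)
    C <- stats::cov2cor(lw$cov)
    shrink <- lw$shrinkage
  } else {
    C <- stats::cor(series)
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  dimnames(C) <- list(ids, ids)
  structure(list(mat = C, region_ids = ids, networks = networks,
                 estimator = estimator, shrinkage = shrink),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %dx%d (%s%s)\n", nrow(x$mat), ncol(x$mat),
              x$estimator,
              if (!is.na(x$shrinkage))
                sprintf(", shrinkage %.3g", x$shrinkage) else ""))
  invisible(x)
}

#' Write a connectivity matrix as TSV (and optionally NPY)
#'
#' @param fc a `connectivity_matrix`.
#' @param path output TSV path (region ids as header).
#' @param npy_path optional path for an NPY (float64) copy.
#' @return `path`, invisibly.
#' @export
write_fc <- function(fc, path, npy_path = NULL) {
  df <- as.data.frame(fc$mat)
  names(df) <- fc$region_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(npy_path)) write_npy(fc$mat, npy_path)
  invisible(path)
}

#' Seed-to-voxel correlation map
#'
#' Pearson correlation between the seed-mask mean time series and every
#' in-brain voxel; `NaN` outside the brain mask and at zero-variance voxels.
#'
#' @param bold 4D [volume_image] (typically denoised).
#' @param seed_mask binary [volume_image] (e.g. the lesion mask).
#' @param brain_mask binary [volume_image].
#' @return 3D [volume_image] of correlations.
#' @export
seed_to_voxel <- function(bold, seed_mask, brain_mask) {
  assert_same_grid(bold = bold, seed_mask = seed_mask, brain_mask = brain_mask)
  if (sum(seed_mask$data) == 0) stop("empty seed mask")
  seed <- colMeans(mask_matrix(bold, seed_mask$data))
  if (stats::sd(seed) == 0) stop("zero-variance seed signal")
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4L])
  out <- rep(NA_real_, prod(d[1:3]))
  inb <- as.logical(brain_mask$data)
  Y <- mat[inb, , drop = FALSE]
  Yc <- Y - rowMeans(Y)
  sc <- seed - mean(seed)
  denom <- sqrt(rowSums(Yc^2) * sum(sc^2))
  r <- as.numeric(Yc %*% sc) / denom
  r[denom == 0] <- NA_real_
  out[inb] <- pmin(1, pmax(-1, r))
  volume_image(array(out, dim = d[1:3]), affine = bold$affine)
}
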