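#' In-memory volumetric image
#'
#' A `volume_image` carries a 3D `(X,Y,Z)` or 4D `(X,Y,Z,T)` numeric array,
#' a 4x4 voxel-to-world affine (0-based voxel indices), and, for 4D series,
#' the repetition time in seconds. It is the common carrier for BOLD runs,
#' binary masks, tissue probability maps, atlas label images and lag maps.
#'
#' @param data numeric array with 3 or 4 dimensions.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   coordinates (mm). Last row must be `(0,0,0,1)`.
#' @param tr_s repetition time in seconds; required (positive) for 4D data,
#'   ignored for 3D.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine = diag(4), tr_s = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  if (any(dim(data)[1:3] < 1L)) stop("all spatial dimensions must be >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("last affine row must be (0,0,0,1)")
  is4d <- length(dim(data)) == 4L
  if (is4d) {
    if (is.null(tr_s) || !is.finite(tr_s) || tr_s <= 0)
      stop("4D volumes require a positive `tr_s` (repetition time, seconds)")
    tr_s <- as.numeric(tr_s)
  } else {
    tr_s <- NULL
  }
  structure(list(data = data, affine = affine, tr_s = tr_s),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %s%s\n", paste(d, collapse = "x"),
              if (!is.null(x$tr_s)) sprintf(" TR=%gs", x$tr_s) else ""))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume_image")

n_timepoints <- function(vol) {
  d <- dim(vol$data)
  if (length(d) != 4L) stop("expected a 4D volume")
  d[4L]
}

#' Check that a volume is a binary mask
#'
#' @param vol a `volume_image`.
#' @return `TRUE` if every voxel is 0 or 1.
#' @export
is_binary_mask <- function(vol) {
  v <- vol$data
  all(v %in% c(0, 1))
}

assert_mask <- function(vol, name = deparse(substitute(vol))) {
  if (!is_binary_mask(vol))
    stop(sprintf("`%s` must be {0,1}-valued", name))
  invisible(vol)
}

assert_prob_map <- function(vol, name = deparse(substitute(vol))) {
  v <- vol$data
  if (any(!is.finite(v)) || min(v) < 0 || max(v) > 1)
    stop(sprintf("`%s` must be a probability map in [0,1]", name))
  invisible(vol)
}

#' Assert that images share one voxel grid and affine
#'
#' Raises an error naming the offending images when spatial shapes differ or
#' affine entries differ by more than `tol`.
#'
#' @param ... named `volume_image` objects (names used in error messages).
#' @param tol absolute tolerance on affine entries.
#' @return Invisibly `TRUE`.
#' @export
assert_same_grid <- function(..., tol = 1e-4) {
  imgs <- list(...)
  nm <- names(imgs)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("image", seq_along(imgs))
  if (length(imgs) < 2L) return(invisible(TRUE))
  ref <- imgs[[1L]]
  rd <- dim(ref$data)[1:3]
  bad <- character(0)
  for (i in seq_along(imgs)[-1L]) {
    d <- dim(imgs[[i]]$data)[1:3]
    if (!all(d == rd) ||
        max(abs(imgs[[i]]$affine - ref$affine)) > tol)
      bad <- c(bad, nm[i])
  }
  if (length(bad))
    stop(sprintf("grid mismatch: %s differ from %s (shape or affine beyond %g)",
                 paste(bad, collapse = ", "), nm[1L], tol))
  invisible(TRUE)
}

# World x-coordinate of every voxel; used for the hemispheric split.
voxel_world_x <- function(vol) {
  d <- dim(vol$data)[1:3]
  idx <- arrayInd(seq_len(prod(d)), d) - 1L   # 0-based
  aff <- vol$affine
  aff[1, 1] * idx[, 1] + aff[1, 2] * idx[, 2] + aff[1, 3] * idx[, 3] + aff[1, 4]
}

# Flatten a 4D volume to a voxels-in-mask x T matrix (mask is logical/0-1 3D).
mask_matrix <- function(bold, mask) {
  d <- dim(bold$data)
  m <- as.logical(mask)
  if (length(m) != prod(d[1:3])) stop("mask does not match grid")
  mat <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4L])
  mat[m, , drop = FALSE]
}
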