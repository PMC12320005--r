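# Tabular and subject-level I/O: BIDS-derivatives style TSV (tab separator,
# "n/a" for missing) and a subject directory layout of NIfTI + TSV + JSON.

#' Write a confounds/time-series table as TSV
#'
#' BIDS-derivatives dialect: tab separated, header row, `n/a` for missing
#' values. Values are written with 6 significant digits so a round-trip
#' preserves them to that precision.
#'
#' @param table a data.frame of equal-length numeric columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confounds <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table)))
    stop("duplicate column names in confounds table")
  fmt <- lapply(table, function(col) {
    out <- vapply(col, function(v)
      if (is.na(v)) "n/a" else sprintf("%.6g", v), character(1))
    out
  })
  m <- do.call(cbind, fmt)
  colnames(m) <- names(table)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounds/time-series table from TSV
#'
#' Missing cells (`n/a`) are imputed: columns named like temporal derivatives
#' (`*_derivative1`, `*_derivative1_power2`) get 0 (the first-frame
#' convention); other columns get their column mean. A warning reports every
#' imputed column.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A data.frame of numeric columns.
#' @export
read_confounds <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged TSV (row widths %s): %s",
                 paste(unique(nf), collapse = ","), path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(hdr))
    stop(sprintf("duplicate column names in %s: %s", path,
                 paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  df <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          check.names = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (anyNA(col)) {
      nmiss <- sum(is.na(col))
      fill <- if (grepl("derivative", nm)) 0 else mean(col, na.rm = TRUE)
      col[is.na(col)] <- fill
      df[[nm]] <- col
      warning(sprintf("imputed %d missing value(s) in column '%s' with %g",
                      nmiss, nm, fill), call. = FALSE)
    }
  }
  df
}

#' Bundle the per-subject images and metadata
#'
#' Validates that all images share one grid/affine, that masks are binary,
#' probability maps are in `[0,1]`, and that the lesion lies inside the brain
#' mask.
#'
#' @param brain_mask,gm_prob,wm_prob,csf_prob,lesion_mask `volume_image`s on
#'   a common grid.
#' @param affected_side `"left"` or `"right"` (hemisphere containing the
#'   lesion).
#' @param motion T x 6 data.frame/matrix of rigid-body parameters with
#'   columns `trans_x,trans_y,trans_z` (mm) and `rot_x,rot_y,rot_z` (rad).
#' @return An object of class `subject_context`.
#' @export
subject_context <- function(brain_mask, gm_prob, wm_prob, csf_prob,
                            lesion_mask, affected_side, motion) {
  assert_same_grid(brain_mask = brain_mask, gm_prob = gm_prob,
                   wm_prob = wm_prob, csf_prob = csf_prob,
                   lesion_mask = lesion_mask)
  assert_mask(brain_mask); assert_mask(lesion_mask)
  assert_prob_map(gm_prob); assert_prob_map(wm_prob); assert_prob_map(csf_prob)
  if (any(lesion_mask$data > brain_mask$data))
    stop("lesion mask has voxels outside the brain mask")
  affected_side <- match.arg(affected_side, c("left", "right"))
  motion <- as.data.frame(motion)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (ncol(motion) != 6L)
    stop("motion table must have exactly 6 columns")
  if (!all(need %in% names(motion))) names(motion) <- need
  motion <- motion[, need]
  structure(list(brain_mask = brain_mask, gm_prob = gm_prob,
                 wm_prob = wm_prob, csf_prob = csf_prob,
                 lesion_mask = lesion_mask, affected_side = affected_side,
                 motion = motion),
            class = "subject_context")
}

#' @export
print.subject_context <- function(x, ...) {
  cat(sprintf("<subject_context> grid %s, lesion %d vox, affected side %s\n",
              paste(dim(x$brain_mask$data), collapse = "x"),
              sum(x$lesion_mask$data), x$affected_side))
  invisible(x)
}

#' Write a subject directory (fMRIPrep-derivative-like layout)
#'
#' Emits `bold.nii.gz`, the five mask/probability images, `motion.tsv`,
#' `atlas.nii.gz` + `networks.tsv` when an atlas is supplied, and a
#' `meta.json` sidecar with `tr_s` and `affected_side`.
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param dir output directory (created if missing).
#' @param atlas optional [atlas_spec] to write alongside.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(bold, ctx, dir, atlas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bold, file.path(dir, "bold.nii.gz"))
  write_volume(ctx$brain_mask, file.path(dir, "brain_mask.nii.gz"), "uint8")
  write_volume(ctx$lesion_mask, file.path(dir, "lesion_mask.nii.gz"), "uint8")
  write_volume(ctx$gm_prob, file.path(dir, "gm_prob.nii.gz"))
  write_volume(ctx$wm_prob, file.path(dir, "wm_prob.nii.gz"))
  write_volume(ctx$csf_prob, file.path(dir, "csf_prob.nii.gz"))
  write_confounds(ctx$motion, file.path(dir, "motion.tsv"))
  if (!is.null(atlas)) {
    write_volume(atlas$labels, file.path(dir, "atlas.nii.gz"), "int16")
    utils::write.table(atlas$networks, file.path(dir, "networks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(tr_s = bold$tr_s, affected_side = ctx$affected_side),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a subject directory written by [write_subject()]
#'
#' @param dir subject directory.
#' @return A list with `bold`, `ctx`, and `atlas` (`NULL` when absent).
#' @export
read_subject <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  bold <- read_volume(file.path(dir, "bold.nii.gz"))
  ctx <- subject_context(
    brain_mask = read_volume(file.path(dir, "brain_mask.nii.gz")),
    gm_prob = read_volume(file.path(dir, "gm_prob.nii.gz")),
    wm_prob = read_volume(file.path(dir, "wm_prob.nii.gz")),
    csf_prob = read_volume(file.path(dir, "csf_prob.nii.gz")),
    lesion_mask = read_volume(file.path(dir, "lesion_mask.nii.gz")),
    affected_side = meta$affected_side,
    motion = read_confounds(file.path(dir, "motion.tsv")))
  atlas <- NULL
  if (file.exists(file.path(dir, "atlas.nii.gz")))
    atlas <- atlas_spec(read_volume(file.path(dir, "atlas.nii.gz")),
                        utils::read.delim(file.path(dir, "networks.tsv")))
  list(bold = bold, ctx = ctx, atlas = atlas)
}

# Minimal NPY (v1.0) writer for a numeric matrix, little-endian float64.
# Used for the portable binary export of connectivity matrices.
write_npy <- function(mat, path) {
  mat <- as.matrix(mat)
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                 nrow(mat), ncol(mat))
  pad <- (64L - ((10L + nchar(hdr) + 1L) %% 64L)) %% 64L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(1L), as.raw(0L)), con)
  writeBin(nchar(hdr), con, size = 2L, endian = "little")
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(t(mat)), con, size = 8L, endian = "little")
  invisible(path)
}
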