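# Small-world generator parameters shared across test files: 16x16x10 grid,
# 120 volumes, 8 regions in 2 networks. Big enough to exercise every mask
# and estimator, small enough to generate in ~0.1 s.
small_params <- function(...) {
  defaults <- list(dim = c(16L, 16L, 10L), n_t = 120L, n_regions = 8L,
                   n_networks = 2L, lesion_size_vox = 40L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_params, args)
}

small_subject <- function(seed = 1L, ...) {
  generate_subject(small_params(seed = seed, ...))
}

# Hand-built 5x5x3 subject context with fully controlled probability maps.
manual_ctx <- function(csf = NULL, wm = NULL, gm = NULL, lesion_idx = integer(0),
                       dim3 = c(5L, 5L, 3L)) {
  z <- array(0, dim3)
  brain <- array(1, dim3)
  csf_p <- if (is.null(csf)) z else csf
  wm_p <- if (is.null(wm)) z else wm
  gm_p <- if (is.null(gm)) z else gm
  les <- array(0, dim3)
  les[lesion_idx] <- 1
  motion <- as.data.frame(matrix(0, 10, 6))
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  subject_context(
    brain_mask = volume_image(brain), gm_prob = volume_image(gm_p),
    wm_prob = volume_image(wm_p), csf_prob = volume_image(csf_p),
    lesion_mask = volume_image(les), affected_side = "left", motion = motion)
}
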