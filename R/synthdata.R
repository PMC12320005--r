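# Synthetic stroke-subject generator.
#
# Emulates the data model the pipelines consume: network-structured BOLD on a
# small ellipsoidal "brain", smooth radial tissue probability maps (WM core,
# GM shell, CSF rim), a k-means GM parcellation grouped into networks, a
# lesion of an exact voxel count whose time series is pure noise plus a
# band-limited artifact, the same artifact injected into remote
# "contaminated" regions (the mechanism behind spurious lesion
# connectivity), a voxelwise hemodynamic lag field injected by circular
# Fourier shift, and random-walk motion traces.

#' Parameters of the synthetic stroke subject
#'
#' Defaults state the emulated world: a 24x24x12 grid at 3 mm, 150 volumes at
#' TR = 2 s, 20 regions in 4 networks with within-network signal correlation
#' 0.6, a 100-voxel lesion carrying a band-limited artifact of amplitude 2
#' (in units of the voxel noise SD, i.e. artifact SNR 2) shared with 3
#' contaminated regions in the unaffected hemisphere, unit noise SD (voxel
#' neural SNR 1), and no injected lag.
#'
#' @param dim 3-vector of grid dimensions.
#' @param n_t number of volumes.
#' @param tr_s repetition time, seconds.
#' @param n_regions,n_networks parcellation size; `n_regions` must be a
#'   multiple-free >= `n_networks` (regions are assigned round-robin).
#' @param r_within target Pearson correlation between region signals within a
#'   network.
#' @param global_share variance share of a global (vascular) signal common to
#'   all regions; it is what a lagged-cross-correlation reference can latch
#'   onto, and it sets the between-network correlation. Must be below
#'   `r_within`.
#' @param lesion_size_vox lesion voxel count (nearest-voxel ball, exact).
#' @param lesion_covers_regions if a positive integer k, the lesion is
#'   instead the union of the k affected-side regions nearest a random
#'   affected-side seed, so lesion-overlapping regions are wholly
#'   non-functional (the large-stroke regime the strength metrics address);
#'   `lesion_size_vox` is then ignored.
#' @param a_les artifact amplitude (SD units) in lesion and contaminated
#'   regions; 0 disables the artifact.
#' @param artifact_rank number of independent artifact time courses mixed
#'   with voxel-specific weights (default 1: one shared course, the
#'   construction recovered by a single ICA component; ranks above 1 emulate
#'   spatially heterogeneous pulsatile artifacts that mean-signal regressors
#'   can only partially capture).
#' @param n_contaminated number of remote regions carrying the artifact.
#' @param artifact_in_lesion if `FALSE`, the artifact is injected only in the
#'   contaminated regions, leaving the lesion pure noise (the null
#'   construction for lesion-ICA specificity).
#' @param lag_by_region_trs optional lags (in TRs, typically integers) per
#'   region; every voxel of a region inherits its lag. `NULL` means no lag.
#'   Recovery against a global reference requires most regions at lag 0
#'   (see [sparse_lag_field()]).
#' @param lag_affected_s additional lag (seconds) applied to every
#'   affected-hemisphere voxel (hemisphere-coherent lag used by the QC gate).
#' @param noise_sd SD of iid voxel noise (neural signals have SD 1).
#' @param physio_amp amplitude of the shared physiological signal added to
#'   WM/CSF voxels (feeds aCompCor).
#' @param motion_scale_mm per-frame SD of the translation random walk;
#'   rotations use `motion_scale_mm / 50` radians.
#' @param affected_side `"left"` or `"right"`.
#' @param baseline additive BOLD baseline intensity.
#' @param seed integer RNG seed; identical seeds give bit-identical subjects.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(dim = c(24L, 24L, 12L), n_t = 150L, tr_s = 2,
                         n_regions = 20L, n_networks = 4L, r_within = 0.6,
                         global_share = 0.4, lesion_size_vox = 100L,
                         lesion_covers_regions = NULL,
                         a_les = 2, artifact_rank = 1L, n_contaminated = 3L,
                         artifact_in_lesion = TRUE,
                         lag_by_region_trs = NULL, lag_affected_s = 0,
                         noise_sd = 1, physio_amp = 0.5,
                         motion_scale_mm = 0.02, affected_side = "left",
                         baseline = 100, seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$dim) == 3L, p$n_t >= 8L, p$tr_s > 0,
            p$n_regions >= p$n_networks, p$r_within > 0, p$r_within < 1,
            p$global_share >= 0, p$global_share < p$r_within,
            p$lesion_size_vox >= 1L, p$noise_sd >= 0)
  if (!is.null(p$lag_by_region_trs)) {
    stopifnot(length(p$lag_by_region_trs) == p$n_regions)
    if (max(abs(p$lag_by_region_trs)) > 4)
      stop("injected lags exceed the +/-4 TR search window")
  }
  if (abs(p$lag_affected_s) > 4 * p$tr_s)
    stop("injected lags exceed the +/-4 TR search window")
  p$affected_side <- match.arg(p$affected_side, c("left", "right"))
  class(p) <- "synth_params"
  p
}

# Band-limited (default 0.009-0.09 Hz) unit-SD series with a FLAT band
# spectrum and random phases (random-phase surrogate construction). The
# flat spectrum keeps the autocorrelation width deterministic, so lagged
# cross-correlation peaks are resolvable at 1 TR; circular band-limiting
# makes circular shifts exact.
bandlimited_series <- function(n_t, tr_s, n = 1L, low_hz = 0.009,
                               high_hz = 0.09) {
  f <- fft_freqs(n_t, tr_s)
  pos <- which(f > 0 & f >= low_hz & f <= high_hz)
  if (!length(pos)) stop("band contains no Fourier bins at this T and TR")
  y <- matrix(0, n_t, n)
  for (j in seq_len(n)) {
    spec <- complex(length.out = n_t)
    ph <- stats::runif(length(pos), 0, 2 * pi)
    spec[pos] <- exp(1i * ph)
    # Hermitian symmetry for a real signal
    spec[n_t + 2L - pos] <- Conj(spec[pos])
    y[, j] <- Re(stats::fft(spec, inverse = TRUE))
  }
  y <- sweep(y, 2L, colMeans(y))
  sweep(y, 2L, apply(y, 2L, stats::sd), "/")
}

fft_freqs <- function(n, tr_s) {
  k <- c(seq(0L, floor(n / 2)), seq(-(ceiling(n / 2) - 1L), -1L))
  k / (n * tr_s)
}

# Circular shift by an arbitrary lag (seconds); positive lag delays the
# series: y(t) = x(t - lag). Exact for any real lag via Fourier phase ramp.
fourier_shift <- function(x, lag_s, tr_s) {
  n <- length(x)
  f <- fft_freqs(n, tr_s)
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * lag_s), inverse = TRUE)) / n
}

#' Generate one synthetic stroke subject
#'
#' See [synth_params()] for the stated world. Returns the BOLD run, the
#' subject context (masks, tissue probabilities, motion, affected side), the
#' atlas with its region-to-network lookup, and the ground truth needed by
#' downstream recovery tests.
#'
#' @param params a [synth_params()] list.
#' @return A list with elements `bold` ([volume_image]), `ctx`
#'   ([subject_context]), `atlas` ([atlas_spec]), and `truth` (list with
#'   `network_of`, `lesion_voxels` (0-based linear indices), `artifact`,
#'   `lag_field` (seconds, `NA` outside regions), `contaminated_regions`,
#'   `region_signals`, `lesion_regions`).
#' @export
generate_subject <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  d <- as.integer(p$dim); n_t <- as.integer(p$n_t)

  ## geometry ---------------------------------------------------------------
  ctr <- (d - 1) / 2
  rad <- 0.45 * d
  idx <- arrayInd(seq_len(prod(d)), d)
  rho <- sqrt(((idx[, 1] - 1 - ctr[1]) / rad[1])^2 +
              ((idx[, 2] - 1 - ctr[2]) / rad[2])^2 +
              ((idx[, 3] - 1 - ctr[3]) / rad[3])^2)
  brain <- rho <= 1
  if (p$lesion_size_vox > sum(brain))
    stop("lesion larger than the brain mask")
  wm_p <- ifelse(brain, stats::plogis((0.45 - rho) * 80), 0)
  csf_p <- ifelse(brain, stats::plogis((rho - 0.85) * 80), 0)
  gm_p <- ifelse(brain, pmax(0, 1 - wm_p - csf_p), 0)
  aff <- matrix(0, 4, 4)
  aff[1:3, 1:3] <- diag(c(3, 3, 3))             # 3 mm isotropic
  aff[1:3, 4] <- -3 * ctr
  aff[4, 4] <- 1
  world_x <- 3 * (idx[, 1] - 1) - 3 * ctr[1]
  affected <- if (p$affected_side == "left") world_x < 0 else world_x > 0

  ## parcellation -----------------------------------------------------------
  gm_vox <- which(gm_p >= 0.5)
  km <- NULL
  for (try in 1:5) {
    km <- tryCatch(stats::kmeans(idx[gm_vox, , drop = FALSE],
                                 centers = p$n_regions, nstart = 5L,
                                 iter.max = 100L),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == p$n_regions) break
    km <- NULL
  }
  if (is.null(km)) stop("could not build a non-degenerate parcellation")
  labels <- integer(prod(d))
  labels[gm_vox] <- km$cluster
  network_of <- ((seq_len(p$n_regions) - 1L) %% p$n_networks) + 1L

  ## lesion: nearest-voxel ball of exact size, or whole affected regions ----
  cand <- gm_vox[affected[gm_vox] & rho[gm_vox] >= 0.55 & rho[gm_vox] <= 0.8]
  if (!length(cand)) cand <- gm_vox[affected[gm_vox]]
  seed_vox <- cand[sample.int(length(cand), 1L)]
  cdist <- sqrt(rowSums(sweep(idx, 2L, idx[seed_vox, ])^2))
  if (!is.null(p$lesion_covers_regions)) {
    k <- as.integer(p$lesion_covers_regions)
    cent_aff <- which(vapply(seq_len(p$n_regions), function(r) {
      vv <- which(labels == r)
      mean(affected[vv]) > 0.5
    }, logical(1)))
    if (length(cent_aff) < k)
      stop("not enough affected-side regions to cover")
    dseed <- vapply(cent_aff, function(r) min(cdist[labels == r]), numeric(1))
    cover <- cent_aff[order(dseed)][seq_len(k)]
    lesion <- labels %in% cover
    lesion_vox <- which(lesion)
  } else {
    in_brain <- which(brain)
    ord <- in_brain[order(cdist[in_brain], in_brain)]
    lesion_vox <- sort(ord[seq_len(p$lesion_size_vox)])
    lesion <- logical(prod(d)); lesion[lesion_vox] <- TRUE
  }

  ## contaminated regions: farthest centroids from the lesion, preferring
  ## networks the lesion regions do not belong to (remote spurious edges are
  ## between-network)
  cent <- km$centers
  les_c <- colMeans(idx[lesion_vox, , drop = FALSE])
  reg_dist <- sqrt(rowSums(sweep(cent, 2L, les_c)^2))
  les_regions0 <- unique(labels[lesion_vox][labels[lesion_vox] > 0L])
  contaminated <- integer(0)
  if (p$n_contaminated > 0L && p$a_les != 0) {
    pref <- which(!network_of %in% network_of[les_regions0])
    pref <- setdiff(pref, les_regions0)
    ranked <- c(pref[order(reg_dist[pref], decreasing = TRUE)],
                setdiff(order(reg_dist, decreasing = TRUE),
                        c(pref, les_regions0)))
    contaminated <- ranked[seq_len(p$n_contaminated)]
  }

  ## latent signals ---------------------------------------------------------
  g0 <- bandlimited_series(n_t, p$tr_s, 1L)[, 1L]
  g <- bandlimited_series(n_t, p$tr_s, p$n_networks)
  e <- bandlimited_series(n_t, p$tr_s, p$n_regions)
  # Sample-orthogonalize network/region signals against the global signal's
  # whole +/-4 TR shift family: finite-sample cross-correlation between the
  # unique signals and the lag reference would otherwise swamp the small
  # lag-discrimination margins at this T.
  shift_family <- function(x) sapply(-4:4, function(k)
    fourier_shift(x, k * p$tr_s, p$tr_s))
  resid_on <- function(M, D) {
    r <- M - D %*% solve(crossprod(D), crossprod(D, M))
    r <- sweep(r, 2L, colMeans(r))
    sweep(r, 2L, apply(r, 2L, stats::sd), "/")
  }
  G0 <- shift_family(g0)
  for (pass in 1:2) {
    for (nn in seq_len(p$n_networks)) {
      others <- setdiff(seq_len(p$n_networks), nn)
      D <- cbind(G0, do.call(cbind, lapply(others, function(m)
        shift_family(g[, m]))))
      g[, nn] <- resid_on(g[, nn, drop = FALSE], D)
    }
  }
  e <- resid_on(e, cbind(G0, do.call(cbind, lapply(seq_len(p$n_networks),
                                                   function(m) shift_family(g[, m])))))
  physio <- bandlimited_series(n_t, p$tr_s, 1L)[, 1L]
  artifact_basis <- bandlimited_series(n_t, p$tr_s, p$artifact_rank)
  artifact <- artifact_basis[, 1L]
  w0 <- sqrt(p$global_share)
  wn <- sqrt(p$r_within - p$global_share)
  we <- sqrt(1 - p$r_within)
  region_sig <- sapply(seq_len(p$n_regions), function(r)
    w0 * g0 + wn * g[, network_of[r]] + we * e[, r])  # T x R

  ## lag field --------------------------------------------------------------
  lag_region <- rep(0, p$n_regions)
  if (!is.null(p$lag_by_region_trs))
    lag_region <- p$tr_s * p$lag_by_region_trs
  lag_field <- rep(NA_real_, prod(d))
  lag_field[labels > 0L] <- lag_region[labels[labels > 0L]]
  if (p$lag_affected_s != 0) {
    sel <- labels > 0L & affected
    lag_field[sel] <- lag_field[sel] + p$lag_affected_s
  }
  if (max(abs(lag_field), na.rm = TRUE) > 4 * p$tr_s + 1e-9)
    stop("injected lag field exceeds the +/-4 TR search window")

  ## assemble BOLD ----------------------------------------------------------
  # Voxelwise lognormal amplitude heterogeneity: real BOLD amplitude varies
  # across voxels, which makes ICA spatial maps heavy-tailed (without it the
  # dense global/physio maps are bimodal indicators, i.e. sub-Gaussian, and
  # tanh FastICA does not converge -- in sklearn either).
  n_vox <- prod(d)
  amp <- exp(stats::rnorm(n_vox, 0, 0.4))
  noise_amp <- p$noise_sd * amp
  noise_amp[lesion_vox] <- p$noise_sd * 0.25  # dead tissue: attenuated, uniform
  bold <- matrix(0, n_vox, n_t)
  bold[brain, ] <- p$baseline +
    noise_amp[brain] *
      matrix(stats::rnorm(sum(brain) * n_t), sum(brain), n_t)

  neural_vox <- which(labels > 0L & !lesion)
  if (length(neural_vox)) {
    grp <- interaction(labels[neural_vox], lag_field[neural_vox], drop = TRUE)
    for (gk in levels(grp)) {
      vv <- neural_vox[grp == gk]
      r <- labels[vv[1L]]; lg <- lag_field[vv[1L]]
      s <- if (lg == 0) region_sig[, r] else
        fourier_shift(region_sig[, r], lg, p$tr_s)
      bold[vv, ] <- bold[vv, ] + amp[vv] * rep(s, each = length(vv))
    }
  }
  tissue_vox <- which(brain & labels == 0L & !lesion)
  if (length(tissue_vox) && p$physio_amp != 0)
    bold[tissue_vox, ] <- bold[tissue_vox, ] +
      (p$physio_amp * amp[tissue_vox]) * rep(physio, each = length(tissue_vox))
  # voxelwise artifact: unit-norm random mixture of the artifact basis
  # (rank 1 reduces to the single shared course)
  artifact_block <- function(vv) {
    if (p$artifact_rank == 1L)
      return(rep(artifact, each = length(vv)))
    W <- matrix(stats::rnorm(length(vv) * p$artifact_rank),
                length(vv), p$artifact_rank)
    W <- W / sqrt(rowSums(W^2))
    t(artifact_basis %*% t(W))                      # n_vv x T
  }
  if (p$a_les != 0 && p$artifact_in_lesion)
    bold[lesion_vox, ] <- bold[lesion_vox, ] +
      (p$a_les * amp[lesion_vox]) * artifact_block(lesion_vox)
  for (r in contaminated) {
    vv <- which(labels == r & !lesion)
    bold[vv, ] <- bold[vv, ] + (p$a_les * amp[vv]) * artifact_block(vv)
  }

  ## motion -----------------------------------------------------------------
  step <- matrix(stats::rnorm(n_t * 6L), n_t, 6L)
  step[, 1:3] <- step[, 1:3] * p$motion_scale_mm
  step[, 4:6] <- step[, 4:6] * (p$motion_scale_mm / 50)
  spikes <- stats::runif(n_t) < 0.03
  step[spikes, 1L] <- step[spikes, 1L] + 0.3
  motion <- apply(step, 2L, cumsum)
  motion[1L, ] <- 0
  motion <- as.data.frame(motion)
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

  ## package up -------------------------------------------------------------
  vol3 <- function(v) volume_image(array(v, dim = d), affine = aff)
  ctx <- subject_context(
    brain_mask = vol3(as.numeric(brain)),
    gm_prob = vol3(gm_p), wm_prob = vol3(wm_p), csf_prob = vol3(csf_p),
    lesion_mask = vol3(as.numeric(lesion)),
    affected_side = p$affected_side, motion = motion)
  bold_img <- volume_image(array(bold, dim = c(d, n_t)), affine = aff,
                           tr_s = p$tr_s)
  atlas <- atlas_spec(vol3(labels),
                      data.frame(region = seq_len(p$n_regions),
                                 network = paste0("net", network_of)))
  les_regions <- sort(unique(labels[lesion_vox][labels[lesion_vox] > 0L]))
  truth <- list(network_of = network_of, lesion_voxels = lesion_vox - 1L,
                artifact = artifact, artifact_basis = artifact_basis,
                lag_field = array(lag_field, dim = d),
                contaminated_regions = sort(contaminated),
                region_signals = region_sig, physio = physio,
                lesion_regions = les_regions, params = p)
  list(bold = bold_img, ctx = ctx, atlas = atlas, truth = truth)
}

#' Sparse per-region lag field
#'
#' Assigns nonzero lags (in TRs) to `length(values_trs)` randomly chosen
#' regions and 0 elsewhere — a focal perfusion-delay pattern that a global
#' reference can resolve.
#'
#' @param n_regions number of regions.
#' @param values_trs lags (TRs) for the lagged regions.
#' @return numeric vector of length `n_regions` for `lag_by_region_trs`.
#' @export
sparse_lag_field <- function(n_regions, values_trs = c(-2, -1, 1, 2)) {
  stopifnot(length(values_trs) <= n_regions)
  lag <- rep(0, n_regions)
  lag[sample.int(n_regions, length(values_trs))] <- values_trs
  lag
}

#' Generate a cohort of synthetic subjects with varied lesion sizes
#'
#' @param n_subjects number of subjects (>= 1).
#' @param lesion_sizes_vox lesion sizes in voxels, recycled to `n_subjects`;
#'   default spans four size bins.
#' @param base_params [synth_params()] defaults shared by all subjects.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @param dir optional directory: when given, each subject is written with
#'   [write_subject()] and a `manifest.tsv` (subject, seed, lesion size,
#'   affected side) is emitted.
#' @return List of subjects as returned by [generate_subject()]; with `dir`,
#'   the manifest data.frame is attached as attribute `"manifest"`.
#' @export
generate_cohort <- function(n_subjects, lesion_sizes_vox = c(5, 30, 100, 250),
                            base_params = synth_params(), seed = 1L,
                            dir = NULL) {
  stopifnot(n_subjects >= 1L)
  if (!length(lesion_sizes_vox)) stop("empty lesion size range")
  sizes <- rep_len(as.integer(lesion_sizes_vox), n_subjects)
  subjects <- vector("list", n_subjects)
  manifest <- data.frame(subject = sprintf("sub-%02d", seq_len(n_subjects)),
                         seed = as.integer(seed) + seq_len(n_subjects),
                         lesion_size_vox = sizes,
                         affected_side = base_params$affected_side)
  for (i in seq_len(n_subjects)) {
    p <- base_params
    p$seed <- manifest$seed[i]
    p$lesion_size_vox <- sizes[i]
    subjects[[i]] <- generate_subject(p)
    if (!is.null(dir))
      write_subject(subjects[[i]]$bold, subjects[[i]]$ctx,
                    file.path(dir, manifest$subject[i]),
                    atlas = subjects[[i]]$atlas)
  }
  if (!is.null(dir))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  attr(subjects, "manifest") <- manifest
  subjects
}
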