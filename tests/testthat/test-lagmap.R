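test_that("band-pass keeps in-band amplitude and rejects out-of-band", {
  n <- 200; tr <- 2
  t0 <- (seq_len(n) - 1) * tr
  in_band <- sin(2 * pi * 0.05 * t0)               # exact FFT bin
  out_band <- sin(2 * pi * 0.2 * t0)
  fi <- bandpass(in_band, tr_s = tr)
  fo <- bandpass(out_band, tr_s = tr)
  expect_gt(max(abs(fi)) / max(abs(in_band)), 0.95)
  expect_lt(max(abs(fo)) / max(abs(out_band)), 0.1)
  expect_equal(bandpass(rep(3, n), tr_s = tr), rep(0, n), tolerance = 1e-10)
  expect_error(bandpass(in_band, tr_s = tr, high_hz = 0.3), "Nyquist")
})

test_that("gray-matter reference averages GM voxels and excludes the lesion", {
  s <- small_subject(seed = 2)
  filt <- bandpass(s$bold)
  ref <- gm_reference(filt, s$ctx$gm_prob, s$ctx$lesion_mask)
  sel <- s$ctx$gm_prob$data >= 0.5 & !as.logical(s$ctx$lesion_mask$data)
  expect_equal(ref, colMeans(strokefc:::mask_matrix(filt, sel)))
  # lesion-only artifact leaves the reference unchanged
  s0 <- small_subject(seed = 2, a_les = 0, n_contaminated = 0)
  sA <- small_subject(seed = 2, a_les = 5, n_contaminated = 0)
  r0 <- gm_reference(bandpass(s0$bold), s0$ctx$gm_prob, s0$ctx$lesion_mask)
  rA <- gm_reference(bandpass(sA$bold), sA$ctx$gm_prob, sA$ctx$lesion_mask)
  expect_equal(r0, rA, tolerance = 1e-8)
  empty <- s$ctx$lesion_mask; empty$data[] <- 1    # lesion = whole grid
  expect_error(gm_reference(filt, s$ctx$gm_prob, empty), "empty gray-matter")
})

test_that("voxel_lag recovers shifts with the documented conventions", {
  set.seed(6)
  x <- strokefc:::bandlimited_series(150, 2)[, 1]
  expect_equal(voxel_lag(x, x, tr_s = 2)$lag_s, 0)
  expect_equal(voxel_lag(x, x, tr_s = 2)$peak_r, 1, tolerance = 1e-12)
  y <- strokefc:::fourier_shift(x, 4, 2)           # delayed 2 samples
  expect_equal(voxel_lag(y, x, tr_s = 2, subsample = FALSE)$lag_s, 4)
  # half-sample delay, sub-TR grid
  h <- strokefc:::fourier_shift(x, 1, 2)
  expect_lt(abs(voxel_lag(h, x, tr_s = 2)$lag_s - 1), 0.3)
  # zero variance -> NaN
  expect_true(is.nan(voxel_lag(rep(1, 150), x, tr_s = 2)$lag_s))
  expect_error(voxel_lag(x[1:9], x[1:9], tr_s = 2), "too short")
})

test_that("voxel_lag is antisymmetric at integer resolution", {
  set.seed(8)
  x <- strokefc:::bandlimited_series(150, 2)[, 1]
  for (k in c(-3, -1, 2, 4)) {
    y <- strokefc:::fourier_shift(x, k * 2, 2)
    a <- voxel_lag(y, x, tr_s = 2, subsample = FALSE)$lag_s
    b <- voxel_lag(x, y, tr_s = 2, subsample = FALSE)$lag_s
    expect_equal(a, -b)
    expect_equal(a, k * 2)
  }
})

test_that("compute_lagmap recovers a noise-free injected lag field exactly", {
  set.seed(41)
  p <- synth_params(seed = 4, noise_sd = 0, a_les = 0,
                    lag_by_region_trs = sparse_lag_field(20))
  s <- generate_subject(p)
  lm_ <- compute_lagmap(s$bold, s$ctx, subsample = FALSE)
  sel <- is.finite(lm_$lag_s$data) & is.finite(s$truth$lag_field)
  expect_identical(mean(lm_$lag_s$data[sel] == s$truth$lag_field[sel]), 1)
})

test_that("lag map is invariant to affine intensity rescaling", {
  s <- small_subject(seed = 5)
  l1 <- compute_lagmap(s$bold, s$ctx)
  b2 <- s$bold; b2$data <- 3.7 * s$bold$data + 120
  l2 <- compute_lagmap(b2, s$ctx)
  expect_equal(l1$lag_s$data, l2$lag_s$data, tolerance = 1e-8)
  expect_equal(l1$mean_lag_affected_s, l2$mean_lag_affected_s,
               tolerance = 1e-8)
})

test_that("QC gate fires on the affected-hemisphere lag excess", {
  s_hi <- generate_subject(synth_params(seed = 1, lag_affected_s = 1.5))
  l_hi <- compute_lagmap(s_hi$bold, s_hi$ctx)
  expect_true(l_hi$excluded)
  expect_gt(l_hi$affected_lag_excess_s, 1)
  s_lo <- generate_subject(synth_params(seed = 1, lag_affected_s = 0.3))
  l_lo <- compute_lagmap(s_lo$bold, s_lo$ctx)
  expect_false(l_lo$excluded)
  expect_lt(l_lo$affected_lag_excess_s, 1)
})

test_that("lag-map outputs are written with a QC JSON", {
  s <- small_subject(seed = 2)
  lm_ <- compute_lagmap(s$bold, s$ctx)
  dir <- tempfile()
  write_lagmap(lm_, dir)
  qc <- jsonlite::read_json(file.path(dir, "lag_qc.json"))
  expect_identical(qc$excluded, lm_$excluded)
  back <- read_volume(file.path(dir, "lag_s.nii.gz"), na_ok = TRUE)
  expect_equal(back$data, lm_$lag_s$data, tolerance = 1e-5)
})
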