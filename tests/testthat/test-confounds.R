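test_that("expand_regressors produces the 4k derivative/quadratic expansion", {
  out <- expand_regressors(data.frame(a = c(2, 2, 2), b = c(0, 1, 3)))
  expect_identical(names(out),
                   c("a", "b", "a_derivative1", "b_derivative1",
                     "a_power2", "b_power2",
                     "a_derivative1_power2", "b_derivative1_power2"))
  expect_equal(out$a_derivative1, c(0, 0, 0))
  expect_equal(out$a_power2, c(4, 4, 4))
  expect_equal(out$b_derivative1, c(0, 1, 2))       # backward difference
  expect_equal(out$b_derivative1_power2, c(0, 1, 4))
  motion <- as.data.frame(matrix(rnorm(60), 10, 6))
  expect_identical(ncol(expand_regressors(motion)), 24L)
  expect_error(expand_regressors(data.frame(a = 1)), "at least 2")
})

test_that("FD (Power) matches its analytic definition", {
  m <- matrix(0, 5, 6)
  expect_equal(fd_power(m), rep(0, 5))
  m2 <- m; m2[3, 1] <- 0.2                          # one 0.2 mm step in x
  expect_equal(fd_power(m2), c(0, 0, 0.2, 0.2, 0, 0)[1:5])
  m3 <- m; m3[4, 6] <- 0.01                         # 0.01 rad about z
  expect_equal(fd_power(m3)[4], 0.5)                # 0.01 * 50 mm
  expect_error(fd_power(m[, 1:5]), "6 columns")
})

test_that("FD (Jenkinson) matches translation closed form and a quadrature oracle", {
  m <- matrix(0, 4, 6)
  expect_equal(fd_jenkinson(m), rep(0, 4))
  m2 <- m; m2[2, 1] <- 0.3
  expect_equal(fd_jenkinson(m2)[2], 0.3, tolerance = 1e-12)
  # oracle: numerical integration of |(A_rel - I) p|^2 over the solid
  # 50 mm sphere with a degree-2-exact 6-point quadrature
  set.seed(13)
  mr <- matrix(rnorm(24, 0, 0.02), 4, 6)
  fd <- fd_jenkinson(mr)
  R <- 50
  pts <- rbind(diag(3), -diag(3)) * R * sqrt(3 / 5)
  for (t in 2:4) {
    rel <- strokefc:::rigid_affine(mr[t, ]) %*%
      solve(strokefc:::rigid_affine(mr[t - 1, ]))
    disp2 <- apply(pts, 1, function(p) {
      q <- rel %*% c(p, 1)
      sum((q[1:3] - p)^2)
    })
    expect_equal(fd[t], sqrt(mean(disp2)), tolerance = 1e-6)
  }
})

test_that("DVARS follows its RMS-difference definition and standardization", {
  # one-voxel mask, series 0,3,3 -> raw 0,3,0
  bold <- volume_image(array(0, c(2, 2, 1, 3)), tr_s = 2)
  bold$data[1, 1, 1, ] <- c(0, 3, 3)
  mask <- volume_image(array(c(1, 0, 0, 0), c(2, 2, 1)))
  dv <- dvars(bold, mask)
  expect_equal(dv$raw, c(0, 3, 0))
  # temporally constant -> zeros
  cb <- volume_image(array(5, c(2, 2, 1, 4)), tr_s = 2)
  allm <- volume_image(array(1, c(2, 2, 1)))
  expect_equal(dvars(cb, allm)$raw, rep(0, 4))
  # standardized long-run white noise has median 1 over nonzero frames
  set.seed(3)
  wn <- volume_image(array(rnorm(4 * 4 * 2 * 400), c(4, 4, 2, 400)), tr_s = 2)
  wm <- volume_image(array(1, c(4, 4, 2)))
  std <- dvars(wn, wm)$standardized
  expect_equal(stats::median(std[-1]), 1)
  expect_error(dvars(cb, volume_image(array(0, c(2, 2, 1)))), "empty")
})

test_that("motion outliers use strict thresholds", {
  expect_identical(flag_motion_outliers(c(0, 0.6), c(0, 0)), c(FALSE, TRUE))
  expect_identical(flag_motion_outliers(c(0.5, 0.2), c(1.5, 1.2)),
                   c(FALSE, FALSE))                 # at threshold: not flagged
  expect_identical(flag_motion_outliers(c(0, 0), c(0, 1.6)), c(FALSE, TRUE))
  expect_error(flag_motion_outliers(c(0, 1), 0), "lengths differ")
})

test_that("noise masks implement threshold, GM dilation and lesion adjustment", {
  dim3 <- c(5L, 5L, 3L)
  wm <- array(0, dim3); wm[2, 2, 2] <- 1            # lesion voxel, pure WM
  wm[4, 4, 2] <- 1                                  # plain WM voxel
  wm[1, 5, 3] <- 1                                  # WM voxel far from GM
  csf <- array(0, dim3); csf[1, 1, 1] <- 1; csf[5, 5, 3] <- 0.98
  gm <- array(0, dim3); gm[4, 3, 2] <- 1            # adjacent to WM voxel
  lin <- function(i, j, k) i + (j - 1L) * 5L + (k - 1L) * 25L
  ctx <- manual_ctx(csf = csf, wm = wm, gm = gm, lesion_idx = lin(2, 2, 2))
  std <- make_noise_masks(ctx, "standard")
  adj <- make_noise_masks(ctx, "lesion_adjusted")
  # lesion voxel with wm_prob 1: WM under standard, CSF under lesion_adjusted
  expect_equal(std$wm_mask$data[2, 2, 2], 1)
  expect_equal(adj$wm_mask$data[2, 2, 2], 0)
  expect_equal(adj$csf_mask$data[2, 2, 2], 1)
  # 0.98 < 0.99 threshold
  expect_equal(std$csf_mask$data[5, 5, 3], 0)
  # GM dilation (1 voxel, 6-connectivity) excludes the adjacent WM voxel
  expect_equal(std$wm_mask$data[4, 4, 2], 0)
  # combined = union
  expect_equal(std$combined_mask$data,
               pmax(std$csf_mask$data, std$wm_mask$data))
  # empty mask errors with advice
  ctx0 <- manual_ctx(csf = csf * 0.5, wm = wm)
  expect_error(make_noise_masks(ctx0, "standard"), "prob_thresh")
})

test_that("lesion-adjusted and standard masks differ only around the lesion", {
  s <- small_subject(seed = 2)
  std <- make_noise_masks(s$ctx, "standard")
  adj <- make_noise_masks(s$ctx, "lesion_adjusted")
  diff_vox <- which(std$combined_mask$data != adj$combined_mask$data)
  les <- which(s$ctx$lesion_mask$data == 1)
  gm_near <- which(strokefc:::dilate6(s$ctx$lesion_mask$data == 1, 2L))
  expect_true(all(diff_vox %in% union(les, gm_near)))
})

test_that("mean signals are voxel means with the lesion-split identity", {
  s <- small_subject(seed = 2)
  masks <- make_noise_masks(s$ctx, "lesion_adjusted")
  sig <- mean_signals(s$bold, s$ctx, masks, lesion_aware = TRUE)
  expect_named(sig, c("global_signal", "csf", "wm", "lesion_signal",
                      "global_signal_excl_lesion"))
  n_les <- sum(s$ctx$lesion_mask$data)
  n_brain <- sum(s$ctx$brain_mask$data)
  recon <- (sig$global_signal_excl_lesion * (n_brain - n_les) +
              sig$lesion_signal * n_les) / n_brain
  expect_equal(sig$global_signal, recon, tolerance = 1e-10)
  # uniform image -> every column constant
  ub <- s$bold; ub$data[] <- 7
  usig <- mean_signals(ub, s$ctx, masks)
  expect_true(all(abs(as.matrix(usig) - 7) < 1e-12))
})

test_that("cosine drift basis has the standard count and orthonormal columns", {
  b <- cosine_drift(150, 2)                         # 300 s / 128 s cutoff
  expect_identical(ncol(b), 4L)
  expect_equal(unname(crossprod(b)), diag(4), tolerance = 1e-10)
  expect_warning(b0 <- cosine_drift(50, 2), "cutoff")   # 100 s < 128 s
  expect_identical(ncol(b0), 0L)
})

test_that("aCompCor retains components to 50% variance, matching an SVD oracle", {
  mask <- volume_image(array(1, c(4, 5, 1)))
  # rank-1 construction: shared course + tiny noise -> k = 1, |r| > 0.99
  set.seed(21)
  course <- rnorm(100)
  Y <- outer(course, runif(20, 0.5, 2)) + matrix(rnorm(2000, 0, 0.01), 100)
  bold <- volume_image(array(t(Y), c(4, 5, 1, 100)), tr_s = 2)
  cc <- acompcor(bold, mask)
  expect_identical(attr(cc, "k"), 1L)
  expect_gt(abs(stats::cor(cc[, 1], course)), 0.99)
  # k matches a direct filtered-SVD cumulative-variance oracle
  for (i in 1:10) {
    set.seed(100 + i)
    Yr <- matrix(rnorm(100 * 20), 100, 20)
    br <- volume_image(array(t(Yr), c(4, 5, 1, 100)), tr_s = 2)
    got <- attr(acompcor(br, mask), "k")
    dct <- cbind(1, cosine_drift(100, 2))
    R <- stats::lm.fit(dct, Yr)$residuals
    R <- scale(R, center = FALSE, scale = apply(R, 2, stats::sd))
    d2 <- svd(R)$d^2
    expect_identical(got, which(cumsum(d2) / sum(d2) >= 0.5)[1])
  }
  # linear drift is removed by the cosine high-pass
  drift <- seq(0, 1, length.out = 100)
  Yd <- outer(drift, rep(1, 20)) + matrix(rnorm(2000, 0, 0.5), 100)
  bd <- volume_image(array(t(Yd), c(4, 5, 1, 100)), tr_s = 2)
  ccd <- acompcor(bd, mask)
  expect_lt(max(abs(stats::cor(ccd, drift))), 0.1)
  # degenerate input errors
  cb <- volume_image(array(1, c(4, 5, 1, 100)), tr_s = 2)
  expect_error(acompcor(cb, mask), "constant")
})

test_that("aCompCor is invariant to voxel order and global rescaling", {
  set.seed(31)
  Y <- matrix(rnorm(80 * 30), 80, 30)
  mask <- volume_image(array(1, c(5, 6, 1)))
  b1 <- volume_image(array(t(Y), c(5, 6, 1, 80)), tr_s = 2)
  cc1 <- acompcor(b1, mask)
  perm <- sample(30)
  b2 <- volume_image(array(t(Y[, perm]), c(5, 6, 1, 80)), tr_s = 2)
  cc2 <- acompcor(b2, mask)
  b3 <- b1; b3$data <- b1$data * 42
  cc3 <- acompcor(b3, mask)
  expect_identical(attr(cc1, "k"), attr(cc2, "k"))
  for (j in seq_len(attr(cc1, "k"))) {
    expect_gt(abs(stats::cor(cc1[, j], cc2[, j])), 1 - 1e-6)
    expect_gt(abs(stats::cor(cc1[, j], cc3[, j])), 1 - 1e-6)
  }
})

test_that("FD and DVARS are jointly zero on motionless constant data", {
  bold <- volume_image(array(3, c(3, 3, 2, 10)), tr_s = 2)
  mask <- volume_image(array(1, c(3, 3, 2)))
  motion <- matrix(0, 10, 6)
  expect_equal(fd_power(motion), rep(0, 10))
  expect_equal(fd_jenkinson(motion), rep(0, 10))
  expect_equal(dvars(bold, mask)$raw, rep(0, 10))
})
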