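test_that("ROI extraction is the unweighted in-region mean", {
  # single-voxel regions return those voxels' series
  d <- c(3L, 2L, 1L)
  lab <- array(0L, d); lab[1, 1, 1] <- 1L; lab[3, 2, 1] <- 2L
  atlas <- atlas_spec(volume_image(lab),
                      data.frame(region = 1:2, network = c("a", "b")))
  arr <- array(rnorm(prod(d) * 10), c(d, 10))
  bold <- volume_image(arr, tr_s = 2)
  rs <- extract_roi_series(bold, atlas)
  expect_equal(rs[, "1"], arr[1, 1, 1, ])
  expect_equal(rs[, "2"], arr[3, 2, 1, ])
  # uniform image -> constant columns
  bu <- bold; bu$data[] <- 4.2
  expect_true(all(abs(extract_roi_series(bu, atlas) - 4.2) < 1e-12))
})

test_that("region means equal the voxel-count weighted split identity", {
  s <- small_subject(seed = 3)
  rs <- extract_roi_series(s$bold, s$atlas)
  lab <- as.integer(round(s$atlas$labels$data))
  d <- dim(s$bold$data)
  mat <- matrix(s$bold$data, prod(d[1:3]), d[4])
  r <- s$atlas$region_ids[1]
  vox <- which(lab == r)
  half <- vox[seq_len(floor(length(vox) / 2))]
  rest <- setdiff(vox, half)
  recon <- (colMeans(mat[half, , drop = FALSE]) * length(half) +
              colMeans(mat[rest, , drop = FALSE]) * length(rest)) /
    length(vox)
  expect_equal(rs[, as.character(r)], recon, tolerance = 1e-12)
})

test_that("empty and out-of-brain regions are handled per contract", {
  d <- c(3L, 2L, 1L)
  lab <- array(0L, d); lab[1, 1, 1] <- 1L
  atlas <- atlas_spec(volume_image(lab),
                      data.frame(region = 1, network = "a"))
  bold <- volume_image(array(rnorm(prod(d) * 5), c(d, 5)), tr_s = 2)
  expect_error(atlas_spec(volume_image(lab), data.frame(region = 2, network = "a")),
               "without a network")
  mask0 <- volume_image(array(0, d))
  expect_warning(expect_error(extract_roi_series(bold, atlas, mask0)),
                 "outside brain")
})

test_that("Ledoit-Wolf correlation is consistent with sample Pearson at large T", {
  set.seed(55)
  # independent noise: both estimators give near-zero off-diagonals (on
  # such data the identity target is the truth, so LW shrinks fully)
  X0 <- matrix(rnorm(10000 * 5), 10000, 5)
  lw0 <- fc_matrix(X0)
  expect_lt(max(abs(lw0$mat[upper.tri(lw0$mat)])), 0.05)
  expect_lte(lw0$shrinkage, 1)
  # correlated series: shrinkage is small and LW tracks sample Pearson
  F1 <- rnorm(10000)
  X <- 0.7 * cbind(F1, F1, F1, -F1, F1) + matrix(rnorm(10000 * 5), 10000, 5)
  lw <- fc_matrix(X)
  sp <- fc_matrix(X, estimator = "sample")
  expect_lt(max(abs(lw$mat - sp$mat)), 0.01)
  expect_identical(lw$estimator, "ledoit_wolf")
  expect_equal(diag(lw$mat), rep(1, 5), ignore_attr = TRUE)
  expect_identical(lw$mat, t(lw$mat))
})

test_that("duplicated columns match the closed-form shrinkage oracle", {
  set.seed(56)
  x <- rnorm(400)
  X <- cbind(x, x, rnorm(400), rnorm(400), rnorm(400))
  colnames(X) <- as.character(1:5)
  lw <- fc_matrix(X)
  expect_gt(lw$mat[1, 2], 0.9)
  # independent arithmetic oracle (explicit sums) for the 2-column case
  Z <- scale(cbind(x, x))
  n <- nrow(Z); p <- 2
  Zc <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Zc) / n
  mu <- (S[1, 1] + S[2, 2]) / p
  delta2 <- sum((S - diag(mu, p))^2) / p
  beta_sum <- 0
  for (t in seq_len(n)) {
    M <- tcrossprod(Zc[t, ])
    beta_sum <- beta_sum + sum((M - S)^2)
  }
  beta2 <- beta_sum / (n^2 * p)
  shr <- min(beta2, delta2) / delta2
  Sig <- shr * diag(mu, p) + (1 - shr) * S
  oracle_r <- Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2])
  lw2 <- fc_matrix(cbind(a = x, b = x))
  expect_equal(lw2$mat[1, 2], oracle_r, tolerance = 1e-6)
})

test_that("fc_matrix rejects degenerate input and names offenders", {
  X <- cbind(a = rnorm(50), b = rep(1, 50))
  expect_error(fc_matrix(X), "b")
  expect_error(fc_matrix(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("connectivity is invariant to per-region affine rescaling", {
  s <- small_subject(seed = 6)
  rs <- extract_roi_series(s$bold, s$atlas)
  fc1 <- fc_matrix(rs)
  rs2 <- sweep(sweep(rs, 2, runif(ncol(rs), 0.5, 3), "*"), 2,
               rnorm(ncol(rs), 100), "+")
  attr(rs2, "atlas") <- attr(rs, "atlas")
  fc2 <- fc_matrix(rs2)
  expect_equal(fc1$mat, fc2$mat, tolerance = 1e-10)
})

test_that("within-network correlation exceeds between-network across seeds", {
  margins <- vapply(1:20, function(sd) {
    s <- small_subject(seed = sd, a_les = 0)
    C <- fc_matrix(extract_roi_series(s$bold, s$atlas))$mat
    net <- s$truth$network_of
    same <- outer(net, net, "==") & upper.tri(C)
    mean(C[same]) - mean(C[!same & upper.tri(C)])
  }, numeric(1))
  expect_gt(min(margins), 0.05)
  expect_gt(mean(margins), 0.1)
})

test_that("seed-to-voxel maps are Pearson correlations against the seed mean", {
  d <- c(4L, 3L, 2L)
  set.seed(77)
  arr <- array(rnorm(prod(d) * 60, 0, 0.01), c(d, 60))
  shared <- rnorm(60)
  arr[1, 1, 1, ] <- shared + rnorm(60, 0, 0.01)
  arr[2, 1, 1, ] <- shared + rnorm(60, 0, 0.01)
  bold <- volume_image(arr, tr_s = 2)
  seed_m <- volume_image(array(0, d)); seed_m$data[1:2, 1, 1] <- 1
  brain <- volume_image(array(1, d))
  rmap <- seed_to_voxel(bold, seed_m, brain)
  expect_gt(rmap$data[1, 1, 1], 0.99)              # homogeneous seed voxel
  expect_lt(abs(rmap$data[4, 3, 2]), 3 / sqrt(60)) # independent voxel
  vals <- rmap$data[is.finite(rmap$data)]
  expect_true(all(vals >= -1 & vals <= 1))
  empty <- volume_image(array(0, d))
  expect_error(seed_to_voxel(bold, empty, brain), "empty seed")
})

test_that("connectivity TSV and NPY exports are readable", {
  s <- small_subject(seed = 2)
  fcm <- fc_matrix(extract_roi_series(s$bold, s$atlas))
  tsv <- tempfile(fileext = ".tsv"); npy <- tempfile(fileext = ".npy")
  write_fc(fcm, tsv, npy_path = npy)
  back <- as.matrix(utils::read.delim(tsv, check.names = FALSE))
  expect_equal(unname(back), unname(fcm$mat), tolerance = 1e-12)
  expect_identical(readBin(npy, "raw", 6)[2:6], charToRaw("NUMPY"))
})
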