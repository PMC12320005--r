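test_that("lesion overlap fractions count voxels per region", {
  d <- c(4L, 2L, 1L)
  lab <- array(0L, d); lab[1:2, 1, 1] <- 1L; lab[3:4, 1, 1] <- 2L
  lab[1:4, 2, 1] <- 3L
  atlas <- atlas_spec(volume_image(lab),
                      data.frame(region = 1:3, network = c("a", "b", "a")))
  les <- volume_image(array(0, d)); les$data[3:4, 1, 1] <- 1  # covers region 2
  ov <- lesion_overlap_regions(atlas, les)
  expect_identical(ov$region, 2L)
  expect_equal(ov$overlap_frac, 1)
  les2 <- volume_image(array(0, d)); les2$data[1, 1, 1] <- 1  # half of region 1
  ov2 <- lesion_overlap_regions(atlas, les2)
  expect_equal(ov2$overlap_frac[ov2$region == 1], 0.5)
  none <- volume_image(array(0, d))
  expect_warning(ov0 <- lesion_overlap_regions(atlas, none), "empty lesion")
  expect_identical(nrow(ov0), 0L)
  # min_overlap_frac is a strict bound
  ov3 <- lesion_overlap_regions(atlas, les2, min_overlap_frac = 0.5)
  expect_identical(nrow(ov3), 0L)
})

test_that("mean strength sums signed edges of lesion regions", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- 0.5; M[1, 3] <- -0.2; M[1, 4] <- 0.3
  M <- M + t(M); diag(M) <- 1
  dimnames(M) <- list(as.character(1:4), as.character(1:4))
  expect_equal(mean_strength(M, 1, "positive"), 0.8)
  expect_equal(mean_strength(M, 1, "negative"), -0.2)
  # zero matrix -> both zero
  Z <- diag(4); dimnames(Z) <- dimnames(M)
  expect_equal(mean_strength(Z, 1:2, "positive"), 0)
  expect_equal(mean_strength(Z, 1:2, "negative"), 0)
  # mean over two lesion regions
  M2 <- diag(4)
  M2[1, 2] <- M2[2, 1] <- 0.8
  M2[3, 2] <- M2[2, 3] <- 0.4
  dimnames(M2) <- dimnames(M)
  expect_equal(mean_strength(M2, c(1, 3), "positive"), 0.6)
  expect_warning(expect_true(is.nan(mean_strength(M, integer(0), "positive"))),
                 "no lesion regions")
})

test_that("positive and negative strengths obey the conservation identity", {
  for (sd in 1:5) {
    fc <- random_fc(12, sd)
    les <- c(2, 5)
    pos <- mean_strength(fc, les, "positive")
    neg <- mean_strength(fc, les, "negative")
    total <- mean(vapply(les, function(i) sum(fc$mat[i, -i]), numeric(1)))
    expect_equal(pos + neg, total, tolerance = 1e-12)
  }
})

test_that("FCC matches the brute-force rank-sum oracle", {
  for (sd in 1:50) {
    fc <- random_fc(20, sd)
    same <- outer(fc$networks, fc$networks, "==")
    ut <- upper.tri(fc$mat)
    z_oracle <- bf_ranksum_z(fc$mat[ut & same], fc$mat[ut & !same])
    expect_lt(abs(fcc(fc) - z_oracle), 1e-10)
  }
})

test_that("FCC equals the closed-form Z under complete separation", {
  R <- 12
  networks <- rep(c("a", "b", "c"), each = 4)
  same <- outer(networks, networks, "==")
  M <- matrix(0.1, R, R)
  M[same] <- 0.8
  diag(M) <- 1
  dimnames(M) <- list(as.character(1:R), as.character(1:R))
  fc <- structure(list(mat = M, region_ids = as.character(1:R),
                       networks = networks, estimator = "sample",
                       shrinkage = NA_real_), class = "connectivity_matrix")
  ut <- upper.tri(M)
  n1 <- sum(ut & same); n2 <- sum(ut & !same); n <- n1 + n2
  tie_term <- (n1^3 - n1 + n2^3 - n2) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z_max <- (n1 * n2 / 2 - 0.5) / sqrt(v)
  expect_equal(fcc(fc), z_max, tolerance = 1e-12)
})

test_that("FCC is invariant under strictly monotone edge transforms", {
  fc <- random_fc(16, 3)
  z1 <- fcc(fc)
  fc2 <- fc
  fc2$mat <- tanh(2 * fc$mat + 0.3)    # strictly monotone
  diag(fc2$mat) <- 1
  expect_equal(fcc(fc2), z1, tolerance = 1e-10)
  expect_error(fcc(random_fc(6, 1, networks = rep("a", 6))), "two networks")
})

test_that("modularity Q matches closed forms and is deterministic", {
  # two disconnected equal-weight 4-cliques: Q = 0.5
  M <- matrix(0, 8, 8)
  M[1:4, 1:4] <- 1; M[5:8, 5:8] <- 1
  diag(M) <- 0
  q <- modularity_q(M, seed = 1)
  expect_equal(as.numeric(q), 0.5, tolerance = 1e-12)
  # complete uniform graph has no structure
  K <- matrix(1, 8, 8); diag(K) <- 0
  expect_lt(abs(as.numeric(modularity_q(K, seed = 1))), 0.05)
  # deterministic given seed
  fc <- random_fc(15, 9)
  expect_identical(as.numeric(modularity_q(fc, seed = 4)),
                   as.numeric(modularity_q(fc, seed = 4)))
  # all-nonpositive -> 0 with warning
  N <- -abs(random_fc(6, 2)$mat); diag(N) <- 0
  expect_warning(q0 <- modularity_q(N, seed = 1), "no positive")
  expect_identical(q0, 0)
})

test_that("compare_pipelines tabulates and orders reports", {
  mk <- function(pipe, pos, subject = "s1") {
    structure(list(subject = subject, pipeline = pipe,
                   lesion_regions = data.frame(),
                   positive_mean_strength = pos,
                   negative_mean_strength = -0.1,
                   fcc_z = 2, q_value = 0.4, n_regions = 8, n_networks = 2),
              class = "metrics_report")
  }
  out <- compare_pipelines(list(mk("A", 3), mk("B", 2), mk("C", 1)))
  expect_identical(nrow(out$table), 12L)           # 3 reports x 4 metrics
  expect_identical(out$ordering$positive_mean_strength, c("A", "B", "C"))
  expect_identical(compare_pipelines(list(mk("A", 2), mk("B", 2)))$ordering$q_value,
                   "tie")
  # missing metric becomes an NA cell without crashing
  r <- mk("A", 1); r$q_value <- NULL
  out2 <- compare_pipelines(list(r, mk("B", 2)))
  expect_true(any(is.na(out2$table$value)))
  bad <- mk("B", 2); bad$n_regions <- 99
  expect_error(compare_pipelines(list(mk("A", 1), bad)), "different atlases")
})

test_that("metrics_report bundles all statistics for a subject", {
  s <- small_subject(seed = 2)
  fcm <- fc_matrix(extract_roi_series(s$bold, s$atlas))
  rep <- metrics_report(fcm, s$atlas, s$ctx$lesion_mask, pipeline = "raw")
  expect_gte(rep$positive_mean_strength, 0)
  expect_lte(rep$negative_mean_strength, 0)
  expect_true(is.finite(rep$fcc_z))
  expect_true(rep$q_value >= 0 && rep$q_value <= 1)
  expect_identical(rep$n_networks, 2L)
})
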