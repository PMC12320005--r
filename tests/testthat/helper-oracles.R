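# independent brute-force rank-sum oracle: pairwise counting route
bf_ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  U <- 0
  for (xi in x) U <- U + sum(xi > y) + 0.5 * sum(xi == y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(0)
  (U - mu - 0.5 * sign(U - mu)) / sqrt(v)
}

random_fc <- function(R, seed, networks = NULL) {
  set.seed(seed)
  M <- matrix(rnorm(R * R, 0, 0.3), R, R)
  M <- (M + t(M)) / 2; diag(M) <- 1
  M[M > 1] <- 1; M[M < -1] <- -1
  dimnames(M) <- list(as.character(1:R), as.character(1:R))
  if (is.null(networks)) networks <- rep(c("a", "b", "c", "d"), length.out = R)
  structure(list(mat = M, region_ids = as.character(1:R),
                 networks = networks, estimator = "sample",
                 shrinkage = NA_real_), class = "connectivity_matrix")
}
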