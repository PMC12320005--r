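# Pipeline-evaluation statistics: lesion-region mean strength (positive /
# negative), functional connectivity contrast (rank-sum Z of within- vs
# between-network edges), and Louvain modularity Q.

#' Regions overlapping the lesion
#'
#' For each atlas region computes `|region & lesion| / |region|` and returns
#' regions whose fraction strictly exceeds `min_overlap_frac` (default 0, so
#' any overlap qualifies). An empty lesion yields an empty result with a
#' warning.
#'
#' @param atlas an [atlas_spec].
#' @param lesion_mask binary [volume_image] on the atlas grid.
#' @param min_overlap_frac strict lower bound on the overlap fraction.
#' @return data.frame with `region`, `overlap_frac`, `n_voxels`.
#' @export
lesion_overlap_regions <- function(atlas, lesion_mask, min_overlap_frac = 0) {
  assert_same_grid(atlas = atlas$labels, lesion = lesion_mask)
  lab <- as.integer(round(atlas$labels$data))
  les <- as.logical(lesion_mask$data)
  if (!any(les)) {
    warning("empty lesion mask: no overlapping regions", call. = FALSE)
    return(data.frame(region = integer(0), overlap_frac = numeric(0),
                      n_voxels = integer(0)))
  }
  ids <- atlas$region_ids
  n_in <- vapply(ids, function(r) sum(lab == r & les), integer(1))
  n_tot <- vapply(ids, function(r) sum(lab == r), integer(1))
  frac <- n_in / n_tot
  keep <- frac > min_overlap_frac
  data.frame(region = ids[keep], overlap_frac = frac[keep],
             n_voxels = n_tot[keep])
}

#' Mean connectivity strength of lesion regions
#'
#' Strength of a region is the sum of its edges to all other regions,
#' restricted to positive (or negative) correlation values; the statistic is
#' the mean strength over the lesion-overlapping regions. The negative
#' variant is reported as a signed number (<= 0).
#'
#' @param fc a `connectivity_matrix` (or plain symmetric matrix).
#' @param lesion_regions region ids (matching `fc` row names / indices).
#' @param sign `"positive"` or `"negative"`.
#' @return scalar; `NaN` with a warning when `lesion_regions` is empty.
#' @export
mean_strength <- function(fc, lesion_regions, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  M <- if (inherits(fc, "connectivity_matrix")) fc$mat else as.matrix(fc)
  if (!length(lesion_regions)) {
    warning("no lesion regions: mean strength undefined", call. = FALSE)
    return(NaN)
  }
  idx <- if (!is.null(rownames(M))) match(as.character(lesion_regions),
                                          rownames(M))
         else as.integer(lesion_regions)
  if (anyNA(idx)) stop("lesion region id(s) not present in the matrix")
  vals <- vapply(idx, function(i) {
    row <- M[i, -i]
    if (sign == "positive") sum(row[row > 0]) else sum(row[row < 0])
  }, numeric(1))
  mean(vals)
}

# Tie-corrected normal-approximation two-sample rank-sum Z with continuity
# correction, signed positive when `x` is stochastically larger than `y`.
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(0)
  cc <- 0.5 * sign(W - mu)
  (W - mu - cc) / sqrt(v)
}

#' Functional connectivity contrast (FCC)
#'
#' Splits the upper-triangle edges into within-network (endpoints share a
#' network) and between-network sets and returns the Wilcoxon rank-sum
#' Z-statistic (normal approximation, tie and continuity corrected), signed
#' so that stochastically larger within-network edges give positive values.
#'
#' @param fc a `connectivity_matrix` with network labels (or a plain matrix
#'   plus `networks`).
#' @param networks character vector of per-region network labels (taken
#'   from `fc` when omitted).
#' @param exclude_regions optional region ids (e.g. lesion regions) whose
#'   edges are excluded.
#' @return scalar Z.
#' @export
fcc <- function(fc, networks = NULL, exclude_regions = NULL) {
  M <- if (inherits(fc, "connectivity_matrix")) fc$mat else as.matrix(fc)
  if (is.null(networks) && inherits(fc, "connectivity_matrix"))
    networks <- fc$networks
  if (is.null(networks)) stop("network labels required")
  if (length(networks) != nrow(M)) stop("one network label per region required")
  keep <- rep(TRUE, nrow(M))
  if (!is.null(exclude_regions)) {
    ids <- if (!is.null(rownames(M))) rownames(M) else seq_len(nrow(M))
    keep <- !(ids %in% as.character(exclude_regions))
    M <- M[keep, keep, drop = FALSE]
    networks <- networks[keep]
  }
  if (length(unique(networks)) < 2L)
    stop("need at least two networks")
  ut <- upper.tri(M)
  same <- outer(networks, networks, "==")
  wne <- M[ut & same]
  bne <- M[ut & !same]
  if (!length(wne) || !length(bne))
    stop("within- or between-network edge set is empty")
  ranksum_z(wne, bne)
}

#' Modularity Q of the positive connectivity graph
#'
#' Zeroes negative edges and the diagonal, runs Louvain community detection
#' with `n_restarts` seeded restarts, and returns the best Newman weighted
#' modularity. An all-nonpositive matrix yields `Q = 0` with a warning.
#'
#' @param fc a `connectivity_matrix` or plain symmetric matrix.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed; restarts use seeds derived from it, so the
#'   result is deterministic.
#' @param n_restarts Louvain restarts (default 10).
#' @return scalar Q with the best partition attached as attribute
#'   `"membership"`.
#' @export
modularity_q <- function(fc, gamma = 1.0, seed = 1L, n_restarts = 10L) {
  M <- if (inherits(fc, "connectivity_matrix")) fc$mat else as.matrix(fc)
  if (nrow(M) < 2L) stop("need at least 2 regions")
  W <- (M + t(M)) / 2
  diag(W) <- 0
  W[W < 0] <- 0
  if (all(W == 0)) {
    warning("no positive edges: Q = 0", call. = FALSE)
    return(0)
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf; best_mem <- NULL
  for (i in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + i - 1L)
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight,
                            resolution = gamma)
    if (q > best_q) { best_q <- q; best_mem <- igraph::membership(cl) }
  }
  structure(best_q, membership = best_mem)
}

#' Full metrics report for one subject x pipeline
#'
#' @param fc a `connectivity_matrix`.
#' @param atlas the [atlas_spec] the matrix was computed on.
#' @param lesion_mask binary [volume_image].
#' @param pipeline pipeline name for bookkeeping.
#' @param subject subject id.
#' @param min_overlap_frac forwarded to [lesion_overlap_regions()].
#' @param q_seed seed for [modularity_q()].
#' @return Object of class `metrics_report` (list of the metric values and
#'   context).
#' @export
metrics_report <- function(fc, atlas, lesion_mask, pipeline = "unknown",
                           subject = "sub-01", min_overlap_frac = 0,
                           q_seed = 1L) {
  ov <- lesion_overlap_regions(atlas, lesion_mask, min_overlap_frac)
  les <- ov$region[ov$region %in% as.integer(fc$region_ids)]
  pos <- if (length(les)) mean_strength(fc, les, "positive") else NaN
  neg <- if (length(les)) mean_strength(fc, les, "negative") else NaN
  structure(list(subject = subject, pipeline = pipeline,
                 lesion_regions = ov,
                 positive_mean_strength = pos,
                 negative_mean_strength = neg,
                 fcc_z = fcc(fc),
                 q_value = as.numeric(modularity_q(fc, seed = q_seed)),
                 n_regions = nrow(fc$mat),
                 n_networks = length(unique(fc$networks))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s / %s: pos %.3f, neg %.3f, FCC %.2f, Q %.3f\n",
    x$subject, x$pipeline, x$positive_mean_strength,
    x$negative_mean_strength, x$fcc_z, x$q_value))
  invisible(x)
}

#' Tabulate and order pipelines across metrics reports
#'
#' @param reports list of `metrics_report`s (any subjects/pipelines; all
#'   must share the atlas size).
#' @return list with `table` (long data.frame: subject, pipeline, metric,
#'   value) and `ordering` (per metric, pipelines sorted by decreasing mean
#'   value, or `"tie"`).
#' @export
compare_pipelines <- function(reports) {
  stopifnot(length(reports) >= 1L)
  nr <- unique(vapply(reports, function(r) r$n_regions, numeric(1)))
  if (length(nr) != 1L) stop("reports use different atlases")
  metrics <- c("positive_mean_strength", "negative_mean_strength",
               "fcc_z", "q_value")
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject = r$subject, pipeline = r$pipeline, metric = metrics,
               value = vapply(metrics, function(m)
                 if (is.null(r[[m]])) NA_real_ else r[[m]], numeric(1)))
  }))
  ordering <- lapply(metrics, function(m) {
    sub <- rows[rows$metric == m & is.finite(rows$value), ]
    if (!nrow(sub)) return("n/a")
    mu <- tapply(sub$value, sub$pipeline, mean)
    if (length(unique(round(mu, 12))) == 1L) return("tie")
    names(sort(mu, decreasing = TRUE))
  })
  names(ordering) <- metrics
  list(table = rows, ordering = ordering)
}
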