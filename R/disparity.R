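#' Post-ordination disparity metrics
#'
#' Computes one of the morphospace metrics on the ordinated coordinates of a
#' group of taxa:
#' \itemize{
#'   \item `SoV` -- sum over axes of the sample variance (n-1 denominator);
#'     a size-and-density metric.
#'   \item `SoR` -- sum over axes of the range (max - min); a size metric.
#'   \item `displacement` -- mean over group members of
#'     `||x - c_ref|| / ||x - c_group||`, a position metric; equals 1 when
#'     the reference is the group's own centroid.
#' }
#'
#' @param coords numeric matrix (taxa x axes), already restricted to the
#'   retained axes; rownames are taxon names.
#' @param group taxon names, at least 2.
#' @param metric `"SoV"`, `"SoR"` or `"displacement"`.
#' @param reference for displacement: `"own-centroid"` (ratio 1 by
#'   definition), `"global-centroid"` (centroid of all rows of `coords`),
#'   or `"given"` with `reference_centroid` supplied (used for
#'   previous-time-bin references).
#' @param reference_centroid numeric vector of length `ncol(coords)`.
#' @param summary `"mean"` (default) or `"median"` of the per-taxon
#'   displacement ratios.
#' @return a single numeric value.
#' @export
metric_value <- function(coords, group = rownames(coords),
                         metric = c("SoV", "SoR", "displacement"),
                         reference = c("global-centroid", "own-centroid",
                                       "given"),
                         reference_centroid = NULL,
                         summary = c("mean", "median")) {
  metric <- match.arg(metric)
  summary <- match.arg(summary)
  missing_taxa <- setdiff(group, rownames(coords))
  if (length(missing_taxa)) stop("taxa not in coords: ",
                                 paste(missing_taxa, collapse = ", "))
  X <- coords[group, , drop = FALSE]
  if (nrow(X) < 2) stop("group must have >= 2 taxa")
  if (metric == "SoV") return(sum(apply(X, 2, stats::var)))
  if (metric == "SoR") return(sum(apply(X, 2, max) - apply(X, 2, min)))
  reference <- match.arg(reference)
  cg <- colMeans(X)
  cref <- switch(reference,
                 "own-centroid" = cg,
                 "global-centroid" = colMeans(coords),
                 "given" = {
                   if (is.null(reference_centroid)) {
                     stop("reference_centroid required for reference='given'")
                   }
                   reference_centroid
                 })
  d_ref <- sqrt(rowSums(sweep(X, 2, cref)^2))
  d_own <- sqrt(rowSums(sweep(X, 2, cg)^2))
  zero <- d_own == 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " member(s) at the group centroid (undefined ratio)")
    if (all(zero)) stop("all members at the group centroid")
    d_ref <- d_ref[!zero]; d_own <- d_own[!zero]
  }
  if (summary == "mean") mean(d_ref / d_own) else stats::median(d_ref / d_own)
}

#' Bootstrap confidence interval for a disparity metric
#'
#' Resamples the group with replacement (at the group size, or at
#' `rarefy_to` for rarefied intervals), recomputes the metric per replicate
#' and returns a percentile interval: two-tailed 2.5/97.5 for WMPD, SoV and
#' displacement; for SoR -- whose subsample values can never exceed the
#' full-sample range -- a one-tailed 5th-percentile lower bound with the
#' upper bound pinned to the point estimate. The point estimate is always
#' computed from the full, unresampled group. WMPD resamples taxa of the
#' distance matrix; the post-ordination metrics resample rows of the
#' ordinated coordinates.
#'
#' @param obj a coordinate matrix (for `SoV`/`SoR`/`displacement`) or an
#'   [mord_matrix()] result (for `WMPD`).
#' @param group taxon names, >= 2 members.
#' @param metric one of `"WMPD"`, `"SoV"`, `"SoR"`, `"displacement"`.
#' @param n_boot odd number of bootstrap replicates (default 9999).
#' @param rarefy_to optional resample size (<= group size), e.g. the
#'   smallest group among the compared bins.
#' @param seed integer seed (default 1234).
#' @param conf confidence level (default 0.95).
#' @param ... passed to [metric_value()] (reference, reference_centroid,
#'   summary).
#' @return a list of class `disparity_estimate`: `group_label`, `metric`,
#'   `value`, `ci_lower`, `ci_upper`, `n_taxa`, `n_boot`, `rarefied_to`,
#'   `replicates`.
#' @export
bootstrap_ci <- function(obj, group, metric = c("SoV", "SoR", "displacement",
                                                "WMPD"),
                         n_boot = 9999, rarefy_to = NULL, seed = 1234,
                         conf = 0.95, ...) {
  metric <- match.arg(metric)
  if (n_boot %% 2 == 0) stop("n_boot must be odd")
  if (length(group) < 2) stop("group must have >= 2 taxa")
  if (!is.null(rarefy_to) && rarefy_to > length(group)) {
    stop("rarefy_to exceeds group size")
  }
  size <- if (is.null(rarefy_to)) length(group) else rarefy_to
  if (metric == "WMPD") {
    stopifnot(inherits(obj, "mord_dist"))
    point <- wmpd(obj, group)
    one <- function(g) {
      D <- obj$D[g, g]; N <- obj$N[g, g]
      ut <- upper.tri(D)
      keep <- ut & !is.na(D) & N > 0
      if (!any(keep)) return(NA_real_)
      sum(N[keep] * D[keep]) / sum(N[keep])
    }
  } else {
    point <- metric_value(obj, group, metric, ...)
    one <- function(g) metric_value(obj, g, metric, ...)
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    g <- sample(group, size, replace = TRUE)
    # a bootstrap draw of a single repeated taxon has no pair information
    while (length(unique(g)) < 2) g <- sample(group, size, replace = TRUE)
    suppressWarnings(one(g))
  }, numeric(1))
  reps_ok <- reps[!is.na(reps)]
  alpha <- 1 - conf
  if (metric == "SoR") {
    ci <- c(stats::quantile(reps_ok, alpha, names = FALSE), point)
  } else {
    ci <- stats::quantile(reps_ok, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }
  structure(list(group_label = paste(deparse(substitute(group)), collapse = ""),
                 metric = metric, value = point,
                 ci_lower = ci[1], ci_upper = ci[2],
                 n_taxa = length(group), n_boot = n_boot,
                 rarefied_to = rarefy_to, replicates = reps),
            class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  cat(sprintf("<disparity_estimate> %s = %.7g [%.7g, %.7g] (n=%d, boot=%d%s)\n",
              x$metric, x$value, x$ci_lower, x$ci_upper, x$n_taxa, x$n_boot,
              if (is.null(x$rarefied_to)) ""
              else paste0(", rarefied to ", x$rarefied_to)))
  invisible(x)
}

#' Significance by confidence-interval non-overlap
#'
#' Two estimates of the same metric differ significantly when their
#' confidence intervals are disjoint; intervals that merely touch (closed
#' intervals) do not count as significant.
#'
#' @param est_a,est_b [bootstrap_ci()] results for the same metric.
#' @return list with `significant` (logical) and the two intervals.
#' @export
ci_overlap_test <- function(est_a, est_b) {
  stopifnot(inherits(est_a, "disparity_estimate"),
            inherits(est_b, "disparity_estimate"))
  if (est_a$metric != est_b$metric) {
    stop("estimates are for different metrics: ", est_a$metric, " vs ",
         est_b$metric)
  }
  disjoint <- est_a$ci_lower > est_b$ci_upper ||
              est_b$ci_lower > est_a$ci_upper
  list(significant = disjoint,
       interval_a = c(est_a$ci_lower, est_a$ci_upper),
       interval_b = c(est_b$ci_lower, est_b$ci_upper))
}

#' PERMANOVA between groups of a morphospace
#'
#' Permutational multivariate analysis of variance on Euclidean distances of
#' the retained ordination axes (via [vegan::adonis2()]), testing whether
#' group positions differ. `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`
#' under free permutation of the group labels.
#'
#' @param coords numeric matrix (taxa x axes).
#' @param groups named factor/character vector of group labels covering the
#'   rows of `coords` to use; each group needs >= 2 members. Taxa absent
#'   from `groups` are dropped.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `groups`, `F`, `R2`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(coords, groups, n_perm = 9999, seed = 1234) {
  groups <- groups[!is.na(groups)]
  taxa <- intersect(rownames(coords), names(groups))
  g <- factor(as.character(groups[taxa]))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("group(s) with < 2 members: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  X <- coords[taxa, , drop = FALSE]
  set.seed(seed)
  fit <- vegan::adonis2(stats::dist(X) ~ g, permutations = n_perm)
  structure(list(groups = levels(g),
                 F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
                 n_permutations = n_perm),
            class = "permanova_result")
}

#' Behaviour of a disparity metric under controlled space reductions
#'
#' Probes which aspect of a morphospace a metric captures. For each rule the
#' points are ranked, nested subsets of growing size are taken from the top
#' of the ranking, the metric is computed on each subset, and its values are
#' regressed on the proportion of points kept:
#' \itemize{
#'   \item `inner-size` / `outer-size` -- grow the subset from the centroid
#'     outwards / from the periphery inwards (size contraction series);
#'   \item `higher-density` / `lower-density` -- grow from the points with
#'     the smallest / largest nearest-neighbour distances;
#'   \item `top-position` / `bottom-position` -- grow from the maximum /
#'     minimum end of axis 1.
#' }
#' A metric responds to an aspect when the paired rules give clearly
#' different slopes (e.g. positive inner-size vs negative outer-size slopes
#' for a size metric); on a symmetric cloud the two position series are
#' mirror images, so a metric blind to position shows near-equal slopes
#' there. Slopes standardized by the full-sample value compare sensitivity
#' across metrics.
#'
#' @param coords numeric matrix of points (>= 20 rows recommended).
#' @param metric `"SoV"`, `"SoR"` or `"displacement"`.
#' @param reductions subset of the six rules (default all).
#' @param proportions fractions of points kept (default 0.2, 0.3, ..., 1).
#' @param seed integer seed (random tie-breaking of equal ranks).
#' @param ... passed to [metric_value()].
#' @return data.frame with columns `metric`, `reduction`, `slope`,
#'   `slope_standardized` (slope / full-sample value), `intercept` and
#'   `value_full` (the metric at proportion 1).
#' @export
metric_diagnostics <- function(coords,
                               metric = c("SoV", "SoR", "displacement"),
                               reductions = c("inner-size", "outer-size",
                                              "higher-density",
                                              "lower-density",
                                              "top-position",
                                              "bottom-position"),
                               proportions = seq(0.2, 1, 0.1),
                               seed = 1234, ...) {
  metric <- match.arg(metric)
  reductions <- match.arg(reductions, several.ok = TRUE)
  n <- nrow(coords)
  if (n < max(10, 2 / min(proportions))) stop("too few points to reduce")
  if (is.null(rownames(coords))) rownames(coords) <- paste0("p", seq_len(n))
  set.seed(seed)
  cen <- colMeans(coords)
  d_cen <- sqrt(rowSums(sweep(coords, 2, cen)^2))
  dd <- as.matrix(stats::dist(coords)); diag(dd) <- Inf
  d_nn <- apply(dd, 1, min)
  ax1 <- coords[, 1]
  jitter_rank <- function(v) rank(v, ties.method = "random")
  rank_for <- list(
    "inner-size"      = jitter_rank(d_cen),   # innermost enter first
    "outer-size"      = jitter_rank(-d_cen),
    "higher-density"  = jitter_rank(d_nn),    # densest neighbourhoods first
    "lower-density"   = jitter_rank(-d_nn),
    "top-position"    = jitter_rank(-ax1),
    "bottom-position" = jitter_rank(ax1))
  rows <- lapply(reductions, function(rule) {
    rk <- rank_for[[rule]]
    vals <- vapply(proportions, function(p) {
      keep <- rk <= max(2, ceiling(p * n))
      metric_value(coords, rownames(coords)[keep], metric, ...)
    }, numeric(1))
    fit <- stats::lm(vals ~ proportions)
    full <- vals[which.max(proportions)]
    data.frame(metric = metric, reduction = rule,
               slope = unname(stats::coef(fit)[2]),
               slope_standardized = unname(stats::coef(fit)[2]) / full,
               intercept = unname(stats::coef(fit)[1]),
               value_full = full,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a character matrix into anatomical partitions
#'
#' @param x a [clado_matrix()].
#' @param partition named list mapping each region to its 1-based character
#'   indices; every character must belong to exactly one region and no
#'   region may be empty.
#' @return named list of [clado_matrix()] objects (ordering flags and
#'   weights preserved).
#' @export
partition_characters <- function(x, partition) {
  stopifnot(inherits(x, "clado_matrix"), is.list(partition))
  if (is.null(names(partition)) || any(!nzchar(names(partition)))) {
    stop("partition regions must be named")
  }
  idx <- unlist(partition, use.names = FALSE)
  m <- ncol(x$codes)
  if (any(lengths(partition) == 0)) {
    stop("empty region(s): ",
         paste(names(partition)[lengths(partition) == 0], collapse = ", "))
  }
  dup <- idx[duplicated(idx)]
  if (length(dup)) stop("character(s) assigned twice: ",
                        paste(unique(dup), collapse = ", "))
  missing_idx <- setdiff(seq_len(m), idx)
  if (length(missing_idx)) {
    stop("unassigned character(s): ",
         paste(utils::head(missing_idx, 10), collapse = ", "))
  }
  if (any(idx < 1 | idx > m)) stop("partition index out of range")
  lapply(partition, function(ii) cm_subset(x, characters = sort(ii)))
}
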