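#' Maximum Observable Rescaled Distance (MORD) matrix
#'
#' For every taxon pair, characters are comparable when both cells carry a
#' state set (missing and inapplicable cells are both non-comparable). The
#' per-character difference is 0/1 by set intersection for unordered
#' characters and the minimum cross-set step distance for ordered ones
#' (polymorphisms resolve to the closest member). Each difference is rescaled
#' by the maximum observable difference of its character: 1 for unordered,
#' the range of states coded anywhere in the matrix for ordered. The pairwise
#' dissimilarity is the weighted sum of differences over the weighted sum of
#' maxima across comparable characters; the comparable weight sum `n_ij` is
#' returned alongside, and pairs with `n_ij = 0` are undefined (`NA`).
#'
#' @param x a [clado_matrix()] with at least two taxa.
#' @return a list of class `mord_dist` with elements `taxa`, `D` (symmetric,
#'   in `[0,1]`, `NA` where undefined), `N` (comparable weight sums) and
#'   `incomparable_pairs` (two-column matrix of taxon names).
#' @references Lloyd, G.T. (2016) Estimating morphological diversity and
#'   tempo with discrete character-taxon matrices. Biol. J. Linn. Soc.
#' @export
mord_matrix <- function(x) {
  stopifnot(inherits(x, "clado_matrix"))
  n <- length(x$taxa)
  if (n < 2) stop("need at least 2 taxa")
  codes <- x$codes
  scored <- codes > 0L
  b <- cm_state_bounds(x)
  lo <- b$lo; hi <- b$hi
  # non-contiguous state sets need exact set arithmetic for ordered chars
  full_range_code <- function(l, h) sum(bitwShiftL(1L, l:h))
  noncontig <- scored &
    matrix(mapply(function(cd, l, h) cd > 0L && cd != full_range_code(l, h),
                  codes, ifelse(is.na(lo), 0L, lo), ifelse(is.na(hi), 0L, hi)),
           n, ncol(codes))
  ord <- x$ordering == "ordered"
  w <- x$weights
  # per-character maximum observable difference
  char_lo <- suppressWarnings(apply(lo, 2, min, na.rm = TRUE))
  char_hi <- suppressWarnings(apply(hi, 2, max, na.rm = TRUE))
  mk <- ifelse(ord, pmax(char_hi - char_lo, 0), 1)
  mk[!is.finite(mk)] <- 0  # characters scored for no taxon
  D <- N <- matrix(0, n, n, dimnames = list(x$taxa, x$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- scored[i, ] & scored[j, ]
      nij <- sum(w[comp])
      N[i, j] <- N[j, i] <- nij
      if (nij == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
      dk <- numeric(sum(comp))
      ci <- codes[i, comp]; cj <- codes[j, comp]
      ordc <- ord[comp]
      # unordered: mismatch iff the state sets are disjoint
      dk[!ordc] <- as.numeric(bitwAnd(ci[!ordc], cj[!ordc]) == 0L)
      if (any(ordc)) {
        gap <- pmax(lo[i, comp][ordc] - hi[j, comp][ordc],
                    lo[j, comp][ordc] - hi[i, comp][ordc], 0)
        # ranges that overlap but with non-contiguous sets: exact min |a-b|
        nc <- (noncontig[i, comp][ordc] | noncontig[j, comp][ordc]) & gap == 0
        if (any(nc)) {
          idx <- which(ordc)[nc]
          gap[nc] <- vapply(idx, function(k) {
            a <- decode_code(ci[k]); bset <- decode_code(cj[k])
            min(abs(outer(a, bset, "-")))
          }, numeric(1))
        }
        dk[ordc] <- gap
      }
      denom <- sum(w[comp] * mk[comp])
      num <- sum(w[comp] * dk)
      D[i, j] <- D[j, i] <- if (denom > 0) num / denom else 0
    }
  }
  und <- which(upper.tri(N) & N == 0, arr.ind = TRUE)
  incomparable <- cbind(x$taxa[und[, 1]], x$taxa[und[, 2]])
  structure(list(taxa = x$taxa, D = D, N = N,
                 incomparable_pairs = incomparable),
            class = "mord_dist")
}

#' @export
print.mord_dist <- function(x, ...) {
  cat("<mord_dist> ", length(x$taxa), " taxa; ",
      nrow(x$incomparable_pairs), " incomparable pair(s)\n", sep = "")
  invisible(x)
}

#' Weighted mean pairwise dissimilarity (WMPD)
#'
#' The mean of pairwise dissimilarities within a group, weighting each pair
#' by its comparable-character weight sum `n_ij`; undefined pairs are
#' skipped. Being computed on the raw distance matrix, WMPD uses all taxa
#' regardless of any trimming needed for ordination.
#'
#' @param dist a [mord_matrix()] result.
#' @param group taxon names (default: all); must have at least 2 members.
#' @return a single numeric value.
#' @export
wmpd <- function(dist, group = dist$taxa) {
  stopifnot(inherits(dist, "mord_dist"))
  group <- intersect(group, dist$taxa)
  if (length(group) < 2) stop("group must have >= 2 taxa present in dist")
  D <- dist$D[group, group]; N <- dist$N[group, group]
  ut <- upper.tri(D)
  keep <- ut & !is.na(D) & N > 0
  if (!any(keep)) stop("no comparable pair within group")
  sum(N[keep] * D[keep]) / sum(N[keep])
}

#' Missing-data bias diagnostic
#'
#' High proportions of missing data can push taxa away from the centroid of
#' a MORD-based space (a repulsion artefact). This tests for it: per-taxon
#' percentage of missing/inapplicable cells is correlated (Pearson) with the
#' taxon's distance from the centroid, either of the ordinated coordinates
#' or, given a distance matrix, of the distance-space (mean squared distance
#' to the other taxa, Gower-centered).
#'
#' @param space either an [mord_matrix()] result or a numeric coordinate
#'   matrix with taxa as rownames.
#' @param x the [clado_matrix()] the space was computed from.
#' @return list with `r`, `p` (two-sided), `missing_pct`,
#'   `centroid_distance`.
#' @export
missing_data_bias_test <- function(space, x) {
  stopifnot(inherits(x, "clado_matrix"))
  if (inherits(space, "mord_dist")) {
    taxa <- space$taxa
    D <- space$D
    if (anyNA(D)) stop("distance matrix has undefined pairs; trim first")
    # squared distance to centroid from Gower-centered -D^2/2
    G <- gower_center(D^2)
    cd <- sqrt(pmax(diag(G), 0))
  } else {
    taxa <- rownames(space)
    cen <- colMeans(space)
    cd <- sqrt(rowSums(sweep(space, 2, cen)^2))
  }
  if (length(taxa) < 4) stop("need at least 4 taxa")
  miss <- 100 * cm_missing_fraction(x)[taxa]
  if (stats::sd(miss) == 0 || stats::sd(cd) == 0) {
    stop("zero variance in missingness or centroid distance")
  }
  ct <- stats::cor.test(miss, cd, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       missing_pct = miss, centroid_distance = cd)
}

# Gower double-centering of a squared-distance matrix: -(I-11'/n) A (I-11'/n)/2
gower_center <- function(D2) {
  n <- nrow(D2)
  A <- -0.5 * D2
  rm_ <- rowMeans(A); gm <- mean(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}
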