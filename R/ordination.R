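#' Trim taxa so that every pair is comparable
#'
#' Ordination needs a complete distance matrix, but cladistic matrices with
#' heavy missing data can leave taxon pairs with no overlapping scored
#' characters. This removes taxa greedily: at each step the taxon involved in
#' the most undefined pairs is dropped (ties broken by higher missing-data
#' fraction, then lexicographically), until no undefined pair remains.
#'
#' @param dist a [mord_matrix()] result.
#' @param matrix_x optional [clado_matrix()] used for the missing-data
#'   tie-break; without it ties fall through to the name order.
#' @return list with `dist` (reduced `mord_dist`) and `removed` (taxon names
#'   in removal order, empty if nothing was trimmed).
#' @export
trim_for_ordination <- function(dist, matrix_x = NULL) {
  stopifnot(inherits(dist, "mord_dist"))
  D <- dist$D; N <- dist$N
  taxa <- dist$taxa
  miss <- if (!is.null(matrix_x)) cm_missing_fraction(matrix_x)[taxa]
          else stats::setNames(rep(0, length(taxa)), taxa)
  removed <- character(0)
  repeat {
    undef <- is.na(D); diag(undef) <- FALSE
    if (!any(undef)) break
    counts <- rowSums(undef)
    worst <- which(counts == max(counts))
    if (length(worst) > 1) {
      worst <- worst[miss[worst] == max(miss[worst])]
    }
    if (length(worst) > 1) worst <- worst[order(names(counts)[worst])[1]]
    drop_name <- rownames(D)[worst[1]]
    removed <- c(removed, drop_name)
    keep <- rownames(D) != drop_name
    D <- D[keep, keep, drop = FALSE]; N <- N[keep, keep, drop = FALSE]
    miss <- miss[keep]
    if (nrow(D) == 0) { warning("all taxa trimmed"); break }
  }
  out <- structure(list(taxa = rownames(D), D = D, N = N,
                        incomparable_pairs = matrix(character(0), 0, 2)),
                   class = "mord_dist")
  list(dist = out, removed = removed)
}

#' Principal coordinates analysis with Lingoes correction
#'
#' Eigendecomposition of the Gower double-centered `-D^2/2`. If the smallest
#' eigenvalue is below `-tol` (non-Euclidean distances), the Lingoes
#' constant `c = |lambda_min|` is added to all squared off-diagonal
#' distances and the decomposition repeated, which makes all eigenvalues
#' non-negative up to numerical noise. Coordinates are eigenvectors scaled
#' by `sqrt(lambda)` over the positive axes; the sign of each axis is fixed
#' by making its largest-magnitude loading positive. Variance fractions are
#' relative to the sum of positive corrected eigenvalues.
#'
#' @param dist a complete [mord_matrix()] result (no undefined pairs; see
#'   [trim_for_ordination()]) or a symmetric numeric distance matrix.
#' @param tol negative-eigenvalue detection tolerance (default `1e-8`).
#' @return list of class `clado_ordination`: `taxa`, `coordinates` (n x k),
#'   `eigenvalues_raw`, `lingoes_constant`, `eigenvalues` (corrected),
#'   `variance_fraction`, `corrected_D` (the distances the coordinates
#'   embed), `trimmed_taxa`.
#' @export
pcoa_lingoes <- function(dist, tol = 1e-8) {
  if (inherits(dist, "mord_dist")) {
    D <- dist$D; taxa <- dist$taxa
  } else {
    D <- as.matrix(dist); taxa <- rownames(D)
  }
  if (anyNA(D)) stop("distance matrix has undefined pairs; run trim_for_ordination() first")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa to ordinate")
  eig_raw <- eigen(gower_center(D^2), symmetric = TRUE)
  lmin <- min(eig_raw$values)
  cc <- 0
  D2 <- D^2
  if (lmin < -tol) {
    cc <- -lmin
    D2 <- D^2 + 2 * cc
    diag(D2) <- 0
  }
  eg <- eigen(gower_center(D2), symmetric = TRUE)
  pos <- eg$values > tol
  lambda <- eg$values[pos]
  V <- eg$vectors[, pos, drop = FALSE]
  coords <- sweep(V, 2, sqrt(lambda), `*`)
  # deterministic axis orientation
  for (k in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, k])), k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- taxa
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(taxa = taxa,
                 coordinates = coords,
                 eigenvalues_raw = eig_raw$values,
                 lingoes_constant = cc,
                 eigenvalues = eg$values,
                 variance_fraction = lambda / sum(lambda),
                 corrected_D = sqrt(D2),
                 trimmed_taxa = character(0)),
            class = "clado_ordination")
}

#' @export
print.clado_ordination <- function(x, ...) {
  cat("<clado_ordination> ", length(x$taxa), " taxa, ",
      ncol(x$coordinates), " positive axes; Lingoes c = ",
      format(x$lingoes_constant, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cumulative variance captured by the first k axes
#'
#' @param ordination a [pcoa_lingoes()] result.
#' @param k number of leading axes, `1 <= k <=` number of positive axes.
#' @return cumulative percentage of (positive-eigenvalue) variance.
#' @export
axis_variance <- function(ordination, k) {
  stopifnot(inherits(ordination, "clado_ordination"))
  kmax <- length(ordination$variance_fraction)
  if (k < 1 || k > kmax) stop("k must be in 1..", kmax)
  100 * sum(ordination$variance_fraction[seq_len(k)])
}
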