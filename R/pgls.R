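#' Distance-based phylogenetic generalized least squares with RRPP
#'
#' Regresses a multivariate response (the first few ordination axes) on
#' explanatory variables while accounting for phylogenetic covariance:
#' response and design are premultiplied by `C^(-1/2)` (symmetric
#' eigendecomposition of the phylogenetic variance-covariance matrix, with a
#' small eigenvalue floor), sums of squares are computed as trace statistics
#' over the response axes using type II comparisons (each term against the
#' model holding all other terms), and significance comes from the residual
#' randomization permutation procedure (RRPP): rows of the reduced-model
#' residuals are permuted, the statistic recomputed, and
#' `p = (1 + #(F_perm >= F_obs)) / (1 + iterations)`.
#'
#' Two term combinations are rejected as confounded: log body mass together
#' with femoral length (they covary strongly), and locomotion together with
#' the humeral/femoral circumference ratio (the latter is used to infer the
#' former).
#'
#' @param coords numeric response matrix (taxa x m axes), rownames = taxa.
#' @param formula one-sided formula of explanatory terms, e.g.
#'   `~ log_body_mass + continent`.
#' @param data data.frame of explanatory variables with a `taxon` column or
#'   taxon rownames. Categorical terms use treatment contrasts with the
#'   alphabetically first level as reference.
#' @param tree a `phylo` with branch durations covering all response taxa;
#'   `NULL` fits ordinary (identity-covariance) least squares.
#' @param iterations number of RRPP permutations (default 999).
#' @param seed integer seed.
#' @param eig_floor lower bound applied to eigenvalues of `C` (default
#'   `1e-10`); guards against near-singularity from minimum-branch-length
#'   compressed trees.
#' @return list of class `dpgls_fit`: `table` (per-term df, SS, R2, F, p),
#'   `SS_total`, `RSS`, `coefficients`, `se` (per response axis),
#'   `n`, `m`, `iterations`, `terms`.
#' @export
dpgls_fit <- function(coords, formula, data, tree = NULL, iterations = 999,
                      seed = 1234, eig_floor = 1e-10) {
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("coords must have taxon rownames")
  if (!is.null(data$taxon)) rownames(data) <- data$taxon
  taxa <- rownames(coords)
  if (!all(taxa %in% rownames(data))) {
    stop("metadata missing for: ",
         paste(setdiff(taxa, rownames(data)), collapse = ", "))
  }
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) stop("empty model (no terms)")
  vars_in <- function(pat) any(grepl(pat, labels))
  if (vars_in("log_body_mass") && vars_in("femoral_length")) {
    stop("disallowed term combination: body mass with femoral length (collinear)")
  }
  if (vars_in("locomotion") && vars_in("circ_ratio")) {
    stop("disallowed term combination: locomotion with circumference ratio ",
         "(the ratio is used to infer locomotion)")
  }
  df <- data[taxa, , drop = FALSE]
  mf <- stats::model.frame(formula, df, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design; aliased term(s) among: ",
         paste(labels, collapse = ", "))
  }
  n <- nrow(X)
  Y <- coords
  if (!is.null(tree)) {
    missing_tips <- setdiff(taxa, tree$tip.label)
    if (length(missing_tips)) {
      stop("taxa absent from tree: ", paste(missing_tips, collapse = ", "))
    }
    tr <- ape::keep.tip(tree, taxa)
    C <- ape::vcv(tr)[taxa, taxa]
    ec <- eigen(C, symmetric = TRUE)
    vals <- pmax(ec$values, eig_floor)
    P <- ec$vectors %*% (t(ec$vectors) / sqrt(vals))
    Y <- P %*% Y
    X <- P %*% X
  }
  asgn <- attr(stats::model.matrix(formula, mf), "assign")
  hat_of <- function(M) {
    if (!ncol(M)) return(matrix(0, n, n))
    qr_m <- qr(M)
    Q <- qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_full <- hat_of(X)
  H_int <- hat_of(X[, asgn == 0, drop = FALSE])
  rss_with <- function(H, Ymat) sum((Ymat - H %*% Ymat)^2)
  RSS_full <- rss_with(H_full, Y)
  SS_total <- rss_with(H_int, Y)
  df_resid <- n - qr(X)$rank
  set.seed(seed)
  perms <- replicate(iterations, sample.int(n), simplify = FALSE)
  rows <- lapply(seq_along(labels), function(i) {
    keep <- asgn != i
    H_red <- hat_of(X[, keep, drop = FALSE])
    df_term <- sum(asgn == i)
    Hdiff <- H_full - H_red
    M_red <- diag(n) - H_red
    SS_obs <- sum((Hdiff %*% Y)^2)
    F_obs <- (SS_obs / df_term) / (RSS_full / df_resid)
    fit_red <- H_red %*% Y
    e_red <- Y - fit_red
    count <- 0L
    for (p in perms) {
      Yp <- fit_red + e_red[p, , drop = FALSE]
      SSp <- sum((Hdiff %*% Yp)^2)
      Fp <- (SSp / df_term) / (rss_with(H_full, Yp) / df_resid)
      if (Fp >= F_obs - 1e-12) count <- count + 1L
    }
    data.frame(term = labels[i], df = df_term, SS = SS_obs,
               R2 = SS_obs / SS_total, F = F_obs,
               p = (1 + count) / (1 + iterations),
               stringsAsFactors = FALSE)
  })
  beta <- solve(crossprod(X), crossprod(X, Y))
  sigma2 <- colSums((Y - X %*% beta)^2) / df_resid
  xtxi <- diag(solve(crossprod(X)))
  se <- sqrt(outer(xtxi, sigma2))
  dimnames(se) <- dimnames(beta)
  structure(list(table = do.call(rbind, rows), SS_total = SS_total,
                 RSS = RSS_full, coefficients = beta, se = se,
                 n = n, m = ncol(Y), iterations = iterations,
                 terms = labels, df_resid = df_resid),
            class = "dpgls_fit")
}

#' @export
print.dpgls_fit <- function(x, ...) {
  cat("<dpgls_fit> n =", x$n, ", response axes =", x$m,
      ", RRPP iterations =", x$iterations, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Derived regression covariates from taxon metadata
#'
#' Adds the standard derived columns used by the regression models:
#' `log_femoral_length = log(femoral_length)`, `circ_ratio =
#' log(humeral_circ)/log(femoral_circ)`, and `tree_shape` (node count to the
#' root; see [phylo_vcv_and_tree_shape()]) when a tree is given.
#'
#' @param metadata a metadata data.frame (see [read_taxon_metadata()]).
#' @param tree optional `phylo` supplying the tree-shape covariate.
#' @return the data.frame with rownames set to `taxon` and the derived
#'   columns appended.
#' @export
make_regression_data <- function(metadata, tree = NULL) {
  df <- as.data.frame(metadata)
  rownames(df) <- df$taxon
  if (!is.null(df$femoral_length)) {
    df$log_femoral_length <- log(df$femoral_length)
  }
  if (!is.null(df$humeral_circ) && !is.null(df$femoral_circ)) {
    df$circ_ratio <- log(df$humeral_circ) / log(df$femoral_circ)
  }
  if (!is.null(tree)) {
    shape <- phylo_vcv_and_tree_shape(tree)$tree_shape
    df$tree_shape <- as.numeric(shape[rownames(df)])
  }
  df
}

#' Fit a set of regression models over a sample of trees
#'
#' Fits every model x tree combination with [dpgls_fit()] and stacks the
#' per-term results. Large tree samples can be subsampled (seeded) to keep
#' run time down; the full sample is just `trees_sample = length(trees)`.
#'
#' @param models list of one-sided formulas (or strings coercible to
#'   formulas).
#' @param coords response matrix (taxa x m axes).
#' @param metadata metadata data.frame; [make_regression_data()] is applied
#'   per tree.
#' @param trees a `multiPhylo`/list of time-calibrated trees (>= 1).
#' @param iterations RRPP iterations per fit (default 999).
#' @param trees_sample number of trees to draw (default all).
#' @param seed integer seed (tree subsampling and RRPP).
#' @return data.frame with one row per model x tree x term: `tree`, `model`,
#'   `term`, `df`, `SS`, `R2`, `F`, `p`.
#' @export
model_suite <- function(models, coords, metadata, trees, iterations = 999,
                        trees_sample = NULL, seed = 1234) {
  if (!length(models)) stop("empty model list")
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  set.seed(seed)
  idx <- seq_along(trees)
  if (!is.null(trees_sample) && trees_sample < length(trees)) {
    idx <- sort(sample(idx, trees_sample))
  }
  out <- list()
  for (ti in idx) {
    df <- make_regression_data(metadata, trees[[ti]])
    for (mi in seq_along(models)) {
      f <- stats::as.formula(models[[mi]])
      fit <- dpgls_fit(coords, f, df, tree = trees[[ti]],
                       iterations = iterations, seed = seed + ti)
      tb <- fit$table
      tb <- cbind(tree = ti,
                  model = paste(deparse(f), collapse = ""),
                  tb, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- tb
    }
  }
  do.call(rbind, out)
}
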