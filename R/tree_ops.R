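#' Minimum-branch-length time calibration
#'
#' Time-scales a cladogram from tip first-appearance ages (FADs): every
#' internal node age is initialized to the oldest FAD among its descendant
#' tips, then a tips-to-root pass raises each parent's age to
#' `max(child age) + mbl` wherever a branch would otherwise be shorter than
#' the minimum. Tip ages are the FADs and are never moved. The result is a
#' `phylo` whose `edge.length` are durations in Myr (all `>= mbl`) with the
#' root age (Ma) stored in `$root.time` and tip ages in `$tip.ages`.
#'
#' @param tree a rooted `phylo` (branch lengths, if any, are ignored).
#' @param fads named numeric vector of tip ages in Ma; every tip must be
#'   present.
#' @param mbl minimum branch duration in Myr (default 0.1).
#' @return a time-scaled `phylo` (fields above). The function is a pure
#'   function of `(topology, fads, mbl)`, hence idempotent.
#' @export
calibrate_mbl <- function(tree, fads, mbl = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(fads))
  if (length(miss)) stop("tip(s) lacking FAD: ", paste(miss, collapse = ", "))
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  age <- numeric(n + nnode)
  age[seq_len(n)] <- fads[tree$tip.label]
  tr <- ape::reorder.phylo(tree, "postorder")
  # pass 1: node age = oldest descendant tip FAD
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    age[p] <- max(age[p], age[ch])
  }
  # pass 2 (tips -> root): enforce the minimum duration
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    age[p] <- max(age[p], age[ch] + mbl)
  }
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out$root.time <- age[n + 1L]
  out$tip.ages <- stats::setNames(age[seq_len(n)], tree$tip.label)
  out
}

# cost vectors for generalized (Sankoff) parsimony on one character.
# states: integer vector of the character's state space (sorted);
# cost c(s,t) = |s-t| if ordered else 0/1.
sankoff_down <- function(tree_post, tip_codes, states, ordered) {
  n_tip <- length(tip_codes)
  k <- length(states)
  cost_mat <- if (ordered) abs(outer(states, states, "-"))
              else 1 - diag(k)
  nn <- n_tip + tree_post$Nnode
  down <- matrix(0, nn, k)
  for (i in seq_len(n_tip)) {
    cd <- tip_codes[i]
    if (cd > 0L) {
      inset <- bitwAnd(cd, bitwShiftL(1L, states)) != 0L
      down[i, ] <- ifelse(inset, 0, Inf)
    } # missing/inapplicable: all-zero row (any state free)
  }
  edge <- tree_post$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    # min over child state t of down[ch,t] + cost(s,t), for each s
    add <- apply(cost_mat + rep(down[ch, ], each = k), 1, min)
    down[p, ] <- down[p, ] + add
  }
  list(down = down, cost_mat = cost_mat)
}

#' Parsimony length of a tree on a character matrix
#'
#' Weighted sum over characters of the minimum number of changes: Fitch-style
#' 0/1 costs for unordered characters, linear step costs `|a - b|` for
#' ordered ones (generalized Sankoff optimization). Missing and inapplicable
#' tips accept any state at no cost; polymorphic tips resolve to the
#' cheapest member of their set. A character's state space is the set of
#' states coded for it anywhere in the matrix (the full range for ordered
#' characters).
#'
#' @param tree a rooted `phylo`; its tips must all occur in `x`.
#' @param x a [clado_matrix()].
#' @return total tree length (numeric; integer-valued under unit weights).
#' @export
parsimony_tree_length <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "clado_matrix"))
  miss <- setdiff(tree$tip.label, x$taxa)
  if (length(miss)) stop("tip(s) missing from matrix: ",
                         paste(miss, collapse = ", "))
  codes <- x$codes[tree$tip.label, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  b <- cm_state_bounds(x)
  total <- 0
  for (ch in seq_len(ncol(codes))) {
    w <- x$weights[ch]
    if (w == 0) next
    cl <- b$lo[tree$tip.label, ch]; chh <- b$hi[tree$tip.label, ch]
    if (all(is.na(cl))) next  # nothing scored on this tree
    ordered <- x$ordering[ch] == "ordered"
    states <- if (ordered) seq(min(cl, na.rm = TRUE), max(chh, na.rm = TRUE))
              else sort(unique(unlist(lapply(codes[!is.na(cl), ch], decode_code))))
    if (length(states) < 2) next
    sk <- sankoff_down(tr, codes[, ch], as.integer(states), ordered)
    root <- length(tree$tip.label) + 1L
    total <- total + w * min(sk$down[root, ])
  }
  total
}

# up-pass cost vectors: cost of the rest of the tree given node's state.
sankoff_up <- function(tree_post, down, cost_mat) {
  k <- ncol(down)
  nn <- nrow(down)
  up <- matrix(0, nn, k)
  edge <- tree_post$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  # preorder = reversed postorder edge order
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sibs <- setdiff(edge[children[[as.character(p)]], 2], ch)
    ctx <- up[p, ]
    for (s in sibs) {
      ctx <- ctx + apply(cost_mat + rep(down[s, ], each = k), 1, min)
    }
    # min over parent state s of ctx[s] + cost(s,t), for each child state t
    up[ch, ] <- apply(cost_mat + rep(ctx, each = k), 1, min)
  }
  up
}

#' Fitch imputation of a discrete tip character
#'
#' Computes most-parsimonious-reconstruction (MPR) state sets for every tip
#' and internal node by a down-pass/up-pass Fitch (unordered Sankoff)
#' optimization. Tips with unknown state enter with the full state set and
#' receive their MPR set: a singleton is an imputation, anything larger is
#' flagged ambiguous. Given several trees, each tree votes with its
#' unambiguous imputation and the majority state is kept (ties or no
#' unambiguous vote stay ambiguous).
#'
#' @param tree a rooted `phylo` or a `multiPhylo` list.
#' @param tip_states named character (or factor) vector; `NA` or `"unknown"`
#'   marks tips to impute. At least one tip must be observed.
#' @param levels state labels; default the sorted observed values.
#' @return for one tree: list with `tip_states` (imputed where possible),
#'   `node_sets` and `tip_sets` (lists of MPR label sets) and logical
#'   `ambiguous` per tip. For several trees: list with `tip_states`,
#'   `ambiguous`, and the per-tree `votes` matrix.
#' @export
fitch_impute_states <- function(tree, tip_states, levels = NULL) {
  tip_states <- replace(tip_states, tip_states %in% "unknown", NA)
  if (is.null(levels)) levels <- sort(unique(stats::na.omit(as.character(tip_states))))
  if (!length(levels)) stop("all tips unknown: nothing to optimize from")
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo"))) {
    per <- lapply(tree, fitch_impute_states, tip_states = tip_states,
                  levels = levels)
    tips <- names(per[[1]]$tip_states)
    votes <- vapply(per, function(r)
      ifelse(r$ambiguous, NA_character_, as.character(r$tip_states[tips])),
      character(length(tips)))
    votes <- matrix(votes, nrow = length(tips),
                    dimnames = list(tips, NULL))
    out <- character(length(tips)); amb <- logical(length(tips))
    for (i in seq_along(tips)) {
      tb <- table(stats::na.omit(votes[i, ]))
      if (!length(tb) || sum(tb == max(tb)) > 1) {
        out[i] <- NA_character_; amb[i] <- TRUE
      } else out[i] <- names(tb)[which.max(tb)]
    }
    return(list(tip_states = stats::setNames(out, tips),
                ambiguous = stats::setNames(amb, tips), votes = votes))
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) stop("tip(s) without an entry: ",
                         paste(miss, collapse = ", "))
  k <- length(levels)
  obs <- as.character(tip_states[tree$tip.label])
  codes <- ifelse(is.na(obs), CM_MISSING,
                  bitwShiftL(1L, match(obs, levels) - 1L))
  if (anyNA(codes)) stop("tip state outside `levels`")
  tr <- ape::reorder.phylo(tree, "postorder")
  sk <- sankoff_down(tr, codes, 0:(k - 1L), ordered = FALSE)
  up <- sankoff_up(tr, sk$down, sk$cost_mat)
  tot <- sk$down + up
  mpr <- apply(tot, 1, function(v) levels[v <= min(v) + 1e-9], simplify = FALSE)
  n_tip <- length(tree$tip.label)
  tip_sets <- mpr[seq_len(n_tip)]
  names(tip_sets) <- tree$tip.label
  node_sets <- mpr[-seq_len(n_tip)]
  imputed <- obs
  amb <- rep(FALSE, n_tip)
  for (i in which(is.na(obs))) {
    if (length(tip_sets[[i]]) == 1L) imputed[i] <- tip_sets[[i]]
    else amb[i] <- TRUE
  }
  list(tip_states = stats::setNames(imputed, tree$tip.label),
       ambiguous = stats::setNames(amb, tree$tip.label),
       tip_sets = tip_sets, node_sets = node_sets)
}

#' Brownian-motion ancestral states for a continuous trait
#'
#' Maximum-likelihood ancestral estimates under Brownian motion on a
#' time-scaled tree (GLS / re-rooting formulation, via
#' [phytools::fastAnc()]). The root estimate is the GLS mean
#' `(1' C^-1 x) / (1' C^-1 1)` with `C` the phylogenetic covariance.
#'
#' @param tree a `phylo` with strictly positive branch durations (calibrate
#'   with [calibrate_mbl()] first if needed).
#' @param x named numeric vector of tip values covering all tips.
#' @return numeric vector of internal-node estimates, named by node number.
#' @export
bm_ancestral_states <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) {
    stop("zero or negative branch duration(s); run calibrate_mbl() first")
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("tip(s) without value: ", paste(miss, collapse = ", "))
  est <- phytools::fastAnc(tree, x[tree$tip.label])
  stats::setNames(as.numeric(est), names(est))
}

#' Phylogenetic covariance matrices and the tree-shape covariate
#'
#' Returns the phylogenetic variance-covariance matrix of the tree as given
#' (shared root-to-ancestor path durations; requires branch lengths) and of
#' the same topology with every branch set to 1. The diagonal of the
#' unit-branch matrix counts the nodes between each tip and the root, a
#' purely topological "tree shape" covariate that is invariant to branch
#' lengths.
#'
#' @param tree a rooted `phylo`.
#' @return list with `C_time` (NULL when the tree has no branch lengths),
#'   `C_unit`, and `tree_shape` (named integer vector).
#' @export
phylo_vcv_and_tree_shape <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  C_unit <- ape::vcv(unit)
  C_time <- if (!is.null(tree$edge.length)) ape::vcv(tree) else NULL
  list(C_time = C_time, C_unit = C_unit,
       tree_shape = stats::setNames(as.integer(round(diag(C_unit))),
                                    rownames(C_unit)))
}
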