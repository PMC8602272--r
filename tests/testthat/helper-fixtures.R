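# shared fixture builders

# clado_matrix from a list of per-taxon state vectors:
# each element of `rows` is a list of cells (integer vectors, "?" or "-")
make_cm <- function(rows, ordering = "unordered", weights = 1) {
  cells <- matrix(do.call(c, lapply(rows, as.list)), nrow = length(rows),
                  byrow = TRUE, dimnames = list(names(rows), NULL))
  clado_matrix(cells, ordering = ordering, weights = weights)
}

# random complete matrix (no missing), binary by default
random_cm <- function(n, m, k = 2, seed = 1) {
  set.seed(seed)
  codes <- matrix(bitwShiftL(1L, sample.int(k, n * m, replace = TRUE) - 1L),
                  n, m)
  cladospace:::new_clado_matrix(codes, sprintf("t%02d", seq_len(n)))
}

# small Newick helpers
tree3 <- function() ape::read.tree(text = "((A,B),C);")

# exhaustive-enumeration parsimony oracle: minimum weighted changes over all
# internal-node labelings. Tips may carry state sets; missing = full set.
brute_parsimony <- function(tree, x) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  total <- 0
  b <- cladospace:::cm_state_bounds(x)
  for (ch in seq_len(ncol(x$codes))) {
    lo <- b$lo[tr$tip.label, ch]
    if (all(is.na(lo))) next
    ordered <- x$ordering[ch] == "ordered"
    sts <- if (ordered) {
      seq(min(lo, na.rm = TRUE), max(b$hi[tr$tip.label, ch], na.rm = TRUE))
    } else {
      sort(unique(unlist(lapply(x$codes[tr$tip.label, ch][!is.na(lo)],
                                cladospace:::decode_code))))
    }
    if (length(sts) < 2) next
    cost <- function(a, bb) if (ordered) abs(a - bb) else as.numeric(a != bb)
    tip_sets <- lapply(x$codes[tr$tip.label, ch], function(cd) {
      if (cd > 0L) intersect(cladospace:::decode_code(cd), sts) else sts
    })
    tip_sets <- lapply(tip_sets, function(s) if (length(s)) s else sts)
    grid <- do.call(expand.grid, rep(list(sts), tr$Nnode))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- as.numeric(grid[g, ])
      node_state <- function(v) if (v <= n_tip) NA else lab[v - n_tip]
      tot <- 0
      for (e in seq_len(nrow(tr$edge))) {
        p <- node_state(tr$edge[e, 1]); chd <- tr$edge[e, 2]
        if (chd <= n_tip) {
          tot <- tot + min(vapply(tip_sets[[chd]], cost, 0, a = p))
        } else {
          tot <- tot + cost(p, node_state(chd))
        }
      }
      best <- min(best, tot)
    }
    total <- total + x$weights[ch] * best
  }
  total
}

# brute-force PERMANOVA pseudo-F from pairwise squared Euclidean distances
brute_permanova_F <- function(X, g) {
  g <- factor(g)
  d2 <- as.matrix(stats::dist(X))^2
  n <- nrow(X)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssa <- sst - ssw
  a <- nlevels(g)
  (ssa / (a - 1)) / (ssw / (n - a))
}
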