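test_that("mbl calibration follows the two-pass rule on hand-traced cases", {
  cherry <- ape::read.tree(text = "(A,B);")
  ct <- calibrate_mbl(cherry, c(A = 10, B = 10), mbl = 0.1)
  expect_equal(ct$root.time, 10.1)
  expect_equal(ct$edge.length, c(0.1, 0.1))
  # unequal tips: node starts at 20, zero branch to B raised by mbl
  ct2 <- calibrate_mbl(cherry, c(A = 10, B = 20), mbl = 0.1)
  expect_equal(ct2$root.time, 20.1)
  expect_equal(sort(ct2$edge.length), c(0.1, 10.1))
  expect_error(calibrate_mbl(cherry, c(A = 10)), "lacking FAD")
})

test_that("mbl calibration is idempotent and respects the minimum", {
  sim <- simulate_timetree(simulation_config(n_tips = 20, seed = 3))
  c1 <- calibrate_mbl(sim$tree, sim$tip_ages)
  expect_true(all(c1$edge.length >= 0.1 - 1e-12))
  expect_equal(c1$tip.ages, sim$tip_ages[names(c1$tip.ages)])
  c2 <- calibrate_mbl(c1, c1$tip.ages)
  expect_equal(c2$edge.length, c1$edge.length)
  expect_equal(c2$root.time, c1$root.time)
})

test_that("parsimony length matches hand-scored examples", {
  tr <- tree3()
  m <- make_cm(list(A = list(0L), B = list(1L), C = list(0L)))
  expect_equal(parsimony_tree_length(tr, m), 1)
  mo <- make_cm(list(A = list(0L), B = list(2L), C = list(0L)),
                ordering = "ordered")
  expect_equal(parsimony_tree_length(tr, mo), 2)
  mm <- make_cm(list(A = list("?"), B = list("?"), C = list("?")))
  expect_equal(parsimony_tree_length(tr, mm), 0)
  # weights multiply the per-character change counts
  mw <- make_cm(list(A = list(0L, 0L), B = list(1L, 1L), C = list(0L, 0L)),
                weights = c(5, 1))
  expect_equal(parsimony_tree_length(tr, mw), 6)
  expect_error(parsimony_tree_length(tr, cm_subset(m, taxa = c("A", "B"))),
               "missing from matrix")
})

test_that("Sankoff lengths equal exhaustive enumeration on small trees", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- LETTERS[1:n]
    rows <- lapply(seq_len(n), function(i) {
      lapply(1:3, function(ch) {
        u <- runif(1)
        if (u < 0.15) "?"
        else if (u < 0.25) sort(sample(0:2, 2))  # polymorphic
        else sample(0:2, 1)
      })
    })
    names(rows) <- LETTERS[1:n]
    ordering <- sample(c("ordered", "unordered"), 3, replace = TRUE)
    m <- make_cm(rows, ordering = ordering)
    expect_equal(parsimony_tree_length(tr, m), brute_parsimony(tr, m),
                 info = paste("replicate", rep))
  }
})

test_that("Fitch imputation returns MPR singletons and flags ambiguity", {
  tr <- tree3()
  fit <- fitch_impute_states(tr, c(A = "biped", B = NA, C = "biped"))
  expect_equal(unname(fit$tip_states["B"]), "biped")
  expect_false(fit$ambiguous[["B"]])
  fit2 <- fitch_impute_states(tr, c(A = "biped", B = NA, C = "quadruped"))
  expect_true(fit2$ambiguous[["B"]])
  expect_setequal(fit2$tip_sets[["B"]], c("biped", "quadruped"))
  # all observed: identity on tips
  fit3 <- fitch_impute_states(tr, c(A = "biped", B = "quadruped",
                                    C = "biped"))
  expect_equal(fit3$tip_states,
               c(A = "biped", B = "quadruped", C = "biped"))
  expect_error(fitch_impute_states(tr, c(A = NA, B = NA, C = NA)),
               "all tips unknown")
})

test_that("multi-tree imputation takes the majority, keeping ties ambiguous", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  states <- c(A = "biped", B = NA, C = "biped", D = "biped")
  multi <- fitch_impute_states(c(t1, t2), states)
  expect_equal(unname(multi$tip_states["B"]), "biped")
  # trees whose per-tree MPR sets stay ambiguous abstain from the vote
  s2 <- c(A = "biped", B = NA, C = "quadruped", D = "quadruped")
  ta <- ape::read.tree(text = "(((A,B),C),D);")   # B is ambiguous here
  tb <- ape::read.tree(text = "(((C,B),A),D);")   # B nests with quadrupeds
  expect_true(fitch_impute_states(ta, s2)$ambiguous[["B"]])
  multi2 <- fitch_impute_states(c(ta, tb), s2)
  expect_equal(unname(multi2$tip_states["B"]), "quadruped")
  # a genuine tie between trees stays ambiguous
  s3 <- c(A = "biped", B = NA, C = "quadruped", D = "biped",
          E = "quadruped")
  t1 <- ape::read.tree(text = "(((B,A),D),(C,E));")
  t2 <- ape::read.tree(text = "(((B,C),E),(A,D));")
  multi3 <- fitch_impute_states(c(t1, t2), s3)
  expect_true(multi3$ambiguous[["B"]])
})

test_that("BM ancestral states honour symmetry and the GLS root formula", {
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  anc <- bm_ancestral_states(tr4, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(unname(anc), rep(1, 3))
  anc2 <- bm_ancestral_states(tr4, c(A = 0, B = 0, C = 2, D = 2))
  expect_equal(unname(anc2[1]), 1)  # root midway by symmetry
  # root equals the GLS mean
  set.seed(8)
  tr <- ape::rcoal(8)
  x <- setNames(rnorm(8), tr$tip.label)
  C <- ape::vcv(tr)
  iC <- solve(C)
  gls_root <- sum(iC %*% x[rownames(C)]) / sum(iC)
  anc3 <- bm_ancestral_states(tr, x)
  expect_equal(unname(anc3[1]), unname(gls_root), tolerance = 1e-8)
  expect_error(bm_ancestral_states(ape::read.tree(text = "((A:0,B:1):1,C:2);"),
                                   c(A = 1, B = 2, C = 3)),
               "calibrate_mbl")
})

test_that("BM ancestral states match brute-force likelihood maximization", {
  set.seed(15)
  tr <- ape::rcoal(5)
  x <- setNames(c(0.3, -1.2, 2.0, 0.8, -0.5), tr$tip.label)
  anc <- bm_ancestral_states(tr, x)
  # oracle: minimize the sum of squared changes per unit branch duration
  obj <- function(v) {
    all_v <- c(x[tr$tip.label], v)
    sum((all_v[tr$edge[, 1]] - all_v[tr$edge[, 2]])^2 / tr$edge.length)
  }
  opt <- optim(rep(mean(x), tr$Nnode), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(anc), opt$par, tolerance = 1e-5)
})

test_that("tree-shape vector counts nodes to the root, blind to branch lengths", {
  bal <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  expect_equal(unname(phylo_vcv_and_tree_shape(bal)$tree_shape), rep(2L, 4))
  cat4 <- ape::read.tree(text = "(((A,B),C),D);")
  expect_equal(sort(unname(phylo_vcv_and_tree_shape(cat4)$tree_shape),
                    decreasing = TRUE), c(3L, 3L, 2L, 1L))
  # time-variant diagonal = root-to-tip durations
  v <- phylo_vcv_and_tree_shape(bal)
  expect_equal(diag(v$C_time)[c("A", "B", "C", "D")],
               c(A = 4, B = 5, C = 10, D = 11))
  scaled <- bal; scaled$edge.length <- bal$edge.length * 7
  expect_equal(phylo_vcv_and_tree_shape(scaled)$tree_shape, v$tree_shape)
})
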