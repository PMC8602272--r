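coords3 <- matrix(c(0, 0, 1, 2, 3, 1), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))

test_that("SoV and SoR match hand arithmetic", {
  expect_equal(metric_value(coords3, metric = "SoR"), 5)          # 3 + 2
  expect_equal(metric_value(coords3, metric = "SoV"), 10 / 3)     # 7/3 + 1
  expect_error(metric_value(coords3, "a", metric = "SoV"), ">= 2")
})

test_that("displacement is 1 against the own centroid and shifts with references", {
  expect_equal(metric_value(coords3, metric = "displacement",
                            reference = "own-centroid"), 1)
  # against a supplied distant reference the ratio must exceed 1 on average
  far <- metric_value(coords3, metric = "displacement", reference = "given",
                      reference_centroid = c(100, 100))
  expect_gt(far, 1)
  # rigid translation moving points and reference together changes nothing
  shifted <- sweep(coords3, 2, c(5, -2), `+`)
  expect_equal(metric_value(shifted, metric = "displacement",
                            reference = "given",
                            reference_centroid = c(105, 98)),
               far)
})

test_that("SoV and SoR are invariant to axis sign flips", {
  flipped <- coords3 %*% diag(c(-1, 1))
  rownames(flipped) <- rownames(coords3)
  expect_equal(metric_value(flipped, metric = "SoV"),
               metric_value(coords3, metric = "SoV"))
  expect_equal(metric_value(flipped, metric = "SoR"),
               metric_value(coords3, metric = "SoR"))
})

test_that("bootstrap intervals behave per metric tail rules", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("t", 1:20), NULL))
  g <- paste0("t", 1:12)
  sor <- bootstrap_ci(X, g, "SoR", n_boot = 399, seed = 8)
  expect_true(all(sor$replicates <= sor$value + 1e-12))
  expect_equal(sor$ci_upper, sor$value)
  expect_lte(sor$ci_lower, sor$value)
  sov <- bootstrap_ci(X, g, "SoV", n_boot = 399, seed = 8)
  expect_lte(sov$ci_lower, sov$value)
  expect_gte(sov$ci_upper, quantile(sov$replicates, 0.5, names = FALSE))
  # identical points: all resamples identical, degenerate interval
  Xc <- matrix(1, 6, 2, dimnames = list(paste0("t", 1:6), NULL))
  cst <- bootstrap_ci(Xc, paste0("t", 1:6), "SoV", n_boot = 99)
  expect_equal(c(cst$value, cst$ci_lower, cst$ci_upper), c(0, 0, 0))
  expect_error(bootstrap_ci(X, g, "SoV", n_boot = 100), "odd")
  expect_error(bootstrap_ci(X, g, "SoV", n_boot = 99, rarefy_to = 13),
               "exceeds group size")
})

test_that("rarefied bootstrap resamples at the rarefied size", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("t", 1:30), NULL))
  g <- paste0("t", 1:20)
  plain <- bootstrap_ci(X, g, "SoV", n_boot = 499, seed = 5)
  rare <- bootstrap_ci(X, g, "SoV", n_boot = 499, rarefy_to = 7, seed = 5)
  expect_equal(rare$rarefied_to, 7)
  expect_equal(rare$value, plain$value)  # point estimate never rarefied
  # smaller resamples -> wider spread of replicate values
  expect_gt(var(rare$replicates), var(plain$replicates))
})

test_that("WMPD bootstrap resamples taxa of the distance matrix", {
  sim <- simulate_dataset(simulation_config(n_tips = 14, n_characters = 50,
                                            seed = 6))
  d <- mord_matrix(sim$matrix)
  est <- bootstrap_ci(d, sim$matrix$taxa, "WMPD", n_boot = 199, seed = 2)
  expect_equal(est$value, wmpd(d))
  expect_true(est$ci_lower <= est$value && est$value <= est$ci_upper)
})

test_that("significance is CI disjointness with closed intervals", {
  mk <- function(lo, hi) structure(list(metric = "SoV", value = (lo + hi) / 2,
                                        ci_lower = lo, ci_upper = hi),
                                   class = "disparity_estimate")
  expect_true(ci_overlap_test(mk(1, 2), mk(3, 4))$significant)
  expect_false(ci_overlap_test(mk(1, 3), mk(2, 4))$significant)
  expect_false(ci_overlap_test(mk(1, 2), mk(2, 3))$significant)  # touching
  other <- mk(1, 2); other$metric <- "SoR"
  expect_error(ci_overlap_test(mk(1, 2), other), "different metrics")
})

test_that("PERMANOVA pseudo-F matches direct sums-of-squares arithmetic", {
  set.seed(9)
  X <- matrix(rnorm(48), 24, 2, dimnames = list(paste0("t", 1:24), NULL))
  g <- setNames(rep(c("u", "v"), each = 12), rownames(X))
  res <- permanova(X, g, n_perm = 199, seed = 1)
  expect_equal(res$F, brute_permanova_F(X, g), tolerance = 1e-10)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  # far-separated groups saturate significance at the permutation floor
  X2 <- X; X2[13:24, ] <- X2[13:24, ] + 50
  res2 <- permanova(X2, g, n_perm = 199, seed = 1)
  expect_equal(res2$p, 1 / 200)
  expect_error(permanova(X, setNames(c("u", rep("v", 23)), rownames(X))),
               "< 2 members")
})

test_that("metric diagnostics separate size and density from position", {
  set.seed(12)
  X <- matrix(rnorm(150 * 8), 150, 8,
              dimnames = list(paste0("p", 1:150), NULL))
  d <- metric_diagnostics(X, "SoV")
  s <- setNames(d$slope_standardized, d$reduction)
  expect_gt(s[["inner-size"]], 0)
  expect_lt(s[["outer-size"]], 0)
  gap_size <- abs(s[["inner-size"]] - s[["outer-size"]])
  gap_density <- abs(s[["higher-density"]] - s[["lower-density"]])
  gap_position <- abs(s[["top-position"]] - s[["bottom-position"]])
  expect_gt(gap_size, 2 * gap_position)
  expect_gt(gap_density, 2 * gap_position)
  # the full-sample end of every series is the unreduced metric
  expect_equal(unique(d$value_full), metric_value(X, metric = "SoV"))
  expect_error(metric_diagnostics(X[1:5, ], "SoV"), "too few")
})

test_that("character partitions preserve bookkeeping and reject bad maps", {
  m <- random_cm(6, 4, seed = 13)
  parts <- partition_characters(m, list(skull = 1:2, limb = 3:4))
  expect_named(parts, c("skull", "limb"))
  expect_equal(cm_n_characters(parts$skull), 2)
  # pairwise comparable weights add up across regions
  sim <- simulate_dataset(simulation_config(n_tips = 10, n_characters = 20,
                                            seed = 14))
  ps <- partition_characters(sim$matrix, list(a = 1:7, b = 8:20))
  expect_equal(mord_matrix(ps$a)$N + mord_matrix(ps$b)$N,
               mord_matrix(sim$matrix)$N)
  expect_error(partition_characters(m, list(a = 1:2, b = 2:4)), "twice")
  expect_error(partition_characters(m, list(a = 1:3)), "unassigned")
  expect_error(partition_characters(m, list(a = 1:4, b = integer(0))),
               "empty region")
})
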