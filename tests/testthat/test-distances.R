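test_that("MORD follows the per-character rescaled difference rule", {
  # A = {0},{1},?   B = {1},{1},{0}: one mismatch over two comparable chars
  m <- make_cm(list(A = list(0L, 1L, "?"), B = list(1L, 1L, 0L)))
  d <- mord_matrix(m)
  expect_equal(d$D["A", "B"], 0.5)
  expect_equal(d$N["A", "B"], 2)
  expect_equal(diag(d$D), c(A = 0, B = 0))
})

test_that("identical fully coded taxa are at distance zero", {
  m <- make_cm(list(A = list(0L, 1L, 2L), B = list(0L, 1L, 2L)))
  expect_equal(mord_matrix(m)$D["A", "B"], 0)
})

test_that("polymorphisms resolve to the closest member state", {
  m <- make_cm(list(A = list(c(0L, 1L)), B = list(1L)))
  expect_equal(mord_matrix(m)$D["A", "B"], 0)
  # ordered: min cross-set step distance, rescaled by the coded range
  m2 <- make_cm(list(A = list(0L), B = list(2L), C = list(3L)),
                ordering = "ordered")
  d2 <- mord_matrix(m2)
  expect_equal(d2$D["A", "B"], 2 / 3)  # range over matrix is 0..3
  expect_equal(d2$D["A", "C"], 1)
  # non-contiguous polymorphic set: {0,3} vs {2} -> min |a-b| = 1
  m3 <- make_cm(list(A = list(c(0L, 3L)), B = list(2L), C = list(0L)),
                ordering = "ordered")
  expect_equal(mord_matrix(m3)$D["A", "B"], 1 / 3)
})

test_that("inapplicable cells are non-comparable, like missing", {
  m <- make_cm(list(A = list(0L, "-"), B = list(1L, 1L)))
  d <- mord_matrix(m)
  expect_equal(d$N["A", "B"], 1)
  expect_equal(d$D["A", "B"], 1)
})

test_that("pairs with no shared scored characters are undefined", {
  m <- make_cm(list(A = list(0L, "?"), B = list("?", 1L), C = list(0L, 1L)))
  d <- mord_matrix(m)
  expect_true(is.na(d$D["A", "B"]))
  expect_equal(nrow(d$incomparable_pairs), 1)
  expect_setequal(as.vector(d$incomparable_pairs), c("A", "B"))
  expect_error(mord_matrix(cm_subset(m, taxa = "A")), "at least 2")
})

test_that("on complete binary matrices MORD equals simple matching mismatch", {
  for (s in 1:20) {
    m <- random_cm(6, 10, k = 2, seed = s)
    d <- mord_matrix(m)
    states <- matrix(vapply(m$codes, function(cd)
      cladospace:::decode_code(cd)[1], integer(1)), 6, 10)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(d$D[i, j], mean(states[i, ] != states[j, ]))
      expect_equal(d$N[i, j], 10)
    }
  }
})

test_that("character weights scale both numerator and comparable weight", {
  m <- make_cm(list(A = list(0L, 0L), B = list(1L, 0L)), weights = c(3, 1))
  d <- mord_matrix(m)
  expect_equal(d$N["A", "B"], 4)
  expect_equal(d$D["A", "B"], 3 / 4)
})

test_that("WMPD is the n_ij-weighted mean pairwise dissimilarity", {
  m <- make_cm(list(A = list(0L, 1L, "?"), B = list(1L, 1L, 0L)))
  d <- mord_matrix(m)
  expect_equal(wmpd(d), 0.5)
  # equal weights reduce WMPD to the plain mean of pairwise distances
  mc <- random_cm(6, 12, seed = 3)
  dc <- mord_matrix(mc)
  expect_equal(wmpd(dc), mean(dc$D[upper.tri(dc$D)]))
  # recomputation identity on a heterogeneous matrix
  sim <- simulate_dataset(simulation_config(n_tips = 15, n_characters = 50,
                                            seed = 9))
  ds <- mord_matrix(sim$matrix)
  ut <- upper.tri(ds$D)
  ok <- ut & !is.na(ds$D) & ds$N > 0
  expect_equal(wmpd(ds), sum(ds$N[ok] * ds$D[ok]) / sum(ds$N[ok]))
  expect_error(wmpd(ds, sim$matrix$taxa[1]), ">= 2 taxa")
})

test_that("dropping a character only changes D for pairs that scored it", {
  sim <- simulate_dataset(simulation_config(n_tips = 10, n_characters = 30,
                                            seed = 5))
  m <- sim$matrix
  d_full <- mord_matrix(m)
  drop_ch <- 7L
  d_red <- mord_matrix(cm_subset(m, characters = setdiff(1:30, drop_ch)))
  scored <- cm_is_scored(m)[, drop_ch]
  for (i in 1:9) for (j in (i + 1):10) {
    if (!(scored[i] && scored[j])) {
      expect_equal(d_red$D[i, j], d_full$D[i, j])
    }
  }
})

test_that("missing-data repulsion is detectable at study-like scale", {
  hits <- 0; n_rep <- 25
  for (s in seq_len(n_rep)) {
    set.seed(s)
    n <- 60; m <- 300
    codes <- matrix(ifelse(stats::runif(n * m) < 0.5, 1L, 2L), n, m)
    rates <- stats::runif(n, 0.3, 0.9)
    for (i in seq_len(n)) codes[i, stats::runif(m) < rates[i]] <- -1L
    xm <- cladospace:::new_clado_matrix(codes, sprintf("t%02d", seq_len(n)))
    d <- mord_matrix(xm)
    if (nrow(d$incomparable_pairs)) {
      tr <- trim_for_ordination(d, xm)
      d <- tr$dist
      xm <- cm_subset(xm, taxa = d$taxa)
    }
    bt <- missing_data_bias_test(d, xm)
    hits <- hits + (bt$r > 0)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("bias test errors on zero variance and is calibrated under the null", {
  m <- random_cm(8, 20, seed = 2)  # no missing data at all
  d <- mord_matrix(m)
  expect_error(missing_data_bias_test(d, m), "zero variance")
  # no association between masking and taxon: p should not pile up low
  set.seed(11)
  lows <- 0; n_rep <- 60
  for (s in seq_len(n_rep)) {
    n <- 20; mm <- 80
    codes <- matrix(ifelse(stats::runif(n * mm) < 0.5, 1L, 2L), n, mm)
    codes[stats::runif(n * mm) < 0.3] <- -1L  # uniform masking, same rate
    xm <- cladospace:::new_clado_matrix(codes, sprintf("t%02d", 1:n))
    d <- mord_matrix(xm)
    bt <- missing_data_bias_test(d, xm)
    lows <- lows + (bt$p < 0.05)
  }
  expect_lte(lows / n_rep, 0.15)
})
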