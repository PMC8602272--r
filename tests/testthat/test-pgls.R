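make_star_data <- function(n = 24, beta = 1.5, seed = 2) {
  set.seed(seed)
  taxa <- sprintf("t%02d", 1:n)
  x <- rnorm(n)
  y <- 1 + beta * x + rnorm(n)
  list(coords = matrix(y, ncol = 1, dimnames = list(taxa, "PCo1")),
       data = data.frame(taxon = taxa, log_body_mass = x,
                         continent = sample(letters[1:3], n, replace = TRUE)),
       star = ape::read.tree(text = paste0("(", paste0(taxa, ":1",
                                                       collapse = ","), ");")))
}

test_that("under identity covariance the fit equals ordinary least squares", {
  d <- make_star_data()
  fit <- dpgls_fit(d$coords, ~ log_body_mass, d$data, tree = NULL,
                   iterations = 49, seed = 1)
  ols <- lm(d$coords[, 1] ~ d$data$log_body_mass)
  expect_equal(fit$coefficients[, 1], coef(ols), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$table$SS, anova(ols)[1, "Sum Sq"], tolerance = 1e-8)
  expect_equal(fit$table$F, anova(ols)[1, "F value"], tolerance = 1e-8)
  expect_equal(fit$se[2, 1], summary(ols)$coefficients[2, 2],
               tolerance = 1e-8)
  # a star phylogeny with equal terminal branches is the same thing
  fit_star <- dpgls_fit(d$coords, ~ log_body_mass, d$data, tree = d$star,
                        iterations = 49, seed = 1)
  expect_equal(fit_star$table$SS, fit$table$SS, tolerance = 1e-8)
  expect_equal(fit_star$table$R2, fit$table$R2, tolerance = 1e-8)
})

test_that("confounded term combinations and singular designs are rejected", {
  d <- make_star_data()
  d$data$femoral_length <- exp(d$data$log_body_mass)
  d$data$circ_ratio <- runif(24)
  d$data$locomotion <- sample(c("biped", "quadruped"), 24, replace = TRUE)
  expect_error(dpgls_fit(d$coords, ~ log_body_mass + femoral_length, d$data),
               "body mass with femoral length")
  expect_error(dpgls_fit(d$coords, ~ locomotion + circ_ratio, d$data),
               "circumference ratio")
  d$data$dup <- d$data$log_body_mass
  expect_error(dpgls_fit(d$coords, ~ log_body_mass + dup, d$data),
               "singular design")
  expect_error(dpgls_fit(d$coords, ~ 1, d$data), "no terms")
})

test_that("taxa absent from the tree are an error", {
  d <- make_star_data()
  small <- ape::keep.tip(d$star, d$star$tip.label[1:20])
  expect_error(dpgls_fit(d$coords, ~ log_body_mass, d$data, tree = small),
               "absent from tree")
})

test_that("RRPP p-values are deterministic and sign-flip invariant", {
  d <- make_star_data()
  f1 <- dpgls_fit(d$coords, ~ log_body_mass, d$data, iterations = 199,
                  seed = 7)
  f2 <- dpgls_fit(d$coords, ~ log_body_mass, d$data, iterations = 199,
                  seed = 7)
  expect_identical(f1$table$p, f2$table$p)
  flipped <- -d$coords
  f3 <- dpgls_fit(flipped, ~ log_body_mass, d$data, iterations = 199,
                  seed = 7)
  expect_equal(f3$table$p, f1$table$p)
  expect_true(all(f1$table$p >= 1 / 200 & f1$table$p <= 1))
})

test_that("type II SS compare each term against all the others", {
  d <- make_star_data(n = 30, seed = 5)
  d$data$z <- rnorm(30)
  fit <- dpgls_fit(d$coords, ~ log_body_mass + z, d$data, iterations = 49,
                   seed = 1)
  full <- lm(d$coords[, 1] ~ d$data$log_body_mass + d$data$z)
  drop_mass <- lm(d$coords[, 1] ~ d$data$z)
  drop_z <- lm(d$coords[, 1] ~ d$data$log_body_mass)
  expect_equal(fit$table$SS[1],
               sum(resid(drop_mass)^2) - sum(resid(full)^2),
               tolerance = 1e-8)
  expect_equal(fit$table$SS[2],
               sum(resid(drop_z)^2) - sum(resid(full)^2), tolerance = 1e-8)
})

test_that("phylogenetic signal in residuals is absorbed by the transform", {
  # BM-correlated response on a real tree: GLS and OLS must differ,
  # and the GLS slope should stay closer to the truth on average
  set.seed(21)
  tr <- ape::rcoal(40)
  C <- ape::vcv(tr)
  L <- chol(C)
  taxa <- tr$tip.label
  x <- as.numeric(t(L) %*% rnorm(40))
  names(x) <- taxa
  y <- 0.8 * x + as.numeric(t(L) %*% rnorm(40)) * 0.5
  coords <- matrix(y, ncol = 1, dimnames = list(taxa, "PCo1"))
  dat <- data.frame(taxon = taxa, log_body_mass = x)
  fit <- dpgls_fit(coords, ~ log_body_mass, dat, tree = tr, iterations = 99,
                   seed = 2)
  expect_equal(unname(fit$coefficients[2, 1]), 0.8, tolerance = 0.35)
  fit_ols <- dpgls_fit(coords, ~ log_body_mass, dat, tree = NULL,
                       iterations = 99, seed = 2)
  expect_false(isTRUE(all.equal(fit$table$SS, fit_ols$table$SS)))
})

test_that("the model suite crosses models with trees deterministically", {
  d <- make_star_data()
  set.seed(4)
  rooted <- ape::rcoal(24, tip.label = sample(d$data$taxon))
  trees <- list(rooted, rooted, rooted)
  tab <- model_suite(list("~ log_body_mass", "~ continent"),
                     d$coords, d$data, trees, iterations = 49, seed = 3)
  expect_equal(nrow(tab), 6)  # 2 models x 3 trees, single-term each
  expect_setequal(unique(tab$tree), 1:3)
  # identical trees give identical per-model results
  one <- subset(tab, model == "~log_body_mass")
  expect_equal(one$R2, rep(one$R2[1], 3))
  tab2 <- model_suite(list("~ log_body_mass", "~ continent"),
                      d$coords, d$data, trees, iterations = 49, seed = 3)
  expect_identical(tab$p, tab2$p)
  expect_error(model_suite(list(), d$coords, d$data, trees), "empty model")
})
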