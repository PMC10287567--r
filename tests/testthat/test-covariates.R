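test_that("pc_regression matches hand least squares and its invariances", {
  # perfect fit on component 1, exactly orthogonal mean-zero noise elsewhere
  set.seed(1)
  n <- 40
  pcs <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  pcs <- sweep(pcs, 2, c(3, 1, 0.5), "*")
  got <- pc_regression(pcs, pcs[, 1])
  expect_equal(got, var(pcs[, 1]) / sum(apply(pcs, 2, var)), tolerance = 1e-9)
  # covariate against itself explains everything
  expect_equal(pc_regression(matrix(pcs[, 1]), pcs[, 1]), 1, tolerance = 1e-12)
  # 6-sample, 2-component fixture vs per-component lm()
  comp <- cbind(c(1, 2, 3, 4, 5, 7), c(2, 1, 4, 3, 6, 5))
  cv <- c(0, 0, 1, 1, 2, 2)
  want <- sum(vapply(1:2, function(j) {
    f <- lm(comp[, j] ~ cv)
    var(fitted(f))
  }, numeric(1))) / sum(apply(comp, 2, var))
  expect_equal(pc_regression(comp, cv), want, tolerance = 1e-9)
  # invariance to affine covariate rescaling and component permutation
  expect_equal(pc_regression(pcs, 3 * pcs[, 1] - 7), got, tolerance = 1e-9)
  expect_equal(pc_regression(pcs[, c(3, 1, 2)], pcs[, 1]), got,
               tolerance = 1e-9)
  # categorical covariates are dummy-encoded
  grp <- rep(c("a", "b", "c", "d"), 10)
  expect_equal(pc_regression(pcs, grp),
               sum(vapply(1:3, function(j) var(fitted(lm(pcs[, j] ~ grp))),
                          numeric(1))) / sum(apply(pcs, 2, var)),
               tolerance = 1e-9)
  # noise covariate explains roughly the dummy-count baseline
  set.seed(2)
  base <- mean(replicate(30, pc_regression(pcs, rnorm(n))))
  expect_lt(abs(base - 1 / (n - 1)), 3 / n)
  expect_error(pc_regression(pcs, rep(1, n)), "single-valued")
  expect_error(pc_regression(pcs[1:2, ], c(1, 2)), "at least 3")
})

test_that("shuffle-null splitting detects planted structure, not noise", {
  set.seed(3)
  n <- 60
  batch <- rep(c("v2", "v3"), each = n / 2)
  pcs <- matrix(rnorm(n * 5), n, 5)
  pcs[batch == "v3", 1] <- pcs[batch == "v3", 1] + 4  # dominant axis
  res <- shuffle_null_split(pcs, batch, seed = 1)
  expect_true(res$split)
  expect_gt(res$observed, res$null_mean + 1.5 * res$null_sd)
  # a covariate randomized at generation rarely splits
  false_splits <- vapply(1:40, function(s) {
    set.seed(100 + s)
    shuffle_null_split(matrix(rnorm(n * 5), n, 5),
                       sample(batch), seed = s)$split
  }, logical(1))
  expect_lte(mean(false_splits), 0.125)  # ~5% rate, binomial slack at n=40
  expect_error(shuffle_null_split(pcs, batch, n_shuffles = 0), "n_shuffles")
  expect_error(shuffle_null_split(pcs, rep("v2", n)), "two levels")
})

test_that("covariate dependence covers continuous, NMI and phi branches", {
  set.seed(4)
  x <- rnorm(300)
  expect_equal(covariate_dependence(x, x), 1, tolerance = 1e-9)
  expect_equal(covariate_dependence(x, 2 * x + 1), 1, tolerance = 1e-9)
  # independent uniforms near zero
  expect_lt(covariate_dependence(runif(1000), runif(1000)), 0.12)
  # continuous vs categorical equals sqrt R^2 of the regression
  g <- rep(c("a", "b", "c"), 100)
  y <- as.numeric(factor(g)) + rnorm(300, sd = 0.5)
  expect_equal(covariate_dependence(y, g),
               sqrt(summary(lm(y ~ g))$r.squared), tolerance = 1e-9)
  # 2x2 table with known phi
  a <- rep(c("x", "x", "z", "z"), c(30, 10, 5, 25))
  b <- rep(c("p", "q", "p", "q"), c(30, 10, 5, 25))
  tab <- matrix(table(a, b), 2, 2)
  phi <- abs((tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
               sqrt(prod(rowSums(tab)) * prod(colSums(tab))))
  expect_equal(covariate_dependence(a, b), phi, tolerance = 1e-9)
  # multi-level categorical pair: identical factors -> NMI 1
  m <- rep(c("a", "b", "c"), times = c(40, 30, 30))
  expect_equal(covariate_dependence(m, m), 1, tolerance = 1e-9)
  expect_error(covariate_dependence(1:2, 1:2), "3 complete pairs")
})

test_that("covariate encodings use the published anchors", {
  sm <- data.frame(smoking = c("never", "former", "current"),
                   age = c(25, 64, 44.5),
                   bmi = c(21.32, 36.86, 29.09),
                   location = c("inferior_turbinate", "trachea",
                                "alveolar_sac"),
                   sex = c("male", "female", "female"))
  sm$ccf_score <- ccf_score(sm$location)
  enc <- encode_covariates(sm)
  expect_equal(enc$smoking, c(0, 0.5, 1))
  expect_equal(enc$age, c(0, 1, 0.5))
  expect_equal(enc$bmi, c(0, 1, 0.5), tolerance = 1e-9)
  expect_equal(enc$nasal, c(1, 0, 0))
  expect_equal(enc$ccf_score, sm$ccf_score)
  expect_error(encode_covariates(data.frame(smoking = "vaper")), "unknown")
})

test_that("VIF screening matches the closed form and flags collinearity", {
  set.seed(5)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  x3 <- rnorm(n)
  fr <- data.frame(x1, x2, x3)
  got <- vif_screen(fr)
  for (j in 1:3) {
    r2 <- summary(lm(fr[[j]] ~ ., data = fr[-j]))$r.squared
    expect_equal(unname(got$vif[j]), 1 / (1 - r2), tolerance = 1e-6)
  }
  expect_true(got$include)
  # orthonormal mean-zero covariates -> VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  expect_equal(unname(vif_screen(q)$vif), rep(1, 3), tolerance = 1e-9)
  # duplicated covariate -> infinite VIF, exclude
  dup <- vif_screen(data.frame(x1, x1b = x1, x3))
  expect_true(any(is.infinite(dup$vif)))
  expect_false(dup$include)
  expect_error(vif_screen(data.frame(x1)), "at least 2")
})

test_that("variance report masks undersampled and single-valued entries", {
  fix <- small_sim()
  sim <- fix$sim
  types <- sim$truth$cells$true_leaf
  # 12 samples in the fixture: a 40-sample minimum masks everything
  vr <- variance_report(sim$atlas, sim$embedding, types,
                        covariates = c("age", "bmi"), min_samples = 40)
  expect_true(all(is.na(vr$fractions)))
  expect_true(all(vr$mask[vr$n_samples < 40] == "insufficient_samples"))
  # single-valued covariate masked with its reason code
  at <- sim$atlas
  at$sample_meta$constant <- 1
  vr2 <- variance_report(at, sim$embedding, types,
                         covariates = c("age", "constant"), min_samples = 5)
  expect_true(all(vr2$mask[, "constant"] %in%
                    c("single_valued", "insufficient_samples")))
  expect_true(any(!is.na(vr2$fractions[, "age"])))
  expect_true(all(vr2$fractions[!is.na(vr2$fractions)] >= 0 &
                    vr2$fractions[!is.na(vr2$fractions)] <= 1))
})
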