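test_that("Spearman screen is rank-exact and flags constant predictors", {
  set.seed(71)
  f <- rnorm(40)
  p <- cbind(mono = exp(2 * f), noise = rnorm(40), const = rep(3, 40))
  expect_warning(res <- spearman_assoc(f, p), "constant")
  expect_equal(res$rs[res$predictor == "mono"], 1)
  expect_lt(res$p_rs[res$predictor == "mono"], 1e-10)
  expect_equal(res$rs[res$predictor == "const"], 0)
  expect_equal(res$p_rs[res$predictor == "const"], 1)
  expect_true(all(res$q_rs >= res$p_rs - 1e-15))

  # invariance to strictly monotone transforms of the feature
  res2 <- suppressWarnings(spearman_assoc(rank(f)^3, p))
  expect_equal(res2$rs, res$rs)

  expect_error(spearman_assoc(f[1:4], p[1:4, ]), class = "too_few_cells")
})

test_that("t-approximation p-values are calibrated under the null", {
  set.seed(72)
  n <- 40; reps <- 2000
  pv <- vapply(seq_len(reps), function(i) {
    spearman_assoc(rnorm(n), matrix(rnorm(n), n, 1))$p_rs
  }, numeric(1))
  expect_equal(mean(pv < 0.05), 0.05, tolerance = 0.3)

  # permutation mode agrees with the t-approximation at moderate rs
  set.seed(73)
  f <- rnorm(30); x <- matrix(0.5 * f + rnorm(30), 30, 1)
  pt_ <- spearman_assoc(f, x)$p_rs
  pp <- spearman_assoc(f, x, method = "permutation", n_perm = 4000)$p_rs
  expect_equal(pp, pt_, tolerance = 0.5)
})

test_that("AIC selection recovers a planted predictor with accurate beta", {
  set.seed(74)
  X <- matrix(rnorm(40 * 10), 40, 10)
  colnames(X) <- sprintf("x%02d", 1:10)
  y <- as.numeric(2 * X[, 3])  # sigma -> 0
  for (strat in c("exhaustive", "stepwise")) {
    fit <- suppressWarnings(aic_select(y, X, strat))
    expect_identical(fit$selected, "x03")
    b <- fit$coefficients$beta[fit$coefficients$predictor == "x03"]
    expect_equal(b, 2, tolerance = 0.05)
  }
})

test_that("exhaustive and stepwise agree on strong-signal instances", {
  set.seed(75)
  for (i in 1:15) {
    X <- matrix(rnorm(40 * 10), 40, 10)
    colnames(X) <- sprintf("x%02d", 1:10)
    tru <- sort(sample(10, sample(1:3, 1)))
    beta <- runif(length(tru), 1, 3)
    y <- as.numeric(X[, tru, drop = FALSE] %*% beta)
    a <- suppressWarnings(aic_select(y, X, "exhaustive"))
    b <- suppressWarnings(aic_select(y, X, "stepwise"))
    expect_identical(sort(a$selected), sort(b$selected))
    expect_identical(sort(match(a$selected, colnames(X))), tru)
  }
})

test_that("the full-set OLS report matches the normal-equations oracle", {
  set.seed(76)
  X <- matrix(rnorm(50 * 4), 50, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(50, 0, 0.2)
  fit <- aic_select(y, X, "exhaustive")
  expect_identical(sort(fit$selected), paste0("v", 1:4))
  beta_hat <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  got <- fit$coefficients$beta[match(c("intercept", paste0("v", 1:4)),
                                     fit$coefficients$predictor)]
  expect_equal(got, as.numeric(beta_hat), tolerance = 1e-8)

  # model-level stats: F-test p equals the F distribution tail by hand
  sm <- summary(lm(y ~ X))
  r2 <- sm$r.squared; k <- 4; n <- 50
  f_hand <- (r2 / k) / ((1 - r2) / (n - k - 1))
  expect_equal(fit$f_stat, f_hand, tolerance = 1e-8)
  expect_equal(fit$p_model, pf(f_hand, k, n - k - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lte(fit$r2_adj, r2)
})

test_that("collinear selections are repaired by dropping aliased columns", {
  # AIC's smaller-model tie preference never co-selects duplicated columns,
  # so exercise the repair path on a forced collinear design directly
  set.seed(77)
  x1 <- rnorm(30)
  X <- cbind(a = x1, b = x1, c = rnorm(30))  # a and b identical
  y <- 2 * x1 + rnorm(30, 0, 0.01)
  expect_warning(fit <- burstlink:::fit_ols_report(y, X, 1:3),
                 "collinear|aliased")
  expect_true("a" %in% fit$selected)
  expect_false("b" %in% fit$selected)
  expect_true("c" %in% fit$selected)

  # selection itself prefers the smaller non-collinear model silently
  fit2 <- aic_select(y, X, "exhaustive")
  expect_false(all(c("a", "b") %in% fit2$selected))
})

test_that("gene panel association restricts the family and validates the panel", {
  set.seed(78)
  n <- 40
  f <- rnorm(n)
  z <- matrix(rnorm(n * 6), n, 6)
  colnames(z) <- c("Slmap", "Scn1a", "Scn1b", "Scn2b", "Scn3b", "Nedd4l")
  z[, "Slmap"] <- rank(f) + rnorm(n, 0, 1e-9)  # monotone in the feature

  res <- gene_panel_association(f, z, c("Slmap", "Scn1a", "Scn2b"))
  tab <- res$table
  expect_equal(nrow(tab), 3)  # BH family = panel size
  expect_equal(tab$rs[tab$predictor == "Slmap"], 1)
  expect_true(tab$selected[tab$predictor == "Slmap"])
  expect_gt(tab$beta[tab$predictor == "Slmap"], 0)

  expect_warning(res2 <- gene_panel_association(f, z, c("Slmap", "NotAGene")),
                 "absent")
  expect_equal(nrow(res2$table), 1)
  expect_error(suppressWarnings(gene_panel_association(f, z, "NotAGene")),
               class = "empty_panel")

  # 11 null genes: no detections at q < 0.05 in a seeded instance
  set.seed(79)
  zn <- matrix(rnorm(n * 11), n, 11)
  colnames(zn) <- paste0("null", 1:11)
  res3 <- gene_panel_association(rnorm(n), zn, colnames(zn))
  expect_lte(sum(res3$table$q_rs < 0.05), 1)
})

test_that("feature_association combines screen and regression coherently", {
  set.seed(80)
  n <- 40
  lat <- rnorm(n)
  M <- cbind(m1 = lat + rnorm(n, 0, 0.4), m2 = rnorm(n), m3 = rnorm(n))
  f <- 2 * lat + rnorm(n, 0, 0.3)
  res <- feature_association(f, M)
  expect_true(res$table$selected[res$table$predictor == "m1"])
  expect_equal(res$table$beta[res$table$predictor == "m1"],
               res$model$coefficients$beta[res$model$coefficients$predictor == "m1"])
  expect_gt(res$model$r2_adj, 0.5)
  expect_lte(res$model$r2_adj, 1)
})
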