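test_that("group-mean imputation fills gaps without touching observed values", {
  m <- matrix(c(1, NA, 3, 5, 6, NA), nrow = 1)
  colnames(m) <- paste0("s", 1:6)
  groups <- rep(c("a", "b"), each = 3)
  out <- impute_group_mean(m, groups)
  expect_equal(out[1, ], c(s1 = 1, s2 = 2, s3 = 3, s4 = 5, s5 = 6, s6 = 5.5))
  # identity on complete data
  full <- matrix(rnorm(12), 3, 4)
  expect_equal(impute_group_mean(full, rep(c("a", "b"), 2)), full)
  # group means preserved exactly by construction
  set.seed(2)
  mm <- matrix(rnorm(40), 4, 10)
  rownames(mm) <- paste0("g", 1:4)
  colnames(mm) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  mm_na <- mm
  mm_na[cbind(c(1, 2, 4), c(2, 7, 9))] <- NA
  imp <- impute_group_mean(mm_na, g)
  for (gi in 1:4) {
    for (gr in c("a", "b")) {
      expect_equal(mean(imp[gi, g == gr]),
                   mean(mm_na[gi, g == gr], na.rm = TRUE))
    }
  }
  bad <- mm
  bad[1, g == "a"] <- NA
  expect_error(impute_group_mean(bad, g), "g1")
})

test_that("scree elbow retains components before the sharpest flattening", {
  expect_identical(retain_components(c(5.8, 1.3, 0.4, 0.3, 0.2)), 2L)
  expect_identical(retain_components(c(5, 1, 0.5), rule = "fixed", k = 2), 2L)
  expect_warning(r <- retain_components(rep(1, 5)), "undefined")
  expect_identical(r, 2L)
  expect_error(retain_components(c(3, 1), rule = "fixed", k = 5), "exceeds")
  expect_identical(
    retain_components(c(6, 2, 1, 1) / 10 * 10, rule = "proportion",
                      min_prop = 0.15),
    2L
  )
})

test_that("correlation-matrix PCA satisfies rank, orthogonality and eigen-sum identities", {
  set.seed(6)
  # two perfectly correlated genes: one component carries all variance
  base <- rnorm(20)
  m <- rbind(g1 = base, g2 = 2 * base + 3)
  colnames(m) <- paste0("s", 1:20)
  p <- fit_pca(m, rule = "fixed", k = 1)
  expect_equal(p$var_explained[1], 1)
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-12)
  # eigenvalues of the correlation matrix sum to the number of genes
  mm <- matrix(2^rnorm(5 * 30), 5, 30,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  pm <- fit_pca(log2(mm), rule = "fixed", k = 3)
  expect_equal(sum(pm$eigenvalues), 5)
  # scores are uncorrelated across retained components and unit variance
  sc <- as.matrix(pm$scores[, -1])
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 3))
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # communalities bounded by 1
  expect_true(all(pm$communalities <= 1 + 1e-8))
  # near-independent genes at large n: flat variance profile
  big <- matrix(rnorm(6 * 4000), 6, 4000,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:4000)))
  pb <- fit_pca(big, rule = "fixed", k = 2)
  expect_equal(max(pb$var_explained), 1 / 6, tolerance = 0.05)
})

test_that("PCA sign convention makes the top-loading gene positive", {
  set.seed(7)
  m <- matrix(rnorm(4 * 12), 4, 12,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  p <- fit_pca(m, rule = "fixed", k = 2)
  for (j in 1:2) {
    l <- p$loadings[[paste0("PC", j)]]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("singular case (more genes than cases) is flagged and scored via pseudo-inverse", {
  set.seed(10)
  m <- matrix(2^rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:8)))
  p <- fit_pca(log2(m), rule = "fixed", k = 2)
  expect_true(p$singular)
  expect_equal(nrow(p$scores), 8)
  expect_false(anyNA(p$scores))
})

test_that("two-group MANOVA matches stats::manova and the Hotelling transform", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 14
    g <- rep(c("a", "b"), each = n / 2)
    x <- cbind(rnorm(n, ifelse(g == "a", 0, 1)), rnorm(n), rnorm(n, 0, 2))
    got <- manova_two_group(x, g)
    fit <- summary(stats::manova(x ~ factor(g)), test = "Wilks")
    stats_row <- fit$stats[1, ]
    expect_equal(got$wilks_lambda, unname(stats_row["Wilks"]),
                 tolerance = 1e-10)
    expect_equal(got$F, unname(stats_row["approx F"]), tolerance = 1e-10)
    expect_equal(got$p, unname(stats_row["Pr(>F)"]), tolerance = 1e-10)
  }
  # p = 1 reduction: single component equals univariate ANOVA F
  y <- rnorm(10, rep(c(0, 2), each = 5))
  g <- rep(c("a", "b"), each = 5)
  got1 <- manova_two_group(matrix(y), g)
  a1 <- anova(lm(y ~ factor(g)))
  expect_equal(got1$F, a1$`F value`[1], tolerance = 1e-10)
})

test_that("eta squared follows F df1 / (F df1 + df2)", {
  expect_equal(round(eta_squared_from_F(12.75, 1, 8), 3), 0.614)
  expect_equal(round(eta_squared_from_F(3.81, 1, 8), 3), 0.323)
  expect_equal(eta_squared_from_F(0, 1, 8), 0)
})

test_that("hierarchical regression satisfies the single-predictor identities", {
  # closed-form identities on printed-style F values
  expect_equal(round(42.50 / (42.50 + 6), 3), 0.876)
  expect_equal(round(15.04 / (15.04 + 7), 3), 0.682)
  expect_equal(round(sqrt(42.50 / (42.50 + 6)), 3), 0.936)
  expect_equal(round(sqrt(15.04 / (15.04 + 7)), 3), 0.826)
  set.seed(19)
  for (rep in 1:5) {
    n <- 10
    g <- rep(c("control", "case"), each = n / 2)
    cv <- sample(c("yes", "no"), n, replace = TRUE)
    y <- rnorm(n) + 2 * (g == "case")
    res <- hierarchical_regression(y, g, cv)
    # R2 = F df1 / (F df1 + df2) and |beta| = sqrt(R2) for one predictor
    expect_equal(res$r2_model1,
                 eta_squared_from_F(res$f_model1, 1, res$df2_m1))
    expect_equal(abs(res$beta_group_m1), sqrt(res$r2_model1))
    expect_gte(res$r2_model2, res$r2_model1 - 1e-12)
    # F-change agrees with anova() model comparison
    zg <- as.numeric(factor(g)) - 1
    zc <- as.numeric(cv == "yes")
    if (sd(zc) > 0 && abs(cor(zg, zc)) < 1 - 1e-10) {
      m1 <- lm(scale(y) ~ scale(zg))
      m2 <- lm(scale(y) ~ scale(zg) + scale(zc))
      av <- anova(m1, m2)
      expect_equal(res$f_change, av$F[2], tolerance = 1e-8)
      expect_equal(res$p_change, av$`Pr(>F)`[2], tolerance = 1e-8)
    }
  }
})

test_that("a covariate identical to group is flagged as collinear with zero R2 gain", {
  g <- rep(c("control", "case"), each = 4)
  cv <- ifelse(g == "case", "yes", "no")
  y <- rnorm(8) + (g == "case")
  res <- hierarchical_regression(y, g, cv)
  expect_true(res$collinear)
  expect_equal(res$delta_r2, 0)
  expect_equal(res$p_change, 1)
})

test_that("unknown covariate entries follow the selected policy", {
  g <- rep(c("control", "case"), each = 5)
  cv <- c("no", "no", "unknown", "no", "no",
          "yes", "yes", "unknown", "yes", "no")
  set.seed(3)
  y <- rnorm(10) + (g == "case")
  absent <- hierarchical_regression(y, g, cv, unknown = "absent")
  dropped <- hierarchical_regression(y, g, cv, unknown = "drop")
  expect_equal(absent$n, 10)
  expect_equal(dropped$n, 8)
})

test_that("module scoring separates groups on a planted-module cohort", {
  cfg <- cohort_config(seed = 42)
  coh <- simulate_cohort(cfg)
  de <- run_de(coh)
  mod <- module_scores(coh, de, q_threshold = 0.2)
  expect_s3_class(mod$pca, "pca_model")
  expect_lt(mod$manova$p, 0.05)
  expect_equal(nrow(mod$anova), mod$pca$n_retained)
  expect_true(all(mod$anova$eta_squared >= 0 & mod$anova$eta_squared < 1))
  expect_equal(nrow(mod$regression), mod$pca$n_retained)
  td <- tidy(mod)
  expect_true(all(c("component", "F", "eta_squared", "delta_r2") %in% names(td)))
})

test_that("component-1 separation strengthens with planted effect size", {
  etas <- vapply(c(0.6, 1.8), function(fc_mult) {
    genes <- sprintf("G%03d", 1:12)
    fc <- stats::setNames(rep(2^(fc_mult * 0.45), 12), genes)
    cfg <- cohort_config(
      n_per_group = 5, n_genes = 12,
      modules = list(list(genes = genes, loading = 0.7)),
      planted_fc = fc, noise_sd = 0.45,
      missing_rate = 0, outlier_rate = 0, seed = 9
    )
    coh <- simulate_cohort(cfg)
    de <- run_de(coh, outlier_rule = "none")
    mod <- module_scores(coh, de, q_threshold = 1, rule = "fixed", k = 1)
    mod$anova$eta_squared[1]
  }, numeric(1))
  expect_gt(etas[2], etas[1])
})
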