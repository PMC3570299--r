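test_that("OLS matches closed-form solutions on toy data", {
  # exact linear relation: slope recovered with zero standard error
  fit <- ols_fit(3 + 2 * (1:10), 1:10)
  expect_equal(fit$beta, 2)
  expect_lt(fit$se, 1e-10)
  # textbook three-point case: slope Sxy/Sxx = 3/2
  fit2 <- ols_fit(c(1, 3, 4), c(0, 1, 2))
  expect_equal(fit2$beta, 1.5)
  expect_equal(fit2$n, 3L)
  # duplicated exposure as covariate is rank-deficient, named in the error
  expect_error(ols_fit(rnorm(10), 1:10, data.frame(dup = 1:10)),
               "rank-deficient.*dup")
  expect_error(ols_fit(rnorm(3), rnorm(3), data.frame(a = rnorm(3), b = rnorm(3))),
               "too few complete cases")
})

test_that("OLS equals the brute-force two-variable solution on random small cases", {
  set.seed(131)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    fit <- ols_fit(y, x)
    # closed form: beta = Sxy/Sxx, se from residual variance on n-2 df
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    res <- y - a - b * x
    se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
    expect_equal(fit$beta, b, tolerance = 1e-10)
    expect_equal(fit$se, se, tolerance = 1e-10)
    expect_equal(fit$ci_lo, b - 1.96 * se, tolerance = 1e-10)
    expect_equal(fit$p_value, 2 * pt(abs(b / se), n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("listwise deletion drops incomplete rows and reports n used", {
  y <- c(1, 2, NA, 4, 5, 6, 7, 8)
  x <- c(1, 2, 3, NA, 5, 6, 7, 8)
  fit <- ols_fit(y, x)
  expect_equal(fit$n, 6L)
})

test_that("single-SNP scans fit every polymorphic variant additively", {
  cat38 <- the_catalog()
  co <- generate_cohort(lean_config(n_duos = 500, seed = 141))
  # inject a strong additive effect at one SNP
  y <- 100 + 3 * co$children[, "rs7903146"] + rnorm(500, 0, 2)
  scan <- single_snp_scan(co$children, y)
  expect_true("rs7903146" %in% scan$exposure)
  hit <- scan[scan$exposure == "rs7903146", ]
  expect_equal(hit$beta, 3, tolerance = 0.15)
  expect_equal(scan$exposure[which.min(scan$p_value)], "rs7903146")
  expect_equal(attr(scan, "bonferroni")$display, 0.001)
  # monomorphic column is skipped with a reason, not an error
  g2 <- cbind(co$children, mono = rep(0L, 500))
  scan2 <- single_snp_scan(g2, y)
  expect_equal(attr(scan2, "skipped")$rsid, "mono")
  expect_equal(nrow(scan2), 38L)
})

test_that("null scans show nominal type-I calibration", {
  co <- generate_cohort(lean_config(n_duos = 400, seed = 142))
  set.seed(143)
  y <- rnorm(400)
  scan <- single_snp_scan(co$children, y)
  frac <- mean(scan$p_value < 0.05)
  expect_lt(frac, 0.2)  # 38 SNPs: a loose binomial bound on 5% rate
})

test_that("confounder scans count tests and expected nominal hits", {
  # synthetic independent grids with known dimensions
  set.seed(151)
  n <- 150
  expos <- as.data.frame(matrix(rbinom(n * 38, 2, 0.3), ncol = 38))
  names(expos) <- paste0("snp", 1:38)
  covs <- data.frame(matrix(rnorm(n * 13), ncol = 13))
  covs$sexf <- factor(sample(c("f", "m"), n, TRUE))
  covs$bf <- factor(sample(letters[1:4], n, TRUE))
  res <- confounder_scan(expos, covs)
  expect_equal(res$n_tests, 570L)
  expect_equal(res$expected_nominal, 29)
  expect_equal(sort(unique(res$grid$test)), c("chisq", "linear"))

  res35 <- confounder_scan(expos[, 1:35], covs)
  expect_equal(res35$n_tests, 525L)
  expect_equal(res35$expected_nominal, 26)
  # null data: observed fraction near alpha
  expect_lt(abs(res$observed_fraction - 0.05), 0.04)
  # constant columns are untestable and excluded from the denominator
  covs$const <- 1
  res2 <- confounder_scan(expos[, 1:2], covs)
  expect_equal(res2$n_tests, 30L)
  expect_equal(nrow(res2$untestable), 2L)
})

test_that("expected-count rounding is half away from zero", {
  expect_equal(round_half_away(28.5), 29)
  expect_equal(round_half_away(26.25), 26)
  expect_equal(round_half_away(0.05 * 100), 5)
  expect_equal(round_half_away(-28.5), -29)
  expect_equal(round_half_away(2.345, 2), 2.35)
})

test_that("maternal-vs-offspring adjustment separates transmission from direct effects", {
  cat38 <- the_catalog()
  t2d <- build_definition(cat38, "t2d")
  # pure offspring effect: unadjusted maternal slope inflated via the ~0.5
  # mother-child score correlation, adjusted slope near zero
  reps <- 40
  unadj <- adj <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(lean_config(
      n_duos = 800, seed = 160 + r,
      iq_model = list(mean = 104.4, sd = 16.4, beta_maternal = 0,
                      beta_offspring = 0.8, score = "t2d",
                      diabetes_effect = 0, confounder_effects = list())))
    sm <- compute_score(co$mothers, t2d, cat38)$score
    sc <- compute_score(co$children, t2d, cat38)$score
    fit <- maternal_effect_fit(co$phenotypes$iq, sm, sc)
    unadj[r] <- fit$beta[fit$model == "unadjusted"]
    adj[r] <- fit$beta[fit$model == "adjusted"]
  }
  expect_gt(mean(unadj), 0.25)            # transmission-induced bias, ~0.5*0.8
  expect_lt(abs(mean(adj)), 3 * sd(adj) / sqrt(reps))
  # constant maternal score cannot be fitted
  expect_error(maternal_effect_fit(rnorm(50), rep(1, 50), rnorm(50)),
               "rank-deficient")
})

test_that("WHO diabetes rule fires at the exact thresholds", {
  expect_true(classify_diabetes(7.0, 5.0))
  expect_false(classify_diabetes(6.99, 6.49))
  expect_false(classify_diabetes(4.95, 4.91))
  expect_true(classify_diabetes(NA, 6.5))
  expect_true(classify_diabetes(7.2, NA))
  expect_identical(classify_diabetes(NA_real_, NA_real_), NA)
  expect_equal(classify_diabetes(c(7.0, 5.0), c(5.0, 5.0)), c(TRUE, FALSE))
})

test_that("glycosuria requires two qualifying occasions", {
  expect_true(classify_glycosuria(c(14.0, 14.2)))
  expect_false(classify_glycosuria(14.0))
  expect_false(classify_glycosuria(c(13.8, 13.8, 13.8)))
  expect_true(classify_glycosuria(c(13.9, 13.9)))       # boundary inclusive
  expect_true(classify_glycosuria(c(250, 251), unit = "mg/dl"))
  expect_equal(classify_glycosuria(list(c(14, 14), 14)), c(TRUE, FALSE))
  expect_error(classify_glycosuria(NA_real_), "at least one occasion")
})

test_that("glucose unit conversion uses the molar-mass constant", {
  expect_equal(round(mgdl_to_mmoll(250), 1), 13.9)
  expect_equal(mgdl_to_mmoll(0), 0)
  expect_equal(mgdl_to_mmoll(180.16), 10)
  expect_error(mgdl_to_mmoll(-1), "negative")
})

test_that("diabetes categories are mutually exclusive with fixed precedence", {
  res <- diabetes_category(c(TRUE, FALSE, FALSE, FALSE),
                           c(TRUE, TRUE, FALSE, FALSE),
                           c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(as.character(res$category),
               c("pre_existing", "gestational", "glycosuria", "none"))
  expect_equal(res$exposed, c(1L, 1L, 1L, 0L))
  # pure function: permuting inputs permutes outputs identically
  idx <- c(3, 1, 4, 2)
  res2 <- diabetes_category(c(TRUE, FALSE, FALSE, FALSE)[idx],
                            c(TRUE, TRUE, FALSE, FALSE)[idx],
                            c(FALSE, TRUE, TRUE, FALSE)[idx])
  expect_equal(as.character(res2$category), as.character(res$category)[idx])
})
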