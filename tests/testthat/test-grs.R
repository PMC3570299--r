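test_that("score definitions carry the published terms and constants", {
  cat38 <- the_catalog()
  fg <- build_definition(cat38, "fasting_glucose")
  t2 <- build_definition(cat38, "t2d")
  expect_equal(fg$scale, 16L)
  expect_equal(fg$denominator, 0.474)
  expect_equal(fg$audit$weight_sum, 0.474)
  expect_equal(t2$scale, 22L)
  expect_equal(t2$denominator, 2.86)          # published constant
  expect_equal(t2$audit$weight_sum, 2.89)     # actual sum of printed weights
  expect_length(intersect(fg$terms$rsid, t2$terms$rsid), 8L)
  # excluded variants never enter either score
  excluded <- c("rs12255372", "rs2237892", "rs1501299", "rs17300539",
                "rs266729", "rs12779790", "rs20417", "rs9939609")
  expect_length(intersect(excluded, c(fg$terms$rsid, t2$terms$rsid)), 0L)
  # the consistent-denominator variant substitutes the true sum
  t2c <- build_definition(cat38, "t2d", consistent_denominator = TRUE)
  expect_equal(t2c$denominator, 2.89)
})

test_that("score computation matches hand arithmetic", {
  cat38 <- the_catalog()
  fg <- build_definition(cat38, "fasting_glucose")
  rsids <- fg$terms$rsid
  # risk-allele homozygote everywhere: minor-allele counts depend on orientation
  orient <- cat38$risk_orientation[match(rsids, cat38$rsid)]
  all_risk2 <- toy_genotypes(ifelse(orient == "minor", 2, 0), rsids)
  expect_equal(compute_score(all_risk2, fg, cat38)$score, 32)
  # heterozygote everywhere: orientation-invariant midpoint
  all_het <- toy_genotypes(rep(1, 16), rsids)
  expect_equal(compute_score(all_het, fg, cat38)$score, 16)
  # two risk alleles at rs560887 only: (2*0.075/0.474)*16
  one_term <- toy_genotypes(ifelse(orient == "minor", 0, 2), rsids)
  one_term[, "rs560887"] <- 0L  # risk allele is major: count 0 = 2 risk alleles
  base <- toy_genotypes(ifelse(orient == "minor", 0, 2), rsids)
  expect_equal(compute_score(base, fg, cat38)$score, 0)
  expect_equal(compute_score(one_term, fg, cat38)$score,
               2 * 0.075 / 0.474 * 16, tolerance = 1e-12)
  expect_equal(round(compute_score(one_term, fg, cat38)$score, 3), 5.063)
})

test_that("missing-genotype policies behave as documented", {
  cat38 <- the_catalog()
  rsids <- build_definition(cat38, "fasting_glucose")$terms$rsid
  g <- toy_genotypes(rep(1, 32), rsids)          # two individuals, all het
  g[2, "rs560887"] <- NA_integer_

  zf <- build_definition(cat38, "fasting_glucose", "zero_fill")
  cc <- build_definition(cat38, "fasting_glucose", "complete_case")
  rn <- build_definition(cat38, "fasting_glucose", "renormalize")

  s_zf <- compute_score(g, zf, cat38)
  s_cc <- compute_score(g, cc, cat38)
  s_rn <- compute_score(g, rn, cat38)

  # complete individual: all three policies agree exactly
  expect_equal(s_zf$score[1], 16)
  expect_equal(s_cc$score[1], 16)
  expect_equal(s_rn$score[1], 16)
  # incomplete individual
  expect_equal(s_cc$score[2], NA_real_)
  expect_equal(s_zf$score[2], (0.474 - 0.075) / 0.474 * 16)
  expect_equal(s_rn$score[2], 16)  # all-het renormalized is still the midpoint
  expect_equal(s_zf$n_observed[2], 15L)

  expect_error(compute_score(g[, -1], zf, cat38), "lacks score variant")
})

test_that("scores stay within [0, 2K] under every policy", {
  cat38 <- the_catalog()
  set.seed(77)
  cfg <- lean_config(n_duos = 300, seed = 77)
  co <- generate_cohort(cfg)
  g <- inject_missingness(co$children, 0.15, seed = 78)
  for (pol in c("zero_fill", "complete_case", "renormalize")) {
    for (trait in c("fasting_glucose", "t2d")) {
      def <- build_definition(cat38, trait, pol)
      s <- compute_score(g, def, cat38)$score
      s <- s[!is.na(s)]
      expect_true(all(s >= 0 & s <= 2 * def$scale),
                  label = paste(trait, pol, "bounds"))
    }
  }
})

test_that("scores are invariant to flipping a variant's allele labelling", {
  cat38 <- the_catalog()
  fg <- build_definition(cat38, "fasting_glucose")
  set.seed(55)
  g <- sapply(risk_allele_freq(cat38, "children")[fg$terms$rsid],
              function(p) rbinom(200, 2, 0.3))
  rownames(g) <- paste0("I", 1:200)
  storage.mode(g) <- "integer"
  s1 <- compute_score(g, fg, cat38)$score

  flipped <- cat38
  i <- which(flipped$rsid == "rs560887")
  tmp <- flipped$major[i]
  flipped$major[i] <- flipped$minor[i]; flipped$minor[i] <- tmp
  flipped$risk_orientation[i] <- "minor"   # was major; risk allele unchanged
  g2 <- g
  g2[, "rs560887"] <- 2L - g2[, "rs560887"]
  fg2 <- build_definition(flipped, "fasting_glucose")
  s2 <- compute_score(g2, fg2, flipped)$score
  expect_equal(s1, s2)
})

test_that("analytic moments agree with an independent closed-form computation", {
  cat38 <- the_catalog()
  for (trait in c("fasting_glucose", "t2d")) {
    def <- build_definition(cat38, trait)
    got <- analytic_score_moments(def, cat38, "children")
    # independent recomputation with an explicit loop over catalogue rows
    mu <- 0; v <- 0
    for (i in seq_len(nrow(def$terms))) {
      row <- cat38[cat38$rsid == def$terms$rsid[i], ]
      p <- if (row$risk_orientation == "minor") row$maf_children else
        1 - row$maf_children
      w <- def$terms$weight[i]
      mu <- mu + w * 2 * p
      v <- v + w^2 * 2 * p * (1 - p)
    }
    expect_equal(got$mean, def$scale / def$denominator * mu)
    expect_equal(got$variance, (def$scale / def$denominator)^2 * v)
  }
  # degenerate symmetric cases
  half <- cat38; half$maf_children <- 0.5
  fg_half <- build_definition(half, "fasting_glucose")
  expect_equal(analytic_score_moments(fg_half, half, "children")$mean, 16)
})

test_that("Monte-Carlo score moments match the analytic values", {
  cat38 <- the_catalog()
  co <- generate_cohort(lean_config(n_duos = 50000, seed = 91))
  for (trait in c("fasting_glucose", "t2d")) {
    def <- build_definition(cat38, trait)
    mom <- analytic_score_moments(def, cat38, "children")
    s <- compute_score(co$children, def, cat38)$score
    expect_lt(abs(mean(s) - mom$mean), 3 * sqrt(mom$variance / length(s)))
    expect_equal(var(s), mom$variance, tolerance = 0.05)
  }
})

test_that("zero-filled scores under missingness are depressed proportionally", {
  cat38 <- the_catalog()
  co <- generate_cohort(lean_config(n_duos = 20000, seed = 92))
  fg <- build_definition(cat38, "fasting_glucose", "zero_fill")
  mom <- analytic_score_moments(fg, cat38, "children")
  g_miss <- inject_missingness(co$children, 0.10, seed = 93)
  s <- compute_score(g_miss, fg, cat38)$score
  expect_equal(mean(s, na.rm = TRUE), 0.9 * mom$mean, tolerance = 0.01)
})

test_that("score summaries describe the distribution", {
  s <- score_summary(rep(5, 10))
  expect_equal(s$mean, 5); expect_equal(s$sd, 0)
  expect_equal(c(s$min, s$max), c(5, 5))
  expect_error(score_summary(c(NA_real_, NA_real_)), "all scores")
  co <- generate_cohort(lean_config(n_duos = 2000, seed = 94))
  cat38 <- the_catalog()
  sm <- score_summary(compute_score(co$children,
                                    build_definition(cat38, "fasting_glucose"),
                                    cat38))
  expect_equal(sm$n, 2000L)
  expect_lt(abs(sm$skewness), 0.3)  # near-normal by CLT over 16 SNPs
})
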