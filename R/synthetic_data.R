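#' Simulation configuration for a synthetic duo cohort
#'
#' Bundles and validates every knob of the cohort generator. Defaults are
#' calibrated to the study population the analysis machinery was built for:
#' fasting glucose 4.95 +/- 0.39 mmol/l overall (girls 4.88, boys 5.01),
#' HbA1c 4.91 +/- 0.31 %, IQ 104.4 +/- 16.4 at mean age 8.6 years, 49.9%
#' boys, and genotype frequencies taken from the variant catalogue. Score
#' effects on phenotypes default to the fitted instrument-validation values
#' (0.02 mmol/l and 0.02 % per weighted allele of the child fasting-glucose
#' score); maternal and offspring score effects on IQ, confounder effects and
#' the maternal diabetes/glycosuria IQ shift default to zero and are scenario
#' knobs.
#'
#' @param seed integer RNG seed; a fixed seed regenerates the cohort exactly.
#' @param n_duos number of mother-child pairs.
#' @param maf_source which catalogue frequency column founders are drawn at.
#' @param fg_model list: `intercept` (mmol/l, female baseline), `beta`
#'   (mmol/l per weighted allele of the child fasting-glucose score), `sd`
#'   (residual mmol/l), `sex_effect` (mmol/l added for boys).
#' @param hba1c_model same structure, in % HbA1c.
#' @param iq_model list: `mean`, `sd` (IQ points), `beta_maternal` and
#'   `beta_offspring` (points per weighted allele of the score named in
#'   `score`), `score` (`"t2d"` or `"fasting_glucose"`), `diabetes_effect`
#'   (IQ shift for children of diabetic/glycosuric mothers),
#'   `confounder_effects` (named list, points per unit of the confounder).
#' @param diabetes_model list: `prevalence` of the combined maternal
#'   diabetes/glycosuria exposure and `log_or_per_allele`, the log-odds slope
#'   on the mother's centred type 2 diabetes score.
#' @param missing_rate per-call probability a panel genotype is set missing
#'   (completely at random).
#' @param structure list: `n_subpops`, `maf_divergence` (absolute frequency
#'   shift between subpopulations), `n_background_snps` (unlinked markers for
#'   the stratification PCA).
#' @param ld_proxies list of `list(rsid=, proxy_rsid=, r2=)` entries: extra
#'   proxy columns simulated in LD with a panel SNP.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_duos = 1000L,
                       maf_source = c("children", "mothers"),
                       fg_model = list(intercept = 4.88, beta = 0.02,
                                       sd = 0.39, sex_effect = 0.13),
                       hba1c_model = list(intercept = 4.91, beta = 0.02,
                                          sd = 0.31, sex_effect = 0),
                       iq_model = list(mean = 104.4, sd = 16.4,
                                       beta_maternal = 0, beta_offspring = 0,
                                       score = "t2d", diabetes_effect = 0,
                                       confounder_effects = list()),
                       diabetes_model = list(prevalence = 0.05,
                                             log_or_per_allele = 0),
                       missing_rate = 0,
                       structure = list(n_subpops = 1L, maf_divergence = 0.1,
                                        n_background_snps = 200L),
                       ld_proxies = list()) {
  maf_source <- match.arg(maf_source)
  cfg <- list(seed = as.integer(seed), n_duos = as.integer(n_duos),
              maf_source = maf_source, fg_model = fg_model,
              hba1c_model = hba1c_model, iq_model = iq_model,
              diabetes_model = diabetes_model, missing_rate = missing_rate,
              structure = structure, ld_proxies = ld_proxies)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c(cfg$fg_model[c("intercept", "beta", "sd", "sex_effect")],
                  cfg$hba1c_model[c("intercept", "beta", "sd", "sex_effect")],
                  cfg$iq_model[c("mean", "sd", "beta_maternal",
                                 "beta_offspring", "diabetes_effect")],
                  cfg$diabetes_model[c("prevalence", "log_or_per_allele")],
                  cfg$iq_model$confounder_effects)
  vals <- unlist(num_fields)
  if (anyNA(vals) || any(!is.finite(vals)))
    abort_valid("simulation config contains missing or non-finite parameters")
  if (cfg$fg_model$sd <= 0 || cfg$hba1c_model$sd <= 0 || cfg$iq_model$sd <= 0)
    abort_valid("residual sds must be > 0")
  if (cfg$n_duos < 0) abort_valid("n_duos must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort_valid("missing_rate must be in [0, 1)")
  prev <- cfg$diabetes_model$prevalence
  if (prev < 0 || prev > 1) abort_valid("prevalence must be in [0, 1]")
  if (!cfg$iq_model$score %in% c("t2d", "fasting_glucose"))
    abort_valid("iq_model$score must be 't2d' or 'fasting_glucose'")
  st <- cfg$structure
  if (st$n_subpops < 1) abort_valid("n_subpops must be >= 1")
  if (st$maf_divergence < 0 || st$maf_divergence > 0.5)
    abort_valid("maf_divergence must be in [0, 0.5]")
  for (px in cfg$ld_proxies) {
    if (is.null(px$rsid) || is.null(px$r2))
      abort_valid("each ld_proxies entry needs rsid and r2")
    if (px$r2 < 0 || px$r2 > 1) abort_valid("proxy r2 must be in [0, 1]")
  }
  invisible(cfg)
}

#' Read a simulation config from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults. The file must carry a `seed`.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort_valid("config file must set a seed")
  base <- formals(sim_config)
  args <- y[intersect(names(y), names(base))]
  # merge nested model lists over the defaults
  for (nm in c("fg_model", "hba1c_model", "iq_model", "diabetes_model",
               "structure")) {
    if (!is.null(y[[nm]])) {
      d <- eval(base[[nm]])
      d[names(y[[nm]])] <- y[[nm]]
      args[[nm]] <- d
    }
  }
  do.call(sim_config, args)
}

# subpopulation-specific allele frequencies: p shifted by +/- divergence,
# spread evenly across subpops, clipped to (0.01, 0.5]
subpop_freqs <- function(p, n_subpops, divergence) {
  if (n_subpops == 1L) return(matrix(p, nrow = 1))
  shifts <- seq(-1, 1, length.out = n_subpops) * divergence
  out <- outer(shifts, p, `+`)
  pmin(pmax(out, 0.01), 0.5)
}

#' Simulate founder (maternal) genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently with genotype probabilities
#' \eqn{(1-p)^2, 2p(1-p), p^2} at the catalogue minor-allele frequency. With
#' more than one subpopulation, individuals are assigned to subpopulations in
#' rotation and drawn at frequencies shifted by the configured divergence
#' (the pooled sample then shows the Wahlund deficit of heterozygotes).
#' Variants the catalogue marks as untyped in mothers fall back to the
#' children's frequency so transmission is still possible; the pipeline
#' blanks those maternal columns after transmission.
#'
#' @param config a `sim_config`.
#' @param catalog a `variant_catalog`.
#' @return dosage matrix with attributes `subpop` (assignment vector) and
#'   `p_matrix` (subpopulation-by-SNP frequencies) used downstream.
#' @export
simulate_mother_genotypes <- function(config, catalog) {
  maf <- catalog[[paste0("maf_", config$maf_source)]]
  fallback <- is.na(maf)
  maf[fallback] <- catalog$maf_children[fallback]
  draw_founders(maf, catalog$rsid, config, id_prefix = "M")
}

draw_founders <- function(p, snp_ids, config, id_prefix) {
  n <- config$n_duos
  st <- config$structure
  pm <- subpop_freqs(p, st$n_subpops, st$maf_divergence)
  subpop <- rep_len(seq_len(st$n_subpops), n)
  mat <- matrix(NA_integer_, nrow = n, ncol = length(p),
                dimnames = list(sprintf("%s%05d", id_prefix, seq_len(n)),
                                snp_ids))
  if (n > 0) {
    for (j in seq_along(p))
      mat[, j] <- stats::rbinom(n, 2L, pm[subpop, j])
  }
  attr(mat, "subpop") <- subpop
  attr(mat, "p_matrix") <- pm
  mat
}

#' Transmit maternal genotypes to children
#'
#' Mendelian transmission: each child receives one allele drawn uniformly
#' from the mother's two, plus one paternal allele drawn from the population
#' (Bernoulli at the subpopulation minor-allele frequency; fathers are not
#' represented as individuals). Expected child frequency equals the
#' population frequency and the parent-offspring genotype correlation is 1/2.
#'
#' @param mother_genotypes matrix from [simulate_mother_genotypes()]
#'   (complete for the panel).
#' @param config a `sim_config`.
#' @param catalog a `variant_catalog` (unused beyond the panel; kept for
#'   interface symmetry).
#' @return child dosage matrix (ids `C...`), same variant panel, with the
#'   mothers' `subpop` attribute carried over.
#' @export
transmit_to_child <- function(mother_genotypes, config, catalog) {
  if (anyNA(mother_genotypes))
    abort_valid("maternal matrix must be complete for transmission")
  n <- nrow(mother_genotypes)
  subpop <- attr(mother_genotypes, "subpop")
  pm <- attr(mother_genotypes, "p_matrix")
  if (is.null(subpop) || is.null(pm))
    abort_valid("mother matrix lacks simulation attributes; use simulate_mother_genotypes()")
  child <- matrix(NA_integer_, nrow = n, ncol = ncol(mother_genotypes),
                  dimnames = list(sub("^M", "C", rownames(mother_genotypes)),
                                  colnames(mother_genotypes)))
  if (n > 0) {
    for (j in seq_len(ncol(child))) {
      g <- mother_genotypes[, j]
      maternal <- ifelse(g == 0L, 0L,
                  ifelse(g == 2L, 1L, stats::rbinom(n, 1L, 0.5)))
      paternal <- stats::rbinom(n, 1L, pm[subpop, j])
      child[, j] <- maternal + paternal
    }
  }
  attr(child, "subpop") <- subpop
  attr(child, "p_matrix") <- pm
  child
}

#' Append a simulated linkage-disequilibrium proxy column
#'
#' Constructs a proxy SNP correlated with an index SNP at a target r-squared
#' using a haplotype copy scheme: the index genotype is decomposed into two
#' allele draws, and each proxy haplotype allele copies the corresponding
#' index allele with probability \eqn{\sqrt{r^2}}, otherwise it is an
#' independent Bernoulli draw at the same allele frequency. The realised
#' squared allelic correlation converges to `r2`.
#'
#' @param genotypes dosage matrix containing `rsid`.
#' @param rsid index SNP column name.
#' @param r2 target squared allelic correlation in `[0, 1]`.
#' @param proxy_rsid name for the new column (default `<rsid>_proxy`).
#' @param p allele frequency for the independent draws; defaults to the
#'   index column's sample frequency.
#' @return the matrix with the proxy column appended.
#' @export
add_ld_proxy <- function(genotypes, rsid, r2,
                         proxy_rsid = paste0(rsid, "_proxy"), p = NULL) {
  if (r2 < 0 || r2 > 1) abort_valid("r2 must be in [0, 1]")
  if (!rsid %in% colnames(genotypes))
    abort_valid("index SNP not in matrix: ", rsid)
  g <- genotypes[, rsid]
  if (anyNA(g)) abort_valid("index column must be complete")
  n <- length(g)
  if (is.null(p)) p <- sum(g) / (2 * n)
  s <- sqrt(r2)
  # decompose genotype into two exchangeable haplotype alleles
  a1 <- ifelse(g == 2L, 1L, ifelse(g == 0L, 0L, stats::rbinom(n, 1L, 0.5)))
  a2 <- g - a1
  copy1 <- stats::rbinom(n, 1L, s)
  copy2 <- stats::rbinom(n, 1L, s)
  b1 <- ifelse(copy1 == 1L, a1, stats::rbinom(n, 1L, p))
  b2 <- ifelse(copy2 == 1L, a2, stats::rbinom(n, 1L, p))
  out <- cbind(genotypes, matrix(as.integer(b1 + b2), ncol = 1,
                                 dimnames = list(NULL, proxy_rsid)))
  for (a in c("subpop", "p_matrix")) attr(out, a) <- attr(genotypes, a)
  out
}

#' Set genotype calls missing completely at random
#'
#' @param genotypes dosage matrix.
#' @param rate per-entry missingness probability in `[0, 1)`.
#' @param seed optional seed applied locally (the enclosing generator seeds
#'   the stream once; pass a seed only for standalone use).
#' @return the matrix with entries knocked out.
#' @export
inject_missingness <- function(genotypes, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) abort_valid("rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(genotypes)
  mask <- stats::rbinom(length(genotypes), 1L, rate) == 1L
  genotypes[mask] <- NA_integer_
  genotypes
}

#' Simulate phenotypes for a duo cohort
#'
#' Generates the phenotype table from the complete (pre-missingness)
#' genotypes. Child fasting glucose and HbA1c are linear in the child
#' fasting-glucose score (centred at its analytic Hardy-Weinberg mean) with
#' a sex effect and Gaussian residuals; child IQ is linear in the centred
#' maternal and offspring scores named by `iq_model$score`, the maternal
#' diabetes/glycosuria indicator and any configured confounder effects;
#' maternal diabetes/glycosuria is Bernoulli with a logistic dependence on
#' the mother's centred type 2 diabetes score, with the intercept solved so
#' the marginal prevalence matches the configuration. Confounders are drawn
#' from fixed, independent marginals (see the package vignette).
#'
#' @param mother_genotypes,child_genotypes complete dosage matrices.
#' @param config a `sim_config`.
#' @param catalog a `variant_catalog`.
#' @return list with `phenotypes` (tibble, one row per family) and `truth`
#'   (generating parameters, analytic score means, true scores).
#' @export
simulate_phenotypes <- function(mother_genotypes, child_genotypes, config,
                                catalog) {
  n <- nrow(child_genotypes)
  fg_def <- build_definition(catalog, "fasting_glucose")
  t2d_def <- build_definition(catalog, "t2d")
  mu_fg <- analytic_score_moments(fg_def, catalog, config$maf_source)$mean
  mu_t2d <- analytic_score_moments(t2d_def, catalog, config$maf_source)$mean

  fggrs_c <- compute_score(child_genotypes, fg_def, catalog)$score
  t2dgrs_c <- compute_score(child_genotypes, t2d_def, catalog)$score
  fggrs_m <- compute_score(mother_genotypes, fg_def, catalog)$score
  t2dgrs_m <- compute_score(mother_genotypes, t2d_def, catalog)$score

  sex <- factor(ifelse(stats::rbinom(n, 1, 0.499) == 1, "male", "female"),
                levels = c("female", "male"))
  male <- as.integer(sex == "male")
  child_age <- stats::rnorm(n, 8.583, 0.275)

  fm <- config$fg_model
  fasting_glucose <- fm$intercept + fm$beta * (fggrs_c - mu_fg) +
    fm$sex_effect * male + stats::rnorm(n, 0, fm$sd)
  hm <- config$hba1c_model
  hba1c <- hm$intercept + hm$beta * (fggrs_c - mu_fg) +
    hm$sex_effect * male + stats::rnorm(n, 0, hm$sd)

  # maternal diabetes/glycosuria: logistic in the centred maternal T2D score,
  # intercept solved so the sample-average probability hits the prevalence
  dm <- config$diabetes_model
  z <- t2dgrs_m - mu_t2d
  if (dm$prevalence == 0) {
    diabetes <- integer(n)
  } else if (dm$prevalence == 1) {
    diabetes <- rep(1L, n)
  } else {
    gamma <- dm$log_or_per_allele
    alpha <- if (gamma == 0 || n == 0) stats::qlogis(dm$prevalence) else
      stats::uniroot(function(a) mean(stats::plogis(a + gamma * z)) - dm$prevalence,
                     interval = stats::qlogis(dm$prevalence) + c(-20, 20))$root
    diabetes <- stats::rbinom(n, 1L, stats::plogis(alpha + gamma * z))
  }
  # split the exposed mothers into the mutually exclusive clinical categories
  category <- rep("none", n)
  exposed <- which(diabetes == 1L)
  if (length(exposed))
    category[exposed] <- sample(c("pre_existing", "gestational", "glycosuria"),
                                length(exposed), replace = TRUE,
                                prob = c(0.2, 0.4, 0.4))
  category <- factor(category,
                     levels = c("none", "pre_existing", "gestational", "glycosuria"))

  conf <- draw_confounders(n)

  im <- config$iq_model
  score_m <- if (im$score == "t2d") t2dgrs_m - mu_t2d else fggrs_m - mu_fg
  score_c <- if (im$score == "t2d") t2dgrs_c - mu_t2d else fggrs_c - mu_fg
  iq <- im$mean + im$beta_maternal * score_m + im$beta_offspring * score_c +
    im$diabetes_effect * diabetes + stats::rnorm(n, 0, im$sd)
  for (nm in names(im$confounder_effects)) {
    if (!nm %in% names(conf)) abort_valid("unknown confounder in effects: ", nm)
    iq <- iq + im$confounder_effects[[nm]] * as.numeric(conf[[nm]])
  }

  phenotypes <- tibble::tibble(
    family_id = sprintf("F%05d", seq_len(n)),
    mother_id = rownames(mother_genotypes),
    child_id = rownames(child_genotypes),
    sex = sex, child_age = child_age,
    fasting_glucose = fasting_glucose, hba1c = hba1c, iq = iq,
    diabetes_glycosuria = diabetes, diabetes_category = category
  )
  phenotypes <- dplyr::bind_cols(phenotypes, conf)

  truth <- list(
    config = config,
    analytic_mean = list(fggrs = mu_fg, t2dgrs = mu_t2d),
    scores = tibble::tibble(family_id = phenotypes$family_id,
                            fggrs_mother = fggrs_m, fggrs_child = fggrs_c,
                            t2dgrs_mother = t2dgrs_m, t2dgrs_child = t2dgrs_c)
  )
  list(phenotypes = phenotypes, truth = truth)
}

# fixed confounder marginals; effects on IQ are opt-in via the config
draw_confounders <- function(n) {
  tibble::tibble(
    maternal_education = sample(1:5, n, TRUE, prob = c(.15, .25, .30, .20, .10)),
    social_class = sample(1:5, n, TRUE, prob = c(.10, .20, .35, .25, .10)),
    parity = stats::rpois(n, 0.8),
    breastfeeding = factor(sample(c("never", "<3m", "3-5m", ">=6m"), n, TRUE,
                                  prob = c(.25, .25, .20, .30)),
                           levels = c("never", "<3m", "3-5m", ">=6m")),
    smoking = stats::rbinom(n, 1, 0.25),
    alcohol_before = stats::rbinom(n, 1, 0.50),
    alcohol_during = stats::rbinom(n, 1, 0.30),
    iron_supplementation = stats::rbinom(n, 1, 0.30),
    gestational_age = stats::rnorm(n, 39.4, 1.8),
    birthweight = stats::rnorm(n, 3400, 500),
    maternal_age = stats::rnorm(n, 28, 5),
    interpregnancy_interval = round(stats::rgamma(n, shape = 2, scale = 12)),
    infection = stats::rbinom(n, 1, 0.15)
  )
}

#' Generate a complete synthetic duo cohort
#'
#' End-to-end generator: Hardy-Weinberg founder mothers at catalogue
#' frequencies (and unlinked background markers for stratification PCA),
#' Mendelian transmission to one child per mother, optional LD proxy
#' columns, phenotypes from the configured models, maternal blanking of
#' child-only variants, and completely-at-random genotype missingness on the
#' typed panel. Deterministic for a fixed config seed.
#'
#' @param config a `sim_config`.
#' @param catalog a `variant_catalog` (defaults to the packaged one with
#'   proxies resolved).
#' @return a `duo_cohort`: list with `mothers`, `children` (panel dosage
#'   matrices), `mothers_background`, `children_background`, `phenotypes`,
#'   `truth`, `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 7, n_duos = 50))
#' dim(cohort$children)
#' @export
generate_cohort <- function(config, catalog = resolve_proxies(load_catalog())) {
  validate_sim_config(config)
  set.seed(config$seed)
  mothers_full <- simulate_mother_genotypes(config, catalog)
  children <- transmit_to_child(mothers_full, config, catalog)

  nbg <- config$structure$n_background_snps
  if (nbg > 0) {
    p_bg <- stats::runif(nbg, 0.05, 0.5)
    bg_cfg <- config
    mothers_bg <- draw_founders(p_bg, sprintf("bg%04d", seq_len(nbg)), bg_cfg, "M")
    children_bg <- transmit_to_child(mothers_bg, bg_cfg, catalog)
  } else {
    mothers_bg <- children_bg <- NULL
  }

  for (px in config$ld_proxies) {
    children <- add_ld_proxy(children, px$rsid, px$r2,
                             proxy_rsid = px$proxy_rsid %||%
                               paste0(px$rsid, "_proxy"))
  }

  ph <- simulate_phenotypes(mothers_full, children, config, catalog)

  # mothers were not typed for the child-only variants
  mothers <- mothers_full
  untyped <- catalog$rsid[!catalog$mother_typed]
  mothers[, intersect(untyped, colnames(mothers))] <- NA_integer_

  if (config$missing_rate > 0) {
    mothers <- inject_missingness(mothers, config$missing_rate)
    children <- inject_missingness(children, config$missing_rate)
  }

  out <- list(mothers = mothers, children = children,
              mothers_background = mothers_bg,
              children_background = children_bg,
              phenotypes = ph$phenotypes, truth = ph$truth, config = config)
  class(out) <- "duo_cohort"
  out
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(sprintf("<duo_cohort> %d duos, %d panel SNPs (children), %d background SNPs, seed %d\n",
              nrow(x$children), ncol(x$children),
              if (is.null(x$children_background)) 0L else ncol(x$children_background),
              x$config$seed))
  invisible(x)
}

#' Write a cohort's genotype and phenotype files
#'
#' Emits the same dosage-matrix and phenotype-table formats the loaders read,
#' plus the full truth record as JSON.
#'
#' @param cohort a `duo_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage(cohort$mothers, file.path(dir, "mothers_dosage.tsv"))
  write_dosage(cohort$children, file.path(dir, "children_dosage.tsv"))
  if (!is.null(cohort$mothers_background)) {
    write_dosage(cohort$mothers_background, file.path(dir, "mothers_background.tsv"))
    write_dosage(cohort$children_background, file.path(dir, "children_background.tsv"))
  }
  ph <- cohort$phenotypes
  utils::write.table(as.data.frame(ph), file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
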