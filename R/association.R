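#' Ordinary least-squares fit with a tidy result row
#'
#' Fits `outcome ~ exposure + covariates` by OLS with conventional standard
#' errors and listwise deletion of incomplete rows, returning the exposure
#' coefficient as a one-row regression result. Collinear covariates are an
#' error naming the offending columns rather than a silently dropped
#' coefficient.
#'
#' @param outcome numeric vector.
#' @param exposure numeric vector.
#' @param covariates optional data.frame of covariates (numeric or factor).
#' @param outcome_label,exposure_label labels carried into the result.
#' @return one-row tibble: `outcome`, `exposure`, `beta`, `se`, `ci_lo`,
#'   `ci_hi`, `p_value`, `n`, `covariates` (comma-joined labels).
#' @examples
#' ols_fit(c(1, 3, 4), c(0, 1, 2))  # slope 1.5
#' @export
ols_fit <- function(outcome, exposure, covariates = NULL,
                    outcome_label = "outcome", exposure_label = "exposure") {
  df <- data.frame(.y = outcome, .x = exposure)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  n_par <- 2L + length(cov_names)
  if (nrow(df) < n_par + 1L)
    abort_valid("too few complete cases (", nrow(df), ") for ", n_par,
                " parameters")
  fml <- stats::as.formula(paste(
    ".y ~ .x", if (length(cov_names))
      paste("+", paste(sprintf("`%s`", cov_names), collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    bad <- names(coefs)[is.na(coefs)]
    abort_valid("rank-deficient model; collinear term(s): ",
                paste(bad, collapse = ", "))
  }
  # a perfect fit (se ~ 0) is a legitimate degenerate input, not a warning
  sm <- suppressWarnings(summary(fit))$coefficients
  beta <- sm[".x", "Estimate"]
  se <- sm[".x", "Std. Error"]
  p <- sm[".x", "Pr(>|t|)"]
  tibble::tibble(outcome = outcome_label, exposure = exposure_label,
                 beta = beta, se = se,
                 ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                 p_value = p, n = nrow(df),
                 covariates = paste(cov_names, collapse = ","))
}

#' Single-SNP additive association scan
#'
#' One OLS fit per SNP of `outcome ~ minor-allele count (+ covariates)`,
#' the additive model with the major-allele homozygote as baseline. SNPs
#' that cannot be fitted (monomorphic in the analysed rows, or too few
#' complete cases) are skipped with the reason recorded. The Bonferroni
#' display threshold for the scan is attached as an attribute.
#'
#' @param genotypes dosage matrix.
#' @param outcome numeric vector aligned with the matrix rows.
#' @param covariates optional data.frame aligned with the rows.
#' @param alpha family-wise rate for the attached Bonferroni threshold.
#' @param outcome_label label for the result rows.
#' @return tibble of per-SNP regression results with a `skipped` attribute
#'   (tibble of `rsid`, `reason`) and a `bonferroni` attribute.
#' @export
single_snp_scan <- function(genotypes, outcome, covariates = NULL,
                            alpha = 0.05, outcome_label = "outcome") {
  validate_genotype_matrix(genotypes)
  results <- list(); skipped <- list()
  for (rs in colnames(genotypes)) {
    g <- genotypes[, rs]
    if (length(unique(g[!is.na(g)])) < 2L) {
      skipped[[rs]] <- "monomorphic in analysed sample"
      next
    }
    res <- tryCatch(
      ols_fit(outcome, g, covariates,
              outcome_label = outcome_label, exposure_label = rs),
      error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[[rs]] <- res else results[[rs]] <- res
  }
  out <- dplyr::bind_rows(results)
  attr(out, "skipped") <- tibble::tibble(
    rsid = names(skipped), reason = unlist(skipped) %||% character(0))
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, ncol(genotypes))
  out
}

#' Exposure-by-covariable confounder scan with expected-null accounting
#'
#' Tests every (exposure, covariable) pair and reports the p-value grid
#' together with the number of nominal associations expected by chance,
#' `round_half_away(alpha * n_tests)`, and the number observed. Test choice
#' follows the variable types: two categorical variables are compared with an
#' (uncorrected) chi-square test of independence, any other pair with the
#' linear-regression slope test. Genotype dosages enter linear tests as
#' additive numeric exposures and chi-square tests as three-level factors.
#' Untestable pairs (a constant column) are recorded and excluded from
#' `n_tests`.
#'
#' @param exposures data.frame (or matrix) of exposure columns.
#' @param covariables data.frame of covariables; factors are treated as
#'   categorical, everything else as numeric.
#' @param alpha nominal level (default 0.05).
#' @return a `scan_result`: list with `grid` (tibble of `exposure`,
#'   `covariable`, `test`, `p_value`), `n_tests`, `alpha`,
#'   `expected_nominal`, `observed_nominal`, `observed_fraction`,
#'   `untestable`.
#' @export
confounder_scan <- function(exposures, covariables, alpha = 0.05) {
  exposures <- as.data.frame(exposures)
  covariables <- as.data.frame(covariables)
  rows <- list(); untestable <- list()
  for (ex in names(exposures)) {
    for (cv in names(covariables)) {
      x <- exposures[[ex]]; y <- covariables[[cv]]
      ok <- !is.na(x) & !is.na(y)
      xi <- x[ok]; yi <- y[ok]
      key <- paste(ex, cv, sep = ":")
      if (length(unique(xi)) < 2L || length(unique(yi)) < 2L) {
        untestable[[key]] <- "constant column"
        next
      }
      categorical <- is.factor(yi) || is.character(yi)
      if (categorical) {
        xf <- factor(xi)
        p <- tryCatch(
          suppressWarnings(stats::chisq.test(table(xf, yi), correct = FALSE)$p.value),
          error = function(e) NA_real_)
        test <- "chisq"
      } else {
        sm <- summary(stats::lm(as.numeric(yi) ~ as.numeric(xi)))$coefficients
        p <- if (nrow(sm) < 2) NA_real_ else sm[2, "Pr(>|t|)"]
        test <- "linear"
      }
      if (is.na(p)) { untestable[[key]] <- "degenerate test"; next }
      rows[[key]] <- tibble::tibble(exposure = ex, covariable = cv,
                                    test = test, p_value = p)
    }
  }
  grid <- dplyr::bind_rows(rows)
  n_tests <- nrow(grid)
  observed <- sum(grid$p_value < alpha)
  out <- list(grid = grid, n_tests = n_tests, alpha = alpha,
              expected_nominal = round_half_away(alpha * n_tests),
              observed_nominal = observed,
              observed_fraction = if (n_tests) observed / n_tests else NA_real_,
              untestable = tibble::tibble(pair = names(untestable),
                                          reason = unlist(untestable) %||% character(0)))
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d tests at alpha %.3g: expected %d nominal, observed %d (%.1f%%)\n",
              x$n_tests, x$alpha, x$expected_nominal, x$observed_nominal,
              100 * x$observed_fraction))
  invisible(x)
}

#' Maternal-versus-offspring score effect on a child outcome
#'
#' The duo-design contrast: regresses the child outcome on the maternal
#' score, unadjusted and adjusted for the child's own score (plus optional
#' principal components). Because mother and child scores correlate at about
#' 0.5 through transmission, a purely offspring-mediated effect inflates the
#' unadjusted maternal coefficient; the adjusted model isolates the maternal
#' (intrauterine) path.
#'
#' @param outcome child outcome vector.
#' @param maternal_score,child_score aligned numeric score vectors.
#' @param pcs optional matrix/data.frame of principal components.
#' @param outcome_label label for the result rows.
#' @return two-row tibble (unadjusted, adjusted) of regression results with
#'   a `model` column.
#' @export
maternal_effect_fit <- function(outcome, maternal_score, child_score,
                                pcs = NULL, outcome_label = "iq") {
  unadj <- ols_fit(outcome, maternal_score,
                   outcome_label = outcome_label,
                   exposure_label = "maternal_score")
  cov <- data.frame(child_score = child_score)
  if (!is.null(pcs)) cov <- cbind(cov, as.data.frame(pcs))
  adj <- ols_fit(outcome, maternal_score, cov,
                 outcome_label = outcome_label,
                 exposure_label = "maternal_score")
  dplyr::bind_rows(
    dplyr::mutate(unadj, model = "unadjusted", .before = 1),
    dplyr::mutate(adj, model = "adjusted", .before = 1))
}

#' WHO rule for diabetes classification
#'
#' Diabetes is diagnosed when fasting plasma glucose is at least 7.0 mmol/l
#' or HbA1c is at least 6.5%. A missing measurement never qualifies; if both
#' are missing the classification is missing.
#'
#' @param fasting_glucose mmol/l (vector, NA allowed).
#' @param hba1c percent (vector, NA allowed).
#' @return logical vector.
#' @export
classify_diabetes <- function(fasting_glucose, hba1c) {
  fg_hit <- !is.na(fasting_glucose) & fasting_glucose >= 7.0
  hb_hit <- !is.na(hba1c) & hba1c >= 6.5
  out <- fg_hit | hb_hit
  out[is.na(fasting_glucose) & is.na(hba1c)] <- NA
  out
}

#' Glycosuria classification over repeated measurements
#'
#' Positive when plasma glucose of at least 13.9 mmol/l (equivalently 250
#' mg/dl) is recorded on at least two occasions.
#'
#' @param measurements numeric vector of one person's occasion measurements,
#'   or a list of such vectors for several people.
#' @param unit `"mmol/l"` or `"mg/dl"` (converted before thresholding).
#' @return logical scalar (vector input) or vector (list input).
#' @export
classify_glycosuria <- function(measurements, unit = c("mmol/l", "mg/dl")) {
  unit <- match.arg(unit)
  one <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) abort_valid("at least one occasion must be recorded")
    # the two printed thresholds (13.9 mmol/l, 250 mg/dl) are equivalent at
    # one decimal, so converted values are compared at that precision
    if (unit == "mg/dl") x <- round(mgdl_to_mmoll(x), 1)
    sum(x >= 13.9) >= 2L
  }
  if (is.list(measurements)) vapply(measurements, one, logical(1)) else one(measurements)
}

#' Convert glucose from mg/dl to mmol/l
#'
#' Uses the glucose molar-mass convention of 18.016 mg/dl per mmol/l (so
#' 250 mg/dl prints as 13.9 mmol/l at one decimal).
#'
#' @param x mg/dl, non-negative.
#' @return mmol/l (full precision; round for display).
#' @export
mgdl_to_mmoll <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort_valid("glucose cannot be negative")
  x / 18.016
}

#' Mutually exclusive maternal diabetes category
#'
#' Collapses the three clinical flags into one category with precedence
#' pre-existing > gestational > glycosuria > none, plus the combined 0/1
#' exposure indicator used in the diabetes/glycosuria contrast.
#'
#' @param pre_existing,gestational,glycosuria logical vectors.
#' @return tibble with `category` (factor: none, pre_existing, gestational,
#'   glycosuria) and `exposed` (integer 0/1).
#' @export
diabetes_category <- function(pre_existing, gestational, glycosuria) {
  stopifnot(is.logical(pre_existing), is.logical(gestational),
            is.logical(glycosuria))
  category <- ifelse(pre_existing, "pre_existing",
              ifelse(gestational, "gestational",
              ifelse(glycosuria, "glycosuria", "none")))
  tibble::tibble(
    category = factor(category,
                      levels = c("none", "pre_existing", "gestational",
                                 "glycosuria")),
    exposed = as.integer(pre_existing | gestational | glycosuria))
}

#' Covariate presets used across the study tables
#'
#' Named covariate sets matching the analysis layouts: `age_sex` (child age
#' and sex), `pcs` (top principal components), `offspring_score_pcs`
#' (child's own score plus components), and `maternal_diabetes_full` (child
#' age and sex, maternal age at delivery, birthweight, gestational age and
#' breastfeeding duration).
#'
#' @param preset preset name.
#' @param phenotypes phenotype tibble the columns are pulled from.
#' @param pcs optional PC score matrix.
#' @param child_score optional child score vector (for
#'   `offspring_score_pcs`).
#' @return data.frame of covariates (possibly zero columns for `none`).
#' @export
covariate_preset <- function(preset = c("none", "age_sex", "pcs",
                                        "offspring_score_pcs",
                                        "maternal_diabetes_full"),
                             phenotypes, pcs = NULL, child_score = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    none = NULL,
    age_sex = data.frame(child_age = phenotypes$child_age,
                         sex = phenotypes$sex),
    pcs = {
      if (is.null(pcs)) abort_valid("preset 'pcs' needs principal components")
      as.data.frame(pcs)
    },
    offspring_score_pcs = {
      if (is.null(child_score))
        abort_valid("preset 'offspring_score_pcs' needs the child score")
      out <- data.frame(child_score = child_score)
      if (!is.null(pcs)) out <- cbind(out, as.data.frame(pcs))
      out
    },
    maternal_diabetes_full = data.frame(
      child_age = phenotypes$child_age, sex = phenotypes$sex,
      maternal_age = phenotypes$maternal_age,
      birthweight = phenotypes$birthweight,
      gestational_age = phenotypes$gestational_age,
      breastfeeding = phenotypes$breastfeeding))
}
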