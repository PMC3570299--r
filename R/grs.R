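#' Build a weighted genetic risk score definition
#'
#' Assembles the fasting-glucose score (16 SNPs, total weight 0.474) or the
#' type 2 diabetes score (22 SNPs, published denominator 2.86) from the
#' catalogue. A score is
#' \deqn{S = \frac{\sum_i w_i g_i}{W} \times K}
#' where \eqn{g_i} is the risk-allele count at SNP \eqn{i}, \eqn{w_i} the
#' published per-allele effect, \eqn{W} the denominator constant and \eqn{K}
#' the number of SNPs, so scores are in "weighted allele" units on a 0 to 2K
#' scale. Variants without a weight for the requested trait (the child-only
#' ADIPOQ trio, the Pima-only COX2 SNP, the low-call-rate CDC123/CAMK1D SNP,
#' the obesity SNP, and the two LD-redundant variants rs12255372 and
#' rs2237892) never enter a definition.
#'
#' The published type 2 diabetes denominator (2.86) differs slightly from the
#' sum of its printed weights (2.89); the published constant is the default,
#' and `consistent_denominator = TRUE` substitutes the true sum. Both the
#' printed denominator and the actual weight sum are recorded in the
#' definition's `audit`.
#'
#' @param catalog a `variant_catalog`, proxies resolved.
#' @param trait `"fasting_glucose"` or `"t2d"`.
#' @param missing_policy how to score individuals with missing genotypes:
#'   `"zero_fill"` (missing terms contribute 0), `"complete_case"` (any
#'   missing term gives a missing score), or `"renormalize"` (denominator
#'   replaced by the per-individual sum of observed weights).
#' @param consistent_denominator use the sum of the printed weights as `W`
#'   instead of the published constant.
#' @return a `score_definition`: list with `name`, `terms` (tibble of `rsid`,
#'   `weight`), `denominator`, `scale`, `missing_policy`, `audit`.
#' @examples
#' cat38 <- resolve_proxies(load_catalog())
#' fg <- build_definition(cat38, "fasting_glucose")
#' fg$denominator          # 0.474
#' nrow(fg$terms)          # 16
#' @export
build_definition <- function(catalog,
                             trait = c("fasting_glucose", "t2d"),
                             missing_policy = c("zero_fill", "complete_case",
                                                "renormalize"),
                             consistent_denominator = FALSE) {
  trait <- match.arg(trait)
  missing_policy <- match.arg(missing_policy)
  wcol <- if (trait == "fasting_glucose") "fg_weight" else "t2d_weight"
  keep <- !is.na(catalog[[wcol]])
  terms <- tibble::tibble(rsid = catalog$rsid[keep],
                          weight = catalog[[wcol]][keep])
  if (!nrow(terms)) abort_valid("catalogue carries no ", trait, " weights")
  weight_sum <- sum(terms$weight)
  published_W <- if (trait == "fasting_glucose") 0.474 else 2.86
  W <- if (consistent_denominator) weight_sum else published_W
  def <- list(
    name = if (trait == "fasting_glucose") "FGGRS" else "T2DGRS",
    trait = trait,
    terms = terms,
    denominator = W,
    scale = nrow(terms),
    missing_policy = missing_policy,
    audit = list(published_denominator = published_W,
                 weight_sum = weight_sum,
                 n_terms = nrow(terms),
                 proxy_audit = attr(catalog, "proxy_audit"))
  )
  class(def) <- "score_definition"
  def
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s: %d terms, W = %g (weights sum to %g), policy = %s\n",
              x$name, x$scale, x$denominator, x$audit$weight_sum, x$missing_policy))
  invisible(x)
}

#' Compute per-individual genetic risk scores
#'
#' Applies a score definition to a minor-allele dosage matrix. Genotypes are
#' oriented to risk-allele counts internally, multiplied by the published
#' weights, normalised by the denominator and rescaled by the SNP count.
#' Missing genotypes are handled by the definition's policy (see
#' [build_definition()]).
#'
#' @param genotypes integer dosage matrix (minor-allele counts).
#' @param definition a `score_definition`.
#' @param catalog the `variant_catalog` (for risk-allele orientation).
#' @return tibble with columns `id`, `score`, `n_observed` (number of
#'   non-missing score terms for the individual).
#' @export
compute_score <- function(genotypes, definition, catalog) {
  validate_genotype_matrix(genotypes)
  need <- definition$terms$rsid
  absent <- setdiff(need, colnames(genotypes))
  if (length(absent))
    abort_valid("genotype matrix lacks score variant(s): ",
                paste(absent, collapse = ", "))
  g_minor <- genotypes[, need, drop = FALSE]
  orient <- catalog$risk_orientation[match(need, catalog$rsid)]
  g_risk <- sweep_orient(g_minor, orient)
  w <- definition$terms$weight
  K <- definition$scale
  W <- definition$denominator

  contrib <- sweep(g_risk, 2, w, `*`)
  n_obs <- rowSums(!is.na(g_risk))
  raw <- rowSums(contrib, na.rm = TRUE)

  score <- switch(definition$missing_policy,
    zero_fill = raw / W * K,
    complete_case = ifelse(n_obs == K, raw / W * K, NA_real_),
    renormalize = {
      w_obs <- rowSums(sweep(!is.na(g_risk), 2, w, `*`))
      ifelse(n_obs > 0, raw / w_obs * K, NA_real_)
    })
  score[n_obs == 0 & definition$missing_policy == "zero_fill"] <- NA_real_

  tibble::tibble(id = rownames(genotypes) %||% character(nrow(genotypes)),
                 score = as.numeric(score),
                 n_observed = as.integer(n_obs))
}

# orientation applied column-wise, preserving NA
sweep_orient <- function(g, orientation) {
  flip <- orientation == "major"
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  g
}

#' Analytic score moments under Hardy-Weinberg equilibrium
#'
#' Closed-form mean and variance of a score over a population in
#' Hardy-Weinberg equilibrium at the catalogue frequencies, assuming
#' independent SNPs: with risk-allele frequency \eqn{p_i},
#' \deqn{E[S] = \frac{K}{W}\sum_i 2 w_i p_i, \qquad
#'       Var[S] = \left(\frac{K}{W}\right)^2 \sum_i 2 w_i^2 p_i (1 - p_i).}
#' Used to calibrate the cohort generator and as a QC reference for observed
#' score distributions.
#'
#' @param definition a `score_definition`.
#' @param catalog a `variant_catalog`.
#' @param maf_source frequency column to use (`"children"` or `"mothers"`).
#' @return list with `mean`, `variance`, `sd`.
#' @export
analytic_score_moments <- function(definition, catalog,
                                   maf_source = c("children", "mothers")) {
  maf_source <- match.arg(maf_source)
  p_all <- risk_allele_freq(catalog, maf_source)
  p <- p_all[definition$terms$rsid]
  if (anyNA(p))
    abort_valid("no ", maf_source, " frequency for: ",
                paste(definition$terms$rsid[is.na(p)], collapse = ", "))
  w <- definition$terms$weight
  k_over_w <- definition$scale / definition$denominator
  list(mean = k_over_w * sum(2 * w * p),
       variance = k_over_w^2 * sum(2 * w^2 * p * (1 - p)),
       sd = k_over_w * sqrt(sum(2 * w^2 * p * (1 - p))))
}

#' Descriptive summary of a score distribution
#'
#' @param scores tibble from [compute_score()] or a numeric vector.
#' @return list with `n`, `mean`, `sd`, `min`, `max`, `skewness`,
#'   `excess_kurtosis`, `n_missing`.
#' @export
score_summary <- function(scores) {
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) abort_valid("all scores are missing")
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       min = min(x), max = max(x),
       skewness = moment_skew(x), excess_kurtosis = moment_kurtosis(x),
       n_missing = n_missing)
}
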