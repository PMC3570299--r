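#' Minor-allele frequency of a genotype column
#'
#' Frequency of the coded (counted) allele, `(n1 + 2 n2) / (2 n)`, over
#' non-missing calls. If the coded allele turns out to be the commoner one the
#' reported MAF is the complement and the result is flagged as flipped, so
#' the returned value is always a true minor-allele frequency.
#'
#' @param genotype integer vector of allele counts (0/1/2/NA).
#' @return list with `maf`, `coded_allele_freq`, `flipped`, `n`.
#' @export
allele_frequency <- function(genotype) {
  g <- genotype[!is.na(genotype)]
  if (!length(g)) abort_valid("no non-missing genotypes")
  if (!all(g %in% c(0L, 1L, 2L))) abort_valid("genotypes must be 0/1/2/NA")
  f <- sum(g) / (2 * length(g))
  flipped <- f > 0.5
  list(maf = if (flipped) 1 - f else f,
       coded_allele_freq = f, flipped = flipped, n = length(g))
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' (n0, n1, n2) against the proportions \eqn{(1-p)^2, 2p(1-p), p^2} expected
#' at the sample allele frequency \eqn{\hat p = (n_1 + 2 n_2) / 2n}. SNPs are
#' flagged at the reporting threshold p <= 0.02. A monomorphic SNP has no
#' degrees of freedom to test and is reported with p = 1 and a degeneracy
#' note rather than an error.
#'
#' @param n0,n1,n2 counts of the three genotype classes (coded-allele count
#'   0, 1, 2).
#' @param min_total minimum informative sample size (default 10).
#' @param flag_threshold reporting threshold on the p-value (default 0.02).
#' @return list with `observed`, `expected`, `p_hat`, `chisq`, `p_value`,
#'   `flag`, `note`.
#' @examples
#' hwe_test(49, 42, 9)  # exact HWE proportions at p = 0.3: chisq 0, p 1
#' @export
hwe_test <- function(n0, n1, n2, min_total = 10, flag_threshold = 0.02) {
  counts <- c(n0, n1, n2)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_valid("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < min_total)
    abort_valid("total count ", n, " below minimum ", min_total)
  p_hat <- (n1 + 2 * n2) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(list(observed = counts, expected = counts, p_hat = p_hat,
                chisq = 0, p_value = 1, flag = FALSE,
                note = "monomorphic: no test possible"))
  }
  expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  chisq <- sum((counts - expected)^2 / expected)
  p_value <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(observed = counts, expected = expected, p_hat = p_hat,
       chisq = chisq, p_value = p_value,
       flag = p_value <= flag_threshold, note = NA_character_)
}

#' Hardy-Weinberg scan over a genotype matrix
#'
#' Runs [hwe_test()] on every column with enough non-missing calls.
#'
#' @param genotypes dosage matrix.
#' @param min_total columns with fewer non-missing calls are skipped.
#' @param flag_threshold reporting threshold (default 0.02).
#' @return tibble: `rsid`, `n0`, `n1`, `n2`, `p_hat`, `chisq`, `p_value`,
#'   `flag`, `note`.
#' @export
hwe_scan <- function(genotypes, min_total = 10, flag_threshold = 0.02) {
  validate_genotype_matrix(genotypes)
  rows <- lapply(colnames(genotypes), function(rs) {
    g <- genotypes[, rs]
    g <- g[!is.na(g)]
    if (length(g) < min_total)
      return(tibble::tibble(rsid = rs, n0 = NA_integer_, n1 = NA_integer_,
                            n2 = NA_integer_, p_hat = NA_real_,
                            chisq = NA_real_, p_value = NA_real_,
                            flag = NA, note = "insufficient calls"))
    h <- hwe_test(sum(g == 0), sum(g == 1), sum(g == 2),
                  min_total = min_total, flag_threshold = flag_threshold)
    tibble::tibble(rsid = rs, n0 = h$observed[1], n1 = h$observed[2],
                   n2 = h$observed[3], p_hat = h$p_hat, chisq = h$chisq,
                   p_value = h$p_value, flag = h$flag, note = h$note)
  })
  dplyr::bind_rows(rows)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return list with `threshold` (`alpha / n_tests`) and `display` (rounded
#'   to one significant figure, the convention used when quoting the cut-off).
#' @examples
#' bonferroni_threshold(0.05, 38)  # threshold 0.001316, displayed 0.001
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) abort_valid("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort_valid("alpha must be in (0, 1)")
  thr <- alpha / n_tests
  list(threshold = thr, display = signif(thr, 1))
}

#' Principal components of a genotype matrix
#'
#' Standard stratification PCA: each SNP column is centred and scaled by
#' \eqn{\sqrt{\hat p (1 - \hat p)}} with \eqn{\hat p} the sample allele
#' frequency, missing calls are mean-imputed beforehand, and the top `k`
#' right-side components of the individuals-by-SNPs matrix are returned.
#' The sign of each component is fixed by making its largest-magnitude SNP
#' loading positive, so results are reproducible across runs.
#'
#' @param genotypes dosage matrix (rows individuals, columns SNPs).
#' @param k number of components (default 10).
#' @return list with `scores` (n x k matrix, columns `PC1..PCk`),
#'   `var_fraction` (length-k numeric), `k`.
#' @export
compute_pcs <- function(genotypes, k = 10) {
  validate_genotype_matrix(genotypes)
  if (k < 1) abort_valid("k must be >= 1")
  X <- genotypes
  storage.mode(X) <- "double"
  # mean-impute, then centre/scale by sqrt(p(1-p))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    m <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- m
    p <- m / 2
    if (is.nan(p) || p <= 0 || p >= 1) { keep[j] <- FALSE; next }
    X[, j] <- (x - m) / sqrt(p * (1 - p))
    keep[j] <- TRUE
  }
  X <- X[, keep, drop = FALSE]
  max_k <- min(nrow(X) - 1L, ncol(X))
  if (k > max_k)
    abort_valid("k = ", k, " exceeds the rank supported by the panel (", max_k, ")")
  sv <- svd(X, nu = k, nv = k)
  # sign convention: largest-|loading| positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, sv$d[seq_len(k)], `*`)
  dimnames(scores) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  list(scores = scores,
       var_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       k = k)
}
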