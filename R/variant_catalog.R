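#' Load the packaged variant catalogue
#'
#' Reads the catalogue of fasting-glucose and type 2 diabetes associated SNPs
#' (38 variants typed in children, 35 of which were also typed in mothers; the
#' three ADIPOQ variants are child-only). Each record carries the major/minor
#' alleles, minor-allele frequencies in mothers, children and the HapMap CEU
#' reference, the risk-allele orientation (whether the trait-raising allele is
#' the major or the minor allele), trait tags, and the per-allele score weights
#' for the 16-SNP fasting-glucose score and the 22-SNP type 2 diabetes score.
#' Two variants are linkage-disequilibrium proxies genotyped in place of the
#' SNP whose published effect they carry; their `proxy_rsid`/`proxy_r2` fields
#' record the substitution.
#'
#' @param path path to a tab-separated catalogue file. Defaults to the
#'   catalogue shipped with the package.
#' @return a tibble of class `variant_catalog`, one row per SNP, with columns
#'   `rsid`, `gene`, `major`, `minor`, `maf_mothers`, `maf_children`,
#'   `maf_ceu`, `risk_orientation`, `traits` (list column of tags),
#'   `fg_weight`, `t2d_weight`, `proxy_rsid`, `proxy_r2`, `alias`,
#'   `mother_typed`.
#' @examples
#' cat38 <- load_catalog()
#' sum(!is.na(cat38$fg_weight))   # 16 score terms
#' sum(!is.na(cat38$t2d_weight))  # 22 score terms
#' @export
load_catalog <- function(path = system.file("extdata", "variant_catalog.tsv",
                                            package = "duoscore")) {
  if (!file.exists(path)) abort_valid("catalogue file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", stringsAsFactors = FALSE)
  required <- c("rsid", "gene", "major", "minor", "maf_mothers",
                "maf_children", "maf_ceu", "risk_orientation", "traits",
                "fg_weight", "t2d_weight", "proxy_rsid", "proxy_r2")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    abort_valid("catalogue is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  if (!"alias" %in% names(raw)) raw$alias <- NA_character_
  if (anyDuplicated(raw$rsid))
    abort_valid("duplicate rsid in catalogue: ",
                paste(unique(raw$rsid[duplicated(raw$rsid)]), collapse = ", "))

  cat_tbl <- tibble::as_tibble(raw)
  cat_tbl$mother_typed <- !is.na(cat_tbl$maf_mothers)
  cat_tbl$traits <- strsplit(cat_tbl$traits, ",", fixed = TRUE)

  validate_catalog(cat_tbl)
  class(cat_tbl) <- c("variant_catalog", class(cat_tbl))
  cat_tbl
}

validate_catalog <- function(cat_tbl) {
  for (i in seq_len(nrow(cat_tbl))) {
    row <- cat_tbl[i, ]
    where <- paste0("catalogue row ", i, " (", row$rsid, "): ")
    for (fld in c("maf_mothers", "maf_children")) {
      f <- row[[fld]]
      if (fld == "maf_mothers" && !row$mother_typed) next  # child-only variant
      if (is.na(f) || f <= 0 || f > 0.5)
        abort_valid(where, fld, " = ", f, " outside (0, 0.5]")
    }
    # the reference column is the frequency of the cohort's minor allele in
    # the external panel, where that allele need not be the minor one
    if (is.na(row$maf_ceu) || row$maf_ceu <= 0 || row$maf_ceu >= 1)
      abort_valid(where, "maf_ceu = ", row$maf_ceu, " outside (0, 1)")
    if (!row$risk_orientation %in% c("major", "minor"))
      abort_valid(where, "risk_orientation must be 'major' or 'minor'")
    if (!all(nchar(c(row$major, row$minor)) == 1L) ||
        !all(c(row$major, row$minor) %in% c("A", "C", "G", "T")))
      abort_valid(where, "alleles must be single nucleotide codes")
    if (row$major == row$minor)
      abort_valid(where, "major and minor allele identical")
    bad <- setdiff(row$traits[[1]], c("fasting_glucose", "t2d", "obesity"))
    if (length(bad))
      abort_valid(where, "unknown trait tag: ", paste(bad, collapse = ", "))
    if (!is.na(row$fg_weight) && row$fg_weight <= 0)
      abort_valid(where, "fg_weight must be strictly positive")
    if (!is.na(row$t2d_weight) && row$t2d_weight <= 0)
      abort_valid(where, "t2d_weight must be strictly positive")
    if (xor(is.na(row$proxy_rsid), is.na(row$proxy_r2)))
      abort_valid(where, "proxy_rsid and proxy_r2 must be given together")
  }
  n_fg <- sum(!is.na(cat_tbl$fg_weight))
  n_t2d <- sum(!is.na(cat_tbl$t2d_weight))
  n_both <- sum(!is.na(cat_tbl$fg_weight) & !is.na(cat_tbl$t2d_weight))
  if (n_fg != 16L)
    abort_valid("catalogue must carry exactly 16 fasting-glucose weights, found ", n_fg)
  if (n_t2d != 22L)
    abort_valid("catalogue must carry exactly 22 type 2 diabetes weights, found ", n_t2d)
  if (n_both != 8L)
    abort_valid("exactly 8 variants must carry both weights, found ", n_both)
  invisible(cat_tbl)
}

#' Write a variant catalogue back to disk
#'
#' Inverse of [load_catalog()]; a written catalogue re-loads to identical
#' records.
#'
#' @param catalog a `variant_catalog`.
#' @param path output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)
  out$traits <- vapply(out$traits, paste, "", collapse = ",")
  out$mother_typed <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Convert minor-allele counts to risk-allele counts
#'
#' Genotypes are stored as minor-allele counts; score construction codes each
#' SNP 0/1/2 by the number of trait-raising (risk) alleles. When the risk
#' allele is the major allele the count is complemented (`2 - g`); when it is
#' the minor allele the count is returned unchanged. Missing genotypes
#' propagate as missing.
#'
#' @param count_minor integer vector of minor-allele counts in `{0, 1, 2}` or `NA`.
#' @param orientation `"major"` or `"minor"` (scalar or vector).
#' @return risk-allele counts with the same shape as `count_minor`.
#' @examples
#' orient_to_risk(c(0, 1, 2), "major")  # 2 1 0
#' @export
orient_to_risk <- function(count_minor, orientation) {
  ok <- is.na(count_minor) | count_minor %in% c(0, 1, 2)
  if (!all(ok))
    abort_valid("genotype counts must be 0, 1, 2 or NA; found: ",
                paste(unique(count_minor[!ok]), collapse = ", "))
  if (!all(orientation %in% c("major", "minor")))
    abort_valid("orientation must be 'major' or 'minor'")
  ifelse(orientation == "minor", count_minor, 2L - count_minor)
}

#' Resolve linkage-disequilibrium proxy substitutions
#'
#' Two catalogued variants were genotyped in place of the SNP whose published
#' effect estimate they carry (same gene, strong LD), and the linked SNP's
#' weight is applied unchanged. This audit step records every substitution and
#' warns when a proxy's r-squared with its source SNP falls below `r2_floor`,
#' since the assumption that the effect transfers weakens with LD.
#'
#' @param catalog a `variant_catalog`.
#' @param r2_floor warn below this r-squared (default 0.5; substitution is
#'   still applied, as published proxies at r-squared 0.8 were).
#' @return the catalogue, with a `proxy_audit` attribute: a tibble of
#'   (`rsid`, `source_rsid`, `r2`, `fg_weight`, `t2d_weight`).
#' @export
resolve_proxies <- function(catalog, r2_floor = 0.5) {
  is_proxy <- !is.na(catalog$proxy_rsid)
  audit <- tibble::tibble(
    rsid = catalog$rsid[is_proxy],
    source_rsid = catalog$proxy_rsid[is_proxy],
    r2 = catalog$proxy_r2[is_proxy],
    fg_weight = catalog$fg_weight[is_proxy],
    t2d_weight = catalog$t2d_weight[is_proxy]
  )
  low <- audit$r2 < r2_floor
  if (any(low))
    warning("proxy r-squared below ", r2_floor, " for: ",
            paste(audit$rsid[low], collapse = ", "),
            " (substitution still applied)", call. = FALSE)
  attr(catalog, "proxy_audit") <- audit
  catalog
}

#' Risk-allele frequencies implied by the catalogue
#'
#' For each variant, the population frequency of the risk allele: the printed
#' minor-allele frequency when the risk allele is the minor allele, otherwise
#' its complement.
#'
#' @param catalog a `variant_catalog`.
#' @param maf_source `"children"` or `"mothers"` frequency column.
#' @return named numeric vector of risk-allele frequencies (NA where the
#'   variant was not typed in the chosen group).
#' @export
risk_allele_freq <- function(catalog, maf_source = c("children", "mothers")) {
  maf_source <- match.arg(maf_source)
  maf <- catalog[[paste0("maf_", maf_source)]]
  p <- ifelse(catalog$risk_orientation == "minor", maf, 1 - maf)
  stats::setNames(p, catalog$rsid)
}
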