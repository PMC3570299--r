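#' Read a genotype dosage matrix
#'
#' Tab-separated table, one row per individual, first column `id`, remaining
#' columns one per rsid holding minor-allele counts 0/1/2 or NA for a missing
#' call.
#'
#' @param path file path.
#' @return integer matrix with individual ids as rownames and rsids as
#'   colnames.
#' @export
read_dosage <- function(path) {
  if (!file.exists(path)) abort_valid("dosage file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "id") abort_valid("first column must be 'id'")
  if (anyDuplicated(raw$id)) abort_valid("duplicate individual ids")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- as.character(raw$id)
  validate_genotype_matrix(mat)
  mat
}

#' Write a genotype dosage matrix
#'
#' @param genotypes integer matrix (rows individuals, columns rsids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(genotypes, path) {
  validate_genotype_matrix(genotypes)
  out <- data.frame(id = rownames(genotypes), genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

validate_genotype_matrix <- function(genotypes) {
  if (!is.matrix(genotypes)) abort_valid("genotypes must be a matrix")
  if ((nrow(genotypes) > 0 && is.null(rownames(genotypes))) ||
      (ncol(genotypes) > 0 && is.null(colnames(genotypes))))
    abort_valid("genotype matrix needs individual ids as rownames and rsids as colnames")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    abort_valid("genotype entries must be 0, 1, 2 or NA")
  invisible(genotypes)
}

#' Read genotypes from a VCF into minor-allele counts
#'
#' Extracts the GT field of a VCF and converts each call to a minor-allele
#' count using the catalogue's allele labels: the count is the number of
#' catalogue minor alleles in the call, with REF/ALT checked against the
#' catalogue's major/minor pair in either order. Sites not in the catalogue
#' are dropped.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param catalog a `variant_catalog`; allele labels and rsids come from here.
#' @return integer dosage matrix as from [read_dosage()].
#' @export
read_vcf_genotypes <- function(path, catalog) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort_valid("VCF ingestion requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- which(ids %in% c(catalog$rsid, catalog$alias))
  if (!length(keep)) abort_valid("no catalogued variants found in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # map aliases to canonical rsids
  canon <- catalog$rsid
  names(canon) <- catalog$rsid
  has_alias <- !is.na(catalog$alias)
  canon <- c(canon, stats::setNames(catalog$rsid[has_alias], catalog$alias[has_alias]))
  rsids <- unname(canon[fix[, "ID"]])

  n_ind <- ncol(gt)
  mat <- matrix(NA_integer_, nrow = n_ind, ncol = length(rsids),
                dimnames = list(colnames(gt), rsids))
  for (j in seq_along(rsids)) {
    rec <- catalog[catalog$rsid == rsids[j], ]
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    if (setequal(c(ref, alt), c(rec$major, rec$minor))) {
      minor_code <- if (alt == rec$minor) "1" else "0"
    } else {
      warning("VCF alleles ", ref, "/", alt, " at ", rsids[j],
              " do not match catalogue ", rec$major, "/", rec$minor,
              "; site set to missing", call. = FALSE)
      next
    }
    alleles <- strsplit(gsub("\\|", "/", gt[j, ]), "/", fixed = TRUE)
    mat[, j] <- vapply(alleles, function(a) {
      if (length(a) != 2L || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == minor_code)
    }, integer(1))
  }
  validate_genotype_matrix(mat)
  mat
}
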