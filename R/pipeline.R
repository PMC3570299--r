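#' Study configuration
#'
#' Wraps a simulation (or file-based cohort) plus analysis settings into the
#' single object [run_study()] consumes.
#'
#' @param simulation a [sim_config()] describing the synthetic cohort, or
#'   `NULL` when `cohort_files` is given.
#' @param cohort_files optional named list of paths (`mothers`, `children`,
#'   `phenotypes`, and optionally `mothers_background`,
#'   `children_background`) in the package's dosage/phenotype formats.
#' @param catalog_path optional path to a catalogue file (default: packaged).
#' @param n_pcs principal components used as stratification covariates
#'   (default 10; reduced with a warning when the background panel cannot
#'   support that many).
#' @param filters inclusion filter specs for [apply_inclusion_filters()].
#' @param stages which analysis stages to run; the default runs everything.
#' @param alpha nominal level for the scans.
#' @return list of class `study_config`.
#' @export
study_config <- function(simulation = sim_config(),
                         cohort_files = NULL,
                         catalog_path = NULL,
                         n_pcs = 10,
                         filters = list(),
                         stages = c("qc", "pca", "scores", "instrument",
                                    "offspring_iq", "maternal_iq",
                                    "diabetes_contrast", "confounder_scan"),
                         alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(simulation) && is.null(cohort_files))
    abort_valid("either a simulation config or cohort files must be given")
  cfg <- list(simulation = simulation, cohort_files = cohort_files,
              catalog_path = catalog_path, n_pcs = n_pcs, filters = filters,
              stages = stages, alpha = alpha)
  class(cfg) <- "study_config"
  cfg
}

#' Read a study config from a YAML file
#'
#' Top-level keys mirror [study_config()]; the `simulation` block is parsed
#' as by [read_sim_config()].
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(y$simulation, tmp)
    sim <- read_sim_config(tmp)
  }
  study_config(simulation = sim,
               cohort_files = y$cohort_files,
               catalog_path = y$catalog_path,
               n_pcs = y$n_pcs %||% 10,
               filters = y$filters %||% list(),
               stages = y$stages %||% c("qc", "pca", "scores", "instrument",
                                        "offspring_iq", "maternal_iq",
                                        "diabetes_contrast", "confounder_scan"),
               alpha = y$alpha %||% 0.05)
}

#' Apply ordered inclusion filters with a participant-flow ledger
#'
#' Each filter names a phenotype column and a rule; rows failing the rule are
#' excluded and the exclusion is recorded as one ledger entry, in declared
#' order, so every analysis n is traceable. Genotype matrices are subset in
#' step with the phenotype table. Re-applying the same filters to an already
#' filtered cohort removes nobody.
#'
#' @param cohort a `duo_cohort`.
#' @param filters list of specs: `list(label =, column =, op =, value =)`
#'   with `op` one of `"present"` (non-missing), `"ge"`, `"le"`, `"gt"`,
#'   `"lt"`, `"eq"`.
#' @return list with `cohort` (filtered) and `ledger` (tibble: `stage`,
#'   `n_remaining`, `n_excluded`, `reason`).
#' @export
apply_inclusion_filters <- function(cohort, filters = list()) {
  ph <- cohort$phenotypes
  ledger <- tibble::tibble(stage = "initial cohort",
                           n_remaining = nrow(ph),
                           n_excluded = 0L, reason = NA_character_)
  keep_all <- rep(TRUE, nrow(ph))
  for (f in filters) {
    if (is.null(f$column) || !f$column %in% names(ph))
      abort_valid("filter references unknown column: ",
                  f$column %||% "<missing>")
    x <- ph[[f$column]]
    op <- f$op %||% "present"
    pass <- switch(op,
      present = !is.na(x),
      ge = !is.na(x) & x >= f$value,
      le = !is.na(x) & x <= f$value,
      gt = !is.na(x) & x > f$value,
      lt = !is.na(x) & x < f$value,
      eq = !is.na(x) & x == f$value,
      abort_valid("unknown filter op: ", op))
    newly_out <- keep_all & !pass
    keep_all <- keep_all & pass
    ledger <- dplyr::bind_rows(ledger, tibble::tibble(
      stage = f$label %||% paste(f$column, op),
      n_remaining = sum(keep_all),
      n_excluded = sum(newly_out),
      reason = f$label %||% paste(f$column, op)))
  }
  idx <- which(keep_all)
  out <- cohort
  out$phenotypes <- ph[idx, , drop = FALSE]
  for (nm in c("mothers", "children", "mothers_background",
               "children_background")) {
    if (!is.null(out[[nm]])) {
      atts <- attributes(out[[nm]])[c("subpop", "p_matrix")]
      out[[nm]] <- out[[nm]][idx, , drop = FALSE]
      if (!is.null(atts$subpop)) attr(out[[nm]], "subpop") <- atts$subpop[idx]
      if (!is.null(atts$p_matrix)) attr(out[[nm]], "p_matrix") <- atts$p_matrix
    }
  }
  if (!is.null(out$truth$scores))
    out$truth$scores <- out$truth$scores[idx, , drop = FALSE]
  list(cohort = out, ledger = ledger)
}

default_confounder_columns <- function() {
  c("maternal_education", "social_class", "maternal_age", "parity",
    "interpregnancy_interval", "smoking", "alcohol_before", "alcohol_during",
    "iron_supplementation", "infection", "sex", "gestational_age",
    "birthweight", "breastfeeding", "child_age")
}

load_cohort_files <- function(files) {
  ph <- utils::read.delim(files$phenotypes, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if ("sex" %in% names(ph)) ph$sex <- factor(ph$sex, levels = c("female", "male"))
  if ("breastfeeding" %in% names(ph))
    ph$breastfeeding <- factor(ph$breastfeeding,
                               levels = c("never", "<3m", "3-5m", ">=6m"))
  out <- list(mothers = read_dosage(files$mothers),
              children = read_dosage(files$children),
              mothers_background = if (!is.null(files$mothers_background))
                read_dosage(files$mothers_background),
              children_background = if (!is.null(files$children_background))
                read_dosage(files$children_background),
              phenotypes = tibble::as_tibble(ph),
              truth = NULL, config = NULL)
  class(out) <- "duo_cohort"
  out
}

#' Run the full study pipeline on a duo cohort
#'
#' Executes the selected stages in order on a simulated or file-based
#' cohort: genotype QC (allele frequencies against the catalogue,
#' Hardy-Weinberg scans in mothers and children), stratification PCA on the
#' background panel, score construction and summaries, instrument validation
#' (child scores against fasting glucose and HbA1c, unadjusted and
#' PC-adjusted), offspring exposures and scores against IQ, maternal scores
#' against offspring IQ (unadjusted and adjusted for the offspring score and
#' PCs), the maternal diabetes/glycosuria IQ contrast under the full
#' covariate preset, and the genotype-confounder scan with expected-null
#' accounting. The result is fully regenerable from the configuration.
#'
#' @param config a `study_config` (or a bare `sim_config`, which is wrapped
#'   with default analysis settings).
#' @return a `study_report` list; see [validate_report()] for the schema.
#' @export
run_study <- function(config) {
  if (inherits(config, "sim_config")) config <- study_config(simulation = config)
  catalog <- resolve_proxies(load_catalog(
    config$catalog_path %||% system.file("extdata", "variant_catalog.tsv",
                                         package = "duoscore")))
  cohort <- if (!is.null(config$cohort_files))
    load_cohort_files(config$cohort_files)
  else generate_cohort(config$simulation, catalog)

  flt <- apply_inclusion_filters(cohort, config$filters)
  cohort <- flt$cohort
  ph <- cohort$phenotypes
  stages <- config$stages
  report <- list(flow_ledger = flt$ledger)

  if ("qc" %in% stages) {
    freq_cmp <- lapply(c("children", "mothers"), function(who) {
      mat <- cohort[[who]]
      rows <- lapply(intersect(colnames(mat), catalog$rsid), function(rs) {
        g <- mat[, rs]
        if (all(is.na(g))) return(NULL)
        af <- allele_frequency(g)
        tibble::tibble(rsid = rs, group = who, maf_observed = af$maf,
                       maf_catalog = catalog[[paste0("maf_", who)]][
                         match(rs, catalog$rsid)],
                       n = af$n)
      })
      dplyr::bind_rows(rows)
    })
    report$qc <- list(
      frequency_comparison = dplyr::bind_rows(freq_cmp),
      hwe_children = hwe_scan(cohort$children),
      hwe_mothers = hwe_scan(cohort$mothers),
      bonferroni = bonferroni_threshold(config$alpha, ncol(cohort$children)))
  }

  pcs <- NULL
  if ("pca" %in% stages && !is.null(cohort$children_background) &&
      nrow(cohort$children_background) > 2) {
    max_k <- min(nrow(cohort$children_background) - 1L,
                 ncol(cohort$children_background))
    k <- config$n_pcs
    if (k > max_k) {
      warning("background panel supports only ", max_k,
              " components; reducing from ", k, call. = FALSE)
      k <- max_k
    }
    pc <- compute_pcs(cohort$children_background, k)
    pcs <- pc$scores
    report$pca <- list(k = k, var_fraction = pc$var_fraction)
  }

  fg_def <- build_definition(catalog, "fasting_glucose")
  t2d_def <- build_definition(catalog, "t2d")
  scores <- list(
    fggrs_child = compute_score(cohort$children, fg_def, catalog)$score,
    t2dgrs_child = compute_score(cohort$children, t2d_def, catalog)$score,
    fggrs_mother = compute_score(cohort$mothers, fg_def, catalog)$score,
    t2dgrs_mother = compute_score(cohort$mothers, t2d_def, catalog)$score)

  if ("scores" %in% stages) {
    report$scores <- list(
      definitions = list(
        fggrs = fg_def$audit[c("n_terms", "published_denominator", "weight_sum")],
        t2dgrs = t2d_def$audit[c("n_terms", "published_denominator", "weight_sum")]),
      analytic = list(
        fggrs = analytic_score_moments(fg_def, catalog, "children"),
        t2dgrs = analytic_score_moments(t2d_def, catalog, "children")),
      summaries = lapply(scores, score_summary))
  }

  if ("instrument" %in% stages) {
    tab <- list()
    for (sc in c("fggrs", "t2dgrs")) {
      for (outc in c("fasting_glucose", "hba1c")) {
        s <- scores[[paste0(sc, "_child")]]
        unadj <- ols_fit(ph[[outc]], s, outcome_label = outc,
                         exposure_label = toupper(sc))
        unadj$model <- "unadjusted"
        tab[[length(tab) + 1L]] <- unadj
        if (!is.null(pcs)) {
          adj <- ols_fit(ph[[outc]], s, as.data.frame(pcs),
                         outcome_label = outc, exposure_label = toupper(sc))
          adj$model <- "adjusted_pcs"
          tab[[length(tab) + 1L]] <- adj
        }
      }
    }
    report$instrument_validation <- dplyr::bind_rows(tab)
  }

  if ("offspring_iq" %in% stages) {
    tab <- list()
    for (outc in c("fasting_glucose", "hba1c")) {
      unadj <- ols_fit(ph$iq, ph[[outc]], outcome_label = "iq",
                       exposure_label = outc)
      unadj$model <- "unadjusted"
      adj <- ols_fit(ph$iq, ph[[outc]],
                     covariate_preset("age_sex", ph),
                     outcome_label = "iq", exposure_label = outc)
      adj$model <- "adjusted_age_sex"
      tab <- c(tab, list(unadj, adj))
    }
    for (sc in c("fggrs", "t2dgrs")) {
      s <- scores[[paste0(sc, "_child")]]
      unadj <- ols_fit(ph$iq, s, outcome_label = "iq",
                       exposure_label = toupper(sc))
      unadj$model <- "unadjusted"
      tab <- c(tab, list(unadj))
      if (!is.null(pcs)) {
        adj <- ols_fit(ph$iq, s, as.data.frame(pcs),
                       outcome_label = "iq", exposure_label = toupper(sc))
        adj$model <- "adjusted_pcs"
        tab <- c(tab, list(adj))
      }
    }
    report$offspring_iq <- dplyr::bind_rows(tab)
  }

  if ("maternal_iq" %in% stages) {
    tab <- list()
    for (sc in c("fggrs", "t2dgrs")) {
      res <- maternal_effect_fit(ph$iq, scores[[paste0(sc, "_mother")]],
                                 scores[[paste0(sc, "_child")]], pcs)
      res$exposure <- paste0("maternal_", toupper(sc))
      tab <- c(tab, list(res))
    }
    report$maternal_iq <- dplyr::bind_rows(tab)
  }

  if ("diabetes_contrast" %in% stages) {
    report$diabetes_contrast <- ols_fit(
      ph$iq, ph$diabetes_glycosuria,
      covariate_preset("maternal_diabetes_full", ph),
      outcome_label = "iq", exposure_label = "maternal_diabetes_glycosuria")
  }

  if ("confounder_scan" %in% stages) {
    covs <- ph[, intersect(default_confounder_columns(), names(ph)),
               drop = FALSE]
    child_snps <- as.data.frame(cohort$children[, catalog$rsid, drop = FALSE])
    mother_rsids <- catalog$rsid[catalog$mother_typed]
    mother_snps <- as.data.frame(cohort$mothers[, mother_rsids, drop = FALSE])
    report$confounder_scan <- list(
      children = confounder_scan(child_snps, covs, config$alpha),
      mothers = confounder_scan(mother_snps, covs, config$alpha))
  }

  report$config <- list(stages = stages, n_pcs = config$n_pcs,
                        alpha = config$alpha,
                        seed = config$simulation$seed %||% NA_integer_)
  class(report) <- "study_report"
  report
}

#' Replicate the study across seeds and summarise parameter recovery
#'
#' Re-runs [run_study()] over `n_replicates` consecutive seeds and
#' summarises, for each generated effect with a configured truth value, the
#' mean estimate, its Monte-Carlo standard error, the empirical SE across
#' replicates, and the empirical coverage of the nominal 95% confidence
#' intervals.
#'
#' @param config a `study_config` with a simulation block.
#' @param n_replicates number of replicates (>= 2).
#' @param stages stages run per replicate (default: the regression stages
#'   needed for recovery, skipping QC/PCA/scans for speed).
#' @return tibble: `target`, `truth`, `mean_estimate`, `empirical_se`,
#'   `mc_se`, `coverage`, `n_replicates`.
#' @export
replicate_study <- function(config, n_replicates,
                            stages = c("instrument", "maternal_iq",
                                       "diabetes_contrast")) {
  if (inherits(config, "sim_config")) config <- study_config(simulation = config)
  if (is.null(config$simulation))
    abort_valid("replicate_study needs a simulation-based config")
  if (n_replicates < 2) abort_valid("n_replicates must be >= 2")
  config$stages <- stages
  sim <- config$simulation

  pull <- function(report) {
    out <- list()
    if (!is.null(report$instrument_validation)) {
      iv <- report$instrument_validation
      pick <- function(o) iv[iv$exposure == "FGGRS" & iv$outcome == o &
                               iv$model == "unadjusted", ]
      out$fg_effect <- pick("fasting_glucose")
      out$hba1c_effect <- pick("hba1c")
    }
    if (!is.null(report$maternal_iq)) {
      mi <- report$maternal_iq
      out$maternal_iq_adjusted <-
        mi[mi$exposure == "maternal_T2DGRS" & mi$model == "adjusted", ]
      out$maternal_iq_unadjusted <-
        mi[mi$exposure == "maternal_T2DGRS" & mi$model == "unadjusted", ]
    }
    if (!is.null(report$diabetes_contrast))
      out$diabetes_contrast <- report$diabetes_contrast
    out
  }
  truths <- c(fg_effect = sim$fg_model$beta,
              hba1c_effect = sim$hba1c_model$beta,
              maternal_iq_adjusted = sim$iq_model$beta_maternal,
              maternal_iq_unadjusted = NA_real_,
              diabetes_contrast = sim$iq_model$diabetes_effect)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$simulation$seed <- sim$seed + r - 1L
    rep_res <- pull(run_study(cfg_r))
    rows[[r]] <- dplyr::bind_rows(lapply(names(rep_res), function(nm) {
      x <- rep_res[[nm]]
      tibble::tibble(target = nm, beta = x$beta, ci_lo = x$ci_lo,
                     ci_hi = x$ci_hi)
    }))
  }
  all_rows <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(all_rows, .data$target)
  out <- dplyr::summarise(
    out,
    mean_estimate = mean(.data$beta),
    empirical_se = stats::sd(.data$beta),
    mc_se = stats::sd(.data$beta) / sqrt(dplyr::n()),
    coverage = mean(.data$ci_lo <= truths[.data$target[1]] &
                      truths[.data$target[1]] <= .data$ci_hi),
    n_replicates = dplyr::n(), .groups = "drop")
  out$truth <- unname(truths[out$target])
  out$coverage[is.na(out$truth)] <- NA_real_
  dplyr::relocate(out, "truth", .after = "target")
}

#' Structural validation of a study report
#'
#' Checks a report against the shipped schema
#' (`inst/schema/study_report_schema.json`): required sections for the
#' stages run, required columns in each table, and every reported n being a
#' positive count.
#'
#' @param report a `study_report`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "study_report_schema.json",
                                            package = "duoscore"))
  for (sec in schema$required) {
    if (is.null(report[[sec]])) abort_valid("report lacks section: ", sec)
  }
  led <- report$flow_ledger
  need <- unlist(schema$properties$flow_ledger$required_columns)
  if (!all(need %in% names(led)))
    abort_valid("flow ledger lacks columns: ",
                paste(setdiff(need, names(led)), collapse = ", "))
  if (any(diff(led$n_remaining) > 0))
    abort_valid("flow ledger n_remaining must be non-increasing")
  reg_cols <- unlist(schema$properties$regression_table$required_columns)
  for (sec in c("instrument_validation", "offspring_iq", "maternal_iq")) {
    tab <- report[[sec]]
    if (is.null(tab)) next
    if (!all(reg_cols %in% names(tab)))
      abort_valid(sec, " lacks columns: ",
                  paste(setdiff(reg_cols, names(tab)), collapse = ", "))
    if (any(tab$n <= 0)) abort_valid(sec, " has non-positive n")
  }
  invisible(TRUE)
}

#' Write a study report to machine- and human-readable files
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- rapply(unclass(report), function(x) {
    if (inherits(x, "scan_result")) unclass(x) else x
  }, classes = "ANY", how = "replace")
  jsonlite::write_json(ser, file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  txt <- file.path(dir, "study_report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("duoscore study report")
  wl(strrep("=", 60))
  wl("Participant flow:")
  utils::capture.output(print(as.data.frame(report$flow_ledger)), file = con)
  for (sec in c("instrument_validation", "offspring_iq", "maternal_iq")) {
    if (is.null(report[[sec]])) next
    wl(""); wl(sec, ":")
    tab <- as.data.frame(report[[sec]])
    tab$beta <- sprintf("%.2f (%.2f, %.2f)", tab$beta, tab$ci_lo, tab$ci_hi)
    utils::capture.output(
      print(tab[, c("model", "outcome", "exposure", "beta", "p_value", "n")]),
      file = con)
  }
  if (!is.null(report$diabetes_contrast)) {
    wl(""); wl("maternal diabetes/glycosuria contrast:")
    utils::capture.output(print(as.data.frame(report$diabetes_contrast)),
                          file = con)
  }
  if (!is.null(report$confounder_scan)) {
    wl(""); wl("confounder scan:")
    for (who in names(report$confounder_scan)) {
      s <- report$confounder_scan[[who]]
      wl(sprintf("  %s: %d tests, expected %d nominal at alpha %.2f, observed %d (%.1f%%)",
                 who, s$n_tests, s$expected_nominal, s$alpha,
                 s$observed_nominal, 100 * s$observed_fraction))
    }
  }
  invisible(dir)
}
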