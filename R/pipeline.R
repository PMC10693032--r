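#' IQR-standardize an exposure
#'
#' `(x - median(x)) / IQR(x)` with quartiles by the linear-interpolation
#' convention (R's default type-7 quantiles). Results downstream read "per
#' one IQR increase in exposure"; centring at the median makes 0 the
#' reference exposure. In the full pipeline this is computed once per
#' trimester on the whole analytic sample, before sex stratification, so one
#' IQR means the same thing in every stratum.
#'
#' @param x numeric vector with at least 4 finite values and positive IQR.
#' @return the standardized vector, with attributes `median` and `iqr`.
#' @export
iqr_standardize <- function(x) {
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 4L)
    stop("need at least 4 finite values to standardize")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                        type = 7)
  iqr <- qs[3L] - qs[1L]
  if (iqr <= 0) stop("degenerate exposure: IQR is zero")
  out <- (x - qs[2L]) / iqr
  attr(out, "median") <- qs[2L]
  attr(out, "iqr") <- iqr
  out
}

#' Cohort descriptives by infant sex
#'
#' Mean (SD) for continuous variables and N (%) for categorical ones, overall
#' and by sex, with two-sided Student t-test p-values (equal variances) for
#' continuous comparisons and per-level 2x2 Pearson chi-square p-values
#' (uncorrected) for categorical ones. Cell-type proportions from `comp` are summarized as
#' continuous variables. Cells whose stratum has fewer than 2 observations
#' are marked not computable (NA).
#'
#' @param cohort cohort data.frame with a `sex` column (`female`/`male`).
#' @param comp optional `cell_composition` aligned to the cohort.
#' @return data.frame with columns `variable`, `level`, `all`, `female`,
#'   `male` (formatted summaries) and numeric `p`.
#' @export
summarize_cohort <- function(cohort, comp = NULL) {
  cohort <- as.data.frame(cohort)
  if (!"sex" %in% names(cohort)) stop("cohort must contain a `sex` column")
  sex <- cohort$sex
  if (!all(sex %in% c("female", "male"))) stop("sex must be female/male")
  is_f <- sex == "female"

  cont_vars <- intersect(c("gestational_age", "maternal_age",
                           "pm25_t1", "pm25_t2", "pm25_t3"), names(cohort))
  cat_vars <- intersect(c("race_ethnicity", "season_of_birth",
                          "preeclampsia", "eclampsia"), names(cohort))
  rows <- list()

  fmt_cont <- function(v) sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  add_cont <- function(name, values) {
    vf <- values[is_f]; vm <- values[!is_f]
    p <- if (length(vf) < 2L || length(vm) < 2L) NA_real_ else
      tryCatch(stats::t.test(vf, vm, var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, level = NA_character_,
      all = fmt_cont(values), female = fmt_cont(vf), male = fmt_cont(vm),
      p = p, stringsAsFactors = FALSE)
  }
  add_cat <- function(name, values) {
    values <- if (is.logical(values)) ifelse(values, "yes", "no") else as.character(values)
    lev <- sort(unique(values))
    if (all(c("yes", "no") %in% lev)) lev <- "yes"  # flags: report the yes row
    for (lv in lev) {
      yes <- values == lv
      tab <- rbind(c(sum(yes & is_f), sum(!yes & is_f)),
                   c(sum(yes & !is_f), sum(!yes & !is_f)))
      p <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) NA_real_ else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      fmt <- function(num, den) sprintf("%d (%.2f%%)", num, 100 * num / den)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = name, level = lv,
        all = fmt(sum(yes), length(yes)),
        female = fmt(sum(yes & is_f), sum(is_f)),
        male = fmt(sum(yes & !is_f), sum(!is_f)),
        p = p, stringsAsFactors = FALSE)
    }
  }

  for (v in cont_vars) add_cont(v, cohort[[v]])
  for (v in cat_vars) add_cat(v, cohort[[v]])
  if (!is.null(comp)) {
    W <- if (inherits(comp, "cell_composition")) comp$values else as.matrix(comp)
    for (ct in colnames(W)) {
      vals <- W[, ct]
      vf <- vals[is_f]; vm <- vals[!is_f]
      p <- if (length(vf) < 2L || length(vm) < 2L) NA_real_ else
        tryCatch(stats::t.test(vf, vm, var.equal = TRUE)$p.value,
                 error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = ct, level = NA_character_,
        all = sprintf("%.3f (%.3f)", mean(vals), stats::sd(vals)),
        female = sprintf("%.3f (%.3f)", mean(vf), stats::sd(vf)),
        male = sprintf("%.3f (%.3f)", mean(vm), stats::sd(vm)),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Default analysis configuration; user values override by name.
default_config <- function() {
  list(
    strata = c("overall", "female", "male"),
    covariates = c("maternal_age", "race_ethnicity", "gestational_age",
                   "season_of_birth"),
    sensitivity_exclude_complications = TRUE,
    run_betareg = TRUE,
    B = 1000L,
    ci_level = 0.95,
    seed = 1L,
    delta = 1e-3,
    min_overlap = 100L,
    f_statistic = "wilks",
    output_dir = NULL
  )
}

# Table-2-shaped wide row block for one stratum's bootstrap fit.
compositional_rows <- function(fit, stratum) {
  ctypes <- fit$basis$cell_types
  tr <- rownames(fit$composition_effects)
  out <- data.frame(stratum = stratum, trimester = tr,
                    stringsAsFactors = FALSE)
  for (ct in ctypes) {
    out[[paste0("delta_", ct)]] <- fit$composition_effects[, ct]
    out[[paste0("lo_", ct)]] <- fit$ci[, ct, "lower"]
    out[[paste0("hi_", ct)]] <- fit$ci[, ct, "upper"]
  }
  out$overall_p <- unname(fit$overall_p[tr])
  out$n <- fit$n_samples
  rownames(out) <- NULL
  out
}

# Table-3-shaped wide row block for one stratum's beta-regression fits.
betareg_rows <- function(fits, stratum, exposures, ci_level) {
  tr <- paste0("t", seq_along(exposures))
  out <- data.frame(stratum = stratum, trimester = tr,
                    stringsAsFactors = FALSE)
  for (ct in names(fits)) {
    est <- lo <- hi <- p <- rep(NA_real_, length(tr))
    f <- fits[[ct]]
    if (!is.null(f) && isTRUE(f$converged)) {
      w <- wald_summary(f, ci_level)
      i <- match(exposures, w$term)
      est <- w$estimate[i]; lo <- w$ci_lower[i]; hi <- w$ci_upper[i]
      p <- w$p[i]
    }
    out[[paste0("est_", ct)]] <- est
    out[[paste0("lo_", ct)]] <- lo
    out[[paste0("hi_", ct)]] <- hi
    out[[paste0("p_", ct)]] <- p
  }
  rownames(out) <- NULL
  out
}

# One full pass of the modelling stage (used for main and sensitivity runs).
model_pass <- function(comp, cohort, cfg, label) {
  ct <- comp$cell_types
  exposures <- c("pm25_t1", "pm25_t2", "pm25_t3")
  comp_tab <- NULL
  beta_tab <- NULL
  notes <- character()
  strat_n <- list()
  design_cols <- list()
  for (stratum in cfg$strata) {
    keep <- if (stratum == "overall") rep(TRUE, nrow(cohort)) else cohort$sex == stratum
    if (!any(keep)) {
      warning("stratum `", stratum, "` is empty; skipped")
      notes <- c(notes, paste0(label, "/", stratum, ": empty, skipped"))
      next
    }
    covs <- if (stratum == "overall") c("sex", cfg$covariates) else cfg$covariates
    sub_cohort <- cohort[keep, , drop = FALSE]
    sub_comp <- comp$values[keep, , drop = FALSE]
    strat_n[[stratum]] <- nrow(sub_cohort)
    fit <- tryCatch(
      bootstrap_inference(sub_comp, sub_cohort, exposures, covs,
                          B = cfg$B, ci_level = cfg$ci_level,
                          seed = cfg$seed, standardize_exposures = FALSE,
                          statistic = cfg$f_statistic),
      error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- c(notes, paste0(label, "/", stratum, "/compositional failed: ",
                               conditionMessage(fit)))
    } else {
      design_cols[[stratum]] <- fit$design_columns
      comp_tab <- rbind(comp_tab, compositional_rows(fit, stratum))
      if (anyNA(fit$overall_p))
        notes <- c(notes, paste0(label, "/", stratum,
                                 ": overall p not computable (singular residual covariance)"))
    }
    if (isTRUE(cfg$run_betareg)) {
      fits <- lapply(stats::setNames(ct, ct), function(cc) {
        f <- tryCatch(
          fit_beta_regression(sub_comp[, cc], sub_cohort, exposures, covs,
                              cell_type = cc, standardize_exposures = FALSE),
          error = function(e) e)
        if (inherits(f, "error")) {
          notes <<- c(notes, paste0(label, "/", stratum, "/betareg/", cc,
                                    " failed: ", conditionMessage(f)))
          NULL
        } else if (!isTRUE(f$converged)) {
          notes <<- c(notes, paste0(label, "/", stratum, "/betareg/", cc,
                                    " did not converge; marked failed"))
          NULL
        } else f
      })
      beta_tab <- rbind(beta_tab, betareg_rows(fits, stratum, exposures,
                                               cfg$ci_level))
    }
  }
  list(compositional = comp_tab, betareg = beta_tab, notes = notes,
       strat_n = strat_n, design_columns = design_cols)
}

#' Run the full exposure-composition analysis
#'
#' Orchestrates the study pipeline: acquire inputs (simulate, or read CSVs),
#' deconvolve bulk methylation against the reference panel, replace rounded
#' zeros, IQR-standardize the three trimester exposures on the full analytic
#' sample, then fit the compositional regression with bootstrap inference and
#' the per-cell-type beta regressions in each configured stratum (`overall`
#' adjusts for infant sex; `female`/`male` are stratified). When
#' `sensitivity_exclude_complications` is on, the modelling stage is rerun
#' excluding participants flagged for preeclampsia or eclampsia. Samples with
#' missing modelled covariates are dropped with a logged count (complete-case
#' rule).
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: `simulate` (arguments to [generate_cohort()]; used when no
#'   paths are given) or `paths` (list with `bulk`, `panel`, `cohort` CSVs);
#'   `panel_args` (arguments to [generate_reference_panel()] when
#'   simulating); `strata`; `covariates`; `B`; `ci_level`; `seed`; `delta`;
#'   `min_overlap`; `sensitivity_exclude_complications`; `run_betareg`;
#'   `f_statistic`; `output_dir` (when set, all tables are written as CSV
#'   plus a machine-readable JSON run log).
#' @return object of class `results_bundle`: composition, descriptives,
#'   compositional and beta-regression result tables (main and sensitivity),
#'   and the run log (seeds, counts at each filter, per-stratum n, notes).
#' @export
run_analysis <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the `yaml` package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$B < 100L) stop("config: B must be >= 100")
  if (cfg$ci_level <= 0.5 || cfg$ci_level >= 1)
    stop("config: ci_level must lie in (0.5, 1)")

  # --- acquire inputs -------------------------------------------------------
  if (!is.null(cfg$paths)) {
    for (p in unlist(cfg$paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    panel <- read_reference_panel(cfg$paths$panel)
    bulk <- read_bulk_matrix(cfg$paths$bulk)
    cohort <- utils::read.csv(cfg$paths$cohort, stringsAsFactors = FALSE)
    sim_meta <- NULL
  } else {
    sim_args <- cfg$simulate
    if (is.null(sim_args)) sim_args <- list(n = 226L)
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    panel_args <- cfg$panel_args
    if (is.null(panel_args)) panel_args <- list()
    if (is.null(panel_args$seed)) panel_args$seed <- cfg$seed
    panel <- do.call(generate_reference_panel, panel_args)
    sim <- do.call(generate_cohort, sim_args)
    cohort <- sim$cohort
    bulk <- mix_bulk(panel, sim$truth)
    sim_meta <- list(n = nrow(cohort), seed = sim_args$seed,
                     noise_sd = sim$truth$noise_sd,
                     composition_noise_sd = sim$truth$composition_noise_sd)
  }
  n_input <- nrow(cohort)

  # --- deconvolution --------------------------------------------------------
  comp <- estimate_composition(bulk, panel, min_overlap = cfg$min_overlap)
  comp <- replace_zeros(comp, delta = cfg$delta)

  # --- sample reconciliation and complete cases -----------------------------
  if (!setequal(comp$sample_ids, cohort$sample_id)) {
    offenders <- c(setdiff(comp$sample_ids, cohort$sample_id),
                   setdiff(cohort$sample_id, comp$sample_ids))
    stop("sample IDs do not reconcile across inputs: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }
  cohort <- cohort[match(comp$sample_ids, cohort$sample_id), , drop = FALSE]
  modelled <- c("sex", "pm25_t1", "pm25_t2", "pm25_t3", cfg$covariates)
  complete <- stats::complete.cases(cohort[, intersect(modelled, names(cohort))])
  n_dropped <- sum(!complete)
  cohort <- cohort[complete, , drop = FALSE]
  comp$values <- comp$values[complete, , drop = FALSE]
  comp$sample_ids <- comp$sample_ids[complete]

  # --- IQR standardization on the full analytic sample ----------------------
  iqr_used <- list()
  for (e in c("pm25_t1", "pm25_t2", "pm25_t3")) {
    s <- iqr_standardize(cohort[[e]])
    iqr_used[[e]] <- c(median = attr(s, "median"), iqr = attr(s, "iqr"))
    cohort[[e]] <- as.numeric(s)
  }

  descriptives <- summarize_cohort(cohort, comp)

  # --- main and sensitivity modelling passes --------------------------------
  main <- model_pass(comp, cohort, cfg, "main")
  sensitivity <- NULL
  n_flagged <- 0L
  if (isTRUE(cfg$sensitivity_exclude_complications)) {
    flagged <- as.logical(cohort$preeclampsia) | as.logical(cohort$eclampsia)
    n_flagged <- sum(flagged)
    keep <- !flagged
    comp_s <- comp
    comp_s$values <- comp$values[keep, , drop = FALSE]
    comp_s$sample_ids <- comp$sample_ids[keep]
    sensitivity <- model_pass(comp_s, cohort[keep, , drop = FALSE], cfg,
                              "sensitivity")
  }

  log <- list(
    seed = cfg$seed, B = cfg$B, ci_level = cfg$ci_level, delta = cfg$delta,
    f_statistic = cfg$f_statistic,
    covariates = cfg$covariates, strata = cfg$strata,
    n_input = n_input, n_dropped_incomplete = n_dropped,
    n_analytic = nrow(cohort),
    n_per_stratum = main$strat_n,
    design_columns = main$design_columns,
    n_complication_flagged = n_flagged,
    n_sensitivity = if (is.null(sensitivity)) NULL else nrow(cohort) - n_flagged,
    iqr_standardization = iqr_used,
    simulated = sim_meta,
    notes = c(main$notes, if (!is.null(sensitivity)) sensitivity$notes),
    package_version = as.character(utils::packageVersion("placomp")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  bundle <- structure(list(
    composition = comp,
    descriptives = descriptives,
    compositional = main$compositional,
    betareg = main$betareg,
    sensitivity_compositional = if (is.null(sensitivity)) NULL else sensitivity$compositional,
    sensitivity_betareg = if (is.null(sensitivity)) NULL else sensitivity$betareg,
    log = log
  ), class = "results_bundle")

  if (!is.null(cfg$output_dir)) write_results_bundle(bundle, cfg$output_dir)
  bundle
}

#' Write a results bundle to CSV files plus a JSON run log
#'
#' @param bundle a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  comp_df <- data.frame(sample_id = bundle$composition$sample_ids,
                        bundle$composition$values, check.names = FALSE)
  wr(comp_df, "composition.csv")
  wr(bundle$descriptives, "descriptives.csv")
  wr(bundle$compositional, "compositional_effects.csv")
  wr(bundle$betareg, "betareg_effects.csv")
  wr(bundle$sensitivity_compositional, "sensitivity_compositional_effects.csv")
  wr(bundle$sensitivity_betareg, "sensitivity_betareg_effects.csv")
  logp <- file.path(dir, "run_log.json")
  jsonlite::write_json(bundle$log, logp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, logp))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Placental composition analysis results\n")
  cat("  analytic n:", x$log$n_analytic,
      "(dropped incomplete:", x$log$n_dropped_incomplete, ")\n")
  if (!is.null(x$compositional)) {
    cat("  compositional overall p by stratum/trimester:\n")
    print(x$compositional[, c("stratum", "trimester", "overall_p")])
  }
  invisible(x)
}
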