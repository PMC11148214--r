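#' Pipeline configuration
#'
#' Collects the inputs and thresholds for the two analysis arms. All
#' threshold defaults are the study constants: genome-wide significance
#' 5e-8, MAF 0.01, clumping r^2 0.001 within a 10,000 kb window, OGTT
#' cut-offs 5.1/10/8.5 mmol/L, enzyme exclusion bounds 90/80/90/240 U/L,
#' clinical reference bounds 45/40/45/120 U/L, overweight at BMI 24 kg/m^2.
#'
#' @param arm `"cohort"`, `"mr"` or `"both"`.
#' @param cohort Participant data frame, or a path readable by
#'   [read_cohort()].
#' @param exposure,outcome Summary-statistics data frames or file paths
#'   ([read_sumstats()]); `exposure` may be a named list/vector of several
#'   exposures, in which case the first is the primary one.
#' @param ld LD table, path, or `NULL` (SNPs treated as independent).
#' @param exclusion_list Character vector of pleiotropic rsids to drop, or
#'   a path to a one-rsid-per-line file.
#' @param lfi,lipids Index/lipid sets analysed in the cohort arm.
#' @param p_threshold,maf_min,r2_threshold,window_kb MR selection/clumping
#'   thresholds.
#' @param gdm_cutoffs,exclusion_bounds,clinical_bounds,overweight_bmi
#'   Cohort thresholds.
#' @param seed Integer seed (weighted-median bootstrap, MR-PRESSO).
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param out_dir Directory for TSV outputs, or `NULL` to skip writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(arm = c("both", "cohort", "mr"),
                       cohort = NULL, exposure = NULL, outcome = NULL,
                       ld = NULL, exclusion_list = character(),
                       lfi = lfi_names(),
                       lipids = c("tg", "tc", "ldl_c", "hdl_c"),
                       p_threshold = 5e-8, maf_min = 0.01,
                       r2_threshold = 0.001, window_kb = 10000,
                       gdm_cutoffs = c(fbg = 5.1, pbg1h = 10, pbg2h = 8.5),
                       exclusion_bounds = c(alt = 90, ast = 80, ggt = 90,
                                            alp = 240),
                       clinical_bounds = c(alt = 45, ast = 40, ggt = 45,
                                           alp = 120),
                       overweight_bmi = 24, seed = 1,
                       presso_n_sim = 10000, out_dir = NULL) {
  arm <- match.arg(arm)
  stopifnot(all(gdm_cutoffs > 0), all(exclusion_bounds > 0),
            all(clinical_bounds > 0), overweight_bmi > 0,
            p_threshold > 0, maf_min > 0, r2_threshold > 0, window_kb > 0)
  structure(as.list(environment()), class = "run_config")
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Cohort arm: attrition filtering and log, derived indices, GDM diagnosis,
#' baseline table, per-LFI quartile logistic models (overall, by subtype,
#' stratified by overweight, and the clinical-range sensitivity rerun),
#' spline nonlinearity screens of each LFI against each glucose channel,
#' and crossover interaction tables for each LFI x lipid pair. MR arm:
#' instrument selection, LD clumping, harmonization (with the action log),
#' F-statistics and the full estimator report. Deterministic given the
#' config seed; any stage error is re-raised with the stage name, keeping
#' partial outputs.
#'
#' @param config A [run_config()].
#' @return List of class `gdm_pipeline` with elements `cohort` and `mr`
#'   (either may be `NULL` depending on `arm`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list(cohort = NULL, mr = NULL)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (config$arm %in% c("cohort", "both") && !is.null(config$cohort)) {
    res$cohort <- stage("cohort", .run_cohort_arm(config))
  }
  if (config$arm %in% c("mr", "both") && !is.null(config$exposure)) {
    res$mr <- stage("mr", .run_mr_arm(config))
  }
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  structure(res, class = "gdm_pipeline")
}

.run_cohort_arm <- function(config) {
  records <- .load_input(config$cohort, read_cohort)
  filt <- apply_inclusion_exclusion(records, config$exclusion_bounds)
  rec <- derive_biomarkers(filt$records)
  dx <- diagnose_gdm(rec$fbg, rec$pbg1h, rec$pbg2h, config$gdm_cutoffs)
  rec$is_gdm <- dx$is_gdm
  rec$subtype <- dx$subtype
  rec$overweight <- rec$bmi >= config$overweight_bmi

  baseline <- baseline_table(rec)
  quartile <- list(); subtype <- list(); strata <- list(); sensitivity <- list()
  rcs <- list()
  for (e in config$lfi) {
    quartile[[e]] <- fit_quartile_logistic(rec, e)
    subtype[[e]] <- fit_subtype_multinomial(rec, e)
    strata[[e]] <- list(
      overweight = tryCatch(
        fit_quartile_logistic(rec[rec$overweight, , drop = FALSE], e),
        error = function(er) er),
      non_overweight = tryCatch(
        fit_quartile_logistic(rec[!rec$overweight, , drop = FALSE], e),
        error = function(er) er))
    sens_rec <- clinical_range_filter(rec, config$clinical_bounds)
    sensitivity[[e]] <- fit_quartile_logistic(sens_rec, e)
    rcs[[e]] <- lapply(stats::setNames(nm = c("fbg", "pbg1h", "pbg2h")),
                       function(ch) fit_rcs(rec, e, ch))
  }
  interaction <- list()
  lip_rec <- rec[stats::complete.cases(rec[, config$lipids, drop = FALSE]), ,
                 drop = FALSE]
  for (e in config$lfi) {
    for (l in config$lipids) {
      interaction[[paste(e, l, sep = "_x_")]] <-
        crossover_interaction(lip_rec, e, l)
    }
  }
  list(attrition = filt$log, n_analytic = nrow(rec),
       n_gdm = sum(rec$is_gdm, na.rm = TRUE),
       prevalence = mean(rec$is_gdm, na.rm = TRUE),
       baseline = baseline, quartile = quartile, subtype = subtype,
       strata = strata, sensitivity = sensitivity, rcs = rcs,
       interaction = interaction, records = rec)
}

.run_mr_arm <- function(config) {
  exposures <- config$exposure
  if (!is.list(exposures) || is.data.frame(exposures)) {
    exposures <- list(exposure = exposures)
  }
  exposures <- lapply(exposures, .load_input, reader = read_sumstats)
  outcome <- .load_input(config$outcome, read_sumstats)
  ld <- .load_input(config$ld, read_ld)
  excl <- config$exclusion_list
  if (is.character(excl) && length(excl) == 1 && file.exists(excl)) {
    excl <- readLines(excl)
  }
  per_exposure <- lapply(names(exposures), function(nm) {
    ex <- exposures[[nm]]
    sel <- select_instruments(ex, config$p_threshold, config$maf_min, excl)
    cl <- clump(sel, ld, config$r2_threshold, config$window_kb)
    h <- harmonize(cl, outcome)
    fs <- f_statistics(h)
    m <- nrow(h$data)
    est <- list(ivw = ivw(h))
    if (m >= 3) {
      est$egger <- mr_egger(h)
      est$weighted_median <- weighted_median(h, seed = config$seed)
    }
    presso <- if (m >= 4) {
      mr_presso(h, n_sim = config$presso_n_sim, seed = config$seed)
    } else NULL
    list(name = nm, n_selected = nrow(sel), n_clumped = nrow(cl),
         harmonized = h, f = fs, estimates = est, presso = presso)
  })
  names(per_exposure) <- names(exposures)
  mvmr_est <- NULL
  if (length(exposures) >= 2) {
    hm <- harmonize_mv(exposures, outcome)
    mvmr_est <- mvmr(hm)
  }
  list(exposures = per_exposure, mvmr = mvmr_est,
       report = mr_report(per_exposure, mvmr_est))
}

#' Assemble the tabular MR report
#'
#' One row per (exposure, method): `n_snps, beta, se, or, ci_low, ci_high,
#' p, q_stat, q_p, egger_intercept, egger_intercept_p, presso_global_p`.
#'
#' @param per_exposure Per-exposure result list from the MR arm.
#' @param mvmr_est Optional MVMR estimate list.
#' @return Data frame.
#' @export
mr_report <- function(per_exposure, mvmr_est = NULL) {
  row_of <- function(exposure, est, q = NULL, egger = NULL, presso = NULL) {
    data.frame(exposure = exposure, method = est$method, n_snps = est$nsnp,
               beta = est$beta, se = est$se, or = est$or,
               ci_low = est$or_low, ci_high = est$or_high, p = est$p,
               q_stat = if (!is.null(q)) q$q else NA_real_,
               q_p = if (!is.null(q)) q$p else NA_real_,
               egger_intercept = if (!is.null(egger)) egger$intercept
                                 else NA_real_,
               egger_intercept_p = if (!is.null(egger)) egger$intercept_p
                                   else NA_real_,
               presso_global_p = if (!is.null(presso)) presso$global_p
                                 else NA_real_)
  }
  rows <- list()
  for (ex in per_exposure) {
    q <- if (nrow(ex$harmonized$data) >= 2) cochran_q(ex$harmonized) else NULL
    for (est in ex$estimates) {
      rows[[length(rows) + 1]] <-
        row_of(ex$name, est, q, ex$estimates$egger, ex$presso)
    }
    if (!is.null(ex$presso) && !is.null(ex$presso$corrected)) {
      cor <- ex$presso$corrected
      cor$method <- "MR-PRESSO (outlier-corrected)"
      rows[[length(rows) + 1]] <- row_of(ex$name, cor, q,
                                         ex$estimates$egger, ex$presso)
    }
  }
  if (!is.null(mvmr_est)) {
    for (est in mvmr_est) {
      rows[[length(rows) + 1]] <- row_of(est$method, est)
    }
  }
  do.call(rbind, rows)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$cohort)) {
    wt(res$cohort$attrition, "attrition.tsv")
    wt(as.data.frame(res$cohort$baseline), "baseline.tsv")
    or_rows <- list()
    add <- function(fit, model, stratum = "all") {
      if (inherits(fit, "gdm_quartile_fit")) {
        tab <- fit$table
        tab$p_trend <- fit$p_trend
        tab$stratum <- stratum
        tab$model <- model
        or_rows[[length(or_rows) + 1]] <<- tab
      }
    }
    for (e in names(res$cohort$quartile)) {
      add(res$cohort$quartile[[e]], "main")
      add(res$cohort$strata[[e]]$overweight, "main", "overweight")
      add(res$cohort$strata[[e]]$non_overweight, "main", "non-overweight")
      add(res$cohort$sensitivity[[e]], "sensitivity")
    }
    wt(do.call(rbind, or_rows), "quartile_or.tsv")
    sub_rows <- lapply(res$cohort$subtype, function(f) f$table)
    wt(do.call(rbind, sub_rows), "subtype_or.tsv")
    int_rows <- do.call(rbind, lapply(res$cohort$interaction, function(f) {
      data.frame(lfi = f$lfi, lipid = f$lipid,
                 p_interaction = f$p_interaction)
    }))
    wt(int_rows, "interaction.tsv")
  }
  if (!is.null(res$mr)) {
    wt(res$mr$report, "mr_report.tsv")
    for (ex in res$mr$exposures) {
      wt(ex$harmonized$log, paste0("instrument_log_", ex$name, ".tsv"))
    }
  }
  invisible(out_dir)
}

#' @export
print.gdm_pipeline <- function(x, ...) {
  if (!is.null(x$cohort)) {
    cat(sprintf("Cohort arm: %d analytic participants, %d GDM (%.1f%%); %d excluded\n",
                x$cohort$n_analytic, x$cohort$n_gdm,
                100 * x$cohort$prevalence, nrow(x$cohort$attrition)))
  }
  if (!is.null(x$mr)) {
    cat("MR arm report:\n")
    rep <- x$mr$report
    rep$or <- sprintf("%.2f (%.2f-%.2f)", rep$or, rep$ci_low, rep$ci_high)
    print(rep[, c("exposure", "method", "n_snps", "or", "p")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
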