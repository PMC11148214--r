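#' Default adjustment set for the cohort models
#'
#' Maternal age, first-trimester BMI, educational level, gravidity, parity,
#' weight gain before the OGTT, gestational age at measurement, smoking and
#' alcohol consumption. BMI enters as a continuous covariate except when the
#' exposure is HSI, whose formula already contains BMI: there BMI is entered
#' as the four-level category instead.
#'
#' @param exposure Name of the exposure column (one of [lfi_names()]).
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function(exposure = "alt") {
  bmi_term <- if (identical(exposure, "hsi")) "bmi_cat" else "bmi"
  c("age", bmi_term, "education", "gravidity", "parity",
    "weight_gain", "ga_weeks", "smoking", "alcohol")
}

# Coerce covariate columns to the types the models expect: education as an
# ordinal integer code, smoking/alcohol as three-level factors keeping
# "unknown" as its own level.
.covariate_frame <- function(records, covariates) {
  edu_levels <- c("primary-or-below", "middle", "high", "college-or-above")
  out <- list()
  for (v in covariates) {
    col <- records[[v]]
    if (is.null(col)) stop("missing covariate column: ", v, call. = FALSE)
    out[[v]] <- switch(v,
      education = if (is.numeric(col)) as.integer(col)
                  else as.integer(factor(as.character(col), levels = edu_levels)),
      smoking = factor(as.character(col), levels = c("no", "yes", "unknown")),
      alcohol = factor(as.character(col), levels = c("no", "yes", "unknown")),
      col)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(low = beta - z * se, high = beta + z * se)
}

#' Quartile logistic model for GDM risk
#'
#' Fits a maximum-likelihood logistic regression of GDM status on exposure
#' quartiles (Q2..Q4 vs Q1) plus the adjustment set, and a second model with
#' the per-quartile median assigned as a continuous score whose Wald p-value
#' is the linear trend test.
#'
#' @param records Cohort table, already filtered and passed through
#'   [derive_biomarkers()].
#' @param exposure Exposure column name (one of [lfi_names()]).
#' @param gdm Logical GDM status vector; defaults to `records$is_gdm`.
#' @param covariates Covariate column names; `character(0)` for an
#'   unadjusted model. Defaults to [default_covariates()].
#' @return Object of class `gdm_quartile_fit` with the per-quartile
#'   odds-ratio table (`$table`), `$p_trend`, the quartile cut points and the
#'   underlying [stats::glm] fits.
#' @export
fit_quartile_logistic <- function(records, exposure,
                                  gdm = records$is_gdm,
                                  covariates = default_covariates(exposure)) {
  qb <- quartile_bin(records[[exposure]])
  dat <- data.frame(y = as.integer(gdm), q = qb$labels)
  med <- tapply(records[[exposure]], qb$labels, stats::median, na.rm = TRUE)
  dat$q_med <- as.numeric(med[as.character(qb$labels)])
  if (length(covariates)) dat <- cbind(dat, .covariate_frame(records, covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]

  rhs <- paste(c("q", covariates), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("y ~", rhs)),
                    family = stats::binomial(), data = dat)
  rhs_tr <- paste(c("q_med", covariates), collapse = " + ")
  fit_tr <- stats::glm(stats::as.formula(paste("y ~", rhs_tr)),
                       family = stats::binomial(), data = dat)

  cf <- summary(fit)$coefficients
  idx <- grep("^q(Q2|Q3|Q4)$", rownames(cf))
  ci <- .wald_ci(cf[idx, 1], cf[idx, 2])
  n_cases <- tapply(dat$y, dat$q, sum)
  n_total <- as.integer(table(dat$q))
  flagged <- any(n_cases == 0 | n_cases == n_total)
  tab <- data.frame(
    exposure = exposure,
    contrast = paste(sub("^q", "", rownames(cf)[idx]), "vs Q1"),
    or = exp(cf[idx, 1]),
    ci_low = exp(ci[, "low"]),
    ci_high = exp(ci[, "high"]),
    p = cf[idx, 4],
    n_cases = as.integer(n_cases[-1]),
    n_total = n_total[-1],
    row.names = NULL
  )
  if (flagged) {
    bad <- which(n_cases[-1] == 0 | n_cases[-1] == n_total[-1])
    tab$ci_low[bad] <- 0
    tab$ci_high[bad] <- Inf
  }
  cf_tr <- summary(fit_tr)$coefficients
  p_trend <- cf_tr["q_med", 4]

  structure(list(exposure = exposure, table = tab, p_trend = p_trend,
                 cuts = qb$cuts, bin_ranges = qb$bin_ranges,
                 n_cases_q1 = as.integer(n_cases[1]), n_total_q1 = n_total[1],
                 flagged = flagged, fit = fit, fit_trend = fit_tr),
            class = "gdm_quartile_fit")
}

#' @export
print.gdm_quartile_fit <- function(x, ...) {
  cat("Quartile logistic model: GDM ~", x$exposure, "\n")
  tab <- x$table
  tab$or <- sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high)
  print(tab[, c("contrast", "or", "p", "n_cases", "n_total")],
        row.names = FALSE, digits = 3)
  cat(sprintf("P for trend (median-assigned): %.4g\n", x$p_trend))
  if (x$flagged) cat("note: empty case cell; Wald CI unreliable\n")
  invisible(x)
}

#' Baseline descriptive table by GDM status
#'
#' Continuous variables are summarised as median (IQR) and compared by the
#' Mann-Whitney rank-sum test; categorical variables as N (column %) with a
#' chi-square test; the ordinal education variable is compared by rank-sum
#' on its ordinal codes.
#'
#' @param records Cohort table (after [derive_biomarkers()] if the derived
#'   indices should appear).
#' @param gdm Logical GDM status; defaults to `records$is_gdm`.
#' @return Data frame of class `gdm_baseline` with one row per variable
#'   level: formatted group summaries, the between-group p-value, and the
#'   raw `n_gdm`, `pct_gdm`, `n_nongdm`, `pct_nongdm` counts for categorical
#'   rows.
#' @export
baseline_table <- function(records, gdm = records$is_gdm) {
  g <- as.logical(gdm)
  if (!any(g, na.rm = TRUE) || !any(!g, na.rm = TRUE)) {
    stop("baseline_table: both GDM and non-GDM groups must be non-empty",
         call. = FALSE)
  }
  keep <- !is.na(g)
  records <- records[keep, , drop = FALSE]
  g <- g[keep]
  n1 <- sum(g); n0 <- sum(!g)

  cont_vars <- intersect(c("age", "bmi", "weight_gain", "alt", "ast", "ggt",
                           "alp", "ast_alt", "hsi"), names(records))
  cat_vars <- intersect(c("education", "gravidity", "parity", "smoking",
                          "alcohol"), names(records))
  rows <- list()
  fmt_med <- function(v) sprintf("%.1f (%.1f, %.1f)",
                                 stats::median(v, na.rm = TRUE),
                                 stats::quantile(v, 0.25, na.rm = TRUE),
                                 stats::quantile(v, 0.75, na.rm = TRUE))
  for (v in cont_vars) {
    x1 <- records[[v]][g]; x0 <- records[[v]][!g]
    p <- suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "", gdm = fmt_med(x1), nongdm = fmt_med(x0),
      p = p, n_gdm = NA_integer_, pct_gdm = NA_real_,
      n_nongdm = NA_integer_, pct_nongdm = NA_real_)
  }
  # collapse gravidity to 1 / >=2 and parity to 0 / >=1 as conventionally shown
  cat_col <- function(v) {
    col <- records[[v]]
    if (v == "gravidity") factor(ifelse(col >= 2, ">=2", "1"), c("1", ">=2"))
    else if (v == "parity") factor(ifelse(col >= 1, ">=1", "0"), c("0", ">=1"))
    else if (v == "education")
      factor(as.character(col), c("primary-or-below", "middle", "high",
                                  "college-or-above"))
    else factor(as.character(col), c("no", "yes", "unknown"))
  }
  for (v in cat_vars) {
    f <- droplevels(cat_col(v))
    t1 <- table(f[g]); t0 <- table(f[!g])
    p <- if (v == "education") {
      suppressWarnings(stats::wilcox.test(as.integer(f)[g],
                                          as.integer(f)[!g])$p.value)
    } else {
      tt <- rbind(as.integer(t1), as.integer(t0))
      tt <- tt[, colSums(tt) > 0, drop = FALSE]
      if (ncol(tt) < 2) NA_real_
      else suppressWarnings(stats::chisq.test(tt)$p.value)
    }
    for (l in names(t1)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l,
        gdm = sprintf("%d (%.1f)", t1[[l]], 100 * t1[[l]] / n1),
        nongdm = sprintf("%d (%.1f)", t0[[l]], 100 * t0[[l]] / n0),
        p = if (l == names(t1)[1]) p else NA_real_,
        n_gdm = as.integer(t1[[l]]), pct_gdm = round(100 * t1[[l]] / n1, 1),
        n_nongdm = as.integer(t0[[l]]),
        pct_nongdm = round(100 * t0[[l]] / n0, 1))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_gdm") <- n1
  attr(out, "n_nongdm") <- n0
  class(out) <- c("gdm_baseline", "data.frame")
  out
}

#' @export
print.gdm_baseline <- function(x, ...) {
  cat(sprintf("Baseline characteristics: GDM (N=%d) vs non-GDM (N=%d)\n",
              attr(x, "n_gdm"), attr(x, "n_nongdm")))
  df <- as.data.frame(x)[, c("variable", "level", "gdm", "nongdm", "p")]
  df$p <- ifelse(is.na(df$p), "",
                 ifelse(df$p < 0.001, "<0.001", sprintf("%.3f", df$p)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Multinomial model for GDM subtypes
#'
#' Maximum-likelihood multinomial logit of subtype (i-IFG, i-IGT, b-GDM;
#' reference = non-GDM) on exposure quartiles plus the adjustment set.
#' Subtypes with an empty quartile cell are dropped from the output with a
#' warning rather than reported with a degenerate CI.
#'
#' @inheritParams fit_quartile_logistic
#' @param subtype Factor of subtype labels (levels none/i-IFG/i-IGT/b-GDM);
#'   defaults to `records$subtype`.
#' @return Object of class `gdm_subtype_fit` with `$table` (one row per
#'   subtype x contrast) and the underlying [nnet::multinom] fit.
#' @export
fit_subtype_multinomial <- function(records, exposure,
                                    subtype = records$subtype,
                                    covariates = default_covariates(exposure)) {
  qb <- quartile_bin(records[[exposure]])
  dat <- data.frame(subtype = factor(subtype, levels = gdm_subtype_levels),
                    q = qb$labels)
  if (length(covariates)) dat <- cbind(dat, .covariate_frame(records, covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]

  counts <- table(dat$subtype, dat$q)
  empty <- rownames(counts)[-1][apply(counts[-1, , drop = FALSE], 1,
                                      function(r) any(r == 0))]
  if (length(empty)) {
    warning("subtype(s) with empty quartile cells omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    dat <- dat[!(as.character(dat$subtype) %in% empty), , drop = FALSE]
  }
  dat$subtype <- droplevels(dat$subtype)
  rhs <- paste(c("q", covariates), collapse = " + ")
  fit <- nnet::multinom(stats::as.formula(paste("subtype ~", rhs)),
                        data = dat, trace = FALSE, maxit = 500)
  sm <- summary(fit)
  co <- sm$coefficients; se <- sm$standard.errors
  if (is.null(dim(co))) {  # single non-reference level
    co <- matrix(co, nrow = 1, dimnames = list(fit$lev[2], names(co)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  idx <- grep("^q(Q2|Q3|Q4)$", colnames(co))
  tabs <- lapply(rownames(co), function(s) {
    b <- co[s, idx]; sse <- se[s, idx]
    ci <- .wald_ci(b, sse)
    data.frame(exposure = exposure, subtype = s,
               contrast = paste(sub("^q", "", colnames(co)[idx]), "vs Q1"),
               or = exp(b), ci_low = exp(ci[, "low"]),
               ci_high = exp(ci[, "high"]),
               p = 2 * stats::pnorm(-abs(b / sse)), row.names = NULL)
  })
  structure(list(exposure = exposure, table = do.call(rbind, tabs),
                 omitted = empty, fit = fit, cuts = qb$cuts),
            class = "gdm_subtype_fit")
}

#' @export
print.gdm_subtype_fit <- function(x, ...) {
  cat("Multinomial subtype model: subtype ~", x$exposure,
      "(reference: non-GDM)\n")
  tab <- x$table
  tab$or <- sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high)
  print(tab[, c("subtype", "contrast", "or", "p")], row.names = FALSE,
        digits = 3)
  if (length(x$omitted))
    cat("omitted (empty cells):", paste(x$omitted, collapse = ", "), "\n")
  invisible(x)
}

#' Crossover (joint-effect) interaction analysis of an LFI with a lipid
#'
#' Dichotomises the liver index and the lipid at their sample medians (or
#' user-supplied cut points), fits a logistic model with both main effects,
#' their product and the adjustment set, and reports the four joint-category
#' odds ratios against the low/low reference plus the multiplicative
#' interaction p-value (Wald test of the product term).
#'
#' @inheritParams fit_quartile_logistic
#' @param lfi Liver-index column name.
#' @param lipid Lipid column name (e.g. `"tg"`, `"tc"`, `"ldl_c"`, `"hdl_c"`).
#' @param cut_lfi,cut_lipid Dichotomisation cut points; default = sample
#'   medians ("high" = strictly above the cut).
#' @return Object of class `gdm_interaction`: `$joint` (4-row OR table,
#'   reference cell OR fixed at 1), `$p_interaction`, the cuts and the fit.
#' @export
crossover_interaction <- function(records, lfi, lipid,
                                  gdm = records$is_gdm,
                                  covariates = default_covariates(lfi),
                                  cut_lfi = NULL, cut_lipid = NULL) {
  keep <- !is.na(records[[lfi]]) & !is.na(records[[lipid]]) & !is.na(gdm)
  records <- records[keep, , drop = FALSE]
  gdm <- gdm[keep]
  if (is.null(cut_lfi)) cut_lfi <- stats::median(records[[lfi]])
  if (is.null(cut_lipid)) cut_lipid <- stats::median(records[[lipid]])
  dat <- data.frame(y = as.integer(gdm),
                    a = as.integer(records[[lfi]] > cut_lfi),
                    b = as.integer(records[[lipid]] > cut_lipid))
  if (length(covariates)) dat <- cbind(dat, .covariate_frame(records, covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  cells <- table(dat$a, dat$b)
  flagged <- any(cells == 0)
  if (flagged) warning("crossover_interaction: empty joint cell", call. = FALSE)

  rhs <- paste(c("a * b", covariates), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("y ~", rhs)),
                    family = stats::binomial(), data = dat)
  V <- stats::vcov(fit)
  b_hat <- stats::coef(fit)
  comb <- function(w) {
    est <- sum(w * b_hat[names(w)])
    se <- sqrt(as.numeric(t(w) %*% V[names(w), names(w)] %*% w))
    c(est, se)
  }
  cells_def <- list(
    "high lfi / low lipid" = c(a = 1),
    "low lfi / high lipid" = c(b = 1),
    "high lfi / high lipid" = c(a = 1, b = 1, `a:b` = 1))
  joint <- data.frame(cell = "low lfi / low lipid", or = 1,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
  for (nm in names(cells_def)) {
    es <- comb(cells_def[[nm]])
    ci <- .wald_ci(es[1], es[2])
    joint <- rbind(joint, data.frame(
      cell = nm, or = exp(es[1]), ci_low = exp(ci[, "low"]),
      ci_high = exp(ci[, "high"]),
      p = 2 * stats::pnorm(-abs(es[1] / es[2]))))
  }
  cf <- summary(fit)$coefficients
  structure(list(lfi = lfi, lipid = lipid, joint = joint,
                 p_interaction = cf["a:b", 4],
                 cuts = c(lfi = cut_lfi, lipid = cut_lipid),
                 flagged = flagged, fit = fit),
            class = "gdm_interaction")
}

#' @export
print.gdm_interaction <- function(x, ...) {
  cat(sprintf("Crossover analysis: %s x %s (cuts %.2f / %.2f)\n",
              x$lfi, x$lipid, x$cuts[1], x$cuts[2]))
  tab <- x$joint
  tab$or <- ifelse(is.na(tab$ci_low), "1.00 (ref)",
                   sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high))
  print(tab[, c("cell", "or", "p")], row.names = FALSE, digits = 3)
  cat(sprintf("P interaction = %.3f\n", x$p_interaction))
  invisible(x)
}
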