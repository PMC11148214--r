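#' Hepatic steatosis index
#'
#' HSI is a non-invasive fatty-liver screen computed from the transaminase
#' ratio and body-mass index: `8 * ALT/AST + BMI + 2` for women (the `+2`
#' term is the female indicator; there is an analogous `+2` for diabetes
#' which is not used here because pre-existing diabetes is an exclusion
#' criterion).
#'
#' @param alt Alanine aminotransferase, U/L. Vectorised.
#' @param ast Aspartate aminotransferase, U/L.
#' @param bmi Body-mass index, kg/m^2.
#' @param female Logical; `TRUE` for a pregnancy cohort (the default).
#' @return Numeric vector of HSI values (unitless).
#' @examples
#' compute_hsi(alt = 21, ast = 14, bmi = 22) # 8*1.5 + 22 + 2 = 36
#' @export
compute_hsi <- function(alt, ast, bmi, female = TRUE) {
  if (any(alt <= 0, na.rm = TRUE) || any(ast <= 0, na.rm = TRUE) ||
      any(bmi <= 0, na.rm = TRUE)) {
    stop("compute_hsi: alt, ast and bmi must all be positive", call. = FALSE)
  }
  8 * (alt / ast) + bmi + ifelse(rep_len(female, length(alt)), 2, 0)
}

#' Subtype labels used for GDM classification
#' @keywords internal
gdm_subtype_levels <- c("none", "i-IFG", "i-IGT", "b-GDM")

#' Diagnose gestational diabetes from a 75 g OGTT
#'
#' Applies the IADPSG-style one-step criteria: GDM if fasting glucose
#' >= 5.1 mmol/L, 1-h post-load >= 10 mmol/L, or 2-h post-load >= 8.5 mmol/L
#' (all thresholds inclusive). Subtypes: `i-IFG` = elevated fasting glucose
#' only; `i-IGT` = elevated post-load glucose (either hour) without elevated
#' fasting glucose; `b-GDM` = both elevated.
#'
#' Records with any missing glucose value are flagged `available = FALSE`
#' with `NA` status rather than silently classified as non-GDM.
#'
#' @param fbg Fasting blood glucose, mmol/L.
#' @param pbg1h 1-h post-load blood glucose, mmol/L.
#' @param pbg2h 2-h post-load blood glucose, mmol/L.
#' @param cutoffs Named numeric vector of diagnostic thresholds
#'   (`fbg`, `pbg1h`, `pbg2h`), mmol/L.
#' @return A data frame with one row per input: `is_gdm`, `subtype`
#'   (factor none/i-IFG/i-IGT/b-GDM), component flags `fbg_high`,
#'   `pbg1h_high`, `pbg2h_high`, and `available`.
#' @examples
#' diagnose_gdm(5.1, 9.9, 8.4)  # i-IFG at the fasting boundary
#' diagnose_gdm(5.0, 10, 8.5)   # i-IGT, both post-load flags
#' @export
diagnose_gdm <- function(fbg, pbg1h, pbg2h,
                         cutoffs = c(fbg = 5.1, pbg1h = 10, pbg2h = 8.5)) {
  n <- max(length(fbg), length(pbg1h), length(pbg2h))
  fbg <- rep_len(fbg, n); pbg1h <- rep_len(pbg1h, n); pbg2h <- rep_len(pbg2h, n)
  if (any(c(fbg, pbg1h, pbg2h) <= 0, na.rm = TRUE)) {
    stop("diagnose_gdm: glucose values must be positive", call. = FALSE)
  }
  available <- !(is.na(fbg) | is.na(pbg1h) | is.na(pbg2h))
  fbg_high <- fbg >= cutoffs[["fbg"]]
  pbg1h_high <- pbg1h >= cutoffs[["pbg1h"]]
  pbg2h_high <- pbg2h >= cutoffs[["pbg2h"]]
  pbg_any <- pbg1h_high | pbg2h_high
  subtype <- rep(NA_character_, n)
  subtype[available & !fbg_high & !pbg_any] <- "none"
  subtype[available & fbg_high & !pbg_any] <- "i-IFG"
  subtype[available & !fbg_high & pbg_any] <- "i-IGT"
  subtype[available & fbg_high & pbg_any] <- "b-GDM"
  data.frame(
    is_gdm = ifelse(available, fbg_high | pbg_any, NA),
    subtype = factor(subtype, levels = gdm_subtype_levels),
    fbg_high = ifelse(available, fbg_high, NA),
    pbg1h_high = ifelse(available, pbg1h_high, NA),
    pbg2h_high = ifelse(available, pbg2h_high, NA),
    available = available
  )
}

# exclusion bounds for abnormally elevated liver enzymes, U/L
.exclusion_bounds <- c(alt = 90, ast = 80, ggt = 90, alp = 240)
# clinical reference upper bounds used for the sensitivity rerun, U/L
.clinical_bounds <- c(alt = 45, ast = 40, ggt = 45, alp = 120)

.history_flags <- c("hypertension", "diabetes", "heart", "hepatobiliary", "kidney")

.split_hx <- function(x) {
  if (is.list(x)) return(x)
  strsplit(ifelse(is.na(x) | x == "", "", as.character(x)), ";", fixed = TRUE)
}

#' Apply the cohort inclusion/exclusion criteria
#'
#' Drops records in this order, attributing each exclusion to the first
#' matching reason: (1) missing liver enzyme tests; (2) missing GDM
#' evaluation (any OGTT value); (3) a history of hypertensive disorders,
#' diabetes, heart, hepatobiliary or kidney disease; (4) abnormally elevated
#' liver enzymes (ALT > 90, AST > 80, GGT > 90 or ALP > 240 U/L, strictly
#' greater).
#'
#' @param records Data frame of participant records (see [read_cohort()] for
#'   the column contract). Must contain `id`, the enzyme columns
#'   `alt`, `ast`, `ggt`, `alp`, the OGTT columns `fbg`, `pbg1h`, `pbg2h`
#'   and `hx_flags` (semicolon-separated history flags, may be empty).
#' @param bounds Named upper bounds (strict) for the enzyme exclusion.
#' @return A list with `records` (the retained rows) and `log`, a data frame
#'   `(id, reason)` with one row per dropped record.
#' @export
apply_inclusion_exclusion <- function(records, bounds = .exclusion_bounds) {
  if (nrow(records) == 0) {
    return(list(records = records,
                log = data.frame(id = character(), reason = character())))
  }
  miss_liver <- is.na(records$alt) | is.na(records$ast) |
    is.na(records$ggt) | is.na(records$alp)
  miss_gdm <- is.na(records$fbg) | is.na(records$pbg1h) | is.na(records$pbg2h)
  hx <- vapply(.split_hx(records$hx_flags),
               function(f) any(f %in% .history_flags), logical(1))
  elevated <- !miss_liver &
    (records$alt > bounds[["alt"]] | records$ast > bounds[["ast"]] |
       records$ggt > bounds[["ggt"]] | records$alp > bounds[["alp"]])
  reason <- rep(NA_character_, nrow(records))
  reason[elevated] <- "elevated liver enzymes"
  reason[hx] <- "medical history"
  reason[miss_gdm] <- "missing GDM evaluation"
  reason[miss_liver] <- "missing liver tests"   # highest priority last
  keep <- is.na(reason)
  list(records = records[keep, , drop = FALSE],
       log = data.frame(id = as.character(records$id[!keep]),
                        reason = reason[!keep]))
}

#' Clinical-reference-range sensitivity filter
#'
#' Drops records with any liver enzyme strictly above the clinical reference
#' range (ALT > 45, AST > 40, GGT > 45, ALP > 120 U/L). Intended for
#' sensitivity reruns on records that already passed
#' [apply_inclusion_exclusion()].
#'
#' @inheritParams apply_inclusion_exclusion
#' @param bounds Named clinical upper bounds (strict).
#' @return The retained records.
#' @export
clinical_range_filter <- function(records, bounds = .clinical_bounds) {
  if (nrow(records) == 0) return(records)
  drop <- records$alt > bounds[["alt"]] | records$ast > bounds[["ast"]] |
    records$ggt > bounds[["ggt"]] | records$alp > bounds[["alp"]]
  records[!drop, , drop = FALSE]
}

#' Quartile binning of a biomarker
#'
#' Cut points are the sample 25th/50th/75th percentiles (linear
#' interpolation, [stats::quantile()] type 7). Bins above Q1 are left-open /
#' right-closed, so a value tied with a cut point falls in the lower bin.
#' Because published quartile bins are usually reported as observed ranges,
#' the per-bin observed min/max are returned alongside the cut points.
#'
#' @param values Numeric vector of positive biomarker values with at least
#'   four distinct values.
#' @return A list of class `quartile_bins`: `labels` (factor Q1..Q4 per
#'   value), `cuts` (the three interior cut points), and `bin_ranges`
#'   (4 x 2 matrix of observed min/max per bin).
#' @export
quartile_bin <- function(values) {
  x <- values
  if (length(unique(x[!is.na(x)])) < 4) {
    stop("quartile_bin: need at least 4 distinct values", call. = FALSE)
  }
  cuts <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE, type = 7)
  labels <- cut(x, breaks = c(-Inf, cuts, Inf),
                labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  if (any(table(labels) == 0)) {
    stop("quartile_bin: degenerate quartiles (empty bin); values too discrete",
         call. = FALSE)
  }
  rng <- t(vapply(levels(labels), function(l) {
    v <- x[!is.na(x) & labels == l]
    c(min(v), max(v))
  }, numeric(2)))
  colnames(rng) <- c("min", "max")
  structure(list(labels = labels, cuts = cuts, bin_ranges = rng),
            class = "quartile_bins")
}

#' @export
print.quartile_bins <- function(x, ...) {
  cat("Quartile bins (cuts at", paste(signif(x$cuts, 4), collapse = ", "),
      ")\n")
  print(data.frame(bin = rownames(x$bin_ranges), x$bin_ranges,
                   n = as.integer(table(x$labels))), row.names = FALSE)
  invisible(x)
}

#' BMI categories used for HSI models and overweight stratification
#'
#' Bins BMI into `<18.5`, `18.5-23.9`, `24.0-27.9`, `>=28` kg/m^2;
#' overweight is BMI >= 24 kg/m^2.
#'
#' @param bmi Numeric BMI, kg/m^2.
#' @return Factor with the four category labels.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 24, 28, Inf),
      labels = c("<18.5", "18.5-23.9", "24.0-27.9", ">=28"), right = FALSE)
}

#' Derived biomarkers for one cohort table
#'
#' Adds the hepatic steatosis index, the AST/ALT ratio, BMI category and the
#' overweight indicator (BMI >= 24 kg/m^2) to a record table.
#'
#' @inheritParams apply_inclusion_exclusion
#' @return `records` with columns `hsi`, `ast_alt`, `bmi_cat`, `overweight`
#'   appended.
#' @export
derive_biomarkers <- function(records) {
  records$hsi <- compute_hsi(records$alt, records$ast, records$bmi)
  records$ast_alt <- records$ast / records$alt
  records$bmi_cat <- bmi_category(records$bmi)
  records$overweight <- records$bmi >= 24
  records
}

#' The liver function indices studied
#' @return Character vector of column names.
#' @export
lfi_names <- function() c("alt", "ast", "ggt", "alp", "ast_alt", "hsi")
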