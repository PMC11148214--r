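.sumstats_cols <- c("rsid", "chr", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

#' Read a GWAS summary-statistics file
#'
#' Tab-delimited with the exact header `rsid, chr, pos, effect_allele,
#' other_allele, eaf, beta, se, pval, n`. Rows violating the range
#' invariants (se <= 0, eaf outside (0,1), pval outside (0,1], identical
#' alleles) are rejected with a line-numbered warning; a duplicate rsid or
#' missing column is an error.
#'
#' @param path File path.
#' @return Validated summary-statistics data frame.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.sumstats_cols, names(x))
  if (length(miss)) {
    stop("sumstats file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- x$se <= 0 | is.na(x$se) |
    x$eaf <= 0 | x$eaf >= 1 | is.na(x$eaf) |
    x$pval <= 0 | x$pval > 1 | is.na(x$pval) |
    toupper(x$effect_allele) == toupper(x$other_allele) |
    is.na(x$beta)
  if (any(bad)) {
    warning(sprintf("read_sumstats: dropped %d malformed row(s) (lines %s)",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  if (anyDuplicated(x$rsid)) {
    stop("read_sumstats: duplicate rsid(s): ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  validate_sumstats(x)
  x
}

#' Write a summary-statistics table
#'
#' Tab-delimited, numerics at 10 significant digits so a write/read
#' round-trip is an identity at that precision.
#'
#' @param x Summary-statistics data frame.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  out <- x[, .sumstats_cols]
  for (v in c("eaf", "beta", "se", "pval")) {
    out[[v]] <- formatC(out[[v]], digits = 10, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD table (`rsid_a`, `rsid_b`, `r2`, tab-delimited)
#' @param path File path.
#' @return Data frame with the three columns.
#' @export
read_ld <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(x))) {
    stop("LD file must have columns rsid_a, rsid_b, r2", call. = FALSE)
  }
  x[, need]
}

#' Write a pairwise LD table
#' @param x Data frame `rsid_a`, `rsid_b`, `r2`.
#' @param path Output path.
#' @export
write_ld <- function(x, path) {
  utils::write.table(x[, c("rsid_a", "rsid_b", "r2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cohort_cols <- c("id", "age", "bmi", "weight_gain", "ga_weeks", "education",
                  "gravidity", "parity", "smoking", "alcohol", "alt", "ast",
                  "ggt", "alp", "tc", "tg", "ldl_c", "hdl_c", "fbg", "pbg1h",
                  "pbg2h", "hx_flags")

#' Read a cohort table
#'
#' CSV or TSV (by extension; `.tsv`/`.txt` are tab-delimited) with the
#' documented header: `id, age, bmi, weight_gain, ga_weeks, education,
#' gravidity, parity, smoking, alcohol, alt, ast, ggt, alp, tc, tg, ldl_c,
#' hdl_c, fbg, pbg1h, pbg2h, hx_flags`; `hx_flags` is semicolon-separated.
#'
#' @param path File path.
#' @return Participant data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(.cohort_cols, names(x))
  if (length(miss)) {
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$hx_flags[is.na(x$hx_flags)] <- ""
  x
}

#' Write a cohort table (CSV)
#' @param x Participant data frame.
#' @param path Output path.
#' @export
write_cohort <- function(x, path) {
  out <- x[, intersect(.cohort_cols, names(x))]
  num <- vapply(out, is.numeric, logical(1))
  for (v in names(out)[num]) out[[v]] <- formatC(out[[v]], digits = 10,
                                                 format = "g")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic bundle (cohort CSV, sumstats TSVs, LD TSV, truth JSON)
#'
#' @param dir Output directory (created if needed).
#' @param cohort Output of [simulate_cohort()], or `NULL`.
#' @param gwas Output of [simulate_gwas_pair()], or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(dir, cohort = NULL, gwas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  if (!is.null(cohort)) {
    write_cohort(cohort$records, file.path(dir, "cohort.csv"))
    truth$cohort <- cohort$truth
  }
  if (!is.null(gwas)) {
    write_sumstats(gwas$exposure, file.path(dir, "exposure.tsv"))
    write_sumstats(gwas$outcome, file.path(dir, "outcome.tsv"))
    write_ld(gwas$ld, file.path(dir, "ld.tsv"))
    truth$gwas <- gwas$truth
  }
  writeLines(.to_json(truth), file.path(dir, "truth.json"))
  invisible(dir)
}

# minimal JSON serializer for the truth record (numbers, strings, logicals,
# named lists, vectors/matrices)
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  one <- function(v) {
    if (is.null(v)) return("null")
    if (is.matrix(v)) {
      return(paste0("[", paste(apply(v, 1, function(r)
        paste0("[", paste(formatC(r, digits = 12, format = "g"),
                          collapse = ","), "]")), collapse = ","), "]"))
    }
    if (is.list(v)) {
      nm <- names(v)
      return(paste0("{", paste0('"', esc(nm), '":',
                                vapply(v, one, character(1)),
                                collapse = ","), "}"))
    }
    fmt <- function(z) {
      if (is.character(z)) paste0('"', esc(z), '"')
      else if (is.logical(z)) ifelse(z, "true", "false")
      else formatC(z, digits = 12, format = "g")
    }
    if (length(v) == 1) fmt(v)
    else paste0("[", paste(vapply(v, fmt, character(1)), collapse = ","), "]")
  }
  one(x)
}
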