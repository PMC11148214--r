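#' Validate a GWAS summary-statistics table
#'
#' Checks the per-SNP association-table contract: required columns, unique
#' rsids, positive standard errors, allele frequency in (0,1), p-values in
#' (0,1], and distinct alleles.
#'
#' @param x Data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n` (and usually `chr`, `pos`).
#' @return `x`, invisibly, after validation.
#' @export
validate_sumstats <- function(x) {
  need <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sumstats missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$rsid)) stop("sumstats: duplicate rsid", call. = FALSE)
  if (any(x$se <= 0)) stop("sumstats: se must be > 0", call. = FALSE)
  if (any(x$eaf <= 0 | x$eaf >= 1)) {
    stop("sumstats: eaf must be in (0,1)", call. = FALSE)
  }
  if (any(x$pval <= 0 | x$pval > 1)) {
    stop("sumstats: pval must be in (0,1]", call. = FALSE)
  }
  if (any(toupper(x$effect_allele) == toupper(x$other_allele))) {
    stop("sumstats: effect and other allele must differ", call. = FALSE)
  }
  invisible(x)
}

#' Select genetic instruments from exposure summary statistics
#'
#' Keeps SNPs at genome-wide significance (p strictly below `p_threshold`)
#' with minor allele frequency strictly above `maf_min`, excluding any rsid
#' on the user-supplied pleiotropy exclusion list (the stand-in for a GWAS
#' Catalog screen of variants associated with other traits).
#'
#' @param sumstats Exposure summary statistics (see [validate_sumstats()]).
#' @param p_threshold Significance threshold (default 5e-8, strict `<`).
#' @param maf_min Minimum minor allele frequency (default 0.01, strict `>`).
#' @param exclusion_list Character vector of rsids to drop.
#' @return The retained rows of `sumstats`.
#' @export
select_instruments <- function(sumstats, p_threshold = 5e-8, maf_min = 0.01,
                               exclusion_list = character()) {
  validate_sumstats(sumstats)
  maf <- pmin(sumstats$eaf, 1 - sumstats$eaf)
  keep <- sumstats$pval < p_threshold & maf > maf_min &
    !(sumstats$rsid %in% exclusion_list)
  out <- sumstats[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no valid instruments", call. = FALSE)
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the lowest-p-value unassigned SNP as the index and
#' discards every unassigned SNP within `window_kb` of it whose pairwise r^2
#' with the index exceeds `r2_threshold`. Ties in p-value are broken by
#' lexicographic rsid order. SNP pairs absent from the LD table are treated
#' as r^2 = 0 (a warning notes that at least one lookup was missing).
#'
#' @param snps Summary statistics with `chr` and `pos` (base pairs) columns.
#' @param ld Data frame `rsid_a`, `rsid_b`, `r2` of pairwise r^2 values
#'   (order-insensitive), or `NULL` to treat all SNPs as independent.
#' @param r2_threshold r^2 above which a neighbour is discarded
#'   (default 0.001).
#' @param window_kb Window half-width in kb (default 10,000).
#' @return The retained (index) SNP rows, in the original row order.
#' @export
clump <- function(snps, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  validate_sumstats(snps)
  if (is.null(snps$pos) || any(is.na(snps$pos)) ||
      is.null(snps$chr) || any(is.na(snps$chr))) {
    stop("clump: chr/pos required for every SNP", call. = FALSE)
  }
  r2_lookup <- new.env(parent = emptyenv())
  if (!is.null(ld) && nrow(ld)) {
    key <- ifelse(ld$rsid_a < ld$rsid_b,
                  paste(ld$rsid_a, ld$rsid_b), paste(ld$rsid_b, ld$rsid_a))
    for (i in seq_along(key)) assign(key[i], ld$r2[i], envir = r2_lookup)
  }
  missing_pair <- FALSE
  get_r2 <- function(a, b) {
    k <- if (a < b) paste(a, b) else paste(b, a)
    if (exists(k, envir = r2_lookup, inherits = FALSE)) {
      get(k, envir = r2_lookup)
    } else {
      missing_pair <<- TRUE
      0
    }
  }
  ord <- order(snps$pval, snps$rsid)
  alive <- rep(TRUE, nrow(snps))
  keep <- logical(nrow(snps))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & snps$chr == snps$chr[i] &
                    abs(snps$pos - snps$pos[i]) <= window_kb * 1000)
    for (j in near) {
      if (get_r2(snps$rsid[i], snps$rsid[j]) > r2_threshold) alive[j] <- FALSE
    }
  }
  if (missing_pair && !is.null(ld)) {
    warning("clump: some SNP pairs missing from the LD table; treated as r2 = 0",
            call. = FALSE)
  }
  snps[keep, , drop = FALSE]
}

.palindromic <- function(a1, a2) {
  p <- paste(toupper(a1), toupper(a2))
  p %in% c("A T", "T A", "C G", "G C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on rsid and expresses every retained outcome
#' effect for the exposure's effect allele. Matching alleles are kept as-is;
#' swapped alleles flip the outcome effect (`beta := -beta`,
#' `eaf := 1 - eaf`); palindromic SNPs (A/T or C/G) are dropped regardless
#' of frequency because their strand cannot be resolved; any other allele
#' configuration is dropped as a mismatch. Every action is logged.
#'
#' @param exposure,outcome Summary-statistics tables
#'   (see [validate_sumstats()]).
#' @return Object of class `harmonized_set`: data frame `$data` with
#'   `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, and `$log` with one `(rsid, action)` row per exposure SNP
#'   (actions: kept, flipped, dropped_palindromic, dropped_mismatch,
#'   dropped_missing).
#' @export
harmonize <- function(exposure, outcome) {
  validate_sumstats(exposure)
  validate_sumstats(outcome)
  om <- match(exposure$rsid, outcome$rsid)
  action <- rep("dropped_missing", nrow(exposure))
  ea_x <- toupper(exposure$effect_allele); oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(outcome$effect_allele[om]); oa_y <- toupper(outcome$other_allele[om])
  found <- !is.na(om)
  pal <- .palindromic(ea_x, oa_x)
  same <- found & ea_x == ea_y & oa_x == oa_y
  swapped <- found & ea_x == oa_y & oa_x == ea_y
  action[found & pal] <- "dropped_palindromic"
  action[found & !pal & same] <- "kept"
  action[found & !pal & swapped] <- "flipped"
  action[found & !pal & !same & !swapped] <- "dropped_mismatch"

  keep <- action %in% c("kept", "flipped")
  if (!any(found)) stop("harmonize: no shared SNPs", call. = FALSE)
  sgn <- ifelse(action[keep] == "flipped", -1, 1)
  dat <- data.frame(
    rsid = exposure$rsid[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    beta_out = sgn * outcome$beta[om[keep]], se_out = outcome$se[om[keep]],
    eaf_exp = exposure$eaf[keep],
    eaf_out = ifelse(sgn < 0, 1 - outcome$eaf[om[keep]],
                     outcome$eaf[om[keep]]),
    row.names = NULL
  )
  structure(list(data = dat,
                 log = data.frame(rsid = exposure$rsid, action = action)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", nrow(x$data), "SNPs retained\n")
  print(table(x$log$action))
  invisible(x)
}

#' Instrument-strength F-statistics
#'
#' Per-SNP F = (beta_exp / se_exp)^2 and their arithmetic mean; a mean at or
#' below the conventional strong-instrument threshold of 10 triggers a
#' weak-instrument warning.
#'
#' @param h A [harmonize()]d set (or its `$data` data frame).
#' @return List with `f` (per-SNP, named by rsid) and `mean_f`.
#' @export
f_statistics <- function(h) {
  d <- .h_data(h)
  if (nrow(d) < 1) stop("f_statistics: need at least one SNP", call. = FALSE)
  f <- (d$beta_exp / d$se_exp)^2
  names(f) <- d$rsid
  mf <- mean(f)
  if (mf <= 10) {
    warning(sprintf("weak instruments: mean F = %.2f <= 10", mf),
            call. = FALSE)
  }
  list(f = f, mean_f = mf)
}

.h_data <- function(h) {
  if (is.data.frame(h)) return(h)
  if (is.list(h) && !is.null(h$data)) return(h$data)
  stop("expected a harmonized set or a data frame of harmonized effects",
       call. = FALSE)
}

new_mr_estimate <- function(method, beta, se, nsnp, p = NULL, df = NULL, ...) {
  z <- beta / se
  if (is.null(p)) {
    p <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  }
  q <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - q * se, ci_high = beta + q * se,
                 or = exp(beta), or_low = exp(beta - q * se),
                 or_high = exp(beta + q * se), p = p, nsnp = nsnp, ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR = %.2f (95%% CI %.2f-%.2f), beta = %.4g (SE %.3g), p = %.3g, nsnp = %d\n",
              x$method, x$or, x$or_low, x$or_high, x$beta, x$se, x$p, x$nsnp))
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran Q = %.2f (df %d), p = %.3g\n",
                x$q_stat, x$q_df, x$q_p))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Wald ratio causal estimate for a single SNP
#'
#' beta = beta_out / beta_exp; the standard error uses the first-order delta
#' method, se_out / |beta_exp| (exposure-side uncertainty enters only
#' through the instrument-strength diagnostics).
#'
#' @param snp One-row harmonized data frame (or list) with `beta_exp`,
#'   `beta_out`, `se_out`.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(snp) {
  d <- .h_data(snp)
  if (d$beta_exp[1] == 0) stop("wald_ratio: beta_exp = 0", call. = FALSE)
  new_mr_estimate("Wald ratio", d$beta_out[1] / d$beta_exp[1],
                  d$se_out[1] / abs(d$beta_exp[1]), nsnp = 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-SNP Wald ratios weighted by the reciprocal of the
#' outcome variance: beta = sum(w theta) / sum(w) with
#' w_j = beta_exp_j^2 / se_out_j^2, equivalent to the zero-intercept
#' weighted regression of beta_out on beta_exp with weights 1/se_out^2.
#' The reported standard error uses multiplicative random effects,
#' `se_fixed * max(1, sqrt(Q/(m-1)))`, which inflates the fixed-effect SE
#' under heterogeneity and never deflates it; the fixed-effect SE is also
#' returned. With one SNP this reduces to [wald_ratio()].
#'
#' @param h A [harmonize()]d set.
#' @return An `mr_estimate` with Cochran Q diagnostics attached
#'   (`q_stat`, `q_df`, `q_p`) and `se_fixed`.
#' @export
ivw <- function(h) {
  d <- .h_data(h)
  if (all(d$beta_exp == 0)) stop("ivw: all beta_exp are zero", call. = FALSE)
  m <- nrow(d)
  if (m == 1) return(wald_ratio(d))
  theta <- d$beta_out / d$beta_exp
  w <- d$beta_exp^2 / d$se_out^2
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (theta - beta)^2)
  scale <- max(1, sqrt(Q / (m - 1)))
  est <- new_mr_estimate("IVW (multiplicative random effects)", beta,
                         se_fixed * scale, nsnp = m,
                         se_fixed = se_fixed,
                         q_stat = Q, q_df = m - 1L,
                         q_p = stats::pchisq(Q, m - 1, lower.tail = FALSE))
  est
}

#' Cochran's Q heterogeneity test across per-SNP Wald ratios
#'
#' Q = sum w_j (theta_j - beta_ivw)^2 with inverse-variance weights
#' w_j = beta_exp_j^2 / se_out_j^2, referred to a chi-square with m-1
#' degrees of freedom.
#'
#' @param h A [harmonize()]d set.
#' @param ivw_beta The IVW point estimate; computed from `h` if omitted.
#' @return List `(q, df, p)`.
#' @export
cochran_q <- function(h, ivw_beta = NULL) {
  d <- .h_data(h)
  if (nrow(d) < 2) stop("cochran_q: need >= 2 SNPs", call. = FALSE)
  theta <- d$beta_out / d$beta_exp
  w <- d$beta_exp^2 / d$se_out^2
  if (is.null(ivw_beta)) ivw_beta <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - ivw_beta)^2)
  df <- nrow(d) - 1L
  list(q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of beta_out on beta_exp with a free intercept and
#' weights 1/se_out^2, after orienting every SNP so beta_exp >= 0. The slope
#' is the causal estimate; the intercept with its p-value is the test for
#' directional pleiotropy. Standard errors use the regression sigma floored
#' at 1 (no deflation below the fixed-effect SE) and t reference with m-2
#' degrees of freedom.
#'
#' @param h A [harmonize()]d set of at least 3 SNPs.
#' @return An `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(h) {
  d <- .h_data(h)
  m <- nrow(d)
  if (m < 3) stop("mr_egger: need >= 3 SNPs", call. = FALSE)
  sgn <- ifelse(d$beta_exp < 0, -1, 1)
  x <- sgn * d$beta_exp
  y <- sgn * d$beta_out
  w <- 1 / d$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma_adj <- max(1, sm$sigma)
  cf <- sm$coefficients
  se_slope <- cf["x", 2] / sm$sigma * sigma_adj
  se_int <- cf["(Intercept)", 2] / sm$sigma * sigma_adj
  new_mr_estimate("MR-Egger", cf["x", 1], se_slope, nsnp = m, df = m - 2,
                  intercept = cf["(Intercept)", 1], intercept_se = se_int,
                  intercept_p = 2 * stats::pt(-abs(cf["(Intercept)", 1] / se_int),
                                              m - 2))
}

#' Weighted-median causal estimate
#'
#' Orders the per-SNP Wald ratios, weights them by the inverse variance of
#' the ratio (normalised to sum to 1), and takes the ratio at cumulative
#' weight 0.5 by linear interpolation. Consistent when at least half the
#' total instrument weight comes from valid instruments. The standard error
#' is a seeded parametric bootstrap: beta_exp and beta_out are resampled
#' from normal distributions with the reported SEs and the estimator is
#' recomputed.
#'
#' @param h A [harmonize()]d set of at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and returns `NA` SE.
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1) {
  d <- .h_data(h)
  if (nrow(d) < 3) stop("weighted_median: need >= 3 SNPs", call. = FALSE)
  wm <- function(beta_exp, beta_out, se_out) {
    theta <- beta_out / beta_exp
    w <- (beta_exp / se_out)^2
    o <- order(theta)
    theta <- theta[o]
    w <- w[o] / sum(w)
    cum <- cumsum(w) - w / 2
    stats::approx(cum, theta, xout = 0.5, rule = 2)$y
  }
  est <- wm(d$beta_exp, d$beta_out, d$se_out)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        be <- stats::rnorm(nrow(d), d$beta_exp, d$se_exp)
        bo <- stats::rnorm(nrow(d), d$beta_out, d$se_out)
        wm(be, bo, d$se_out)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  new_mr_estimate("Weighted median", est, se, nsnp = nrow(d),
                  p = if (is.na(se)) NA_real_ else
                    2 * stats::pnorm(-abs(est / se)))
}

# Run code with a private RNG state so callers' streams are untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Multivariable MR (MVMR)
#'
#' Zero-intercept weighted multivariable regression of the outcome effects
#' on the matrix of exposure effects with weights 1/se_out^2, giving each
#' exposure's direct effect conditional on the others (typically used to
#' condition a liver-enzyme effect on BMI). Standard errors use the same
#' multiplicative random-effects convention as [ivw()] (residual scale
#' floored at the fixed-effect value).
#'
#' @param h_multi List (or class `harmonized_multi`) with `beta_exp`
#'   (m x k matrix, columns named by exposure), `se_exp` (m x k), `beta_out`
#'   and `se_out` (length m), all harmonized to a common effect-allele
#'   orientation.
#' @return Named list of `mr_estimate` objects, one per exposure.
#' @export
mvmr <- function(h_multi) {
  X <- as.matrix(h_multi$beta_exp)
  y <- h_multi$beta_out
  w <- 1 / h_multi$se_out^2
  m <- nrow(X); k <- ncol(X)
  if (m <= k) stop("mvmr: need more SNPs than exposures", call. = FALSE)
  zero_col <- apply(X, 2, function(c) all(c == 0))
  if (any(zero_col)) {
    warning("mvmr: exposure(s) with all-zero effects dropped: ",
            paste(colnames(X)[zero_col], collapse = ", "), call. = FALSE)
    X <- X[, !zero_col, drop = FALSE]
    k <- ncol(X)
  }
  if (qr(X)$rank < k) {
    stop("mvmr: exposure effect matrix is rank deficient", call. = FALSE)
  }
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  bhat <- solve(XtX, crossprod(Xw, yw))
  resid <- yw - Xw %*% bhat
  sigma2 <- sum(resid^2) / (m - k)
  V <- solve(XtX) * max(1, sigma2)
  out <- lapply(seq_len(k), function(j) {
    new_mr_estimate(paste0("MVMR (", colnames(X)[j], ")"),
                    bhat[j], sqrt(V[j, j]), nsnp = m)
  })
  names(out) <- colnames(X)
  out
}

#' Harmonize several exposures and one outcome for MVMR
#'
#' Restricts to SNPs present (and non-palindromic, allele-compatible) in
#' every exposure and the outcome, orienting all effects to the first
#' exposure's effect allele.
#'
#' @param exposures Named list of exposure summary-statistics tables.
#' @param outcome Outcome summary statistics.
#' @return Object of class `harmonized_multi` (see [mvmr()]).
#' @export
harmonize_mv <- function(exposures, outcome) {
  stopifnot(length(exposures) >= 2, !is.null(names(exposures)))
  ref <- exposures[[1]]
  hs <- lapply(exposures[-1], function(e) harmonize(ref, e))
  ho <- harmonize(ref, outcome)
  common <- Reduce(intersect, c(list(ho$data$rsid),
                                lapply(hs, function(h) h$data$rsid)))
  if (length(common) == 0) stop("harmonize_mv: no shared SNPs", call. = FALSE)
  i_ref <- match(common, ref$rsid)
  beta_exp <- cbind(ref$beta[i_ref])
  se_exp <- cbind(ref$se[i_ref])
  for (h in hs) {
    i <- match(common, h$data$rsid)
    beta_exp <- cbind(beta_exp, h$data$beta_out[i])
    se_exp <- cbind(se_exp, h$data$se_out[i])
  }
  colnames(beta_exp) <- colnames(se_exp) <- names(exposures)
  io <- match(common, ho$data$rsid)
  structure(list(rsid = common, beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = ho$data$beta_out[io],
                 se_out = ho$data$se_out[io]),
            class = "harmonized_multi")
}
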