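#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based horizontal-pleiotropy diagnostic. The global test
#' compares the observed weighted residual sum of squares of leave-one-out
#' IVW fits against its parametric null distribution (`n_sim` seeded draws
#' of beta_exp and beta_out from normal distributions with the reported
#' SEs); the empirical p-value is floored at 1/`n_sim`. Each SNP's observed
#' squared residual is compared with its own simulated distribution to give
#' a per-SNP outlier p-value, Bonferroni-adjusted across SNPs. When
#' outliers are found, the outlier-corrected estimate is the IVW fit on the
#' remaining SNPs, and a distortion test compares the observed
#' corrected-minus-full difference against differences obtained by removing
#' random SNP subsets of the same size.
#'
#' @param h A [harmonize()]d set of at least 4 SNPs.
#' @param n_sim Parametric simulations for the null distributions
#'   (default 10000).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed Integer seed.
#' @param significance_threshold Declared threshold the global p-value will
#'   be compared against downstream; a warning is issued when 1/`n_sim`
#'   cannot resolve it.
#' @return List of class `mr_presso`: `global_rss`, `global_p`, `outliers`
#'   (rsids), `outlier_p` (Bonferroni-adjusted, named), `corrected`
#'   (`mr_estimate` on non-outliers, `NULL` when no outliers),
#'   `distortion_p` (`NA` when no outliers), and `raw` (full-set IVW).
#' @export
mr_presso <- function(h, n_sim = 10000, outlier_alpha = 0.05, seed = 1,
                      significance_threshold = 0.05) {
  d <- .h_data(h)
  m <- nrow(d)
  if (m < 4) stop("mr_presso: need >= 4 SNPs", call. = FALSE)
  if (1 / n_sim > significance_threshold) {
    warning(sprintf(
      "mr_presso: empirical p floor 1/%d exceeds the declared threshold %g",
      n_sim, significance_threshold), call. = FALSE)
  }
  w <- 1 / d$se_out^2
  loo_slopes <- function(x, y) {
    sxy <- sum(w * x * y); sxx <- sum(w * x^2)
    (sxy - w * x * y) / (sxx - w * x^2)
  }
  slope_loo <- loo_slopes(d$beta_exp, d$beta_out)
  res_obs <- w * (d$beta_out - slope_loo * d$beta_exp)^2
  rss_obs <- sum(res_obs)

  sim <- .with_seed(seed, {
    rss_sim <- numeric(n_sim)
    exceed <- numeric(m)            # per-SNP count of sim residual >= observed
    chunk <- 2000L
    done <- 0L
    while (done < n_sim) {
      s <- min(chunk, n_sim - done)
      Xs <- matrix(stats::rnorm(m * s, d$beta_exp, d$se_exp), m, s)
      Ys <- matrix(stats::rnorm(m * s, slope_loo * d$beta_exp, d$se_out), m, s)
      sxy <- colSums(w * Xs * Ys)
      sxx <- colSums(w * Xs^2)
      num <- sweep(-(w * Xs * Ys), 2, sxy, `+`)
      den <- sweep(-(w * Xs^2), 2, sxx, `+`)
      slo <- num / den
      res <- w * (Ys - slo * Xs)^2
      rss_sim[(done + 1):(done + s)] <- colSums(res)
      exceed <- exceed + rowSums(res >= res_obs)
      done <- done + s
    }
    list(rss_sim = rss_sim, exceed = exceed)
  })
  global_p <- max(mean(sim$rss_sim >= rss_obs), 1 / n_sim)
  p_raw <- pmax(sim$exceed / n_sim, 1 / n_sim)
  p_adj <- pmin(p_raw * m, 1)
  names(p_adj) <- d$rsid
  outliers <- d$rsid[p_adj < outlier_alpha]

  raw <- ivw(d)
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers)) {
    keep <- !(d$rsid %in% outliers)
    if (sum(keep) >= 2) {
      corrected <- ivw(d[keep, , drop = FALSE])
      d_obs <- corrected$beta - raw$beta
      n_rm <- length(outliers)
      d_sim <- .with_seed(seed + 1L, {
        vapply(seq_len(min(n_sim, 2000L)), function(i) {
          drop <- sample.int(m, n_rm)
          ivw(d[-drop, , drop = FALSE])$beta - raw$beta
        }, numeric(1))
      })
      distortion_p <- mean(abs(d_sim) >= abs(d_obs))
    }
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outliers = outliers, outlier_p = p_adj,
                 corrected = corrected, distortion_p = distortion_p,
                 raw = raw, n_sim = n_sim),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4g, p = %.3g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected)) {
      cat("outlier-corrected "); print(x$corrected)
      cat(sprintf("distortion test p = %.3g\n", x$distortion_p))
    }
  } else {
    cat("no outliers detected\n")
  }
  invisible(x)
}
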