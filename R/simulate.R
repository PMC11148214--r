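#' Configuration for the synthetic pregnancy cohort
#'
#' Defaults emulate a hospital-based pregnancy cohort screened at 8-14
#' gestational weeks: log-normal liver enzymes and lipids with a realistic
#' correlation structure, covariate frequencies in the range typically
#' reported for such cohorts, and OGTT glucose channels whose shared
#' intercept is calibrated so the realized GDM prevalence matches
#' `prevalence_target` (default 18.2%).
#'
#' Biomarker effects are expressed per standard deviation of the
#' log-biomarker, in standard-deviation units of each glucose channel; the
#' default effect matrix is zero (a pure null), so analyses that need signal
#' set the relevant entries explicitly.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param prevalence_target Target realized GDM prevalence (default 0.182).
#' @param effects 8 x 3 matrix (rows `alt`, `ast`, `ggt`, `alp`, `tg`,
#'   `tc`, `ldl_c`, `hdl_c`; columns `fbg`, `pbg1h`, `pbg2h`) of per-SD
#'   effects on each channel's latent value, in channel SDs.
#' @param interaction List `(lfi, lipid, effect)` adding
#'   `effect * z(lfi) * z(lipid)` to every post-load channel; effect 0 by
#'   default. `lfi` may be any of [lfi_names()], `lipid` any lipid column.
#' @param age_effect,bmi_effect Covariate effects on every channel
#'   (channel SDs per year of age beyond the mean / per SD of log-BMI).
#' @param log_means,log_sds Length-8 biomarker log-scale locations/spreads.
#' @param corr 8 x 8 biomarker log-scale correlation matrix
#'   (positive definite).
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 10000, seed = 1, prevalence_target = 0.182,
                              effects = matrix(0, 8, 3),
                              interaction = list(lfi = "ast_alt",
                                                 lipid = "tg", effect = 0),
                              age_effect = 0.03, bmi_effect = 0.30,
                              log_means = log(c(alt = 13, ast = 16.5,
                                                ggt = 11, alp = 49,
                                                tg = 1.3, tc = 4.4,
                                                ldl_c = 2.3, hdl_c = 1.7)),
                              log_sds = c(0.45, 0.22, 0.40, 0.22,
                                          0.35, 0.15, 0.25, 0.18),
                              corr = .default_biomarker_corr()) {
  stopifnot(prevalence_target > 0, prevalence_target < 1,
            nrow(effects) == 8, ncol(effects) == 3,
            length(log_means) == 8, length(log_sds) == 8,
            all(dim(corr) == c(8, 8)))
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("biomarker correlation matrix not positive definite",
                         call. = FALSE)
  dimnames(effects) <- list(.biomarker_names, .channel_names)
  structure(list(n = n, seed = seed, prevalence_target = prevalence_target,
                 effects = effects, interaction = interaction,
                 age_effect = age_effect, bmi_effect = bmi_effect,
                 log_means = log_means, log_sds = log_sds, corr = corr),
            class = "cohort_sim_config")
}

.biomarker_names <- c("alt", "ast", "ggt", "alp", "tg", "tc", "ldl_c", "hdl_c")
.channel_names <- c("fbg", "pbg1h", "pbg2h")
# channel means and SDs (mmol/L) before the calibrated shared shift
.channel_mu <- c(fbg = 4.4, pbg1h = 7.6, pbg2h = 6.6)
.channel_sd <- c(fbg = 0.45, pbg1h = 1.5, pbg2h = 1.3)

.default_biomarker_corr <- function() {
  R <- diag(8)
  dimnames(R) <- list(.biomarker_names, .biomarker_names)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("alt", "ast", 0.65); set_r("alt", "ggt", 0.45)
  set_r("ast", "ggt", 0.35); set_r("alt", "alp", 0.15)
  set_r("ast", "alp", 0.15); set_r("ggt", "alp", 0.20)
  set_r("alt", "tg", 0.20); set_r("ggt", "tg", 0.25)
  set_r("tg", "tc", 0.35); set_r("tc", "ldl_c", 0.80)
  set_r("tc", "hdl_c", 0.25); set_r("tg", "hdl_c", -0.25)
  set_r("ldl_c", "hdl_c", 0.10)
  R
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a pregnancy cohort with known ground truth
#'
#' Draws covariates and multivariate log-normal biomarkers, builds the
#' three OGTT glucose channels as linear predictors on the standardized
#' log-biomarkers plus covariates plus noise, and calibrates a shared
#' intercept shift across the channels by bisection so that the realized
#' GDM prevalence (through [diagnose_gdm()]) hits the configured target
#' within +/- 0.01. Fully reproducible under the config seed.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `records` (a participant table ready for
#'   [apply_inclusion_exclusion()] / [derive_biomarkers()]) and `truth`
#'   (the realized ground-truth parameters, including the effect matrix,
#'   the calibrated shift and the realized prevalence).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n
  .with_seed(config$seed, {
    age <- round(.rtrunc_norm(n, 28.5, 3.8, 18, 45), 0)
    bmi <- round(exp(stats::rnorm(n, log(21.2), 0.12)), 1)
    education <- sample(c("primary-or-below", "middle", "high",
                          "college-or-above"), n, TRUE,
                        prob = c(0.168, 0.153, 0.309, 0.370))
    gravidity <- sample(1:4, n, TRUE, prob = c(0.445, 0.330, 0.150, 0.075))
    parity <- sample(0:2, n, TRUE, prob = c(0.683, 0.280, 0.037))
    smoking <- sample(c("no", "yes", "unknown"), n, TRUE,
                      prob = c(0.982, 0.011, 0.007))
    alcohol <- sample(c("no", "yes", "unknown"), n, TRUE,
                      prob = c(0.979, 0.013, 0.008))
    weight_gain <- round(.rtrunc_norm(n, 12, 3.6, 0, 30), 1)
    ga_weeks <- round(stats::runif(n, 8, 14), 1)

    L <- chol(config$corr)
    Z <- matrix(stats::rnorm(n * 8), n, 8) %*% L   # standardized log scale
    colnames(Z) <- .biomarker_names
    bio <- exp(sweep(sweep(Z, 2, config$log_sds, `*`), 2,
                     config$log_means, `+`))
    bio <- round(bio, 2)

    # latent linear predictor per channel, in channel-SD units
    lp <- Z %*% config$effects
    zbmi <- (log(bmi) - log(21.2)) / 0.12
    lp <- lp + config$age_effect * (age - 28.5) + config$bmi_effect * zbmi
    ia <- config$interaction
    if (!is.null(ia) && ia$effect != 0) {
      z_lfi <- if (ia$lfi == "ast_alt") {
        scale(Z[, "ast"] - Z[, "alt"])[, 1]   # log AST/ALT, standardized
      } else if (ia$lfi == "hsi") {
        h <- compute_hsi(bio[, "alt"], bio[, "ast"], bmi)
        scale(log(h))[, 1]
      } else scale(Z[, ia$lfi])[, 1]
      z_lip <- scale(Z[, ia$lipid])[, 1]
      lp[, c("pbg1h", "pbg2h")] <- lp[, c("pbg1h", "pbg2h")] +
        ia$effect * z_lfi * z_lip
    }
    eps <- matrix(stats::rnorm(n * 3), n, 3)
    latent <- sweep(sweep(lp + eps, 2, .channel_sd, `*`), 2, .channel_mu, `+`)
    colnames(latent) <- .channel_names

    prev_at <- function(delta) {
      g <- round(sweep(latent, 2, delta * .channel_sd, `+`), 1)
      g[g <= 0] <- 0.1
      mean(diagnose_gdm(g[, 1], g[, 2], g[, 3])$is_gdm)
    }
    lo <- -3; hi <- 3
    if (prev_at(lo) > config$prevalence_target ||
        prev_at(hi) < config$prevalence_target) {
      stop("simulate_cohort: prevalence target unattainable under config",
           call. = FALSE)
    }
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (prev_at(mid) < config$prevalence_target) lo <- mid else hi <- mid
      if (hi - lo < 1e-9) break
    }
    delta <- (lo + hi) / 2
    glucose <- round(sweep(latent, 2, delta * .channel_sd, `+`), 1)
    glucose[glucose <= 0] <- 0.1
    realized <- mean(diagnose_gdm(glucose[, 1], glucose[, 2],
                                  glucose[, 3])$is_gdm)
    if (abs(realized - config$prevalence_target) > 0.01 && n >= 2000) {
      warning(sprintf(
        "simulate_cohort: realized prevalence %.3f misses target %.3f",
        realized, config$prevalence_target), call. = FALSE)
    }

    records <- data.frame(
      id = sprintf("P%05d", seq_len(n)), age = age, bmi = bmi,
      weight_gain = weight_gain, ga_weeks = ga_weeks,
      education = education, gravidity = gravidity, parity = parity,
      smoking = smoking, alcohol = alcohol,
      alt = bio[, "alt"], ast = bio[, "ast"], ggt = bio[, "ggt"],
      alp = bio[, "alp"], tc = bio[, "tc"], tg = bio[, "tg"],
      ldl_c = bio[, "ldl_c"], hdl_c = bio[, "hdl_c"],
      fbg = glucose[, "fbg"], pbg1h = glucose[, "pbg1h"],
      pbg2h = glucose[, "pbg2h"], hx_flags = "",
      stringsAsFactors = FALSE
    )
    truth <- list(effects = config$effects, interaction = config$interaction,
                  intercept_shift = delta, realized_prevalence = realized,
                  prevalence_target = config$prevalence_target,
                  seed = config$seed)
    list(records = records, truth = truth)
  })
}

#' Configuration for simulated two-sample GWAS summary statistics
#'
#' Emulates a large exposure GWAS (UK-Biobank scale, default n = 300,000)
#' and a smaller binary-outcome GWAS (FinnGen scale, default n = 120,000).
#' Instrument effects (gamma) are half-normal, i.e. the effect allele is
#' oriented exposure-increasing as in a post-selection instrument list;
#' `gamma_sd = 0.03` gives a mean instrument F-statistic near 100, the
#' order reported for liver-enzyme instruments.
#'
#' @param m_snps Number of instruments.
#' @param seed Integer seed.
#' @param n_exp,n_out GWAS sample sizes.
#' @param maf_range Uniform range for the minor allele frequency.
#' @param gamma_sd Scale of the half-normal instrument-effect distribution.
#' @param theta True causal effect (log-OR per unit exposure).
#' @param pleiotropy One of `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (mean `pleio_mean`).
#' @param pleio_mean,pleio_sd Direct-effect distribution for invalid SNPs.
#' @param fraction_invalid Fraction of SNPs receiving a direct effect when
#'   `pleiotropy != "none"`.
#' @param fraction_palindromic Fraction of SNPs drawn with A/T or C/G
#'   allele pairs.
#' @param ld_block_size SNPs per LD block (1 = independent).
#' @param ld_r2 Within-block pairwise r^2.
#' @return List of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(m_snps = 100, seed = 1, n_exp = 3e5, n_out = 1.2e5,
                            maf_range = c(0.1, 0.4), gamma_sd = 0.03,
                            theta = 0,
                            pleiotropy = c("none", "balanced", "directional"),
                            pleio_mean = 0.02, pleio_sd = 0.01,
                            fraction_invalid = 1, fraction_palindromic = 0,
                            ld_block_size = 1, ld_r2 = 0.8) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(m_snps >= 1, n_exp > 0, n_out > 0,
            fraction_invalid >= 0, fraction_invalid <= 1,
            fraction_palindromic >= 0, fraction_palindromic <= 1)
  structure(list(m_snps = m_snps, seed = seed, n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range, gamma_sd = gamma_sd, theta = theta,
                 pleiotropy = pleiotropy, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, fraction_invalid = fraction_invalid,
                 fraction_palindromic = fraction_palindromic,
                 ld_block_size = ld_block_size, ld_r2 = ld_r2),
            class = "gwas_sim_config")
}

#' Simulate an exposure/outcome summary-statistics pair with known truth
#'
#' Standard two-sample MR generative model on the summary level: per SNP j,
#' maf ~ Uniform(range); gamma_j half-normal(`gamma_sd`);
#' se_exp_j = (2 maf (1-maf) n_exp)^(-1/2); beta_exp_j ~ N(gamma_j, se_exp);
#' alpha_j from the pleiotropy mode on the invalid fraction;
#' beta_out_j ~ N(theta gamma_j + alpha_j, se_out) with se_out analogous
#' under n_out. P-values are two-sided normal. SNPs are laid out in LD
#' blocks (consecutive positions within a window, exchangeable within-block
#' r^2) so that [clump()] has structure to prune; distinct blocks are
#' separated by more than the default clumping window.
#'
#' @param config A [gwas_sim_config()].
#' @return List with `exposure` and `outcome` summary-statistics tables,
#'   `ld` (pairwise r^2 table, zero rows when blocks have size 1) and
#'   `truth` (theta, per-SNP gamma and alpha, invalid indicator).
#' @export
simulate_gwas_pair <- function(config = gwas_sim_config()) {
  stopifnot(inherits(config, "gwas_sim_config"))
  m <- config$m_snps
  .with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    gamma <- abs(stats::rnorm(m, 0, config$gamma_sd))
    invalid <- rep(FALSE, m)
    alpha <- numeric(m)
    if (config$pleiotropy != "none" && config$fraction_invalid > 0) {
      n_inv <- round(config$fraction_invalid * m)
      invalid[sample.int(m, n_inv)] <- TRUE
      mu <- if (config$pleiotropy == "directional") config$pleio_mean else 0
      alpha[invalid] <- stats::rnorm(n_inv, mu, config$pleio_sd)
    }
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out)
    beta_exp <- stats::rnorm(m, gamma, se_exp)
    beta_out <- stats::rnorm(m, config$theta * gamma + alpha, se_out)

    pal <- stats::runif(m) < config$fraction_palindromic
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    reg_pairs <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                          "T", "G", "G", "T", "T", "C", "C", "T"),
                        ncol = 2, byrow = TRUE)
    pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, TRUE), ,
                                     drop = FALSE]
    alleles <- matrix("", m, 2)
    if (any(pal)) alleles[pal, ] <- pick(pal_pairs, sum(pal))
    if (any(!pal)) alleles[!pal, ] <- pick(reg_pairs, sum(!pal))

    bs <- max(1L, as.integer(config$ld_block_size))
    block <- (seq_len(m) - 1L) %/% bs
    chr <- (block %% 22L) + 1L
    # blocks 50 Mb apart (beyond the 10 Mb default window); 100 kb in-block
    pos <- (block %/% 22L) * 5e7 + ((seq_len(m) - 1L) %% bs) * 1e5 + 1e6
    ld <- data.frame(rsid_a = character(), rsid_b = character(),
                     r2 = numeric())
    rsid <- sprintf("rs%05d", seq_len(m))
    if (bs > 1) {
      pairs <- do.call(rbind, lapply(split(seq_len(m), block), function(ix) {
        if (length(ix) < 2) return(NULL)
        cmb <- utils::combn(ix, 2)
        data.frame(rsid_a = rsid[cmb[1, ]], rsid_b = rsid[cmb[2, ]],
                   r2 = config$ld_r2)
      }))
      if (!is.null(pairs)) ld <- pairs
    }
    make_tab <- function(beta, se, n) data.frame(
      rsid = rsid, chr = chr, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = maf, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
      n = n, stringsAsFactors = FALSE)
    list(exposure = make_tab(beta_exp, se_exp, config$n_exp),
         outcome = make_tab(beta_out, se_out, config$n_out),
         ld = ld,
         truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                      invalid = invalid, maf = maf, seed = config$seed))
  })
}

#' Estimator-recovery report against simulation ground truth
#'
#' Tabulates bias, RMSE, 95% CI coverage and power (rejection of beta = 0)
#' for each estimator over simulation replicates.
#'
#' @param truth True causal effect: a scalar, or a vector with one value
#'   per replicate.
#' @param estimates Data frame with one row per replicate: columns
#'   `method`, `beta`, `ci_low`, `ci_high`, `p` (as produced by stacking
#'   `mr_estimate` fields).
#' @return Data frame with one row per method: `n_rep`, `bias`, `rmse`,
#'   `coverage`, `power`.
#' @export
truth_report <- function(truth, estimates) {
  stopifnot(all(c("method", "beta", "ci_low", "ci_high", "p") %in%
                  names(estimates)))
  n_per <- table(estimates$method)
  if (length(truth) > 1 && any(n_per != length(truth))) {
    stop("truth_report: replicate count mismatch between truth and estimates",
         call. = FALSE)
  }
  do.call(rbind, lapply(split(estimates, estimates$method), function(e) {
    th <- rep_len(truth, nrow(e))
    data.frame(method = e$method[1], n_rep = nrow(e),
               bias = mean(e$beta - th),
               rmse = sqrt(mean((e$beta - th)^2)),
               coverage = mean(e$ci_low <= th & th <= e$ci_high),
               power = mean(e$p < 0.05), row.names = NULL)
  }))
}
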