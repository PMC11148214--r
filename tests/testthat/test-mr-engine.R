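make_ss <- function(rsid, ea, oa, eaf, beta, se, pval = NULL, n = 1e5,
                    chr = 1, pos = seq_along(rsid) * 1e6) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(rsid = rsid, chr = chr, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

test_that("instrument selection applies strict p and MAF thresholds", {
  ss <- make_ss(paste0("rs", 1:5), "A", "G", c(0.3, 0.995, 0.011, 0.3, 0.3),
                beta = 0.1, se = 0.01,
                pval = c(5.0e-8, 1e-9, 1e-9, 4.9e-8, 1e-9))
  out <- select_instruments(ss, exclusion_list = "rs5")
  expect_setequal(out$rsid, c("rs3", "rs4"))   # rs1 at boundary p, rs2 MAF .005
  expect_error(select_instruments(ss[ss$rsid == "rs1", ]),
               "no valid instruments")
  expect_identical(select_instruments(make_ss("rs9", "A", "G", 0.2, 0.1,
                                              0.01, 1e-10))$rsid, "rs9")
})

test_that("clumping follows the greedy p-value rule with window and r2 bounds", {
  two <- function(pos2, r2, p = c(1e-10, 1e-9)) {
    snps <- make_ss(c("rsA", "rsB"), "A", "G", 0.3, 0.1, 0.01, pval = p,
                    pos = c(1e6, pos2))
    ld <- data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = r2)
    clump(snps, ld)$rsid
  }
  expect_equal(two(1e6 + 5e6, 0.5), "rsA")        # in window, correlated
  expect_setequal(two(1e6 + 5e6, 0.0005), c("rsA", "rsB"))  # r2 below 0.001
  expect_setequal(two(1e6 + 10001 * 1000, 0.9), c("rsA", "rsB"))  # 10,001 kb
  expect_equal(two(1e6 + 10000 * 1000, 0.9), "rsA")  # exactly at the window
  snps <- make_ss(c("rsA", "rsB"), "A", "G", 0.3, 0.1, 0.01,
                  pval = c(1e-9, 1e-9))
  snps$pos <- NULL
  expect_error(clump(snps, NULL), "pos")
})

test_that("clumped output matches an independent greedy trace on random instances", {
  set.seed(91)
  for (i in 1:8) {
    m <- sample(5:20, 1)
    snps <- make_ss(sprintf("rs%02d", 1:m), "A", "G",
                    eaf = runif(m, 0.05, 0.5), beta = 0.1, se = 0.01,
                    pval = round(runif(m, 1e-12, 1e-8), 14),
                    chr = sample(1:2, m, TRUE),
                    pos = sample.int(3e7, m))
    pairs <- t(combn(m, 2))
    take <- runif(nrow(pairs)) < 0.4
    ld <- data.frame(rsid_a = snps$rsid[pairs[take, 1]],
                     rsid_b = snps$rsid[pairs[take, 2]],
                     r2 = runif(sum(take)))
    got <- suppressWarnings(clump(snps, ld, 0.1, 5000))
    expect_equal(sort(got$rsid), oracle_clump(snps, ld, 0.1, 5000))
    # no retained pair violates the (window, r2) constraint
    if (nrow(got) > 1) {
      cmb <- t(combn(nrow(got), 2))
      for (k in seq_len(nrow(cmb))) {
        a <- got[cmb[k, 1], ]; b <- got[cmb[k, 2], ]
        near <- a$chr == b$chr && abs(a$pos - b$pos) <= 5000 * 1000
        hit <- ld[(ld$rsid_a == a$rsid & ld$rsid_b == b$rsid) |
                    (ld$rsid_a == b$rsid & ld$rsid_b == a$rsid), ]
        r2 <- if (nrow(hit)) hit$r2[1] else 0
        expect_false(near && r2 > 0.1)
      }
    }
  }
})

test_that("harmonization flips swapped alleles and drops palindromic/mismatched SNPs", {
  exp <- make_ss(c("rs1", "rs2", "rs3", "rs4"),
                 ea = c("A", "A", "A", "A"), oa = c("G", "T", "G", "G"),
                 eaf = c(0.3, 0.3, 0.3, 0.3), beta = 0.10, se = 0.01)
  out <- make_ss(c("rs1", "rs2", "rs3", "rs5"),
                 ea = c("G", "A", "A", "A"), oa = c("A", "T", "C", "G"),
                 eaf = c(0.7, 0.3, 0.4, 0.3), beta = c(-0.05, 0.02, 0.03, 0.1),
                 se = 0.02)
  h <- harmonize(exp, out)
  expect_equal(h$data$rsid, "rs1")
  expect_equal(h$data$beta_out, 0.05)   # sign flipped with the allele swap
  expect_equal(h$data$eaf_out, 0.3)
  acts <- setNames(h$log$action, h$log$rsid)
  expect_equal(acts[["rs2"]], "dropped_palindromic")
  expect_equal(acts[["rs3"]], "dropped_mismatch")
  expect_equal(acts[["rs4"]], "dropped_missing")
  expect_error(harmonize(exp, make_ss("rs99", "A", "G", 0.3, 0.1, 0.01)),
               "shared")
})

test_that("F-statistics follow (beta/se)^2 with a boundary warning at 10", {
  h <- list(data = data.frame(rsid = "rs1", beta_exp = 0.1, se_exp = 0.01,
                              beta_out = 0, se_out = 1))
  expect_equal(unname(f_statistics(h)$f), 100)
  h$data$beta_exp <- 0.0316227766
  expect_warning(fs <- f_statistics(h), "weak")
  expect_equal(fs$mean_f, 10, tolerance = 1e-8)
  h3 <- list(data = data.frame(rsid = c("a", "b"), beta_exp = 0.1,
                               se_exp = 0.01, beta_out = 0, se_out = 1))
  expect_equal(f_statistics(h3)$mean_f, unname(f_statistics(h3)$f[1]))
})

test_that("Wald ratio divides effects with delta-method SE and sign invariance", {
  d <- data.frame(rsid = "rs1", beta_exp = 0.1, se_exp = 0.01,
                  beta_out = 0.05, se_out = 0.02)
  w <- wald_ratio(d)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  d2 <- d; d2$beta_exp <- -d$beta_exp; d2$beta_out <- -d$beta_out
  w2 <- wald_ratio(d2)
  expect_equal(w2$beta, w$beta)
  expect_equal(w2$se, w$se)
  d$beta_out <- 0
  expect_equal(wald_ratio(d)$beta, 0)
  d$beta_exp <- 0
  expect_error(wald_ratio(d), "beta_exp")
})

test_that("IVW equals the zero-intercept WLS oracle and reduces to the Wald ratio", {
  h <- fixed_harmonized()
  est <- ivw(h)
  w <- 1 / h$data$se_out^2
  expect_equal(est$beta,
               oracle_wls_slope(h$data$beta_exp, h$data$beta_out, w),
               tolerance = 1e-10)
  one <- list(data = h$data[1, ])
  expect_equal(ivw(one)$beta, wald_ratio(h$data[1, ])$beta)
  expect_equal(ivw(one)$se, wald_ratio(h$data[1, ])$se)
  # homogeneous ratios: Q = 0 and the random-effects SE equals the fixed SE
  hom <- list(data = data.frame(rsid = c("a", "b", "c"),
                                beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01,
                                beta_out = c(0.05, 0.10, 0.20),
                                se_out = 0.02))
  e2 <- ivw(hom)
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$q_stat, 0)
  expect_equal(e2$se, e2$se_fixed)
  bad <- hom; bad$data$beta_exp <- 0
  expect_error(ivw(bad), "zero")
})

test_that("Cochran's Q is zero for homogeneous ratios and df tracks SNP count", {
  hom <- list(data = data.frame(rsid = c("a", "b"),
                                beta_exp = c(0.1, 0.2), se_exp = 0.01,
                                beta_out = c(0.03, 0.06), se_out = 0.02))
  q <- cochran_q(hom)
  expect_equal(q$q, 0)
  expect_equal(q$p, 1)
  expect_equal(q$df, 1)
  dup <- list(data = rbind(hom$data,
                           transform(hom$data[1, ], rsid = "a2")))
  expect_equal(cochran_q(dup)$df, 2)
})

test_that("Q test holds its size under the homogeneous generator null", {
  rej <- vapply(1:300, function(i) {
    g <- simulate_gwas_pair(gwas_sim_config(m_snps = 50, seed = 5000 + i,
                                            theta = 0))
    cochran_q(harmonize(g$exposure, g$outcome))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("MR-Egger matches the free-intercept WLS oracle and exact-line data", {
  h <- fixed_harmonized()
  e <- mr_egger(h)
  w <- 1 / h$data$se_out^2
  line <- oracle_wls_line(h$data$beta_exp, h$data$beta_out, w)
  expect_equal(e$beta, unname(line["slope"]), tolerance = 1e-10)
  expect_equal(e$intercept, unname(line["intercept"]), tolerance = 1e-10)
  # data exactly through the origin: intercept 0, slope = common ratio
  hom <- list(data = data.frame(rsid = c("a", "b", "c"),
                                beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01,
                                beta_out = c(0.05, 0.10, 0.20),
                                se_out = 0.02))
  e2 <- mr_egger(hom)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(list(data = hom$data[1:2, ])), ">= 3")
})

test_that("weighted median interpolates at half weight with a seeded bootstrap", {
  h <- list(data = data.frame(rsid = c("a", "b", "c"),
                              beta_exp = 0.1, se_exp = 0.01,
                              beta_out = c(0.04, 0.05, 0.06), se_out = 0.02))
  wm <- weighted_median(h, n_boot = 0)
  expect_equal(wm$beta, 0.5)
  wm1 <- weighted_median(h, n_boot = 25, seed = 99)
  wm2 <- weighted_median(h, n_boot = 25, seed = 99)
  expect_identical(wm1$se, wm2$se)
  expect_error(weighted_median(list(data = h$data[1:2, ])), ">= 3")
})

test_that("MVMR matches the multivariable WLS oracle and reduces to IVW", {
  set.seed(95)
  m <- 20
  X <- cbind(alt = abs(rnorm(m, 0.05, 0.02)), bmi = rnorm(m, 0, 0.02))
  y <- 0.3 * X[, 1] + 0.1 * X[, 2] + rnorm(m, 0, 0.01)
  se_out <- runif(m, 0.008, 0.02)
  hm <- list(beta_exp = X, se_exp = X * 0 + 0.005, beta_out = y,
             se_out = se_out)
  est <- mvmr(hm)
  orc <- oracle_wls_multi(X, y, 1 / se_out^2)
  expect_equal(est$alt$beta, orc[1], tolerance = 1e-10)
  expect_equal(est$bmi$beta, orc[2], tolerance = 1e-10)
  # all-zero second exposure: first estimate equals the univariable IVW
  hm0 <- hm; hm0$beta_exp[, 2] <- 0
  expect_warning(est0 <- mvmr(hm0), "all-zero")
  uni <- ivw(list(data = data.frame(rsid = seq_len(m), beta_exp = X[, 1],
                                    se_exp = 0.005, beta_out = y,
                                    se_out = se_out)))
  expect_equal(est0$alt$beta, uni$beta, tolerance = 1e-10)
  # duplicated exposure column: rank deficiency is an error
  hmd <- hm; hmd$beta_exp[, 2] <- hmd$beta_exp[, 1]
  expect_error(mvmr(hmd), "rank deficient")
})

test_that("all estimators are invariant to a SNP's reported orientation", {
  g <- simulate_gwas_pair(gwas_sim_config(m_snps = 12, seed = 321,
                                          theta = 0.2))
  h1 <- harmonize(g$exposure, g$outcome)
  flip_rs <- h1$data$rsid[c(2, 5)]
  expo2 <- g$exposure; out2 <- g$outcome
  for (r in flip_rs) {
    expo2 <- flip_snp(expo2, r)
    out2 <- flip_snp(out2, r)
  }
  h2 <- harmonize(expo2, out2)
  h2$data <- h2$data[match(h1$data$rsid, h2$data$rsid), ]
  expect_equal(ivw(h2)$beta, ivw(h1)$beta)
  expect_equal(ivw(h2)$se, ivw(h1)$se)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta)
  expect_equal(mr_egger(h2)$intercept, mr_egger(h1)$intercept)
  expect_equal(weighted_median(h2, n_boot = 0)$beta,
               weighted_median(h1, n_boot = 0)$beta)
})

test_that("sumstats validation enforces the declared invariants", {
  ok <- make_ss(c("rs1", "rs2"), "A", "G", 0.3, 0.1, 0.01)
  expect_silent(validate_sumstats(ok))
  dup <- ok; dup$rsid <- c("rs1", "rs1")
  expect_error(validate_sumstats(dup), "duplicate")
  se0 <- ok; se0$se[1] <- 0
  expect_error(validate_sumstats(se0), "se")
  same <- ok; same$other_allele[1] <- "A"
  expect_error(validate_sumstats(same), "allele")
})
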