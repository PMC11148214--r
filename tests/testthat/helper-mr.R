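# Independent oracles for the MR-arm tests, written against the normal
# equations / greedy definitions directly so they share no code with the
# implementation under test.

# Zero-intercept weighted least squares via explicit normal equations.
oracle_wls_slope <- function(x, y, w) sum(w * x * y) / sum(w * x^2)

# Weighted simple regression with intercept, via closed-form sums.
oracle_wls_line <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

# Multivariable zero-intercept WLS via explicit normal equations.
oracle_wls_multi <- function(X, y, w) {
  A <- matrix(0, ncol(X), ncol(X))
  b <- numeric(ncol(X))
  for (i in seq_along(y)) {
    A <- A + w[i] * tcrossprod(X[i, ])
    b <- b + w[i] * X[i, ] * y[i]
  }
  solve(A, b)
}

# Independent greedy clump trace: lowest p first (ties by rsid), drop
# neighbours within the window whose r2 exceeds the threshold.
oracle_clump <- function(snps, ld, r2_threshold, window_kb) {
  r2_of <- function(a, b) {
    hit <- (ld$rsid_a == a & ld$rsid_b == b) | (ld$rsid_a == b & ld$rsid_b == a)
    if (any(hit)) ld$r2[which(hit)[1]] else 0
  }
  remaining <- snps[order(snps$pval, snps$rsid), ]
  kept <- character()
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$rsid)
    near <- remaining$chr == idx$chr &
      abs(remaining$pos - idx$pos) <= window_kb * 1000
    high <- vapply(remaining$rsid, function(r) {
      r != idx$rsid && r2_of(idx$rsid, r) > r2_threshold
    }, logical(1))
    remaining <- remaining[!(remaining$rsid == idx$rsid | (near & high)), ,
                           drop = FALSE]
  }
  sort(kept)
}

# Flip a SNP's reported orientation in a sumstats table (allele swap with
# complementary bookkeeping); harmonized results must be invariant.
flip_snp <- function(ss, rsid) {
  i <- which(ss$rsid == rsid)
  tmp <- ss$effect_allele[i]
  ss$effect_allele[i] <- ss$other_allele[i]
  ss$other_allele[i] <- tmp
  ss$beta[i] <- -ss$beta[i]
  ss$eaf[i] <- 1 - ss$eaf[i]
  ss
}

# Small fixed harmonized set used by several estimator tests.
fixed_harmonized <- function() {
  list(data = data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    beta_exp = c(0.10, 0.20, 0.15), se_exp = c(0.01, 0.01, 0.01),
    beta_out = c(0.05, 0.08, 0.09), se_out = c(0.02, 0.02, 0.02)))
}
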