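test_that("HSI formula reproduces hand arithmetic and rejects bad input", {
  expect_equal(compute_hsi(alt = 7, ast = 7, bmi = 20), 30)
  expect_equal(compute_hsi(alt = 21, ast = 14, bmi = 22), 36)
  expect_equal(compute_hsi(alt = 10, ast = 20, bmi = 18.5), 24.5)
  expect_equal(compute_hsi(10, 20, 18.5, female = FALSE), 22.5)
  expect_error(compute_hsi(0, 20, 22), "positive")
  expect_error(compute_hsi(10, 20, -1), "positive")
})

test_that("HSI is monotone in ALT and BMI and depends on the enzyme ratio only", {
  set.seed(11)
  for (i in 1:20) {
    alt <- runif(1, 5, 80); ast <- runif(1, 5, 80); bmi <- runif(1, 16, 35)
    expect_gt(compute_hsi(alt + 1, ast, bmi), compute_hsi(alt, ast, bmi))
    expect_gt(compute_hsi(alt, ast, bmi + 0.5), compute_hsi(alt, ast, bmi))
    k <- runif(1, 0.5, 3)
    expect_equal(compute_hsi(k * alt, k * ast, bmi),
                 compute_hsi(alt, ast, bmi))
    expect_gt(compute_hsi(alt, ast, bmi), bmi + 2)
  }
})

test_that("OGTT diagnosis applies inclusive thresholds and the subtype rules", {
  d <- diagnose_gdm(c(5.1, 5.0, 5.0, 5.1), c(9.9, 10.0, 9.9, 10.0),
                    c(8.4, 8.5, 8.4, 8.4))
  expect_equal(as.character(d$subtype), c("i-IFG", "i-IGT", "none", "b-GDM"))
  expect_equal(d$is_gdm, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(d$pbg1h_high[2] && d$pbg2h_high[2])
  expect_true(all(d$available))
})

test_that("missing glucose flags the record instead of calling it non-GDM", {
  d <- diagnose_gdm(c(5.5, NA), c(9, 9), c(6, 6))
  expect_false(d$available[2])
  expect_true(is.na(d$is_gdm[2]))
  expect_true(is.na(d$subtype[2]))
  expect_error(diagnose_gdm(-1, 9, 6), "positive")
})

test_that("every complete glucose triple gets exactly one subtype and counts add up", {
  set.seed(21)
  fbg <- runif(500, 3.5, 6.5)
  p1 <- runif(500, 5, 12)
  p2 <- runif(500, 4, 10.5)
  d <- diagnose_gdm(fbg, p1, p2)
  expect_false(anyNA(d$subtype))
  tab <- table(d$subtype)
  expect_equal(sum(tab), 500)
  expect_equal(sum(tab[c("i-IFG", "i-IGT", "b-GDM")]), sum(d$is_gdm))
  expect_equal(tab[["none"]], sum(!d$is_gdm))
  # subtype definitions in terms of the component flags
  expect_true(all((d$subtype == "i-IFG") ==
                    (d$fbg_high & !d$pbg1h_high & !d$pbg2h_high)))
  expect_true(all((d$subtype == "b-GDM") ==
                    (d$fbg_high & (d$pbg1h_high | d$pbg2h_high))))
})

test_that("inclusion/exclusion drops by first matching reason in order", {
  recs <- rbind(
    base_record("ok"),
    base_record("alt91", alt = 91),
    base_record("alt90", alt = 90),
    base_record("hx", hx = "diabetes"),
    base_record("hx_and_alt", alt = 95, hx = "hypertension;kidney"),
    base_record("no_liver", alt = NA),
    base_record("no_ogtt", fbg = NA),
    base_record("benign_hx", hx = "other"))
  out <- apply_inclusion_exclusion(recs)
  expect_setequal(out$records$id, c("ok", "alt90", "benign_hx"))
  lg <- out$log
  expect_equal(lg$reason[lg$id == "alt91"], "elevated liver enzymes")
  expect_equal(lg$reason[lg$id == "hx"], "medical history")
  expect_equal(lg$reason[lg$id == "hx_and_alt"], "medical history")
  expect_equal(lg$reason[lg$id == "no_liver"], "missing liver tests")
  expect_equal(lg$reason[lg$id == "no_ogtt"], "missing GDM evaluation")
})

test_that("the exclusion filter is idempotent and handles empty input", {
  recs <- rbind(base_record("a"), base_record("b", ast = 85),
                base_record("c", ggt = 91), base_record("d", alp = 241))
  once <- apply_inclusion_exclusion(recs)
  twice <- apply_inclusion_exclusion(once$records)
  expect_identical(once$records, twice$records)
  expect_equal(nrow(twice$log), 0)
  empty <- apply_inclusion_exclusion(recs[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$log), 0)
})

test_that("clinical-range filter is strict at the bounds", {
  recs <- rbind(base_record("at_bounds", alt = 45, ast = 40, ggt = 45,
                            alp = 120),
                base_record("alt46", alt = 46),
                base_record("alp121", alp = 121))
  out <- clinical_range_filter(recs)
  expect_equal(out$id, "at_bounds")
  expect_equal(nrow(clinical_range_filter(recs[0, ])), 0)
})

test_that("quartile bins use interpolated cuts with ties going to the lower bin", {
  # integer sample whose type-7 quartiles are 10 / 13 / 19, giving the bin
  # layout 1-10, 11-13, 14-19, 20+ reported for ALT
  x <- c(2, 6, 9, 10, 11, 12, 13, 14, 17, 19, 22, 30, 87)
  qb <- quartile_bin(x)
  expect_equal(unname(qb$cuts), c(10, 13, 19))
  expect_equal(as.character(qb$labels[x == 14]), "Q3")
  expect_equal(as.character(qb$labels[x == 10]), "Q1")
  expect_equal(as.character(qb$labels[x == 13]), "Q2")
  expect_equal(as.character(qb$labels[x == 19]), "Q3")
  expect_equal(as.character(qb$labels[x == 22]), "Q4")
  expect_equal(unname(qb$bin_ranges["Q2", ]), c(11, 13))
})

test_that("equally spaced values split evenly; degenerate input errors", {
  qb <- quartile_bin(1:8)
  expect_equal(as.integer(table(qb$labels)), c(2, 2, 2, 2))
  expect_error(quartile_bin(rep(5, 10)), "distinct")
  expect_error(quartile_bin(c(1, 2, 3)), "distinct")
})

test_that("quartile bins partition any sample with every value labelled once", {
  set.seed(31)
  for (i in 1:10) {
    x <- round(rlnorm(200, log(13), 0.5))   # integer-valued, heavy ties
    x <- x + 1  # keep positive
    qb <- try(quartile_bin(x), silent = TRUE)
    if (inherits(qb, "try-error")) next   # degenerate tie structure
    expect_false(anyNA(qb$labels))
    expect_equal(length(qb$labels), length(x))
    # each bin's observed range is disjoint from the next bin's
    expect_true(all(qb$bin_ranges[-4, "max"] < qb$bin_ranges[-1, "min"]))
  }
})

test_that("derived biomarkers and BMI categories follow their definitions", {
  recs <- derive_biomarkers(rbind(base_record("a", alt = 20, ast = 10),
                                  base_record("b", alt = 10, ast = 25)))
  expect_equal(recs$ast_alt, c(0.5, 2.5))
  expect_equal(recs$hsi, compute_hsi(recs$alt, recs$ast, recs$bmi))
  expect_equal(as.character(bmi_category(c(18.4, 18.5, 23.9, 24, 27.9, 28))),
               c("<18.5", "18.5-23.9", "18.5-23.9", "24.0-27.9", "24.0-27.9",
                 ">=28"))
  recs$bmi <- c(23.9, 24)
  expect_equal(derive_biomarkers(recs)$overweight, c(FALSE, TRUE))
})
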