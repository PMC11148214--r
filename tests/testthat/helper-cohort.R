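# Shared fixtures for the cohort-arm tests, built in code.

# Diagnose, derive and attach GDM status to a simulated cohort.
prep_cohort <- function(cs) {
  r <- derive_biomarkers(cs$records)
  dx <- diagnose_gdm(r$fbg, r$pbg1h, r$pbg2h)
  r$is_gdm <- dx$is_gdm
  r$subtype <- dx$subtype
  r
}

# Reconstruct the categorical structure of a published baseline table
# (9,148 women, 1,668 with GDM) from its printed counts, with glucose
# values that reproduce the group assignment under diagnose_gdm().
table1_records <- function() {
  expand <- function(level, n) rep(level, n)
  mk_group <- function(n, edu, grav, par, smo, alc, gdm) {
    data.frame(
      id = character(n),
      education = c(expand("primary-or-below", edu[1]), expand("middle", edu[2]),
                    expand("high", edu[3]), expand("college-or-above", edu[4])),
      gravidity = c(expand(1L, grav[1]), expand(2L, grav[2])),
      parity = c(expand(0L, par[1]), expand(1L, par[2])),
      smoking = c(expand("no", smo[1]), expand("yes", smo[2]),
                  expand("unknown", smo[3])),
      alcohol = c(expand("no", alc[1]), expand("yes", alc[2]),
                  expand("unknown", alc[3])),
      fbg = if (gdm) 5.5 else 4.5, pbg1h = 7, pbg2h = 6,
      stringsAsFactors = FALSE)
  }
  g1 <- mk_group(1668, c(305, 262, 521, 580), c(684, 984), c(1060, 608),
                 c(1637, 22, 9), c(1639, 17, 12), gdm = TRUE)
  g0 <- mk_group(7480, c(1243, 1138, 2303, 2796), c(3373, 4107),
                 c(5185, 2295), c(7352, 82, 46), c(7325, 104, 51),
                 gdm = FALSE)
  out <- rbind(g1, g0)
  out$id <- sprintf("T%05d", seq_len(nrow(out)))
  out
}

# Minimal valid participant row for filter tests.
base_record <- function(id = "x", alt = 15, ast = 17, ggt = 12, alp = 50,
                        fbg = 4.5, pbg1h = 7, pbg2h = 6, hx = "") {
  data.frame(id = id, age = 28, bmi = 21, weight_gain = 12, ga_weeks = 11,
             education = "high", gravidity = 1L, parity = 0L,
             smoking = "no", alcohol = "no",
             alt = alt, ast = ast, ggt = ggt, alp = alp,
             tc = 4.4, tg = 1.3, ldl_c = 2.3, hdl_c = 1.7,
             fbg = fbg, pbg1h = pbg1h, pbg2h = pbg2h, hx_flags = hx,
             stringsAsFactors = FALSE)
}
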