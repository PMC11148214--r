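#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis (Harrell parameterisation):
#' for k knots the basis has k-1 columns (the linear term plus k-2 nonlinear
#' terms), each nonlinear term scaled by the squared boundary-knot span so
#' coefficients stay on comparable scales. The fitted curve is constrained
#' to be linear beyond the boundary knots (its second derivative vanishes
#' outside them).
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing numeric vector of knot locations
#'   (length >= 3).
#' @return Matrix with `length(knots) - 1` columns: `x` and `x'1` ...
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3 || is.unsorted(knots, strictly = TRUE)) {
    stop("rcs_basis: knots must be >= 3 strictly increasing values",
         call. = FALSE)
  }
  span2 <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
      span2
  }
  colnames(B) <- c("x", paste0("x'", seq_len(k - 2)))
  B
}

#' Default knot placement for a 4-knot restricted cubic spline
#'
#' Knots at the 5th/35th/65th/95th percentiles of the exposure, the standard
#' 4-knot default.
#'
#' @param x Numeric exposure values.
#' @param n_knots Number of knots (quantile schedules available for 3-5).
#' @return Numeric vector of knot locations.
#' @export
rcs_knots <- function(x, n_knots = 4) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("rcs_knots: supported n_knots are 3-5", call. = FALSE))
  kn <- unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
  if (is.unsorted(kn, strictly = TRUE)) {
    stop("rcs_knots: tied knot locations; exposure too discrete",
         call. = FALSE)
  }
  kn
}

#' Restricted-cubic-spline dose-response model with nonlinearity test
#'
#' Regresses a continuous glucose outcome on a 4-knot restricted cubic
#' spline of the exposure plus the adjustment set. The nonlinearity p-value
#' is the F-test comparing this model with the model containing only the
#' linear exposure term. If `p_nonlinear >= 0.05` the linear model is
#' retained; otherwise a single-breakpoint piecewise model is fitted with
#' [fit_piecewise()].
#'
#' @inheritParams fit_quartile_logistic
#' @param outcome Continuous glucose column (`"fbg"`, `"pbg1h"` or
#'   `"pbg2h"`).
#' @param n_knots Number of spline knots (default 4).
#' @param alpha Decision threshold for the nonlinearity test.
#' @return Object of class `rcs_fit`: knot locations, spline coefficients,
#'   `p_nonlinear`, `chosen` ("linear" or "piecewise"), the linear-term
#'   p-value, and the retained downstream fit (linear lm or piecewise).
#' @export
fit_rcs <- function(records, exposure, outcome, n_knots = 4,
                    covariates = default_covariates(exposure),
                    alpha = 0.05) {
  dat <- data.frame(y = records[[outcome]], x = records[[exposure]])
  if (length(covariates)) dat <- cbind(dat, .covariate_frame(records, covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 50) {
    stop("fit_rcs: fewer than 50 complete observations; spline basis unstable",
         call. = FALSE)
  }
  knots <- rcs_knots(dat$x, n_knots)
  B <- rcs_basis(dat$x, knots)
  nl <- B[, -1, drop = FALSE]
  colnames(nl) <- paste0("s", seq_len(ncol(nl)))
  dat2 <- cbind(dat, nl)
  rhs_lin <- paste(c("x", covariates), collapse = " + ")
  rhs_rcs <- paste(c("x", colnames(nl), covariates), collapse = " + ")
  fit_lin <- stats::lm(stats::as.formula(paste("y ~", rhs_lin)), data = dat2)
  fit_spl <- stats::lm(stats::as.formula(paste("y ~", rhs_rcs)), data = dat2)
  p_nonlinear <- stats::anova(fit_lin, fit_spl)[2, "Pr(>F)"]

  chosen <- if (p_nonlinear >= alpha) "linear" else "piecewise"
  downstream <- if (chosen == "linear") fit_lin
  else fit_piecewise(records, exposure, outcome, covariates)
  structure(list(exposure = exposure, outcome = outcome, knots = knots,
                 coefficients = stats::coef(fit_spl),
                 p_nonlinear = p_nonlinear, chosen = chosen,
                 breakpoint = if (chosen == "piecewise") downstream$breakpoint
                              else NULL,
                 fit_spline = fit_spl, fit_linear = fit_lin,
                 downstream = downstream, n = nrow(dat)),
            class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("RCS (%d knots) of %s on %s, n = %d\n",
              length(x$knots), x$outcome, x$exposure, x$n))
  cat("knots:", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat(sprintf("P nonlinear = %.4g -> %s model retained\n",
              x$p_nonlinear, x$chosen))
  if (!is.null(x$breakpoint))
    cat(sprintf("breakpoint at %s = %.3g\n", x$exposure, x$breakpoint))
  invisible(x)
}

#' Single-breakpoint piecewise (segmented) linear model
#'
#' Fits `y ~ x + (x - bp)_+ + covariates` over a profile grid of candidate
#' breakpoints at the 10th-90th exposure percentiles, keeping the breakpoint
#' with the smallest residual sum of squares. The hinge parameterisation
#' enforces continuity at the breakpoint. If the profile has no interior
#' minimum (best candidate on the grid edge), the linear fit is returned
#' with a warning.
#'
#' @inheritParams fit_rcs
#' @param n_grid Number of candidate breakpoints.
#' @return Object of class `piecewise_fit`: `$breakpoint`, slopes below and
#'   above with standard errors, `$linear_fallback`, and the winning lm fit.
#' @export
fit_piecewise <- function(records, exposure, outcome,
                          covariates = default_covariates(exposure),
                          n_grid = 81) {
  dat <- data.frame(y = records[[outcome]], x = records[[exposure]])
  if (length(covariates)) dat <- cbind(dat, .covariate_frame(records, covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10) {
    warning("fit_piecewise: too few observations; returning linear fit",
            call. = FALSE)
    return(.piecewise_linear_fallback(dat, covariates, exposure, outcome))
  }
  grid <- unique(stats::quantile(dat$x, seq(0.10, 0.90, length.out = n_grid),
                                 names = FALSE, type = 7))
  rhs <- paste(c("x", "hinge", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  rss <- vapply(grid, function(bp) {
    dat$hinge <- pmax(dat$x - bp, 0)
    sum(stats::resid(stats::lm(fml, data = dat))^2)
  }, numeric(1))
  best <- which.min(rss)
  if (best == 1L || best == length(grid)) {
    warning("fit_piecewise: no interior RSS minimum; returning linear fit",
            call. = FALSE)
    return(.piecewise_linear_fallback(dat, covariates, exposure, outcome))
  }
  bp <- grid[best]
  dat$hinge <- pmax(dat$x - bp, 0)
  fit <- stats::lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  V <- stats::vcov(fit)
  slope_above <- cf["x", 1] + cf["hinge", 1]
  se_above <- sqrt(V["x", "x"] + V["hinge", "hinge"] + 2 * V["x", "hinge"])
  structure(list(exposure = exposure, outcome = outcome, breakpoint = bp,
                 slope_below = cf["x", 1], se_below = cf["x", 2],
                 slope_above = slope_above, se_above = se_above,
                 slope_change = cf["hinge", 1], se_change = cf["hinge", 2],
                 linear_fallback = FALSE, fit = fit, n = nrow(dat)),
            class = "piecewise_fit")
}

.piecewise_linear_fallback <- function(dat, covariates, exposure, outcome) {
  rhs <- paste(c("x", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  cf <- summary(fit)$coefficients
  structure(list(exposure = exposure, outcome = outcome, breakpoint = NA_real_,
                 slope_below = cf["x", 1], se_below = cf["x", 2],
                 slope_above = cf["x", 1], se_above = cf["x", 2],
                 slope_change = 0, se_change = NA_real_,
                 linear_fallback = TRUE, fit = fit, n = nrow(dat)),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise model of %s on %s, n = %d\n",
              x$outcome, x$exposure, x$n))
  if (x$linear_fallback) {
    cat(sprintf("linear fallback: slope %.4g (SE %.3g)\n",
                x$slope_below, x$se_below))
  } else {
    cat(sprintf("breakpoint %.4g; slope below %.4g (SE %.3g), above %.4g (SE %.3g)\n",
                x$breakpoint, x$slope_below, x$se_below,
                x$slope_above, x$se_above))
  }
  invisible(x)
}
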