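# Agreement analysis between Doppler-ultrasound and computed ICA peak
# systolic velocities: probe-offset adjustment, Bland-Altman limits of
# agreement, ICC(2,1), ordinary regression, relative errors, margin
# coverage, per-grade subgroup tables and ICC-based sample-size planning.
# All functions take the paired-measurement tibble first and return tibbles,
# so they chain with the pipe.

check_pairs <- function(pairs, n_min = 1) {
  pairs <- tibble::as_tibble(pairs)
  abort_if(!all(c("psv_dus", "psv_cfd") %in% names(pairs)),
           "`pairs` needs columns psv_dus and psv_cfd")
  abort_if(nrow(pairs) < n_min,
           paste0("need at least ", n_min, " measurement pairs"))
  abort_if(any(!is.finite(pairs$psv_dus)) || any(!is.finite(pairs$psv_cfd)) ||
             any(pairs$psv_dus <= 0) || any(pairs$psv_cfd <= 0),
           "PSV values must be positive and finite")
  pairs
}

#' Adjust a DUS PSV reading for probe-placement offset
#'
#' An ultrasound sampling volume placed up to one sample-volume radius
#' (0.4 mm) off the vessel centerline under-reads the centerline velocity.
#' Assuming a parabolic velocity profile, the centerline value implied by a
#' reading at radial offset `d` in a vessel of radius `R` is
#' `psv / (1 - (d/R)^2)`.
#'
#' @param psv_measured Measured PSV (cm/s), vectorized.
#' @param vessel_radius Lumen radius at the sampling site (mm), vectorized.
#' @param offset Radial probe offset (mm), default 0.4 (one sampling volume).
#' @return Adjusted PSV (cm/s).
#' @export
adjust_dus_psv <- function(psv_measured, vessel_radius, offset = 0.4) {
  abort_if(any(!is.finite(psv_measured)) || any(psv_measured < 0),
           "`psv_measured` must be non-negative")
  abort_if(any(!is.finite(vessel_radius)) || any(vessel_radius <= 0),
           "`vessel_radius` must be positive")
  abort_if(!is.numeric(offset) || any(offset < 0) || any(offset >= vessel_radius),
           "`offset` must satisfy 0 <= offset < vessel_radius")
  psv_measured / (1 - (offset / vessel_radius)^2)
}

#' Bland-Altman agreement statistics
#'
#' Differences are computed as CFD minus DUS. The bias is their mean, the
#' spread the sample standard deviation (n - 1 denominator), and the limits
#' of agreement `bias +/- 1.96 sd`.
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd` (cm/s).
#' @return One-row tibble: `n`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 2)
  d <- pairs$psv_cfd - pairs$psv_dus
  bias <- mean(d)
  sd_d <- stats::sd(d)
  tibble::tibble(n = length(d), bias = bias, sd_diff = sd_d,
                 loa_lower = bias - 1.96 * sd_d,
                 loa_upper = bias + 1.96 * sd_d)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement: from the
#' two-way ANOVA mean squares (subjects x methods),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd`.
#' @return The ICC (dimensionless, in `[-1, 1]`).
#' @export
icc_2_1 <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 3)
  Y <- cbind(pairs$psv_dus, pairs$psv_cfd)
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_total <- sum((Y - grand)^2)
  abort_if(ss_total <= 0, "zero total variance: ICC undefined")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Agreement regression of computed on measured PSV
#'
#' Ordinary least squares `PSV_CFD = intercept + slope * PSV_DUS`, with the
#' standard error of the slope from the residual variance.
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd`.
#' @return One-row tibble: `intercept`, `slope`, `slope_se`, `r2`.
#' @export
regress_agreement <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 3)
  abort_if(stats::sd(pairs$psv_dus) == 0, "zero predictor variance")
  fit <- stats::lm(psv_cfd ~ psv_dus, data = pairs)
  res <- stats::residuals(fit)
  n <- nrow(pairs)
  sxx <- sum((pairs$psv_dus - mean(pairs$psv_dus))^2)
  sst <- sum((pairs$psv_cfd - mean(pairs$psv_cfd))^2)
  tibble::tibble(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 slope_se = sqrt(sum(res^2) / (n - 2) / sxx),
                 r2 = 1 - sum(res^2) / sst)
}

#' Relative error statistics
#'
#' Per-pair error as a percentage of the mean of the two measurements,
#' `e = 100 (cfd - dus) / ((cfd + dus)/2)`; returns its mean and sample SD.
#' A single pair has no SD; 0 is returned with the `sd_defined` flag unset.
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd`.
#' @return One-row tibble: `mean_pct`, `sd_pct`, `sd_defined`.
#' @export
relative_error_stats <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 1)
  m <- (pairs$psv_cfd + pairs$psv_dus) / 2
  abort_if(any(m == 0), "pair with zero mean: relative error undefined")
  e <- 100 * (pairs$psv_cfd - pairs$psv_dus) / m
  tibble::tibble(mean_pct = mean(e),
                 sd_pct = if (length(e) > 1) stats::sd(e) else 0,
                 sd_defined = length(e) > 1)
}

#' Fraction of pairs within a relative margin
#'
#' Fraction of pairs whose absolute difference is within `margin` times the
#' DUS value — the clinically tolerated DUS interobserver band (30% by
#' default).
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd`.
#' @param margin Relative margin (0.3 = 30%).
#' @return Fraction in `[0, 1]`.
#' @export
within_margin <- function(pairs, margin = 0.3) {
  pairs <- check_pairs(pairs, n_min = 1)
  abort_if(!is_number(margin) || margin <= 0, "`margin` must be positive")
  mean(abs(pairs$psv_cfd - pairs$psv_dus) <= margin * pairs$psv_dus)
}

#' Per-grade agreement table
#'
#' The full agreement summary, one row per NASCET grade present plus a
#' `total` row: sample size, mean +/- SD of each modality, mean +/- SD of
#' the differences, relative error statistics and ICC(2,1). Grades with
#' fewer than three pairs report no ICC (flagged in `icc_defined`).
#'
#' @param pairs Data frame with columns `psv_dus`, `psv_cfd` and `grade`.
#' @return An `agreement_report`: a tibble of per-grade rows with the
#'   Bland-Altman columns, plus attributes carrying the overall regression
#'   and margin coverage. Use [tidy()]/[glance()] to extract.
#' @export
subgroup_report <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 2)
  abort_if(!"grade" %in% names(pairs), "`pairs` needs a `grade` column")
  grades <- c(intersect(c("free", "mild", "moderate", "severe"),
                        unique(as.character(pairs$grade))), "total")
  one <- function(g) {
    sub <- if (g == "total") pairs else pairs[as.character(pairs$grade) == g, ]
    d <- sub$psv_cfd - sub$psv_dus
    re <- relative_error_stats(sub)
    icc_ok <- nrow(sub) >= 3
    tibble::tibble(
      grade = g, n = nrow(sub),
      mean_cfd = mean(sub$psv_cfd), sd_cfd = stats::sd(sub$psv_cfd),
      mean_dus = mean(sub$psv_dus), sd_dus = stats::sd(sub$psv_dus),
      mean_diff = mean(d), sd_diff = stats::sd(d),
      rel_err_mean = re$mean_pct, rel_err_sd = re$sd_pct,
      icc = if (icc_ok) icc_2_1(sub) else NA_real_,
      icc_defined = icc_ok)
  }
  rep_tbl <- dplyr::bind_rows(lapply(grades, one))
  ba <- bland_altman(pairs)
  structure(rep_tbl,
            regression = regress_agreement(pairs),
            bland_altman = ba,
            within_margin = within_margin(pairs),
            class = c("agreement_report", class(rep_tbl)))
}

#' @export
tidy.agreement_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "agreement_report")
  attr(out, "regression") <- NULL
  attr(out, "bland_altman") <- NULL
  attr(out, "within_margin") <- NULL
  out
}

#' @export
glance.agreement_report <- function(x, ...) {
  ba <- attr(x, "bland_altman")
  rg <- attr(x, "regression")
  tot <- x[x$grade == "total", ]
  tibble::tibble(n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
                 loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                 icc = tot$icc,
                 intercept = rg$intercept, slope = rg$slope,
                 slope_se = rg$slope_se, r2 = rg$r2,
                 rel_err_mean = tot$rel_err_mean, rel_err_sd = tot$rel_err_sd,
                 within_margin = attr(x, "within_margin"))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement_report (DUS vs CFD, ICA PSV)\n")
  print(tidy(x), ...)
  g <- glance(x)
  cat(sprintf("bias %.1f cm/s, LoA [%.1f, %.1f]; ICC %.2f; CFD = %.1f + %.3f DUS (R2 %.2f)\n",
              g$bias, g$loa_lower, g$loa_upper, g$icc, g$intercept, g$slope, g$r2))
  invisible(x)
}

#' Bland-Altman panel for an agreement analysis
#'
#' @param object An [subgroup_report()] result (or any pairs tibble via
#'   [plot_bland_altman()]).
#' @param ... Unused.
#' @export
autoplot.agreement_report <- function(object, ...) {
  stop("autoplot on agreement_report needs the source pairs; use plot_bland_altman(pairs)")
}

#' Bland-Altman and scatter panels of paired PSV data
#'
#' @param pairs Data frame with `psv_dus`, `psv_cfd` and optionally `grade`.
#' @param margin Relative margin drawn on the scatter panel.
#' @return A ggplot object (Bland-Altman panel).
#' @export
plot_bland_altman <- function(pairs, margin = 0.3) {
  pairs <- check_pairs(pairs, n_min = 2)
  ba <- bland_altman(pairs)
  df <- tibble::tibble(m = (pairs$psv_cfd + pairs$psv_dus) / 2,
                       d = pairs$psv_cfd - pairs$psv_dus,
                       grade = if ("grade" %in% names(pairs))
                         as.character(pairs$grade) else "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d,
                                   colour = .data$grade)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_lower, ba$loa_upper),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "mean PSV of both modalities (cm/s)",
                  y = "PSV difference CFD - DUS (cm/s)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Sample size for an ICC-based agreement study
#'
#' Smallest number of subjects for which a one-sided alpha-level test of
#' `H0: ICC = icc_min` attains the requested power at `ICC = icc_expected`,
#' by the Walter-Eliasziw-Donner log-variance approximation: with
#' `theta(r) = (1 + (k-1) r) / (1 - r)` the requirement is
#' `ln(theta1/theta0)^2 >= (z_a + z_b)^2 * 2 * (1/(n-1) + 1/(n(k-1)))`.
#'
#' @param icc_min Minimum acceptable ICC (null hypothesis).
#' @param icc_expected Anticipated ICC (alternative).
#' @param alpha One-sided significance level.
#' @param power Target power.
#' @param raters Number of raters/methods per subject (k, default 2).
#' @return The required number of subjects (integer).
#' @export
sample_size_icc <- function(icc_min = 0.75, icc_expected = 0.9, alpha = 0.05,
                            power = 0.8, raters = 2) {
  abort_if(!is_number(icc_min) || !is_number(icc_expected) ||
             icc_min <= 0 || icc_expected >= 1 || icc_min >= icc_expected,
           "need 0 < icc_min < icc_expected < 1")
  abort_if(!is_number(alpha) || alpha <= 0 || alpha >= 1, "`alpha` in (0,1)")
  abort_if(!is_number(power) || power <= 0 || power >= 1, "`power` in (0,1)")
  abort_if(!is_number(raters) || raters < 2, "`raters` must be at least 2")
  k <- raters
  theta <- function(r) (1 + (k - 1) * r) / (1 - r)
  lnC2 <- log(theta(icc_expected) / theta(icc_min))^2
  zz <- (stats::qnorm(1 - alpha) + stats::qnorm(power))^2
  for (n in 2:10000) {
    v <- 2 * (1 / (n - 1) + 1 / (n * (k - 1)))
    if (lnC2 >= zz * v) return(n)
  }
  rlang::abort("no feasible sample size below 10000")
}
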