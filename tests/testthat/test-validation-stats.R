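# Agreement statistics against closed forms and brute-force oracles.

test_that("the probe-offset adjustment follows the parabolic correction", {
  expect_equal(adjust_dus_psv(100, 2.0, 0), 100)
  expect_rel(adjust_dus_psv(100, 2.0, 0.4), 100 / (1 - 0.04), 1e-12)
  expect_rel(adjust_dus_psv(100, 1e6, 0.4), 100, 1e-10)  # wide-vessel limit
  expect_error(adjust_dus_psv(100, 0.3, 0.4), "offset")
  # >= identity, strictly increasing in offset, invertible
  offs <- seq(0, 1.9, by = 0.1)
  adj <- adjust_dus_psv(100, 2.0, offs)
  expect_true(all(adj >= 100))
  expect_true(all(diff(adj) > 0))
  back <- adj * (1 - (offs / 2.0)^2)
  expect_equal(back, rep(100, length(offs)), tolerance = 1e-12)
})

test_that("Bland-Altman reproduces its identities and Monte-Carlo truth", {
  d <- 7.5
  pairs <- data.frame(psv_dus = c(90, 110, 130), psv_cfd = c(90, 110, 130) + d)
  ba <- bland_altman(pairs)
  expect_equal(ba$bias, d)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_lower, d); expect_equal(ba$loa_upper, d)
  # LoA symmetry at machine precision on arbitrary data
  set.seed(8)
  pr <- data.frame(psv_dus = runif(50, 50, 200))
  pr$psv_cfd <- pr$psv_dus * runif(50, 0.8, 1.3)
  ba2 <- bland_altman(pr)
  expect_equal(ba2$loa_upper - ba2$bias, ba2$bias - ba2$loa_lower,
               tolerance = 1e-12)
  # seeded Monte-Carlo: differences ~ N(10, 20^2)
  set.seed(123)
  n <- 1e5
  base <- runif(n, 100, 200)
  mc <- data.frame(psv_dus = base, psv_cfd = base + rnorm(n, 10, 20))
  bam <- bland_altman(mc)
  expect_lt(abs(bam$bias - 10), 0.2)
  expect_rel(bam$loa_upper, 10 + 1.96 * 20, 0.01)
  expect_rel(bam$loa_lower, 10 - 1.96 * 20, 0.05)
  expect_error(bland_altman(mc[1, ]), "at least 2")
})

test_that("the printed total-row moments give the printed upper limit", {
  expect_equal(round(13 + 1.96 * 32), 76)
  expect_equal(round(13 - 1.96 * 32), -50)  # printed lower limit is -49 cm/s
})

test_that("ICC(2,1) matches limits and a brute-force ANOVA oracle", {
  # perfect agreement
  p <- data.frame(psv_dus = c(80, 100, 150, 220), psv_cfd = c(80, 100, 150, 220))
  expect_equal(icc_2_1(p), 1)
  # no subject variance, independent noise: ICC near zero
  set.seed(21)
  n <- 1e4
  noise <- data.frame(psv_dus = 100 + rnorm(n, 0, 10),
                      psv_cfd = 100 + rnorm(n, 0, 10))
  expect_lt(abs(icc_2_1(noise)), 0.05)
  # 6-subject worked example against the ANOVA decomposition from aov()
  set.seed(33)
  s <- rnorm(6, 120, 40)
  six <- data.frame(psv_dus = abs(s + rnorm(6, 0, 12)) + 1,
                    psv_cfd = abs(1.08 * s + rnorm(6, 0, 12)) + 1)
  df <- data.frame(y = c(six$psv_dus, six$psv_cfd),
                   subj = factor(rep(1:6, 2)), meth = factor(rep(1:2, each = 6)))
  av <- summary(stats::aov(y ~ subj + meth, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]; msc <- av["meth", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(icc_2_1(six), oracle, tolerance = 1e-12)
  expect_error(icc_2_1(data.frame(psv_dus = c(1, 1, 1), psv_cfd = c(1, 1, 1))),
               "zero total variance")
})

test_that("agreement regression matches exact lines and normal equations", {
  x <- c(60, 90, 120, 180, 240)
  exact <- data.frame(psv_dus = x, psv_cfd = 2 * x + 1)
  fit <- regress_agreement(exact)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  set.seed(4)
  rnd <- data.frame(psv_dus = runif(40, 50, 250))
  rnd$psv_cfd <- 10 + 1.1 * rnd$psv_dus + rnorm(40, 0, 15)
  rnd$psv_cfd <- abs(rnd$psv_cfd) + 1
  f2 <- regress_agreement(rnd)
  X <- cbind(1, rnd$psv_dus)
  beta <- solve(t(X) %*% X, t(X) %*% rnd$psv_cfd)
  expect_equal(c(f2$intercept, f2$slope), as.vector(beta), tolerance = 1e-10)
  resid <- rnd$psv_cfd - X %*% beta
  se <- sqrt(sum(resid^2) / (40 - 2) * solve(t(X) %*% X)[2, 2])
  expect_equal(f2$slope_se, se, tolerance = 1e-10)
  # permuted responses decorrelate the slope
  set.seed(9)
  big <- data.frame(psv_dus = runif(5e3, 50, 250))
  big$psv_cfd <- sample(big$psv_dus)
  expect_lt(abs(regress_agreement(big)$slope), 0.05)
})

test_that("relative errors use the per-pair mean denominator", {
  same <- data.frame(psv_dus = c(90, 120), psv_cfd = c(90, 120))
  expect_equal(unlist(relative_error_stats(same)[, 1:2]),
               c(mean_pct = 0, sd_pct = 0))
  one <- relative_error_stats(data.frame(psv_dus = 90, psv_cfd = 110))
  expect_equal(one$mean_pct, 20)
  expect_false(one$sd_defined)
  set.seed(14)
  coh <- data.frame(psv_dus = runif(60, 40, 250))
  coh$psv_cfd <- coh$psv_dus * runif(60, 0.7, 1.4)
  e <- 100 * (coh$psv_cfd - coh$psv_dus) / ((coh$psv_cfd + coh$psv_dus) / 2)
  rs <- relative_error_stats(coh)
  expect_equal(rs$mean_pct, mean(e), tolerance = 1e-12)
  expect_equal(rs$sd_pct, stats::sd(e), tolerance = 1e-12)
})

test_that("margin coverage counts pairs within the DUS-relative band", {
  ident <- data.frame(psv_dus = c(100, 150), psv_cfd = c(100, 150))
  expect_equal(within_margin(ident), 1)
  expect_equal(within_margin(data.frame(psv_dus = 100, psv_cfd = 200)), 0)
  set.seed(6)
  coh <- data.frame(psv_dus = runif(300, 50, 250))
  coh$psv_cfd <- coh$psv_dus * runif(300, 0.5, 1.6)
  expect_equal(within_margin(coh, 0.3),
               mean(abs(coh$psv_cfd - coh$psv_dus) <= 0.3 * coh$psv_dus))
})

test_that("the subgroup table mirrors the cohort structure", {
  cc <- cohort_config(seed = 42)
  pairs <- simulate_paired_measurements(simulate_cohort(cc), cc)
  rep <- subgroup_report(pairs)
  tbl <- tidy(rep)
  expect_equal(tbl$n[match(c("free", "mild", "moderate", "total"), tbl$grade)],
               c(7L, 24L, 6L, 37L))
  tot <- tbl[tbl$grade == "total", ]
  expect_equal(tot$mean_diff, tot$mean_cfd - tot$mean_dus, tolerance = 1e-12)
  # single-grade cohort: the total row equals the grade row
  sub <- pairs[pairs$grade == "mild", ]
  r1 <- tidy(subgroup_report(sub))
  expect_equal(unlist(r1[r1$grade == "mild", -1]),
               unlist(r1[r1$grade == "total", -1]))
  # grades with n < 3 report no ICC but keep the other columns
  tiny <- pairs[c(which(pairs$grade == "free")[1:2],
                  which(pairs$grade == "mild")), ]
  rt <- tidy(subgroup_report(tiny))
  expect_true(is.na(rt$icc[rt$grade == "free"]))
  expect_false(rt$icc_defined[rt$grade == "free"])
  expect_false(is.na(rt$mean_diff[rt$grade == "free"]))
  expect_error(subgroup_report(pairs[, c("psv_dus", "psv_cfd")]), "grade")
})

test_that("ICC sample size matches a simulation-based power oracle", {
  n_impl <- sample_size_icc(0.75, 0.9, 0.05, 0.8, raters = 2)
  # one-way random-effects simulation of the alpha-level F test of
  # H0: ICC = 0.75 under truth ICC = 0.9, k = 2
  power_at <- function(n, icc_true = 0.9, icc0 = 0.75, reps = 5000) {
    k <- 2
    theta0 <- (1 + (k - 1) * icc0) / (1 - icc0)
    crit <- theta0 * stats::qf(0.95, n - 1, n * (k - 1))
    set.seed(1000 + n)
    hits <- 0L
    for (r in seq_len(reps)) {
      subj <- stats::rnorm(n, 0, sqrt(icc_true))
      y <- matrix(subj, n, k) + matrix(stats::rnorm(n * k, 0, sqrt(1 - icc_true)), n, k)
      msb <- k * stats::var(rowMeans(y))
      msw <- sum((y - rowMeans(y))^2) / (n * (k - 1))
      if (msb / msw > crit) hits <- hits + 1L
    }
    hits / reps
  }
  pw <- vapply((n_impl - 3):(n_impl + 3), power_at, numeric(1))
  n_sim <- ((n_impl - 3):(n_impl + 3))[which(pw >= 0.8)[1]]
  expect_lte(abs(n_impl - n_sim), 2)
  # monotonicities
  expect_gt(sample_size_icc(0.75, 0.9, 0.05, 0.9), n_impl)
  expect_lt(sample_size_icc(0.75, 0.95, 0.05, 0.8), n_impl)
  expect_error(sample_size_icc(0.9, 0.75), "icc_min")
})
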