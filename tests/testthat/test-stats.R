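# small simulated datasets for the mixed model
sim_lmm_data <- function(n_lines = 20, per = 6, beta_lat = 0.03,
                         sd_line = 0.3, sd_e = 0.4, seed = 1) {
  set.seed(seed)
  d <- data.frame(line = rep(sprintf("L%02d", seq_len(n_lines)), each = per),
                  latitude = rep(runif(n_lines, 42, 65), each = per))
  d$y <- 24 + beta_lat * d$latitude +
    rep(rnorm(n_lines, 0, sd_line), each = per) + rnorm(nrow(d), 0, sd_e)
  d
}

test_that("with no group variance the fit collapses to ordinary regression", {
  d <- sim_lmm_data(sd_line = 0, seed = 3)
  f <- fit_random_intercept(y ~ latitude, d, groups = "line")
  ols <- lm(y ~ latitude, d)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-6)
  expect_lt(f$sigma2_u, 0.01)
})

test_that("balanced designs reproduce closed-form GLS solutions", {
  # balanced groups, intercept-only: GLS estimate is the grand mean at any
  # variance ratio
  d <- data.frame(line = rep(c("A", "B", "C"), each = 4),
                  y = c(1, 2, 3, 4, 11, 12, 13, 14, 6, 7, 8, 9))
  f <- fit_random_intercept(y ~ 1, d, groups = "line")
  expect_equal(unname(coef(f)), mean(d$y))
  # a covariate with the same centred pattern within every group is
  # orthogonal to the group structure: GLS slope = OLS slope exactly
  d$x <- rep(c(-1.5, -0.5, 0.5, 1.5), 3)
  f2 <- fit_random_intercept(y ~ x, d, groups = "line")
  expect_equal(unname(coef(f2)["x"]), unname(coef(lm(y ~ x, d))["x"]))
})

test_that("ML and REML fits agree with lme4 on coefficients and likelihood", {
  skip_if_not_installed("lme4")
  d <- sim_lmm_data(seed = 7)
  f <- fit_random_intercept(y ~ latitude, d, groups = "line")
  m <- lme4::lmer(y ~ latitude + (1 | line), d, REML = FALSE)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$sigma2_u, unname(unlist(lme4::VarCorr(m))),
               tolerance = 1e-4)
  fr <- fit_random_intercept(y ~ latitude, d, groups = "line",
                             method = "REML")
  mr <- lme4::lmer(y ~ latitude + (1 | line), d, REML = TRUE)
  expect_equal(fr$loglik, as.numeric(logLik(mr)), tolerance = 1e-6)
  expect_equal(fr$sigma2, sigma(mr)^2, tolerance = 1e-5)
})

test_that("degenerate designs are caught", {
  d <- sim_lmm_data(seed = 5)
  d$dup <- d$latitude * 2
  expect_error(fit_random_intercept(y ~ latitude + dup, d, groups = "line"),
               "singular")
  d1 <- data.frame(line = "L01", x = 1:8, y = 2 + 0.5 * (1:8) + rnorm(8))
  expect_warning(f1 <- fit_random_intercept(y ~ x, d1, groups = "line"),
                 "ordinary least squares")
  expect_equal(unname(coef(f1)), unname(coef(lm(y ~ x, d1))),
               tolerance = 1e-6)
})

test_that("model methods behave like standard R model objects", {
  d <- sim_lmm_data(seed = 11)
  f <- fit_random_intercept(y ~ latitude, d, groups = "line")
  expect_length(fitted(f), nrow(d))
  expect_equal(fitted(f) + residuals(f), d$y)
  expect_equal(attr(logLik(f), "df"), 4)     # 2 fixed + 2 variances
  expect_equal(predict(f, data.frame(latitude = 50)),
               unname(coef(f)[1] + 50 * coef(f)[2]))
  # conditional residuals have smaller spread than marginal ones
  expect_lt(sd(residuals(f, "conditional")), sd(residuals(f, "marginal")))
  expect_output(print(summary(f)), "Fixed effects")
})

test_that("the likelihood-ratio test is valid on nested ML fits", {
  d <- sim_lmm_data(seed = 13)
  full <- fit_random_intercept(y ~ latitude, d, groups = "line")
  red <- fit_random_intercept(y ~ 1, d, groups = "line")
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)               # adding a term never hurts ML
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  other <- fit_random_intercept(y ~ 1, sim_lmm_data(seed = 14),
                                groups = "line")
  expect_error(likelihood_ratio_test(full, other), "identical data")
  expect_error(likelihood_ratio_test(red, full), "not nested")
})

test_that("planted fixed effects are recovered without systematic bias", {
  nrep <- 200
  est <- vapply(seq_len(nrep), function(i) {
    d <- sim_lmm_data(beta_lat = 0.03, seed = 2000 + i)
    unname(coef(fit_random_intercept(y ~ latitude, d,
                                     groups = "line"))["latitude"])
  }, numeric(1))
  mcse <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - 0.03), 3 * mcse)
})

test_that("GLM deviance on a 2x2 table equals the hand-computed G statistic", {
  tab <- data.frame(
    rhythmic = rep(c(TRUE, FALSE, TRUE, FALSE), c(90, 10, 68, 32)),
    sex = rep(c("M", "F"), each = 100),
    population = "COR", mating = "virgin")
  res <- rhythmicity_glm(tab, factors = "sex")
  # independent oracle: G = 2 * sum O log(O/E) on the 2x2 margins
  O <- c(90, 10, 68, 32)
  E <- c(79, 21, 79, 21)
  G <- 2 * sum(O * log(O / E))
  expect_equal(res$chisq, G, tolerance = 1e-8)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)
  # identical proportions give a null deviance
  tab0 <- within(tab, rhythmic <- rep(rep(c(TRUE, FALSE), c(80, 20)), 2))
  expect_lt(rhythmicity_glm(tab0, factors = "sex")$chisq, 1e-8)
})

test_that("complete separation is flagged as unreliable", {
  tab <- data.frame(rhythmic = rep(c(TRUE, FALSE), each = 30),
                    sex = rep(c("M", "F"), each = 30))
  expect_warning(res <- rhythmicity_glm(tab, factors = "sex"), "separation")
  expect_false(res$reliable)
})

test_that("a planted sex effect on rhythmicity is detected with high power", {
  nrep <- 60
  set.seed(321)
  hits <- vapply(seq_len(nrep), function(i) {
    tab <- data.frame(
      rhythmic = c(runif(150) < 0.9, runif(150) < 0.68),
      sex = rep(c("M", "F"), each = 150))
    rhythmicity_glm(tab, factors = "sex")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("phase-tau regression recovers a planted slope and rejects degeneracy", {
  gen <- function(seed) {
    set.seed(seed)
    n_lines <- 10; per <- 6
    d <- data.frame(line = rep(sprintf("L%d", 1:n_lines), each = per))
    d$peak <- (5 + rnorm(nrow(d), 0, 1.5)) %% 24
    d$tau_hat <- 24 + 0.2 * circ_diff(d$peak, 5) +
      rep(rnorm(n_lines, 0, 0.1), each = per) + rnorm(nrow(d), 0, 0.15)
    d
  }
  est <- vapply(1:100, function(i)
    unname(coef(phase_tau_regression(gen(i)))["peak_c"]), numeric(1))
  mcse <- sd(est) / sqrt(100)
  expect_lt(abs(mean(est) - 0.2), 3 * mcse)
  d <- gen(1); d$peak <- 5
  expect_error(phase_tau_regression(d), "constant")
  expect_error(phase_tau_regression(d[1:2, ]), "fewer than 3")
})

test_that("slope confidence intervals cover an absent effect at the nominal rate", {
  cover <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    n_lines <- 10; per <- 6
    d <- data.frame(line = rep(sprintf("L%d", 1:n_lines), each = per))
    d$peak <- (5 + rnorm(nrow(d), 0, 1.5)) %% 24
    d$tau_hat <- 24 + rep(rnorm(n_lines, 0, 0.1), each = per) +
      rnorm(nrow(d), 0, 0.15)
    f <- phase_tau_regression(d)
    b <- coef(f)["peak_c"]; s <- f$se["peak_c"]
    b - 1.96 * s <= 0 && 0 <= b + 1.96 * s
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.995)
})

test_that("summarize_cline orders populations by latitude and finds the slope", {
  set.seed(77)
  mk <- function(pop, lat, tau, n = 30)
    data.frame(individual_id = paste0(pop, 1:n), population = pop,
               latitude = lat, line = paste0(pop, "_L", rep(1:5, len = n)),
               sex = "F", mating = "virgin", rhythmic = TRUE,
               tau_hat = tau + rnorm(n, 0, 0.2))
  tab <- rbind(mk("COR", 42.38, 24.6), mk("OUL", 65.06, 25.42))
  cl <- summarize_cline(tab, subgroup = list(sex = "F"))
  expect_equal(cl$populations$population, c("COR", "OUL"))
  d <- diff(cl$populations$mean_tau)
  expect_lt(abs(d - 0.82), 0.15)
  expect_gt(cl$slope, 0)
  # same tau duplicated at two latitudes: slope indistinguishable from 0
  tab0 <- rbind(mk("A", 45, 24.5), mk("B", 60, 24.5))
  cl0 <- summarize_cline(tab0)
  expect_lt(abs(cl0$slope), 3 * cl0$slope_se + 1e-6)
  expect_error(summarize_cline(tab, subgroup = list(sex = "M")), "empty")
})

test_that("cohort_table blanks tau for arrhythmic individuals and joins markers", {
  tau <- data.frame(individual_id = c("a", "b"), rhythmic = c(TRUE, FALSE),
                    tau_hat = c(24.5, 23.9))
  mk <- data.frame(individual_id = "a", onset = 1, peak = 5, offset = 12)
  ct <- cohort_table(tau, mk)
  expect_true(is.na(ct$tau_hat[ct$individual_id == "b"]))
  expect_equal(ct$peak[ct$individual_id == "a"], 5)
})
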