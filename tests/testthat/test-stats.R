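test_that("Shapiro-Wilk wrapper returns W = 1 for a symmetric triple and rejects misuse", {
  res <- shapiro_wilk(c(1, 2, 3), variable = "x")
  expect_equal(res$W, 1, tolerance = 1e-6)
  expect_error(shapiro_wilk(c(2, 2, 2)), class = "pdgait_precondition_error")
  expect_error(shapiro_wilk(c(1, 2)), class = "pdgait_precondition_error")
  set.seed(99)
  expect_lt(shapiro_wilk(rexp(50))$p, 0.05)
})

test_that("normality gate picks Pearson only when both margins are normal", {
  norm <- tibble::tibble(normal = TRUE)
  skew <- tibble::tibble(normal = FALSE)
  expect_equal(choose_method(norm, norm), "pearson")
  expect_equal(choose_method(skew, norm), "spearman")
  expect_equal(choose_method(skew, skew), "spearman")
})

test_that("correlation estimates, p-values and Fisher-z CIs are correct", {
  res <- correlate(c(1, 2, 3, 4), c(2, 4, 6, 8), "pearson")
  expect_equal(res$r, 1)
  res2 <- correlate(c(1, 2, 3, 4), c(1, 8, 27, 64), "spearman")
  expect_equal(res2$r, 1)

  # hand-evaluated Fisher-z oracle at r = 0.6, n = 19
  set.seed(5)
  x <- rnorm(19)
  y <- as.numeric(0.6 * scale(x) +
                    sqrt(1 - 0.36) * scale(resid(lm(rnorm(19) ~ x))))
  r_obs <- cor(x, y)
  res3 <- correlate(x, y, "pearson")
  z <- atanh(r_obs)
  expect_equal(c(res3$ci_lower, res3$ci_upper),
               tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(16)), tolerance = 1e-12)
  # t-test p-value oracle
  tstat <- r_obs * sqrt(17 / (1 - r_obs^2))
  expect_equal(res3$p, 2 * pt(-abs(tstat), 17), tolerance = 1e-12)

  expect_error(correlate(rep(1, 5), 1:5, "pearson"),
               class = "pdgait_precondition_error")
})

test_that("OLS matches the normal-equations oracle and flags rank deficiency", {
  set.seed(10)
  X <- tibble::tibble(RI = rnorm(10), WM = rnorm(10), MR = rnorm(10))
  y <- 1 + 2 * X$WM + rnorm(10, sd = 0.3)
  fit <- ols_fit(X, y, dependent = "y")
  M <- cbind(1, as.matrix(X))
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(fit$B, as.numeric(beta), tolerance = 1e-10)
  resid <- y - M %*% beta
  s2 <- sum(resid^2) / (10 - 4)
  expect_equal(fit$SE, unname(sqrt(diag(s2 * solve(t(M) %*% M)))),
               tolerance = 1e-10)
  expect_true(attr(fit, "adj_r_squared") <= attr(fit, "r_squared"))
  expect_true(all(fit$ci_lower <= fit$B & fit$B <= fit$ci_upper))

  # exact linear response
  y2 <- 1 + 2 * X$WM
  fit2 <- ols_fit(X["WM"], y2)
  expect_equal(fit2$B, c(1, 2), tolerance = 1e-10)
  expect_equal(attr(fit2, "r_squared"), 1, tolerance = 1e-10)

  Xd <- dplyr::mutate(X, dup = WM)
  expect_error(ols_fit(Xd, y), "dup", class = "pdgait_rank_error")
})

test_that("VIF is exact for orthogonal and correlation-0.5 designs", {
  a <- c(1, -1, 1, -1)
  c2 <- c(1, 1, -1, -1)
  expect_equal(vif(data.frame(a = a, b = c2))$vif, c(1, 1), tolerance = 1e-12)
  b <- 0.5 * a + sqrt(3) / 2 * c2 # sample correlation with a exactly 0.5
  expect_equal(cor(a, b), 0.5, tolerance = 1e-12)
  expect_equal(vif(data.frame(a = a, b = b))$vif,
               c(4 / 3, 4 / 3), tolerance = 1e-10)
  expect_true(all(is.infinite(vif(data.frame(a = a, b = a))$vif)))
})

test_that("MANOVA agrees with an independent implementation on all four statistics", {
  set.seed(77)
  co <- simulate_cohort(n = 19, marginals = gaussian_marginals(),
                        seed = 77)$cohort
  X <- co[c("response_inhibition", "working_memory", "mental_rotation")]
  Y <- as.matrix(co[c("tug_sit_to_stand", "tug_walk1", "tug_turn",
                      "tug_walk2")])
  mine <- manova_battery(X, Y)
  fit <- lm(Y ~ response_inhibition + working_memory + mental_rotation,
            data = X)
  ref <- car::Manova(fit, type = "III")
  # compare the Wilks/Pillai/HL/Roy values and dfs per term
  ref_sum <- summary(ref, multivariate = TRUE)
  for (term in c("(Intercept)", "working_memory")) {
    tt <- ref_sum$multivariate.tests[[term]]
    eig <- Re(eigen(solve(tt$SSPE) %*% tt$SSPH, only.values = TRUE)$values)[1]
    mt <- mine[mine$term == term, ]
    expect_equal(mt$value[mt$statistic == "Wilks' lambda"], 1 / (1 + eig),
                 tolerance = 1e-8)
    expect_equal(mt$value[mt$statistic == "Hotelling-Lawley trace"], eig,
                 tolerance = 1e-8)
    expect_equal(mt$value[mt$statistic == "Pillai's trace"], eig / (1 + eig),
                 tolerance = 1e-8)
  }
})

test_that("single-response MANOVA reduces to OLS via Wilks = 1 - R2", {
  co <- simulate_cohort(n = 19, seed = 31)$cohort
  X <- co[c("response_inhibition", "working_memory", "mental_rotation")]
  y <- co$tug_walk2
  mv <- manova_battery(X, data.frame(y = y), include_overall = TRUE)
  # full-model identity: omnibus Wilks equals 1 - R2 of the OLS fit
  fit <- ols_fit(X, y)
  expect_equal(mv$value[mv$term == "overall" & mv$statistic == "Wilks' lambda"],
               1 - attr(fit, "r_squared"), tolerance = 1e-10)
  wm <- mv[mv$term == "working_memory" & mv$statistic == "Wilks' lambda", ]
  expect_equal(wm$p, fit$p[fit$term == "working_memory"], tolerance = 1e-8)
  tval <- fit$t[fit$term == "working_memory"]
  expect_equal(wm$F, tval^2, tolerance = 1e-8)
  # one-df terms: the four statistics share one F and p
  for (term in unique(mv$term)) {
    Fs <- mv$F[mv$term == term]
    ps <- mv$p[mv$term == term]
    expect_lt(max(Fs) - min(Fs), 1e-8)
    expect_lt(max(ps) - min(ps), 1e-10)
  }
})

test_that("the full battery has the contracted shape and engages the Spearman gate", {
  co <- suppressMessages(simulate_cohort(n = 19, seed = 55)$cohort)
  rep <- suppressWarnings(suppressMessages(run_full_battery(co)))
  expect_equal(nrow(rep$normality), 22)
  expect_equal(nrow(rep$correlations), 57)
  expect_equal(length(unique(rep$ols$dependent)), 19)
  expect_equal(sort(unique(rep$manova$block)),
               c("tug", "walking_dt", "walking_st"))
  expect_equal(nrow(rep$vif), 3)
  # every pair involving a skewed margin must run Spearman
  ri_rows <- rep$correlations[rep$correlations$predictor == "response_inhibition", ]
  if (!rep$normality$normal[rep$normality$variable == "response_inhibition"]) {
    expect_true(all(ri_rows$method == "spearman"))
  }
  # an all-missing column is dropped with a warning, battery completes
  co2 <- co
  co2$toe_clearance_dt <- NA_real_
  expect_warning(rep2 <- suppressMessages(run_full_battery(co2)),
                 class = "pdgait_log")
  expect_equal(nrow(rep2$correlations), 54)
})

test_that("lognormal margins force the Spearman gate in small cohorts", {
  hits <- 0L
  for (k in 1:40) {
    co <- simulate_cohort(n = 19, seed = 500 + k)$cohort
    sw <- shapiro_wilk(co$response_inhibition, "ri")
    if (!sw$normal) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.8)
})
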