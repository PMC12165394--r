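#' Shapiro-Wilk normality check
#'
#' Wraps the Royston approximation of the Shapiro-Wilk test and attaches the
#' normality flag used to gate the correlation method choice.
#'
#' @param x Numeric sample (3 <= n <= 5000, nonzero variance).
#' @param variable Variable name recorded in the result.
#' @param alpha Significance level for the normality flag.
#'
#' @return One-row tibble: `variable`, `n`, `W`, `p`, `normal`.
#' @export
#' @examples
#' shapiro_wilk(rnorm(19))
shapiro_wilk <- function(x, variable = deparse(substitute(x)), alpha = 0.05) {
  force(variable)
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000 finite values.",
          class = "pdgait_precondition_error")
  }
  if (sd(x) == 0) {
    abort("Shapiro-Wilk is undefined for a constant sample.",
          class = "pdgait_precondition_error")
  }
  sw <- shapiro.test(x)
  tibble::tibble(
    variable = variable,
    n = length(x),
    W = unname(sw$statistic),
    p = sw$p.value,
    normal = sw$p.value > alpha
  )
}

#' Choose the correlation method from two normality results
#'
#' Pearson if both variables passed the normality check, Spearman if either
#' failed — the conservative reading of "Pearson or Spearman depending on the
#' normality test".
#'
#' @param nx,ny One-row tibbles from [shapiro_wilk()], or logical flags.
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(nx, ny) {
  flag <- function(v) if (is.data.frame(v)) v$normal[1] else isTRUE(v)
  if (flag(nx) && flag(ny)) "pearson" else "spearman"
}

#' Pairwise correlation with Fisher-z confidence interval
#'
#' Pearson r with a two-sided t-test (df = n - 2) and Fisher-z 95% CI
#' (SE = 1/sqrt(n - 3)); Spearman rho with the t-approximation for the
#' p-value and a Fisher-z CI with the Fieller-corrected SE
#' sqrt(1.06 / (n - 3)).
#'
#' @param x,y Numeric samples of equal length (pairwise-complete, n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @param predictor,dependent Names recorded in the result.
#' @param conf_level Confidence level.
#'
#' @return One-row tibble: `predictor`, `dependent`, `method`, `n`, `r`,
#'   `p`, `ci_lower`, `ci_upper`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      predictor = "x", dependent = "y", conf_level = 0.95) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) {
    abort("Correlation requires at least 4 complete pairs.",
          class = "pdgait_precondition_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a zero-variance sample.",
          class = "pdgait_precondition_error")
  }
  r <- cor(x, y, method = method)
  # t-approximation for both methods (Spearman exact p is not used)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  se_z <- if (method == "pearson") 1 / sqrt(n - 3) else sqrt(1.06 / (n - 3))
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(max(-1 + 1e-15, min(1 - 1e-15, r)))
  ci <- tanh(z + c(-1, 1) * zcrit * se_z)
  tibble::tibble(
    predictor = predictor, dependent = dependent, method = method,
    n = n, r = r, p = p, ci_lower = ci[1], ci_upper = ci[2]
  )
}

#' Multivariable ordinary least squares fit
#'
#' Regresses one response on the three cognitive predictors (plus intercept)
#' and reports, per term, the coefficient, standard error, t statistic,
#' two-sided p (df = n - k - 1) and 95% CI, together with R-squared and
#' adjusted R-squared.
#'
#' @param X Data frame of predictors (columns used as given).
#' @param y Numeric response.
#' @param dependent Name recorded in the result.
#' @param conf_level Confidence level for the coefficient CIs.
#'
#' @return An `ols_result`: a tibble with one row per term and attributes
#'   `r_squared`, `adj_r_squared`, `n`, `dependent`.
#' @export
ols_fit <- function(X, y, dependent = "y", conf_level = 0.95) {
  X <- as.data.frame(X)
  ok <- complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n <= ncol(X) + 1) {
    abort("OLS requires n > number of terms.", class = "pdgait_precondition_error")
  }
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "pdgait_rank_error")
  }
  fit <- lm(y ~ ., data = X)
  sm <- summary(fit)
  cf <- sm$coefficients
  dfres <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, dfres)
  out <- tibble::tibble(
    dependent = dependent,
    term = rownames(cf),
    B = unname(cf[, 1]), SE = unname(cf[, 2]),
    t = unname(cf[, 3]), p = unname(cf[, 4]),
    ci_lower = unname(cf[, 1] - tcrit * cf[, 2]),
    ci_upper = unname(cf[, 1] + tcrit * cf[, 2])
  )
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "adj_r_squared") <- sm$adj.r.squared
  attr(out, "n") <- n
  attr(out, "dependent") <- dependent
  attr(out, "fit") <- fit
  class(out) <- c("ols_result", class(out))
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j on
#' the remaining predictors (with intercept). Perfect collinearity yields an
#' infinite VIF, reported as `Inf`.
#'
#' @param X Data frame or matrix of at least two predictors.
#' @return Tibble with columns `predictor` and `vif`.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) {
    abort("VIF needs at least two predictors.",
          class = "pdgait_precondition_error")
  }
  out <- purrr::map_dfr(names(X), function(j) {
    fit <- lm(stats::reformulate(setdiff(names(X), j), response = j), data = X)
    r2 <- summary(fit)$r.squared
    tibble::tibble(predictor = j,
                   vif = if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2))
  })
  out
}

# F approximations for the four multivariate statistics, one hypothesis term
# with df q_h against error df df_e, p responses, eigenvalues lambda of
# solve(E) %*% H
multivariate_stats <- function(lambda, p, q_h, df_e) {
  s <- min(p, q_h)
  m <- (abs(p - q_h) - 1) / 2
  n_star <- (df_e - p - 1) / 2
  wilks <- prod(1 / (1 + lambda))
  pillai <- sum(lambda / (1 + lambda))
  hl <- sum(lambda)
  roy <- max(lambda)

  # Rao's F for Wilks
  t_den <- p^2 + q_h^2 - 5
  t_rao <- if (t_den > 0) sqrt((p^2 * q_h^2 - 4) / t_den) else 1
  w_df1 <- p * q_h
  w_df2 <- t_rao * (df_e - (p - q_h + 1) / 2) - (p * q_h - 2) / 2
  lam_t <- wilks^(1 / t_rao)
  F_w <- (1 - lam_t) / lam_t * w_df2 / w_df1
  p_w <- pf(F_w, w_df1, w_df2, lower.tail = FALSE)

  # Pillai trace F
  p_df1 <- s * (2 * m + s + 1)
  p_df2 <- s * (2 * n_star + s + 1)
  F_p <- (2 * n_star + s + 1) / (2 * m + s + 1) * pillai / (s - pillai)
  p_p <- pf(F_p, p_df1, p_df2, lower.tail = FALSE)

  # Hotelling-Lawley trace F (Pillai-Samson form)
  h_df1 <- s * (2 * m + s + 1)
  h_df2 <- 2 * (s * n_star + 1)
  F_h <- h_df2 * hl / (s * h_df1)
  p_h <- pf(F_h, h_df1, h_df2, lower.tail = FALSE)

  # Roy's greatest root: upper-bound F
  d <- max(p, q_h)
  r_df1 <- d
  r_df2 <- df_e - d + q_h
  F_r <- roy * r_df2 / r_df1
  p_r <- pf(F_r, r_df1, r_df2, lower.tail = FALSE)

  tibble::tibble(
    statistic = c("Wilks' lambda", "Pillai's trace", "Hotelling-Lawley trace",
                  "Roy's greatest root"),
    value = c(wilks, pillai, hl, roy),
    F = c(F_w, F_p, F_h, F_r),
    num_df = c(w_df1, p_df1, h_df1, r_df1),
    den_df = c(w_df2, p_df2, h_df2, r_df2),
    p = c(p_w, p_p, p_h, p_r),
    note = c("", "", "", "upper bound")
  )
}

#' Multivariate analysis of variance for a multi-response regression
#'
#' Fits the multivariate linear model `Y ~ X` (continuous predictors plus
#' intercept) and, for each term, forms the hypothesis SSCP from the
#' coefficient contrast and the residual SSCP, takes the eigenvalues of
#' `solve(E) %*% H`, and reports Wilks' lambda, Pillai's trace, the
#' Hotelling-Lawley trace and Roy's greatest root with their F
#' approximations (Rao, Pillai, Pillai-Samson; Roy as an upper bound). For a
#' one-degree-of-freedom term all four statistics carry the same exact F.
#'
#' @param X Data frame of predictors.
#' @param Y Data frame or matrix of responses.
#' @param include_overall Also test all predictor slopes jointly (the
#'   omnibus regression term, hypothesis df = number of predictors); for a
#'   single response its Wilks' lambda equals `1 - R^2` of the OLS fit.
#'
#' @return A `manova_result` tibble with one row per term and statistic.
#' @export
manova_battery <- function(X, Y, include_overall = FALSE) {
  X <- as.data.frame(X); Y <- as.matrix(Y)
  if (ncol(X) < 1 || ncol(Y) < 1) {
    abort("MANOVA needs at least one predictor and one response.",
          class = "pdgait_precondition_error")
  }
  ok <- complete.cases(X) & complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y); k <- ncol(X)
  if (n <= p + k) {
    abort("MANOVA requires n > predictors + responses.",
          class = "pdgait_precondition_error")
  }
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  XtX <- crossprod(M)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    abort("Design matrix is singular.", class = "pdgait_rank_error")
  })
  B <- XtX_inv %*% crossprod(M, Y)
  E <- crossprod(Y - M %*% B)
  df_e <- n - ncol(M)
  E_inv <- tryCatch(solve(E), error = function(e) {
    abort("Error SSCP matrix is singular.", class = "pdgait_rank_error")
  })
  term_stats <- function(L, label) {
    q_h <- nrow(L)
    LB <- L %*% B
    H <- t(LB) %*% solve(L %*% XtX_inv %*% t(L)) %*% LB
    lambda <- Re(eigen(E_inv %*% H, only.values = TRUE)$values)
    lambda <- pmax(sort(lambda, decreasing = TRUE)[seq_len(min(p, q_h))], 0)
    dplyr::mutate(multivariate_stats(lambda, p, q_h, df_e),
                  term = label, .before = 1)
  }
  out <- purrr::map_dfr(seq_len(ncol(M)), function(j) {
    L <- matrix(0, 1, ncol(M)); L[1, j] <- 1
    term_stats(L, colnames(M)[j])
  })
  if (include_overall && k >= 1) {
    L <- cbind(matrix(0, k, 1), diag(k))
    out <- dplyr::bind_rows(out, term_stats(L, "overall"))
  }
  attr(out, "n") <- n
  attr(out, "df_error") <- df_e
  class(out) <- c("manova_result", class(out))
  out
}
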