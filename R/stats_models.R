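#' Pearson correlation with t and permutation tests
#'
#' Product-moment correlation between two site-level variables, with the
#' two-sided t test on `n - 2` degrees of freedom and, optionally, a
#' permutation test obtained by shuffling `y` a fixed number of times under
#' a reproducible seed. The permutation p-value uses the add-one estimator
#' `(1 + #{|r*| >= |r|}) / (n_perm + 1)`.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite, non-constant.
#' @param n_perm number of permutations; 0 (default) skips the permutation
#'   test.
#' @param seed integer seed for the permutation shuffles.
#' @return object of class `nis_cor`: list with elements `r`, `n`, `df`,
#'   `t`, `p`, `p_perm`, `n_perm`.
#' @examples
#' d <- packaged_table1()
#' pearson_cor(d$aquaculture, d$nis_prop)
#' @export
pearson_cor <- function(x, y, n_perm = 0, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in correlation input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else Inf * sign(r)
  p <- 2 * stats::pt(-abs(t_stat), df)
  p_perm <- NA_real_
  if (n_perm > 0) {
    r_obs <- abs(r)
    hits <- with_local_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(x, sample(y))) >= r_obs - 1e-12
      }, logical(1)))
    })
    p_perm <- (1 + hits) / (n_perm + 1)
  }
  structure(list(r = r, n = n, df = df, t = t_stat, p = p,
                 p_perm = p_perm, n_perm = n_perm),
            class = "nis_cor")
}

#' @export
print.nis_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (df = %d), t = %.3f, p = %s\n",
              x$r, x$df, x$t, fmt_p(x$p)))
  if (!is.na(x$p_perm)) {
    cat(sprintf("  permutation p = %s (%d shuffles)\n",
                fmt_p(x$p_perm), x$n_perm))
  }
  invisible(x)
}

#' Bonferroni threshold and significance flags
#'
#' Family-wise correction for `m` simultaneous tests at level `alpha`:
#' the per-test threshold is `alpha / m` and a p-value is flagged
#' significant when it falls below that threshold.
#'
#' @param p numeric vector of p-values.
#' @param m family size (number of tests); must be >= 1.
#' @param alpha family-wise level (default 0.05).
#' @return list with `threshold` and logical vector `significant`.
#' @examples
#' bonferroni(c(0.0019, 0.03), m = 12)   # threshold 0.00417: TRUE FALSE
#' @export
bonferroni <- function(p, m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  thr <- alpha / m
  list(threshold = thr, significant = !is.na(p) & p < thr)
}

#' Screen a response against a family of covariates
#'
#' Pairwise Pearson correlations of one response column against each
#' covariate, with Bonferroni correction over the declared family (by
#' default the number of covariates screened) and optional permutation
#' p-values.
#'
#' @param data a [study_dataset()] or data frame.
#' @param response response column name.
#' @param variables covariate column names.
#' @param n_perm,seed passed to [pearson_cor()].
#' @param alpha family-wise level for the Bonferroni flag.
#' @param m family size for the correction; defaults to
#'   `length(variables)`.
#' @return data frame of class `nis_screen` with one row per covariate:
#'   `variable`, `r`, `df`, `t`, `p`, `p_perm`, `significant` (Bonferroni
#'   flag); the Bonferroni threshold is attached as attribute
#'   `"threshold"`.
#' @export
correlation_screen <- function(data, response, variables,
                               n_perm = 0, seed = 1L, alpha = 0.05,
                               m = length(variables)) {
  stopifnot(response %in% names(data), all(variables %in% names(data)))
  res <- lapply(seq_along(variables), function(i) {
    ct <- pearson_cor(data[[variables[i]]], data[[response]],
                      n_perm = n_perm, seed = seed + i)
    data.frame(variable = variables[i], r = ct$r, df = ct$df, t = ct$t,
               p = ct$p, p_perm = ct$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  bf <- bonferroni(out$p, m = m, alpha = alpha)
  out$significant <- bf$significant
  attr(out, "threshold") <- bf$threshold
  class(out) <- c("nis_screen", "data.frame")
  out
}

#' @export
print.nis_screen <- function(x, ...) {
  cat(sprintf("Correlation screen (Bonferroni threshold %.4g):\n",
              attr(x, "threshold")))
  df <- as.data.frame(x)
  df$r <- round(df$r, 4); df$t <- round(df$t, 3)
  df$p <- fmt_p(df$p); df$p_perm <- fmt_p(df$p_perm)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Multiple linear regression with an overall ANOVA F test
#'
#' Least-squares fit of a response on several site covariates, reporting
#' per-coefficient t tests and the overall ANOVA-type significance test
#' `F = (SSR / k) / (SSE / (n - k - 1))` with `k` predictors and `n` sites,
#' plus the multiple correlation R, R-squared and adjusted R-squared.
#'
#' @param data a [study_dataset()] or data frame.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @return object of class `nis_mlr`: list with `coefficients` (matrix with
#'   estimate/SE/t/p rows per term), `R`, `R2`, `R2_adj`, `F`, `df1`, `df2`,
#'   `p_overall`, `n`, `k`, `perfect_fit` flag, and the underlying `lm` fit
#'   in `$fit`.
#' @seealso [coef.nis_mlr()], [predict.nis_mlr()], [residuals.nis_mlr()]
#' @examples
#' d <- packaged_table1()
#' m <- fit_mlr(d, "nis_prop", c("status_local", "aquaculture"))
#' coef(m)
#' @export
fit_mlr <- function(data, response, predictors) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)),
            length(predictors) >= 1L)
  df <- as.data.frame(data)[, c(response, predictors)]
  n <- nrow(df)
  k <- length(predictors)
  if (n <= k + 1L) {
    stop(sprintf("need n > k + 1 sites (n = %d, k = %d)", n, k),
         call. = FALSE)
  }
  X <- stats::model.matrix(stats::reformulate(predictors), df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(predictors, response), data = df)
  y <- df[[response]]
  sse <- sum(stats::resid(fit)^2)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  df2 <- n - k - 1L
  perfect <- sse < 1e-12 * max(1, ssr)
  f_stat <- if (perfect) Inf else (ssr / k) / (sse / df2)
  r2 <- ssr / (ssr + sse)
  structure(list(
    coefficients = summary(fit)$coefficients,
    R = sqrt(r2), R2 = r2,
    R2_adj = 1 - (1 - r2) * (n - 1) / df2,
    F = f_stat, df1 = k, df2 = df2,
    p_overall = if (perfect) 0 else stats::pf(f_stat, k, df2, lower.tail = FALSE),
    n = n, k = k, perfect_fit = perfect,
    response = response, predictors = predictors, fit = fit
  ), class = "nis_mlr")
}

#' @export
coef.nis_mlr <- function(object, ...) stats::coef(object$fit)

#' @export
predict.nis_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$fit)
  else stats::predict(object$fit, newdata = as.data.frame(newdata), ...)
}

#' @export
residuals.nis_mlr <- function(object, ...) stats::resid(object$fit)

#' @export
print.nis_mlr <- function(x, ...) {
  cat(sprintf("Multiple linear regression: %s ~ %d predictors (n = %d)\n",
              x$response, x$k, x$n))
  cat(sprintf("  multiple R = %.3f, R2 = %.3f, adj R2 = %.3f\n",
              x$R, x$R2, x$R2_adj))
  cat(sprintf("  overall F = %.3f on (%d, %d) df, p = %s%s\n",
              x$F, x$df1, x$df2, fmt_p(x$p_overall),
              if (x$perfect_fit) "  [perfect fit: SSE = 0]" else ""))
  invisible(x)
}

#' @export
summary.nis_mlr <- function(object, ...) {
  print(object)
  stats::printCoefmat(object$coefficients, signif.stars = FALSE)
  invisible(object)
}

#' Bivariate normal-family GLM with deviance G test
#'
#' Fits `y ~ x` as a generalized linear model with a normal (Gaussian)
#' error distribution and either the identity link (equivalent to ordinary
#' least squares) or the log link (fitting a logarithmic mean curve). The
#' slope test is the likelihood-ratio G statistic against the
#' intercept-only model, `G = 2 (l_full - l_null)` on the profiled normal
#' log-likelihood, referred to a chi-square with 1 df. The dispersion is
#' reported as `phi = deviance / (n - 2)`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param link `"identity"` (default) or `"log"`. The log link requires a
#'   positive response mean.
#' @return object of class `nis_glm`: list with `link`, `slope`,
#'   `intercept`, `phi`, `G`, `p_slope`, `r2` (squared correlation of the
#'   identity fit, `NA` for log link), `n`, and the underlying `glm` fit.
#' @examples
#' d <- packaged_table1()
#' fit_glm_normal(d$aquaculture, d$nis_prop)
#' @export
fit_glm_normal <- function(x, y, link = c("identity", "log")) {
  link <- match.arg(link)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in GLM input", call. = FALSE)
  }
  n <- length(y)
  fam <- stats::gaussian(link = link)
  dat <- data.frame(x = x, y = y)
  if (link == "log") {
    if (mean(y) <= 0) stop("log link needs a positive response mean",
                           call. = FALSE)
    # keep IRLS fitted means strictly positive from the first step
    mustart <- pmax(y, 0.05 * mean(y[y > 0]))
    fit <- stats::glm(y ~ x, family = fam, data = dat, mustart = mustart,
                      control = stats::glm.control(maxit = 100))
    null_fit <- stats::glm(y ~ 1, family = fam, data = dat,
                           mustart = rep(mean(y), n))
  } else {
    fit <- stats::glm(y ~ x, family = fam, data = dat)
    null_fit <- stats::glm(y ~ 1, family = fam, data = dat)
  }
  if (!fit$converged) {
    stop(sprintf("GLM IRLS did not converge in %d iterations (link %s)",
                 fit$iter, link), call. = FALSE)
  }
  G <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                     as.numeric(stats::logLik(null_fit))))
  structure(list(
    link = link,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    phi = stats::deviance(fit) / (n - 2),
    G = G,
    p_slope = stats::pchisq(G, df = 1, lower.tail = FALSE),
    r2 = if (link == "identity") stats::cor(x, y)^2 else NA_real_,
    n = n, fit = fit
  ), class = "nis_glm")
}

#' @export
print.nis_glm <- function(x, ...) {
  cat(sprintf("Normal-family GLM (%s link), n = %d\n", x$link, x$n))
  cat(sprintf("  slope = %.4f, intercept = %.4f, phi = %.4f\n",
              x$slope, x$intercept, x$phi))
  cat(sprintf("  G = %.3f, p(slope = 0) = %s\n", x$G, fmt_p(x$p_slope)))
  invisible(x)
}

#' @export
coef.nis_glm <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.nis_glm <- function(object, ...) stats::resid(object$fit, ...)

#' Durbin-Watson autocorrelation test with permutation p-value
#'
#' Lag-1 autocorrelation statistic of an ordered residual sequence,
#' `DW = sum (e_t - e_{t-1})^2 / sum e_t^2`, bounded in [0, 4] with
#' expectation about 2 under exchangeability. The p-value is obtained by
#' permuting the residual order under a fixed seed (two-sided: departures
#' toward 0 or 4 both count against exchangeability).
#'
#' @param residuals numeric vector in a meaningful order (dataset row
#'   order).
#' @param n_perm number of order permutations (default 9999).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`.
#' @export
durbin_watson <- function(residuals, n_perm = 9999, seed = 1L) {
  stopifnot(length(residuals) >= 3)
  ss <- sum(residuals^2)
  if (ss == 0) stop("zero residual variance", call. = FALSE)
  dw <- function(e) sum(diff(e)^2) / sum(e^2)
  stat <- dw(residuals)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) dw(sample(residuals)), numeric(1))
    })
    p_lo <- (1 + sum(perm <= stat + 1e-12)) / (n_perm + 1)
    p_hi <- (1 + sum(perm >= stat - 1e-12)) / (n_perm + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  list(statistic = stat, p = p, n_perm = n_perm)
}

#' Breusch-Pagan homoskedasticity test
#'
#' Lagrange-multiplier test regressing squared residuals on the model
#' covariates: the statistic is `n` times the R-squared of that auxiliary
#' regression, referred to a chi-square with as many degrees of freedom as
#' covariates.
#'
#' @param x covariates of the original fit: a numeric vector, matrix or
#'   data frame (without intercept column).
#' @param residuals residuals of the original fit.
#' @return list with `statistic`, `df`, `p`.
#' @export
breusch_pagan <- function(x, residuals) {
  X <- as.matrix(x)
  stopifnot(nrow(X) == length(residuals))
  e2 <- residuals^2
  if (stats::var(e2) == 0) {
    return(list(statistic = 0, df = ncol(X), p = 1))
  }
  aux <- stats::lm.fit(cbind(1, X), e2)
  ssr <- sum((aux$fitted.values - mean(e2))^2)
  sst <- sum((e2 - mean(e2))^2)
  stat <- nrow(X) * ssr / sst
  list(statistic = stat, df = ncol(X),
       p = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE))
}
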