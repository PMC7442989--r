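#' @title Association of carrier status with Lp(a) and meta-analysis
#' @description
#' Lp(a) concentrations are strongly right-skewed, so effect estimates
#' (beta, SE, CI) are reported on the original mg/dL scale while
#' p-values and variance explained come from the same design refit on
#' rank-based inverse-normal transformed Lp(a). Per-study estimates are
#' pooled by fixed-effect inverse-variance meta-analysis with Cochran's
#' Q and I-squared heterogeneity.
#' @name association
NULL

#' Rank-based inverse-normal transformation
#'
#' `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with average ranks for ties
#' (Blom offset). Strictly monotone on tie-free data.
#'
#' @param values numeric vector (at least 2 finite values, not all equal).
#' @return transformed vector, `NA` preserved.
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("need at least 2 finite values")
  if (length(unique(values[ok])) < 2L)
    stop("inverse-normal transform undefined: all values identical")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Covariate-adjusted linear regression on two scales
#'
#' Ordinary least squares of the outcome on the term of interest plus
#' covariates. `beta`, `se` and the 95% CI come from the original-scale
#' fit; `p` from the identical design refit on the inverse-normal
#' transformed outcome; `partial_r2` is the R-squared difference between
#' the transformed-scale model with and without the term.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome outcome column name (e.g. `"lpa"`).
#' @param term column name of the term of interest (numeric or 0/1).
#' @param covariates character vector of adjustment column names.
#' @return list of class `regression_result`: `term`, `beta`, `se`,
#'   `ci95`, `p`, `partial_r2`, `n`.
#' @export
fit_linear <- function(data, outcome, term, covariates = c("age", "sex")) {
  cols <- c(outcome, term, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  rhs <- paste(c(term, covariates), collapse = " + ")
  f_full <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::lm(f_full, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  d$.y_int <- inverse_normal_transform(d[[outcome]])
  fit_int <- stats::lm(stats::as.formula(paste(".y_int ~", rhs)), data = d)
  p <- summary(fit_int)$coefficients[term, "Pr(>|t|)"]
  red <- if (length(covariates))
    stats::lm(stats::as.formula(
      paste(".y_int ~", paste(covariates, collapse = " + "))), data = d)
  else stats::lm(.y_int ~ 1, data = d)
  partial_r2 <- summary(fit_int)$r.squared - summary(red)$r.squared
  structure(list(term = term, beta = unname(beta), se = unname(se),
                 ci95 = unname(beta + c(-1, 1) * 1.959964 * se),
                 p = unname(p), partial_r2 = partial_r2, n = nrow(d)),
            class = "regression_result")
}

#' Reciprocal adjustment of two correlated null variants
#'
#' Fits the carrier-status effect of each variant adjusted for the other
#' (plus covariates), and optionally the second variant's effect within
#' samples negative for the first — the design that shows whether a
#' nested variant carries information beyond its haplotype background.
#'
#' @param data data.frame with both carrier indicators (0/1 columns) and
#'   covariates.
#' @param outcome outcome column name.
#' @param term_a,term_b the two carrier-indicator column names.
#' @param covariates adjustment columns.
#' @param subset_negative_a also fit `term_b` restricted to
#'   `term_a == 0` samples.
#' @return list: `a_adjusted_for_b`, `b_adjusted_for_a`
#'   (`regression_result`s), and optionally `b_in_a_negative`.
#' @export
reciprocal_adjustment <- function(data, outcome, term_a, term_b,
                                  covariates = c("age", "sex"),
                                  subset_negative_a = TRUE) {
  if (all(data[[term_a]] == data[[term_b]], na.rm = TRUE))
    stop("rank-deficient design; collinear terms: ", term_a, ", ", term_b)
  out <- list(
    a_adjusted_for_b = fit_linear(data, outcome, term_a,
                                  c(term_b, covariates)),
    b_adjusted_for_a = fit_linear(data, outcome, term_b,
                                  c(term_a, covariates)))
  if (subset_negative_a)
    out$b_in_a_negative <- fit_linear(data[data[[term_a]] == 0, ,
                                           drop = FALSE],
                                      outcome, term_b, covariates)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null by enumeration when the smaller group has at most
#' `exact_max` observations and there are no cross-group ties; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max largest small-group size for the exact path.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 10L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(length(a), length(b)) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights `w_i = 1 / se_i^2`; pooled `beta = sum(w_i b_i) / sum(w_i)`,
#' `se = sqrt(1 / sum(w_i))`, 95% CI `beta +- 1.959964 se`, two-sided z
#' p-value; heterogeneity `Q = sum(w_i (b_i - beta)^2)` on `k - 1`
#' degrees of freedom and `I2 = 100 * max(0, (Q - df) / Q)`.
#'
#' @param beta per-study effect estimates.
#' @param se per-study standard errors (all positive).
#' @param labels optional study labels.
#' @return list of class `meta_result`: `beta`, `se`, `ci95`, `z`, `p`,
#'   `Q`, `df`, `I2`, `k`, `weights`, `studies`.
#' @export
fixed_effect_meta <- function(beta, se, labels = NULL) {
  k <- length(beta)
  if (k < 1L) stop("need at least one study")
  if (length(se) != k) stop("'beta' and 'se' lengths differ")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  Q <- sum(w * (beta - b)^2)
  df <- k - 1L
  I2 <- if (Q > 0) 100 * max(0, (Q - df) / Q) else 0
  z <- b / s
  structure(list(beta = b, se = s, ci95 = b + c(-1, 1) * 1.959964 * s,
                 z = z, p = 2 * pnorm(-abs(z)), Q = Q, df = df, I2 = I2,
                 k = k, weights = w,
                 studies = labels %||% paste0("study", seq_len(k))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis (%d studies)\n  beta = %.2f mg/dL [%.2f; %.2f], SE = %.2f\n  z = %.2f, p = %.3g\n  Q = %.3f (df = %d), I2 = %.1f%%\n",
    x$k, x$beta, x$ci95[1], x$ci95[2], x$se, x$z, x$p, x$Q, x$df, x$I2))
  invisible(x)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "Linear regression, term '%s' (n = %d)\n  beta = %.2f mg/dL [%.2f; %.2f], SE = %.2f\n  p (inverse-normal scale) = %.3g, partial R2 = %.4f\n",
    x$term, x$n, x$beta, x$ci95[1], x$ci95[2], x$se, x$p, x$partial_r2))
  invisible(x)
}
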