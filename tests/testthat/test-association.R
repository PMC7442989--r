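test_that("inverse-normal transform matches the Blom closed form and is monotone", {
  z <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(z, qnorm((1:3 - 3 / 8) / 3.25))
  expect_equal(z[2], 0)
  expect_equal(z[1], -z[3])
  set.seed(3)
  x <- rlnorm(101)
  zx <- inverse_normal_transform(x)
  expect_equal(order(zx), order(x))
  expect_equal(zx[order(x)][51], 0)  # odd n: middle value maps to 0
  # ties share the average-rank value
  zt <- inverse_normal_transform(c(5, 5, 1, 9))
  expect_equal(zt[1], zt[2])
  expect_error(inverse_normal_transform(rep(2, 5)), "identical")
  expect_error(inverse_normal_transform(3), "at least 2")
})

test_that("linear fit matches the normal-equations oracle and exact relations", {
  d <- data.frame(y = c(2, 4, 5, 8, 9, 13),
                  x = c(1, 2, 3, 4, 5, 6),
                  z = c(0, 1, 0, 1, 0, 1))
  fit <- fit_linear(d, "y", "x", covariates = "z")
  or <- ols_oracle(d$y, cbind(1, d$x, d$z))
  expect_equal(fit$beta, or$beta[2], tolerance = 1e-10)
  expect_equal(fit$se, or$se[2], tolerance = 1e-10)
  expect_equal(fit$ci95, fit$beta + c(-1, 1) * 1.959964 * fit$se)
  # exact linear outcome: beta exact, zero residual
  d2 <- data.frame(y = 3 + 2 * (1:8), x = 1:8, z = rep(0:1, 4))
  fit2 <- suppressWarnings(fit_linear(d2, "y", "x", covariates = "z"))
  expect_equal(fit2$beta, 2, tolerance = 1e-10)
  expect_equal(fit2$se, 0, tolerance = 1e-8)
  # collinear design errors with the offending column named
  d3 <- data.frame(y = rnorm(10), a = rep(0:1, 5), b = rep(0:1, 5))
  expect_error(fit_linear(d3, "y", "a", covariates = "b"), "collinear")
  expect_error(fit_linear(d3, "y", "missing_col"), "not found")
})

test_that("a planted carrier effect is recovered within its own 95% CI", {
  set.seed(1204)
  n <- 5000
  carrier <- rbinom(n, 1, 0.016)
  age <- rnorm(n, 60, 10)
  sex <- rbinom(n, 1, 0.5)
  lpa <- pmax(rlnorm(n, log(11), 1.0) + 14 - 12 * carrier +
                0.05 * (age - 60) + sex, 0.1)
  d <- data.frame(lpa = lpa, carrier = carrier, age = age, sex = sex)
  fit <- fit_linear(d, "lpa", "carrier")
  expect_gt(-12, fit$ci95[1])
  expect_lt(-12, fit$ci95[2])
  expect_lt(fit$p, 0.05)
  expect_gt(fit$partial_r2, 0)
})

test_that("reciprocal adjustment separates a nested variant from its causal background", {
  set.seed(88)
  n <- 6000
  rs <- rbinom(n, 1, 0.05)                    # causal splice-null carrier
  r21x <- ifelse(rs == 1, rbinom(n, 1, 0.3), 0)  # strictly nested subset
  age <- rnorm(n, 55, 8); sex <- rbinom(n, 1, 0.5)
  lpa <- pmax(rlnorm(n, log(10), 0.9) + 13 - 12 * rs, 0.1)
  d <- data.frame(lpa = lpa, r21x = r21x, rs = rs, age = age, sex = sex)
  rec <- reciprocal_adjustment(d, "lpa", "r21x", "rs")
  # nested variant carries no signal beyond its background
  expect_gt(rec$a_adjusted_for_b$ci95[2], 0)
  expect_lt(rec$a_adjusted_for_b$ci95[1], 0)
  # the background variant survives adjustment, and within negatives
  expect_lt(rec$b_adjusted_for_a$ci95[2], 0)
  expect_lt(rec$b_in_a_negative$ci95[2], 0)
  expect_lt(abs(rec$b_adjusted_for_a$beta + 12), 4)
  # independent planted effects both survive adjustment
  v1 <- rbinom(n, 1, 0.05); v2 <- rbinom(n, 1, 0.05)
  lpa2 <- pmax(rlnorm(n, log(10), 0.9) + 13 - 10 * v1 - 10 * v2, 0.1)
  d2 <- data.frame(lpa = lpa2, v1 = v1, v2 = v2, age = age, sex = sex)
  rec2 <- reciprocal_adjustment(d2, "lpa", "v1", "v2",
                                subset_negative_a = FALSE)
  expect_lt(rec2$a_adjusted_for_b$ci95[2], 0)
  expect_lt(rec2$b_adjusted_for_a$ci95[2], 0)
  # identical carrier sets are collinear
  d3 <- data.frame(lpa = lpa, u = r21x, w = r21x, age = age, sex = sex)
  expect_error(reciprocal_adjustment(d3, "lpa", "u", "w"), "collinear")
})

test_that("Wilcoxon rank-sum: exact enumeration and approximation agree", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # large-sample path tracks the exact path on tie-free data
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    p_exact <- wilcoxon_rank_sum(a, b, exact_max = 10)
    p_approx <- wilcoxon_rank_sum(a, b, exact_max = 0)
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("fixed-effect meta matches formulas, invariances and metafor", {
  one <- fixed_effect_meta(-5, 2)
  expect_equal(one$beta, -5)
  expect_equal(one$se, 2)
  expect_equal(one$Q, 0)
  expect_equal(one$I2, 0)
  eq <- fixed_effect_meta(c(-10, -6), c(2, 2))
  expect_equal(eq$beta, -8)
  m <- fixed_effect_meta(c(-13.0, -12.6, -9.9), c(3.6, 3.5, 3.1))
  w <- 1 / c(3.6, 3.5, 3.1)^2
  expect_equal(m$beta, sum(w * c(-13.0, -12.6, -9.9)) / sum(w))
  expect_equal(m$se, sqrt(1 / sum(w)))
  expect_true(m$beta >= min(-13, -12.6, -9.9) && m$beta <= -9.9)
  expect_lte(m$se, min(c(3.6, 3.5, 3.1)))
  # I2 invariant under common rescaling
  m2 <- fixed_effect_meta(10 * c(-13.0, -12.6, -9.9),
                          10 * c(3.6, 3.5, 3.1))
  expect_equal(m2$I2, m$I2)
  expect_equal(m2$beta, 10 * m$beta)
  # independent implementation as cross-check
  rma <- metafor::rma(yi = c(-13.0, -12.6, -9.9),
                      sei = c(3.6, 3.5, 3.1), method = "FE")
  expect_equal(m$beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
  expect_equal(m$p, rma$pval, tolerance = 1e-10)
  expect_equal(m$Q, rma$QE, tolerance = 1e-10)
  expect_equal(m$I2, rma$I2, tolerance = 1e-6)
  expect_error(fixed_effect_meta(numeric(0), numeric(0)), "at least one")
  expect_error(fixed_effect_meta(c(1, 2), c(1, 0)), "positive")
})

test_that("pooled 95% CI covers a common true effect at nominal rate", {
  set.seed(515)
  true <- -11
  ses <- c(3.6, 3.5, 3.1)
  cover <- 0
  for (i in 1:200) {
    betas <- rnorm(3, true, ses)
    m <- fixed_effect_meta(betas, ses)
    if (m$ci95[1] <= true && true <= m$ci95[2]) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.93)
  expect_lte(cover / 200, 0.97)
})
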