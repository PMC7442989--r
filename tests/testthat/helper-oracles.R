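# Independent brute-force oracles used across the suite.

# Exact two-sided Fisher p for a 2x3 table by full enumeration over tables
# with both margins fixed (multivariate hypergeometric). Tables whose
# probability is <= the observed one (relative tolerance 1e-7 for exact
# ties) are summed.
fisher_2x3_enum <- function(tab) {
  stopifnot(dim(tab) == c(2, 3))
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  cs <- colSums(tab)
  pr <- function(a) exp(sum(lchoose(cs, a)) - lchoose(n, r1))
  pobs <- pr(tab[1, ])
  tot <- 0
  for (a1 in 0:min(r1, cs[1])) for (a2 in 0:min(r1 - a1, cs[2])) {
    a3 <- r1 - a1 - a2
    if (a3 < 0 || a3 > cs[3]) next
    p <- pr(c(a1, a2, a3))
    if (p <= pobs * (1 + 1e-7)) tot <- tot + p
  }
  tot
}

# Direct haplotype counting for two-locus tables WITHOUT double
# heterozygotes (carrier with rs genotype 1): every individual's phase is
# then unambiguous, so ML haplotype frequencies are plain counts / 2n.
count_haplotypes_direct <- function(g) {
  ok <- !is.na(g$rs_genotype) & !is.na(g$r21x_status)
  a <- as.integer(g$r21x_status[ok] == "+")
  b <- g$rs_genotype[ok]
  stopifnot(!any(a == 1L & b == 1L))
  h <- c(p11 = 0, p10 = 0, p01 = 0, p00 = 0)
  for (i in seq_along(a)) {
    add <- if (a[i] == 0 && b[i] == 0) c(0, 0, 0, 2)
      else if (a[i] == 0 && b[i] == 1) c(0, 0, 1, 1)
      else if (a[i] == 0 && b[i] == 2) c(0, 0, 2, 0)
      else if (a[i] == 1 && b[i] == 0) c(0, 1, 0, 1)
      else c(1, 0, 1, 0)  # carrier, rs hom: haplotypes 11 + 01
    h <- h + add
  }
  h / (2 * length(a))
}

# OLS via the normal equations, with classical SEs.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# Observed-data log-likelihood of a 2x3 genotype table under HWE given
# haplotype frequencies (independent of the package's internal version).
hap_loglik_oracle <- function(p, g) {
  ok <- !is.na(g$rs_genotype) & !is.na(g$r21x_status)
  a <- as.integer(g$r21x_status[ok] == "+")
  b <- g$rs_genotype[ok]
  gp <- function(ai, bi) {
    if (ai == 0 && bi == 0) p[4]^2
    else if (ai == 0 && bi == 1) 2 * p[3] * p[4]
    else if (ai == 0 && bi == 2) p[3]^2
    else if (ai == 1 && bi == 0) 2 * p[2] * p[4]
    else if (ai == 1 && bi == 1) 2 * (p[1] * p[4] + p[2] * p[3])
    else 2 * p[1] * p[3]
  }
  sum(log(mapply(gp, a, b)))
}

# Random genotype table from cell probabilities over the 2x3 grid.
random_genotype_table <- function(n, probs) {
  cells <- expand.grid(a = 0:1, b = 0:2)
  idx <- sample(nrow(cells), n, replace = TRUE, prob = probs)
  data.frame(sample = sprintf("S%03d", seq_len(n)),
             population = "SIM",
             rs_genotype = cells$b[idx],
             r21x_status = ifelse(cells$a[idx] == 1, "+", "-"),
             stringsAsFactors = FALSE)
}

# A Ct plate with exact per-side component moments, for checking the
# quantile arithmetic of the two-component fit.
exact_moment_plate <- function(n_lo, mu_lo, sd_lo, n_hi, mu_hi, sd_hi,
                               seed = 1) {
  set.seed(seed)
  std <- function(n, mu, s) {
    x <- rnorm(n)
    (x - mean(x)) / sd(x) * s + mu
  }
  c(std(n_lo, mu_lo, sd_lo), std(n_hi, mu_hi, sd_hi))
}
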