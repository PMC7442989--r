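test_that("carrier frequency and HWE allele-frequency conversion match cohort counts", {
  expect_equal(carrier_frequency(74, 4771), 74 / 4771)
  expect_equal(round(100 * carrier_frequency(74, 4771), 1), 1.6)
  expect_equal(round(100 * carrier_frequency(63, 3040), 1), 2.1)
  expect_equal(carrier_frequency(0, 100), 0)
  expect_error(carrier_frequency(1, 0), "positive")
  expect_equal(round(100 * maf_from_carrier_freq(74 / 4771), 2), 0.78)
  expect_equal(maf_from_carrier_freq(0), 0)
  expect_error(maf_from_carrier_freq(1), "\\[0, 1\\)")
  # algebraic inverse on a grid
  c_grid <- seq(0.001, 0.99, by = 0.007)
  expect_equal(carrier_freq_from_maf(maf_from_carrier_freq(c_grid)),
               c_grid, tolerance = 1e-12)
})

test_that("EM equals direct haplotype counting when no double heterozygotes exist", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    # zero mass on the (carrier, rs het) cell -> every phase is known
    probs <- runif(6, 0.05, 1)
    probs[4] <- 0  # cell order (0,0),(1,0),(0,1),(1,1),(0,2),(1,2)
    g <- random_genotype_table(n, probs)
    if (all(g$r21x_status == "+") || all(g$r21x_status == "-")) next
    h <- em_haplotype_freqs(g)
    expect_equal(unname(h$p), unname(count_haplotypes_direct(g)),
                 tolerance = 1e-6)
  }
})

test_that("EM handles corner tables and recovers generating frequencies at large n", {
  g0 <- data.frame(sample = c("a", "b"), population = "X",
                   rs_genotype = c(0L, 0L), r21x_status = c("-", "-"))
  h0 <- em_haplotype_freqs(g0)
  expect_equal(unname(h0$p), c(0, 0, 0, 1))
  expect_true(h0$monomorphic)
  p_true <- c(0.012, 0.0001, 0.014, 0.9739)
  g <- simulate_two_locus_genotypes(two_locus_params(
    p_true[1], p_true[2], p_true[3], p_true[4], 20000, seed = 23))
  h <- em_haplotype_freqs(g)
  se <- sqrt(p_true * (1 - p_true) / (2 * 20000))
  expect_true(all(abs(h$p - p_true) <= 3 * pmax(se, 1e-4)))
})

test_that("EM ascends the observed-data log-likelihood on random tables", {
  set.seed(17)
  for (i in 1:20) {
    g <- random_genotype_table(sample(20:80, 1), runif(6, 0.05, 1))
    if (all(g$r21x_status == "+") || all(g$r21x_status == "-") ||
        length(unique(g$rs_genotype)) == 1L) next
    h <- em_haplotype_freqs(g)
    expect_true(all(diff(h$loglik) >= -1e-9))
    # final loglik matches the independent oracle at the fitted point
    expect_equal(h$loglik[length(h$loglik)], hap_loglik_oracle(h$p, g),
                 tolerance = 1e-8)
  }
})

test_that("LD statistics match the defining formulas and bounds", {
  ld1 <- ld_stats(c(0.1, 0, 0, 0.9))
  expect_equal(ld1$Dprime, 1)
  expect_equal(ld1$R2, 1)
  pA <- 0.3; pB <- 0.2
  ld0 <- ld_stats(c(pA * pB, pA * (1 - pB), (1 - pA) * pB,
                    (1 - pA) * (1 - pB)))
  expect_equal(ld0$D, 0)
  expect_equal(ld0$R2, 0)
  # hand evaluation of a cohort-like table
  p <- c(0.008, 0.0002, 0.018, 0.9738)
  ld <- ld_stats(p)
  pA <- 0.0082; pB <- 0.026
  D <- 0.008 - pA * pB
  expect_equal(ld$D, D)
  expect_equal(ld$Dprime, D / min(pA * (1 - pB), (1 - pA) * pB))
  expect_equal(ld$R2, D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  expect_lte(ld$R2, ld$Dprime^2)
  expect_error(ld_stats(c(0, 0, 0.3, 0.7)), "monomorphic")
})

test_that("R2 <= Dprime^2 and |Dprime| <= 1 over random haplotype draws", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 1000) {
    p <- rexp(4); p <- p / sum(p)
    pA <- p[1] + p[2]; pB <- p[1] + p[3]
    if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) next
    ld <- ld_stats(p)
    expect_lte(abs(ld$Dprime), 1 + 1e-12)
    expect_gte(ld$R2, -1e-12)
    expect_lte(ld$R2, ld$Dprime^2 + 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("LD relabelling invariance: swapping the minor allele flips D only", {
  set.seed(7)
  for (i in 1:50) {
    p <- rexp(4); p <- p / sum(p)
    ld <- ld_stats(p)
    # relabel locus B alleles: swap columns (p11<->p10, p01<->p00)
    ld_swap <- ld_stats(p[c(2, 1, 4, 3)])
    expect_equal(abs(ld_swap$Dprime), abs(ld$Dprime), tolerance = 1e-9)
    expect_equal(ld_swap$R2, ld$R2, tolerance = 1e-9)
    expect_equal(ld_swap$D, -ld$D, tolerance = 1e-9)
  }
})

test_that("per-population LD reports NA for groups without carriers", {
  g1 <- simulate_two_locus_genotypes(two_locus_params(
    0.012, 0.0001, 0.014, 0.9739, 503, population = "EURlike", seed = 3))
  g2 <- simulate_two_locus_genotypes(two_locus_params(
    0, 0, 0.05, 0.95, 300, population = "AFRlike", seed = 4))
  ld <- ld_from_genotypes(rbind(g1, g2), by = "population")
  afr <- ld[ld$group == "AFRlike", ]
  eur <- ld[ld$group == "EURlike", ]
  expect_true(is.na(afr$Dprime) && is.na(afr$R2))
  expect_gt(eur$Dprime, 0.85)   # coupling: carriers sit on the SNP background
  expect_lt(eur$R2, 0.8)        # frequencies differ, so correlation is modest
})

test_that("Fisher proxy scan matches closed forms and the enumeration oracle", {
  status <- rep(c("+", "-"), each = 10)
  bal <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  perf <- c(rep(1, 10), rep(0, 10))
  res <- fisher_proxy_scan(status, data.frame(bal = bal, perf = perf),
                           table_shape = "2x2")
  expect_identical(res$snp[1], "perf")
  expect_equal(res$p[res$snp == "bal"], 1)
  expect_equal(res$p[res$snp == "perf"], 2 / choose(20, 10),
               tolerance = 1e-12)
  # 2x2 row/column swap invariance on an unbalanced table
  st2 <- rep(c("+", "-"), c(10, 10))
  g2 <- c(rep(1, 7), rep(0, 3), rep(1, 2), rep(0, 8))
  p_orig <- fisher_proxy_scan(st2, data.frame(x = g2),
                              table_shape = "2x2")$p
  p_swap <- fisher_proxy_scan(ifelse(g2 == 1, "+", "-"),
                              data.frame(x = as.integer(st2 == "+")),
                              table_shape = "2x2")$p
  expect_equal(p_orig, p_swap, tolerance = 1e-12)
  # random 2x3 tables against full enumeration
  set.seed(19)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    st <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.4, 0.6))
    geno <- sample(0:2, n, replace = TRUE)
    tab <- table(factor(st, levels = c("+", "-")),
                 factor(geno, levels = 0:2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_pkg <- fisher_proxy_scan(st, data.frame(snp = geno))$p
    expect_equal(p_pkg, fisher_2x3_enum(tab), tolerance = 1e-12)
    expect_gte(p_pkg, 0); expect_lte(p_pkg, 1)
  }
  # degenerate 1xk table
  expect_equal(fisher_proxy_scan(rep("+", 6),
                                 data.frame(x = c(0, 1, 2, 0, 1, 2)))$p, 1)
})

test_that("allelic-location probability is the class fraction to the observed power", {
  expect_equal(allele_location_probability(0.275, 12), 0.275^12)
  expect_equal(signif(allele_location_probability(0.275, 12), 3), 1.87e-7)
  expect_equal(allele_location_probability(1, 5), 1)
  expect_equal(allele_location_probability(0.5, 2), 0.25)
  expect_error(allele_location_probability(1.2, 3), "class_fraction")
})
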