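#' @title Population genetics of a carrier-status locus
#' @description
#' Carrier-frequency/allele-frequency conversions under Hardy-Weinberg
#' equilibrium, EM haplotype-frequency estimation and linkage
#' disequilibrium (D, D', R2) between a locus observed only as carrier
#' status (the repeat-internal nonsense variant) and a biallelic SNP,
#' Fisher exact proxy-SNP scanning, and the allelic-location probability.
#'
#' Because most KIV-2 repeats remain wild type, no narrow-sense genotype
#' exists for the repeat-internal variant; carriers are coded as
#' heterozygous (one variant haplotype) throughout. Homozygotes are
#' negligibly rare at a minor allele frequency of about 1%.
#' @name popgen
NULL

#' Carrier frequency from counts
#'
#' @param n_carriers number of carriers.
#' @param n_total number of typed individuals.
#' @return `n_carriers / n_total`.
#' @export
carrier_frequency <- function(n_carriers, n_total) {
  if (n_total <= 0) stop("'n_total' must be positive")
  if (n_carriers < 0 || n_carriers > n_total)
    stop("'n_carriers' must be between 0 and 'n_total'")
  n_carriers / n_total
}

#' Minor allele frequency from carrier frequency under HWE
#'
#' Solves `c = 1 - (1 - q)^2` for `q`: with carriers comprising
#' heterozygotes and homozygotes, HWE gives `q = 1 - sqrt(1 - c)`.
#'
#' @param c carrier frequency in `[0, 1)`.
#' @return allele frequency `q`.
#' @seealso [carrier_freq_from_maf()] for the inverse.
#' @export
maf_from_carrier_freq <- function(c) {
  if (any(c < 0 | c >= 1)) stop("carrier frequency must be in [0, 1)")
  1 - sqrt(1 - c)
}

#' Carrier frequency from minor allele frequency under HWE
#'
#' @param q allele frequency.
#' @return carrier frequency `1 - (1 - q)^2`.
#' @export
carrier_freq_from_maf <- function(q) {
  if (any(q < 0 | q > 1)) stop("allele frequency must be in [0, 1]")
  1 - (1 - q)^2
}

# 2 x 3 genotype count table (r21x copies 0/1 x rs minor count 0/1/2),
# carriers coded heterozygous; pairwise-complete individuals only
two_locus_counts <- function(g) {
  ok <- !is.na(g$rs_genotype) & !is.na(g$r21x_status)
  a <- as.integer(g$r21x_status[ok] == "+")
  b <- g$rs_genotype[ok]
  if (any(!b %in% 0:2)) stop("rs_genotype must be 0, 1 or 2")
  counts <- matrix(0L, 2, 3, dimnames = list(r21x = 0:1, rs = 0:2))
  for (i in seq_along(a)) counts[a[i] + 1L, b[i] + 1L] <-
      counts[a[i] + 1L, b[i] + 1L] + 1L
  counts
}

two_locus_loglik <- function(p, counts) {
  # genotype probabilities under HWE given haplotype freqs p = (p11,p10,p01,p00)
  gp <- matrix(0, 2, 3)
  gp[1, 1] <- p[4]^2
  gp[1, 2] <- 2 * p[3] * p[4]
  gp[1, 3] <- p[3]^2
  gp[2, 1] <- 2 * p[2] * p[4]
  gp[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
  gp[2, 3] <- 2 * p[1] * p[3]
  sum(counts[counts > 0] * log(gp[counts > 0]))
}

#' EM haplotype-frequency estimation for carrier status vs a SNP
#'
#' Standard two-locus EM under HWE with the carrier-status locus coded as
#' heterozygous. Only double heterozygotes (carrier with one rs minor
#' allele) are phase-ambiguous; the E step splits their mass between the
#' coupling (11/00) and repulsion (10/01) phases by the current odds, the
#' M step re-estimates haplotype frequencies from expected counts.
#' Initialization at linkage equilibrium (product of marginal allele
#' frequencies).
#'
#' @param g data.frame with columns `rs_genotype` (0/1/2 or `NA`) and
#'   `r21x_status` (`"+"`, `"-"` or `NA`); missing rows dropped pairwise.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap.
#' @return list of class `haplotype_freqs`: `p` (named p11, p10, p01,
#'   p00), `loglik` (trace, one value per iteration), `n` (individuals
#'   used), `monomorphic` flag.
#' @export
em_haplotype_freqs <- function(g, tol = 1e-10, max_iter = 1000L) {
  counts <- two_locus_counts(g)
  n <- sum(counts)
  if (n < 1L) stop("no individuals with both loci observed")
  # known haplotype counts from unambiguous cells
  pA <- sum(counts[2, ]) / (2 * n)              # R21X allele freq (carrier=het)
  pB <- sum(counts[, 2] + 2 * counts[, 3]) / (2 * n)
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  p <- pmax(p, 0)
  n_dh <- counts[2, 2]
  # fixed contributions (haplotype counts) from phase-unambiguous cells
  fixed <- c(
    p11 = counts[2, 3],
    p10 = counts[2, 1],
    p01 = counts[1, 2] + 2 * counts[1, 3] + counts[2, 3],
    p00 = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    loglik <- c(loglik, two_locus_loglik(p, counts))
    coup <- p[1] * p[4]
    rep_ <- p[2] * p[3]
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    hap <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    p_new <- hap / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  names(p) <- c("p11", "p10", "p01", "p00")
  structure(list(p = p, loglik = loglik, n = n, monomorphic = mono),
            class = "haplotype_freqs")
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' `D = p11 - pA*pB`; `D' = D / Dmax` with
#' `Dmax = min(pA(1-pB), (1-pA)pB)` for `D > 0` and
#' `min(pA*pB, (1-pA)(1-pB))` for `D < 0` (`D' = 0` at `D = 0`);
#' `R2 = D^2 / (pA(1-pA) pB(1-pB))`. A high `|D'|` with low `R2` means
#' one variant's haplotypes are a subset of the other's despite very
#' different allele frequencies.
#'
#' @param h a `haplotype_freqs` object or a length-4 numeric
#'   (p11, p10, p01, p00).
#' @return list of class `ld_stats`: `D`, `Dmax`, `Dprime`, `R2`, `pA`,
#'   `pB`.
#' @export
ld_stats <- function(h) {
  p <- if (inherits(h, "haplotype_freqs")) h$p else h
  stopifnot(length(p) == 4, all(p >= -1e-12), abs(sum(p) - 1) < 1e-6)
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("LD undefined: a locus is monomorphic")
  D <- p[1] - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else D / Dmax
  R2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = unname(D), Dmax = unname(Dmax),
                 Dprime = unname(Dprime), R2 = unname(R2),
                 pA = unname(pA), pB = unname(pB)),
            class = "ld_stats")
}

#' LD between carrier status and a SNP, optionally per population
#'
#' Composes [em_haplotype_freqs()] and [ld_stats()]; groups with a
#' monomorphic locus (e.g. no carriers at all) get `NA` LD, matching the
#' "NA/NA" convention for populations without carriers.
#'
#' @param g two-locus genotype data.frame (columns `rs_genotype`,
#'   `r21x_status`, optional grouping column).
#' @param by optional name of a grouping column (e.g. `"population"` or
#'   `"super_population"`); `NULL` pools everything.
#' @return data.frame (group, n, pA, pB, D, Dprime, R2).
#' @export
ld_from_genotypes <- function(g, by = NULL) {
  groups <- if (is.null(by)) list(all = g) else split(g, g[[by]])
  rows <- lapply(names(groups), function(nm) {
    gi <- groups[[nm]]
    h <- em_haplotype_freqs(gi)
    if (h$monomorphic)
      return(data.frame(group = nm, n = h$n,
                        pA = unname(h$p[1] + h$p[2]),
                        pB = unname(h$p[1] + h$p[3]),
                        D = NA_real_, Dprime = NA_real_, R2 = NA_real_,
                        stringsAsFactors = FALSE))
    ld <- ld_stats(h)
    data.frame(group = nm, n = h$n, pA = ld$pA, pB = ld$pB, D = ld$D,
               Dprime = ld$Dprime, R2 = ld$R2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fisher exact proxy-SNP scan
#'
#' Builds a carrier-status x genotype contingency table for each
#' candidate SNP and computes the Fisher exact p-value (two-sided, sum of
#' table probabilities not exceeding the observed table's), returning
#' candidates ranked by p. The default 2x3 table uses genotype classes
#' 0/1/2; `"2x2"` collapses genotype to minor-allele carriership.
#'
#' @param carrier_status character vector of `"+"`/`"-"` per sample.
#' @param candidate_genotypes data.frame or matrix, one column per SNP,
#'   entries 0/1/2 (or `NA`), rows aligned with `carrier_status`.
#' @param table_shape `"2x3"` or `"2x2"`.
#' @return data.frame (snp, p) sorted ascending by p.
#' @export
fisher_proxy_scan <- function(carrier_status, candidate_genotypes,
                              table_shape = c("2x3", "2x2")) {
  table_shape <- match.arg(table_shape)
  candidate_genotypes <- as.data.frame(candidate_genotypes)
  if (ncol(candidate_genotypes) < 1L) stop("no candidate SNPs supplied")
  stopifnot(length(carrier_status) == nrow(candidate_genotypes))
  ps <- vapply(names(candidate_genotypes), function(snp) {
    geno <- candidate_genotypes[[snp]]
    if (table_shape == "2x2") geno <- as.integer(geno >= 1L)
    ok <- !is.na(carrier_status) & !is.na(geno)
    tab <- table(factor(carrier_status[ok], levels = c("+", "-")),
                 factor(geno[ok]))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  out <- data.frame(snp = names(candidate_genotypes), p = unname(ps),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Probability that all observed alleles fall in one size class
#'
#' Under the null that the variant is distributed over allele sizes in
#' proportion to the population allele-size distribution, the chance that
#' all `n_observed` independently sampled variant-bearing alleles fall
#' inside a size class of population frequency `class_fraction` is
#' `class_fraction ^ n_observed`.
#'
#' @param class_fraction population frequency of the allele-size class.
#' @param n_observed number of independently sampled variant alleles.
#' @return the probability.
#' @export
allele_location_probability <- function(class_fraction, n_observed) {
  if (class_fraction < 0 || class_fraction > 1)
    stop("'class_fraction' must be in [0, 1]")
  if (n_observed < 0) stop("'n_observed' must be non-negative")
  class_fraction^n_observed
}
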