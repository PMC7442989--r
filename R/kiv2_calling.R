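#' @title Collapsed-repeat variant calling from read fractions
#' @description
#' When all KIV-2 repeat copies are collapsed onto a single reference
#' repeat, a variant present on one or a few repeats appears as a
#' low-level mutation in a fraction of reads, analogous to a somatic
#' variant. Calling therefore combines a mutation-level cutoff with a
#' binomial test against the sequencing-error null, and confidence is
#' tiered by coverage: 340x (single-end) and 780x (paired-end,
#' bidirectional confirmation) are the published high-confidence depths
#' for calling at a mutation level of at least 1%.
#' @name kiv2_repeat_calling
NULL

#' Published high-confidence coverage presets (reads)
#' @format named integer vector with elements `single` and `paired`.
#' @export
coverage_presets <- c(single = 340L, paired = 780L)

#' Call carrier status from a pileup count
#'
#' A sample is a carrier iff the mutation level `L = m / n` reaches
#' `level_cutoff` and a one-sided binomial test of `m` mutant reads in
#' `n` against `error_rate` rejects at `alpha`. The coverage tier is
#' `coverage_780` at depth >= 780, `coverage_340` at depth >= 340, else
#' `unfiltered`; the call is high-confidence when depth reaches the
#' preset for the sequencing mode.
#'
#' @param mutant_reads,depth mutant read count `m` and total depth `n`.
#' @param mode `"single"` or `"paired"`.
#' @param level_cutoff minimum mutation level called (default 1%).
#' @param error_rate per-base sequencing error probability.
#' @param alpha binomial-test significance level.
#' @param presets named coverage thresholds, see [coverage_presets].
#' @return list of class `mutation_call`: `level`, `status`, `tier`,
#'   `high_confidence`, `p_error`.
#' @export
call_sample <- function(mutant_reads, depth, mode = c("paired", "single"),
                        level_cutoff = 0.01, error_rate = 1e-3,
                        alpha = 0.05, presets = coverage_presets) {
  mode <- match.arg(mode)
  if (depth <= 0) stop("'depth' must be positive")
  if (mutant_reads < 0 || mutant_reads > depth)
    stop("'mutant_reads' must be between 0 and 'depth'")
  L <- mutant_reads / depth
  p_err <- stats::binom.test(mutant_reads, depth, p = error_rate,
                             alternative = "greater")$p.value
  status <- if (L >= level_cutoff && p_err < alpha) "carrier"
            else "non_carrier"
  tier <- if (depth >= presets["paired"]) "coverage_780"
          else if (depth >= presets["single"]) "coverage_340"
          else "unfiltered"
  structure(list(level = L, status = status, tier = tier,
                 high_confidence = depth >= presets[[mode]],
                 p_error = p_err),
            class = "mutation_call")
}

#' Call carrier status for a table of pileups
#'
#' Vectorized [call_sample()] over a pileup table.
#'
#' @param pileups data.frame (sample, population, super_population,
#'   mutant_reads, depth, mode).
#' @inheritParams call_sample
#' @return the input with `level`, `status`, `tier`, `high_confidence`
#'   columns appended.
#' @export
call_pileups <- function(pileups, level_cutoff = 0.01, error_rate = 1e-3,
                         alpha = 0.05, presets = coverage_presets) {
  calls <- lapply(seq_len(nrow(pileups)), function(i)
    call_sample(pileups$mutant_reads[i], pileups$depth[i],
                mode = pileups$mode[i], level_cutoff = level_cutoff,
                error_rate = error_rate, alpha = alpha, presets = presets))
  pileups$level <- vapply(calls, `[[`, numeric(1), "level")
  pileups$status <- vapply(calls, `[[`, character(1), "status")
  pileups$tier <- vapply(calls, `[[`, character(1), "tier")
  pileups$high_confidence <- vapply(calls, `[[`, logical(1),
                                    "high_confidence")
  pileups
}

wilson_lower <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

cp_lower <- function(x, n, conf = 0.95) {
  if (x == 0) 0 else qbeta((1 - conf) / 2, x, n - x + 1)
}

#' Minimal coverage for confident low-level calling
#'
#' For each mutation level `L`, the smallest depth `n` such that the
#' lower bound of the two-sided 95% binomial confidence interval for the
#' expected mutant count `x = round(L * n)` stays above zero. The CI
#' method is pluggable (Wald, Wilson, Clopper-Pearson); `"preset"`
#' returns the published constants (340x single-end, 780x paired-end)
#' independent of any derivation.
#'
#' @param levels mutation levels in (0, 1).
#' @param method `"preset"`, `"wald"`, `"wilson"` or `"clopper-pearson"`.
#' @param mode sequencing mode, used by `"preset"` only.
#' @param conf confidence level of the binomial interval.
#' @param n_max search cap; an unsatisfiable criterion is reported `NA`
#'   (unbounded).
#' @return data.frame (level, min_coverage).
#' @export
min_coverage_table <- function(levels,
                               method = c("preset", "wald", "wilson",
                                          "clopper-pearson"),
                               mode = c("single", "paired"),
                               conf = 0.95, n_max = 1e6) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (any(levels <= 0 | levels >= 1)) stop("levels must be in (0, 1)")
  z <- qnorm(1 - (1 - conf) / 2)
  min_n <- vapply(levels, function(L) {
    if (method == "preset") return(as.numeric(coverage_presets[[mode]]))
    if (method == "wald") {
      # lower bound L - z*sqrt(L(1-L)/n) > 0  <=>  n > z^2 (1-L)/L
      n <- floor(z^2 * (1 - L) / L) + 1
      return(if (n > n_max) NA_real_ else n)
    }
    lower <- switch(method, wilson = wilson_lower,
                    `clopper-pearson` = cp_lower)
    for (n in seq_len(n_max)) {
      x <- round(L * n)
      if (x >= 1 && lower(x, n, conf) > 0) return(as.numeric(n))
    }
    NA_real_
  }, numeric(1))
  data.frame(level = levels, min_coverage = min_n)
}

tier_depth <- c(unfiltered = 0L, coverage_340 = 340L, coverage_780 = 780L)

#' Per-population carrier counts and frequencies by coverage tier
#'
#' Restricts to samples whose depth reaches the tier's coverage floor,
#' then reports individuals, carriers and carrier frequency per group —
#' the shape of the published worldwide-frequency table. Frequencies in
#' empty groups are `NA`.
#'
#' @param calls data.frame as returned by [call_pileups()] (needs
#'   `depth`, `status` and the grouping column).
#' @param tier `"unfiltered"`, `"coverage_340"` or `"coverage_780"`.
#' @param by grouping column name (default `"super_population"`).
#' @return data.frame (group, tier, individuals, carriers,
#'   carrier_frequency).
#' @export
population_summary <- function(calls, tier = c("unfiltered",
                                               "coverage_340",
                                               "coverage_780"),
                               by = "super_population") {
  tier <- match.arg(tier)
  keep <- calls$depth >= tier_depth[[tier]]
  # group levels come from the unfiltered table so a group emptied by the
  # coverage filter still appears (with NA frequency)
  groups <- split(calls[keep, , drop = FALSE],
                  factor(calls[[by]][keep], levels = unique(calls[[by]])))
  if (!length(groups))
    return(data.frame(group = character(), tier = character(),
                      individuals = integer(), carriers = integer(),
                      carrier_frequency = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(names(groups), function(nm) {
    gi <- groups[[nm]]
    n <- nrow(gi)
    k <- sum(gi$status == "carrier")
    data.frame(group = nm, tier = tier, individuals = n, carriers = k,
               carrier_frequency = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
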