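#' @title Synthetic-data generators for the KIV-2 null-variant pipeline
#' @description
#' Generators for every input the pipeline consumes: qPCR Ct plates,
#' two-locus genotypes under Hardy-Weinberg equilibrium, collapsed-repeat
#' pileup counts, and skewed Lp(a) phenotypes with per-allele isoform
#' contributions. Each generator returns truth labels alongside the data
#' so downstream calls can be scored without external datasets.
#' @name simulate
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  x
}

#' Parameters for a simulated qPCR plate
#'
#' Carrier Ct values follow the PCR doubling law: a carrier with `r` mutant
#' repeats out of a maximum of `r_max` amplifies `log2(r_max / r)` cycles
#' later than the earliest-amplifying carrier, so 1--3 mutant repeats span
#' at most `log2(3) ~ 1.58` cycles. Non-carriers show late unspecific
#' amplification. Defaults bracket validated assay ranges of 30.3--31.7
#' cycles (carriers) and 37.3--39.7 cycles (non-carriers).
#'
#' @param n_samples number of wells.
#' @param carrier_frequency probability a sample is a true carrier.
#' @param mu_carrier_base earliest carrier Ct (cycles).
#' @param sigma_carrier carrier Ct SD (cycles).
#' @param mu_noncarrier mean non-carrier Ct (cycles).
#' @param sigma_noncarrier non-carrier Ct SD (cycles).
#' @param mutant_repeat_range integer range of mutant KIV-2 repeat counts
#'   carried by a carrier, inclusive.
#' @param pcr_failure_rate probability a well fails PCR (missing control Ct).
#' @param intermediate_rate probability of a contaminant well with Ct
#'   uniform between the two component means.
#' @param seed integer RNG seed.
#' @return an object of class `ct_plate_params`.
#' @export
ct_plate_params <- function(n_samples = 384L,
                            carrier_frequency = 0.02,
                            mu_carrier_base = 30.3,
                            sigma_carrier = 0.4,
                            mu_noncarrier = 38.5,
                            sigma_noncarrier = 0.6,
                            mutant_repeat_range = c(1L, 3L),
                            pcr_failure_rate = 0.005,
                            intermediate_rate = 0.005,
                            seed = 1L) {
  if (n_samples < 0) stop("'n_samples' must be non-negative")
  check_prob(carrier_frequency, "carrier_frequency")
  check_prob(pcr_failure_rate, "pcr_failure_rate")
  check_prob(intermediate_rate, "intermediate_rate")
  if (sigma_carrier < 0 || sigma_noncarrier < 0)
    stop("Ct standard deviations must be non-negative")
  mutant_repeat_range <- as.integer(mutant_repeat_range)
  if (length(mutant_repeat_range) != 2L || any(mutant_repeat_range < 1L) ||
      mutant_repeat_range[1] > mutant_repeat_range[2])
    stop("'mutant_repeat_range' must be an increasing pair of positive integers")
  if (mu_carrier_base >= mu_noncarrier)
    stop("carrier Ct must precede (be smaller than) non-carrier Ct")
  structure(list(
    n_samples = as.integer(n_samples),
    carrier_frequency = carrier_frequency,
    mu_carrier_base = mu_carrier_base,
    sigma_carrier = sigma_carrier,
    mu_noncarrier = mu_noncarrier,
    sigma_noncarrier = sigma_noncarrier,
    mutant_repeat_range = mutant_repeat_range,
    pcr_failure_rate = pcr_failure_rate,
    intermediate_rate = intermediate_rate,
    seed = as.integer(seed)
  ), class = "ct_plate_params")
}

#' Simulate one allele-specific qPCR plate
#'
#' Draws each well as carrier, non-carrier, PCR failure or intermediate
#' contaminant. Carrier Ct = `mu_carrier_base + log2(r_max / r) + N(0,
#' sigma_carrier)` with the mutant repeat count `r` uniform over
#' `mutant_repeat_range`; non-carrier Ct ~ `N(mu_noncarrier,
#' sigma_noncarrier)`. PCR failures have both channels missing;
#' intermediate wells are uniform between the two component means.
#'
#' @param params a [ct_plate_params()] object.
#' @param plate_id plate label stamped on every record.
#' @return list with `records` (data.frame: sample_id, plate_id, ct_mutant,
#'   ct_control) and `truth` (data.frame: sample_id, truth in
#'   carrier/non_carrier/intermediate/pcr_failure, mutant_repeats).
#' @export
simulate_ct_plate <- function(params, plate_id = "plate1") {
  stopifnot(inherits(params, "ct_plate_params"))
  n <- params$n_samples
  ids <- sprintf("%s_S%04d", plate_id, seq_len(n))
  if (n == 0L) {
    rec <- data.frame(sample_id = character(), plate_id = character(),
                      ct_mutant = numeric(), ct_control = numeric(),
                      stringsAsFactors = FALSE)
    tr <- data.frame(sample_id = character(), truth = character(),
                     mutant_repeats = integer(), stringsAsFactors = FALSE)
    return(list(records = rec, truth = tr))
  }
  set.seed(params$seed)
  u <- runif(n)
  p_fail <- params$pcr_failure_rate
  p_int <- params$intermediate_rate
  p_car <- (1 - p_fail - p_int) * params$carrier_frequency
  truth <- ifelse(u < p_fail, "pcr_failure",
           ifelse(u < p_fail + p_int, "intermediate",
           ifelse(u < p_fail + p_int + p_car, "carrier", "non_carrier")))

  rng <- params$mutant_repeat_range
  r_max <- rng[2]
  reps <- rep(NA_integer_, n)
  is_car <- truth == "carrier"
  reps[is_car] <- sample(seq(rng[1], rng[2]), sum(is_car), replace = TRUE)

  # fitted carrier component mean under the repeat model, for contaminants
  mu_car_mean <- params$mu_carrier_base +
    mean(log2(r_max / seq(rng[1], rng[2])))

  ct <- rep(NA_real_, n)
  ct[is_car] <- params$mu_carrier_base + log2(r_max / reps[is_car]) +
    rnorm(sum(is_car), 0, params$sigma_carrier)
  is_non <- truth == "non_carrier"
  ct[is_non] <- rnorm(sum(is_non), params$mu_noncarrier,
                      params$sigma_noncarrier)
  is_int <- truth == "intermediate"
  ct[is_int] <- runif(sum(is_int), mu_car_mean, params$mu_noncarrier)

  ct_control <- rnorm(n, 26, 0.5)
  ct_control[truth == "pcr_failure"] <- NA_real_

  list(
    records = data.frame(sample_id = ids, plate_id = plate_id,
                         ct_mutant = ct, ct_control = ct_control,
                         stringsAsFactors = FALSE),
    truth = data.frame(sample_id = ids, truth = truth,
                       mutant_repeats = reps, stringsAsFactors = FALSE)
  )
}

#' Simulate qPCR plates consistent with a genotype table
#'
#' Lays a cohort out on 384-well plates and draws each sample's Ct from
#' the carrier or non-carrier component according to its `r21x_status`,
#' so plate calls can be scored against the genotype truth. PCR failures
#' and intermediate contaminants occur at the plate-parameter rates
#' irrespective of genotype.
#'
#' @param genotypes data.frame with columns `sample` and `r21x_status`.
#' @param plate_size wells per plate.
#' @param prefix plate-label prefix.
#' @param seed integer RNG seed.
#' @param base_params a [ct_plate_params()] object supplying the Ct
#'   component parameters (its `n_samples`, `carrier_frequency` and
#'   `seed` are ignored).
#' @return data.frame of plate records (sample_id, plate_id, ct_mutant,
#'   ct_control); attribute `"well_class"` holds a data.frame
#'   (sample_id, well_class) with `ok`, `intermediate` (contaminated
#'   well, Ct unrelated to genotype) or `pcr_failure`.
#' @export
simulate_study_plates <- function(genotypes, plate_size = 384L,
                                  prefix = "P", seed = 1L,
                                  base_params = ct_plate_params()) {
  n <- nrow(genotypes)
  n_plates <- ceiling(n / plate_size)
  plate_of <- rep(seq_len(n_plates), each = plate_size, length.out = n)
  rng <- base_params$mutant_repeat_range
  r_max <- rng[2]
  records <- NULL
  well_class <- NULL
  for (pl in seq_len(n_plates)) {
    idx <- which(plate_of == pl)
    sim <- simulate_ct_plate(ct_plate_params(
      n_samples = length(idx), carrier_frequency = 0,
      mu_carrier_base = base_params$mu_carrier_base,
      sigma_carrier = base_params$sigma_carrier,
      mu_noncarrier = base_params$mu_noncarrier,
      sigma_noncarrier = base_params$sigma_noncarrier,
      mutant_repeat_range = rng,
      pcr_failure_rate = base_params$pcr_failure_rate,
      intermediate_rate = base_params$intermediate_rate,
      seed = seed + pl), plate_id = sprintf("%s%02d", prefix, pl))
    rec <- sim$records
    rec$sample_id <- genotypes$sample[idx]
    carr <- genotypes$r21x_status[idx] == "+" &
      !is.na(genotypes$r21x_status[idx]) & !is.na(rec$ct_mutant)
    r <- sample(seq(rng[1], rng[2]), sum(carr), replace = TRUE)
    rec$ct_mutant[carr] <- base_params$mu_carrier_base + log2(r_max / r) +
      rnorm(sum(carr), 0, base_params$sigma_carrier)
    cls <- ifelse(sim$truth$truth == "pcr_failure", "pcr_failure",
           ifelse(sim$truth$truth == "intermediate" & !carr,
                  "intermediate", "ok"))
    well_class <- rbind(well_class,
                        data.frame(sample_id = rec$sample_id,
                                   well_class = cls,
                                   stringsAsFactors = FALSE))
    records <- rbind(records, rec)
  }
  attr(records, "well_class") <- well_class
  records
}

#' Parameters for two-locus genotype simulation
#'
#' Haplotype frequencies are over (R21X allele present, rs minor allele
#' present): `p11 + p10 + p01 + p00 = 1`.
#'
#' @param p11,p10,p01,p00 haplotype frequencies.
#' @param n_individuals number of diploid individuals.
#' @param missing_rate per-locus missingness probability.
#' @param population population label stamped on every record.
#' @param seed integer RNG seed.
#' @return an object of class `two_locus_params`.
#' @export
two_locus_params <- function(p11, p10, p01, p00, n_individuals,
                             missing_rate = 0, population = "POP1",
                             seed = 1L) {
  p <- c(p11, p10, p01, p00)
  if (any(p < 0)) stop("haplotype frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (within 1e-9)")
  check_prob(missing_rate, "missing_rate")
  structure(list(p = p, n_individuals = as.integer(n_individuals),
                 missing_rate = missing_rate, population = population,
                 seed = as.integer(seed)),
            class = "two_locus_params")
}

#' Simulate diploid two-locus genotypes under HWE
#'
#' Each individual receives two haplotypes drawn i.i.d. from the four
#' haplotype frequencies. The SNP locus is reported as a minor-allele
#' count 0/1/2; the repeat-internal locus only as carrier status (`+` if
#' at least one R21X haplotype), mirroring that no narrow-sense genotype
#' is observable inside the copy-number repeat.
#'
#' @param params a [two_locus_params()] object.
#' @return data.frame (sample, population, rs_genotype, r21x_status) with
#'   the phased haplotype truth in attribute `"haplotypes"` (n x 2 matrix
#'   of haplotype indices 1=11, 2=10, 3=01, 4=00).
#' @export
simulate_two_locus_genotypes <- function(params) {
  stopifnot(inherits(params, "two_locus_params"))
  n <- params$n_individuals
  set.seed(params$seed)
  if (n == 0L) {
    out <- data.frame(sample = character(), population = character(),
                      rs_genotype = integer(), r21x_status = character(),
                      stringsAsFactors = FALSE)
    attr(out, "haplotypes") <- matrix(integer(), 0, 2)
    return(out)
  }
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = params$p),
                ncol = 2)
  has_r21x <- hap <= 2L           # haplotypes 11, 10 carry R21X
  has_minor <- hap %in% c(1L, 3L) # haplotypes 11, 01 carry the rs minor allele
  dim(has_minor) <- dim(hap)
  rs_geno <- rowSums(has_minor)
  r21x <- ifelse(rowSums(has_r21x) >= 1L, "+", "-")
  if (params$missing_rate > 0) {
    rs_geno[runif(n) < params$missing_rate] <- NA_integer_
    r21x[runif(n) < params$missing_rate] <- NA_character_
  }
  out <- data.frame(sample = sprintf("IND%05d", seq_len(n)),
                    population = params$population,
                    rs_genotype = as.integer(rs_geno),
                    r21x_status = r21x, stringsAsFactors = FALSE)
  attr(out, "haplotypes") <- hap
  out
}

#' Parameters for Lp(a) phenotype simulation
#'
#' Total Lp(a) is the sum of two per-allele contributions. Each expressed
#' allele with `k` KIV repeats contributes a lognormal amount with median
#' `median_scale * 2^(-(k - 11) / median_halving_kiv)` mg/dL, so smaller
#' isoforms (low molecular weight, `<= lmw_threshold` KIV) produce several-
#' fold more Lp(a) than large ones. A null-flagged allele contributes
#' exactly 0 (nonsense/splice null). The total is floored at the assay
#' detection limit of 0.1 mg/dL.
#'
#' @param n_individuals number of individuals.
#' @param isoform_mean,isoform_sd mean/SD of the discretized normal
#'   isoform-size distribution over 11--50 KIV repeats.
#' @param lmw_threshold KIV count at or below which an allele counts as
#'   low molecular weight.
#' @param median_scale per-allele median contribution at 11 KIV (mg/dL).
#' @param median_halving_kiv KIV repeats over which the per-allele median
#'   contribution halves.
#' @param allele_noise_sd log-scale SD of the per-allele contribution.
#' @param detection_limit assay floor (mg/dL).
#' @param null_allele_kiv_range KIV range onto which a null-carrying
#'   allele is placed (the variant sits on moderately large isoforms).
#' @param age_effect,sex_effect additive covariate effects (mg/dL per
#'   year of age / for sex = 1).
#' @param seed integer RNG seed.
#' @return an object of class `lpa_sim_params`.
#' @export
lpa_sim_params <- function(n_individuals = 5000L,
                           isoform_mean = 29,
                           isoform_sd = 6,
                           lmw_threshold = 22L,
                           median_scale = 141,
                           median_halving_kiv = 3.5,
                           allele_noise_sd = 0.8,
                           detection_limit = 0.1,
                           null_allele_kiv_range = c(27L, 32L),
                           age_effect = 0.02,
                           sex_effect = 0.5,
                           seed = 1L) {
  if (n_individuals < 0) stop("'n_individuals' must be non-negative")
  if (detection_limit < 0) stop("'detection_limit' must be non-negative")
  if (allele_noise_sd < 0) stop("'allele_noise_sd' must be non-negative")
  structure(list(n_individuals = as.integer(n_individuals),
                 isoform_mean = isoform_mean, isoform_sd = isoform_sd,
                 lmw_threshold = as.integer(lmw_threshold),
                 median_scale = median_scale,
                 median_halving_kiv = median_halving_kiv,
                 allele_noise_sd = allele_noise_sd,
                 detection_limit = detection_limit,
                 null_allele_kiv_range = as.integer(null_allele_kiv_range),
                 age_effect = age_effect, sex_effect = sex_effect,
                 seed = as.integer(seed)),
            class = "lpa_sim_params")
}

draw_isoform_sizes <- function(n, mean, sd) {
  k <- 11:50
  w <- dnorm(k, mean, sd)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate Lp(a) phenotypes with per-allele truth
#'
#' @param params an [lpa_sim_params()] object.
#' @param genotypes optional data.frame as returned by
#'   [simulate_two_locus_genotypes()]; when supplied, individuals with
#'   `r21x_status == "+"` have one allele (placed in
#'   `null_allele_kiv_range`) flagged null, and rs minor-allele copies
#'   null further alleles. When `NULL`, no null alleles are planted.
#' @return data.frame of phenotype records (sample, lpa, age, sex, egfr,
#'   uacr, r21x, rs41272114_genotype, kiv_allele1, kiv_allele2) with the
#'   per-allele contribution truth in attribute `"allele_contributions"`.
#' @export
simulate_lpa_phenotypes <- function(params, genotypes = NULL) {
  stopifnot(inherits(params, "lpa_sim_params"))
  n <- params$n_individuals
  if (!is.null(genotypes)) {
    if (nrow(genotypes) != n)
      stop("genotype table length does not match 'n_individuals'")
  }
  set.seed(params$seed + 1L)
  k1 <- draw_isoform_sizes(n, params$isoform_mean, params$isoform_sd)
  k2 <- draw_isoform_sizes(n, params$isoform_mean, params$isoform_sd)
  null1 <- rep(FALSE, n)
  null2 <- rep(FALSE, n)
  r21x <- rep("-", n)
  rs_geno <- rep(0L, n)
  if (!is.null(genotypes) && n > 0) {
    r21x <- ifelse(is.na(genotypes$r21x_status), "-", genotypes$r21x_status)
    rs_geno <- ifelse(is.na(genotypes$rs_genotype), 0L,
                      genotypes$rs_genotype)
    rng <- params$null_allele_kiv_range
    carr <- which(r21x == "+")
    # the nonsense variant sits on a moderately large allele: force allele 1
    # into the stated KIV range and silence it
    if (length(carr)) {
      k1[carr] <- sample(seq(rng[1], rng[2]), length(carr), replace = TRUE)
      null1[carr] <- TRUE
    }
    # rs splice-null copies beyond those explained by R21X silence allele 2
    extra <- which(rs_geno - (r21x == "+") >= 1L)
    null2[extra] <- TRUE
  }
  med1 <- params$median_scale * 2^(-(k1 - 11) / params$median_halving_kiv)
  med2 <- params$median_scale * 2^(-(k2 - 11) / params$median_halving_kiv)
  c1 <- ifelse(null1, 0, rlnorm(n, log(med1), params$allele_noise_sd))
  c2 <- ifelse(null2, 0, rlnorm(n, log(med2), params$allele_noise_sd))
  age <- round(pmin(pmax(rnorm(n, 57, 10), 18), 90))
  sex <- rbinom(n, 1L, 0.5)
  lpa <- pmax(c1 + c2 + params$age_effect * (age - 57) +
                params$sex_effect * sex, params$detection_limit)
  egfr <- pmax(rnorm(n, 90, 18), 5)
  uacr <- rlnorm(n, log(15), 1.2)
  out <- data.frame(
    sample = if (!is.null(genotypes) && n > 0) genotypes$sample
             else sprintf("IND%05d", seq_len(n)),
    lpa = lpa, age = age, sex = sex, egfr = egfr, uacr = uacr,
    r21x = r21x, rs41272114_genotype = rs_geno,
    kiv_allele1 = k1, kiv_allele2 = k2, stringsAsFactors = FALSE)
  attr(out, "allele_contributions") <- cbind(c1, c2)
  out
}

#' Parameters for collapsed-repeat pileup simulation
#'
#' @param n_samples number of samples.
#' @param carrier_frequency probability a sample carries the variant.
#' @param coverage_fn function(n) returning n integer read depths.
#' @param mutation_level_fn function(n) returning n mutation levels, the
#'   fraction of KIV-2 repeats carrying the variant (support about
#'   0.01--0.10).
#' @param sequencing_error_rate per-base error probability.
#' @param mode `"single"` or `"paired"` sequencing.
#' @param population,super_population labels stamped on every record.
#' @param seed integer RNG seed.
#' @return an object of class `pileup_sim_params`.
#' @export
pileup_sim_params <- function(n_samples = 500L,
                              carrier_frequency = 0.02,
                              coverage_fn = function(n)
                                pmax(1L, as.integer(round(
                                  rlnorm(n, log(600), 0.5)))),
                              mutation_level_fn = function(n)
                                runif(n, 0.01, 0.10),
                              sequencing_error_rate = 1e-3,
                              mode = c("paired", "single"),
                              population = "POP1",
                              super_population = "EUR",
                              seed = 1L) {
  if (n_samples < 0) stop("'n_samples' must be non-negative")
  check_prob(carrier_frequency, "carrier_frequency")
  check_prob(sequencing_error_rate, "sequencing_error_rate")
  mode <- match.arg(mode)
  structure(list(n_samples = as.integer(n_samples),
                 carrier_frequency = carrier_frequency,
                 coverage_fn = coverage_fn,
                 mutation_level_fn = mutation_level_fn,
                 sequencing_error_rate = sequencing_error_rate,
                 mode = mode, population = population,
                 super_population = super_population,
                 seed = as.integer(seed)),
            class = "pileup_sim_params")
}

#' Simulate collapsed-repeat pileup counts
#'
#' In a collapsed alignment every KIV-2 repeat maps onto one reference
#' repeat, so a variant on a few repeats appears as a low-level mutation
#' in a fraction `L` of reads. Mutant reads are
#' `Binomial(depth, L + error)` for carriers and `Binomial(depth, error)`
#' for non-carriers.
#'
#' @param params a [pileup_sim_params()] object.
#' @return list with `pileups` (data.frame: sample, population,
#'   super_population, mutant_reads, depth, mode) and `truth` (data.frame:
#'   sample, truth, mutation_level).
#' @export
simulate_pileups <- function(params) {
  stopifnot(inherits(params, "pileup_sim_params"))
  n <- params$n_samples
  set.seed(params$seed + 2L)
  ids <- sprintf("PU%05d", seq_len(n))
  is_car <- runif(n) < params$carrier_frequency
  depth <- params$coverage_fn(n)
  stopifnot(length(depth) == n, all(depth >= 1))
  L <- rep(0, n)
  L[is_car] <- params$mutation_level_fn(sum(is_car))
  p <- pmin(L + params$sequencing_error_rate, 1)
  m <- rbinom(n, depth, p)
  list(
    pileups = data.frame(sample = ids, population = params$population,
                         super_population = params$super_population,
                         mutant_reads = m, depth = depth,
                         mode = params$mode, stringsAsFactors = FALSE),
    truth = data.frame(sample = ids,
                       truth = ifelse(is_car, "carrier", "non_carrier"),
                       mutation_level = L, stringsAsFactors = FALSE)
  )
}
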