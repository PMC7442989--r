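#' @title File dialects and the end-to-end pipeline
#' @description
#' Readers and writers for the pipeline's plain-text dialects (plate CSV,
#' genotype/pileup TSV, phenotype CSV, results JSON), a minimal GT-only
#' VCF reader for the biallelic SNP, and [run_pipeline()], which ties the
#' stages together from a single YAML/list configuration. All files are
#' headered; missing values are encoded as "NA".
#' @name io_pipeline
NULL

write_delim_na <- function(x, path, sep) {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
}

#' Write / read a qPCR plate table (CSV)
#'
#' Columns: sample_id, plate_id, ct_mutant, ct_control. On reading, a
#' `column_map` (named vector `internal = "file column"`) adapts external
#' instrument exports; undetermined-Ct strings ("Undetermined", "") are
#' read as missing, never as a sentinel cycle number.
#'
#' @param records plate data.frame.
#' @param path file path.
#' @param column_map optional named character vector mapping internal
#'   column names to file column names.
#' @return `read_plate_csv` returns the plate data.frame.
#' @export
write_plate_csv <- function(records, path) write_delim_na(records, path, ",")

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path, column_map = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", "", "Undetermined"))
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(x))
    if (length(missing_cols))
      stop("mapped columns absent from file: ",
           paste(missing_cols, collapse = ", "))
    for (internal in names(column_map))
      names(x)[names(x) == column_map[[internal]]] <- internal
  }
  need <- c("sample_id", "plate_id", "ct_mutant", "ct_control")
  if (!all(need %in% names(x)))
    stop("plate file must provide columns: ", paste(need, collapse = ", "))
  x$ct_mutant <- as.numeric(x$ct_mutant)
  x$ct_control <- as.numeric(x$ct_control)
  x[need]
}

#' Write / read a two-locus genotype table (TSV)
#'
#' Columns: sample, population, rs_genotype (0/1/2/NA), r21x_status
#' (+/-/NA).
#' @param genotypes genotype data.frame.
#' @param path file path.
#' @return `read_genotype_tsv` returns the genotype data.frame.
#' @export
write_genotype_tsv <- function(genotypes, path)
  write_delim_na(genotypes, path, "\t")

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("sample", "population", "rs_genotype", "r21x_status")
  if (!all(need %in% names(x)))
    stop("genotype file must provide columns: ",
         paste(need, collapse = ", "))
  bad <- which(!x$rs_genotype %in% c(0:2, NA))
  if (length(bad))
    stop("malformed rs_genotype at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' Write / read a pileup table (TSV)
#'
#' Columns: sample, population, super_population, mutant_reads, depth,
#' mode.
#' @param pileups pileup data.frame.
#' @param path file path.
#' @return `read_pileup_tsv` returns the pileup data.frame.
#' @export
write_pileup_tsv <- function(pileups, path) write_delim_na(pileups, path, "\t")

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("sample", "population", "super_population", "mutant_reads",
            "depth", "mode")
  if (!all(need %in% names(x)))
    stop("pileup file must provide columns: ", paste(need, collapse = ", "))
  bad <- which(x$mutant_reads > x$depth)
  if (length(bad))
    stop("mutant_reads exceeds depth at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' Write / read a phenotype table (CSV)
#' @param phenotypes phenotype data.frame.
#' @param path file path.
#' @return `read_phenotype_csv` returns the phenotype data.frame.
#' @export
write_phenotype_csv <- function(phenotypes, path)
  write_delim_na(phenotypes, path, ",")

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  if (!"lpa" %in% names(x)) stop("phenotype file must provide column 'lpa'")
  x
}

#' Write / read carrier calls (TSV)
#' @param calls calls data.frame (sample_id, plate_id, status).
#' @param path file path.
#' @return `read_calls_tsv` returns the calls data.frame.
#' @export
write_calls_tsv <- function(calls, path) write_delim_na(calls, path, "\t")

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))

#' Read diploid genotypes of one biallelic SNP from a VCF
#'
#' Minimal GT-only reader: the first variant record is used, FILTER/QUAL
#' are ignored, and genotypes are returned as minor-allele counts. Any
#' non-diploid GT is an error.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return data.frame (sample, rs_genotype).
#' @export
read_vcf_snp <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) < 1L) stop("VCF contains no variant records")
  gt <- vcfR::extract.gt(v, element = "GT")[1, ]
  alleles <- strsplit(gt, "[/|]")
  n_alleles <- lengths(alleles)
  if (any(n_alleles != 2L & !is.na(gt)))
    stop("non-diploid GT in VCF for sample(s): ",
         paste(utils::head(names(gt)[n_alleles != 2L], 5), collapse = ", "))
  counts <- vapply(alleles, function(a) {
    if (anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  data.frame(sample = names(gt), rs_genotype = unname(counts),
             stringsAsFactors = FALSE)
}

#' Super-population assignment for 1000G-style population codes
#'
#' Reads the editable mapping shipped under `extdata/` and joins it onto
#' a population-label vector; unknown labels map to their literal value.
#'
#' @param populations character vector of population codes.
#' @param map_path optional path to a two-column TSV (population,
#'   super_population); defaults to the packaged map.
#' @return character vector of super-population labels.
#' @export
super_population_of <- function(populations, map_path = NULL) {
  map_path <- map_path %||% system.file("extdata", "superpopulations.tsv",
                                        package = "lpakiv2")
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  idx <- match(populations, map$population)
  ifelse(is.na(idx), populations, map$super_population[idx])
}

#' Default pipeline configuration
#'
#' Stage parameters for the full synthetic-study pipeline; any element
#' can be overridden via `run_pipeline(config = ...)`. Every seed is
#' explicit so reruns are byte-identical.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested list of stage parameters.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    studies = list(
      list(name = "studyA", n = 4771L, carrier_frequency = 0.016),
      list(name = "studyB", n = 3099L, carrier_frequency = 0.018),
      list(name = "studyC", n = 3040L, carrier_frequency = 0.021)),
    haplotypes = list(p11 = 0.008, p10 = 0.0002, p01 = 0.018,
                      p00 = 0.9738),
    ct = list(alpha_tail = 0.025, n_bootstrap = 100L, control_cutoff = 35,
              min_separation = 3, plate_size = 384L),
    kiv2 = list(n_samples = 1000L, carrier_frequency = 0.02,
                level_cutoff = 0.01, error_rate = 1e-3,
                tier = "unfiltered"),
    association = list(covariates = c("age", "sex"))
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config(config$seed %||% 1L)
  known <- names(base)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

stage_log <- function(stage, fmt, ...)
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the configured studies, calls carrier status from the qPCR
#' plates, derives population-genetic summaries (carrier frequency, HWE
#' MAF, LD with the proxy SNP), calls the collapsed-repeat pileup set,
#' fits the per-study carrier association and pools it by fixed-effect
#' meta-analysis. Every artifact is written under `out_dir` together
#' with a manifest (config, seeds, package version, per-stage counts).
#'
#' @param config configuration list or YAML file path; see
#'   [default_pipeline_config()].
#' @param out_dir artifact directory (created if absent).
#' @return invisibly, a list with the per-study summaries, the LD table,
#'   the tiered pileup summary and the `meta_result`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("lpakiv2_run")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  study_rows <- list()
  est_beta <- est_se <- numeric(0)
  hp <- cfg$haplotypes

  for (si in seq_along(cfg$studies)) {
    st <- cfg$studies[[si]]
    sseed <- seed + 1000L * si
    stage <- paste0("study:", st$name)

    gt <- run_stage(stage, simulate_two_locus_genotypes(two_locus_params(
      hp$p11, hp$p10, hp$p01, hp$p00, n_individuals = st$n,
      population = st$name, seed = sseed)))

    # Ct distribution driven by the true genotype status, one 384-well
    # plate per block of samples
    records <- run_stage(stage, simulate_study_plates(
      gt, plate_size = cfg$ct$plate_size,
      prefix = paste0(st$name, "_P"), seed = sseed))
    write_plate_csv(records, file.path(out_dir,
                                       paste0(st$name, "_plates.csv")))

    calls <- run_stage(stage, call_plates(
      records, control_cutoff = cfg$ct$control_cutoff,
      alpha_tail = cfg$ct$alpha_tail, n_bootstrap = cfg$ct$n_bootstrap,
      min_separation = cfg$ct$min_separation, seed = sseed))
    write_calls_tsv(calls$calls, file.path(out_dir,
                                           paste0(st$name, "_calls.tsv")))
    called <- calls$calls$status %in% c("carrier", "non_carrier")
    stage_log(stage,
              "samples read %d, QC-failed %d, ambiguous-excluded %d, called %d",
              nrow(calls$calls),
              sum(calls$calls$status == "excluded_pcr_failure"),
              sum(calls$calls$status == "excluded_ambiguous"), sum(called))

    cf <- calls$summary$carrier_frequency
    pheno <- run_stage(stage, simulate_lpa_phenotypes(
      lpa_sim_params(n_individuals = st$n, seed = sseed), genotypes = gt))
    write_phenotype_csv(pheno, file.path(out_dir,
                                         paste0(st$name, "_pheno.csv")))
    # join the qPCR calls back onto the phenotypes by sample id
    call_status <- calls$calls$status[match(pheno$sample,
                                            calls$calls$sample_id)]
    pheno$r21x_called <- as.integer(call_status == "carrier")
    pheno$r21x_called[!call_status %in% c("carrier", "non_carrier")] <- NA
    fit <- run_stage(stage, fit_linear(pheno, "lpa", "r21x_called",
                                       cfg$association$covariates))
    est_beta <- c(est_beta, fit$beta)
    est_se <- c(est_se, fit$se)

    ldrow <- run_stage(stage, ld_from_genotypes(gt))
    study_rows[[si]] <- data.frame(
      study = st$name, n = st$n, carriers = calls$summary$n_carrier,
      carrier_frequency = cf, maf = maf_from_carrier_freq(cf),
      exclusion_rate = calls$summary$exclusion_rate,
      beta = fit$beta, se = fit$se, p = fit$p,
      partial_r2 = fit$partial_r2, Dprime = ldrow$Dprime, R2 = ldrow$R2,
      stringsAsFactors = FALSE)
  }
  studies <- do.call(rbind, study_rows)
  write_delim_na(studies, file.path(out_dir, "study_summary.tsv"), "\t")

  meta <- run_stage("meta", fixed_effect_meta(
    est_beta, est_se, labels = vapply(cfg$studies, `[[`, "", "name")))

  pu <- run_stage("kiv2", simulate_pileups(pileup_sim_params(
    n_samples = cfg$kiv2$n_samples,
    carrier_frequency = cfg$kiv2$carrier_frequency, seed = seed + 77L)))
  pucalls <- run_stage("kiv2", call_pileups(
    pu$pileups, level_cutoff = cfg$kiv2$level_cutoff,
    error_rate = cfg$kiv2$error_rate))
  tiers <- do.call(rbind, lapply(
    c("unfiltered", "coverage_340", "coverage_780"),
    function(t) population_summary(pucalls, tier = t)))
  write_delim_na(tiers, file.path(out_dir, "pileup_summary.tsv"), "\t")

  jsonlite::write_json(
    list(meta = meta[c("beta", "se", "ci95", "p", "Q", "df", "I2")]),
    file.path(out_dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lpakiv2")),
    r_version = R.version.string,
    config = cfg,
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))))
  manifest$config$kiv2$coverage_presets <- as.list(coverage_presets)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("meta", "pooled beta %.2f [%.2f; %.2f], I2 = %.1f",
            meta$beta, meta$ci95[1], meta$ci95[2], meta$I2)
  invisible(list(studies = studies, meta = meta, pileup_tiers = tiers,
                 out_dir = out_dir))
}
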