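#' @title Allele-specific qPCR carrier calling
#' @description
#' The mutant-specific channel amplifies early in carriers and late
#' (unspecifically) in non-carriers, giving two well-separated Ct
#' distributions per plate. Calling proceeds per plate: control-channel
#' QC, a bagged-clustering discrimination threshold, a two-component
#' normal fit, and exclusion of samples falling in the overlap of the
#' upper carrier and lower non-carrier quantile tails.
#' @name ct_genotyping
NULL

CALL_STATUSES <- c("carrier", "non_carrier", "excluded_ambiguous",
                   "excluded_pcr_failure", "no_carrier_cluster")

#' Control-channel quality control
#'
#' A positive amplification control detects false-negative wells caused by
#' PCR failure: wells whose control channel did not amplify (missing Ct)
#' or amplified later than `control_cutoff` are routed to
#' `excluded_pcr_failure`.
#'
#' @param records data.frame with columns `sample_id`, `ct_mutant`,
#'   `ct_control` (missing Ct encoded as `NA`).
#' @param control_cutoff latest acceptable control Ct (cycles).
#' @return list with `passing` and `failures` data.frames.
#' @export
qc_control <- function(records, control_cutoff = 35) {
  if (nrow(records) == 0L) stop("no records supplied")
  fail <- is.na(records$ct_control) | records$ct_control > control_cutoff
  if (all(fail)) warning("all samples failed control-channel QC")
  list(passing = records[!fail, , drop = FALSE],
       failures = records[fail, , drop = FALSE])
}

# one Lloyd pass-to-convergence 2-means in 1-D, initialized at given centers
kmeans_1d_2 <- function(x, init) {
  centers <- sort(init)
  for (i in 1:100) {
    mid <- mean(centers)
    lo <- x < mid
    if (!any(lo) || all(lo)) break
    new <- c(mean(x[lo]), mean(x[!lo]))
    if (max(abs(new - centers)) < 1e-12) {
      centers <- new
      break
    }
    centers <- new
  }
  centers
}

#' Bagged-clustering discrimination threshold
#'
#' Estimates the Ct threshold separating carriers from non-carriers by
#' bagging a 1-D 2-means clusterer: each of `n_bootstrap` bootstrap
#' resamples is clustered into two classes (centers initialized at the
#' resample minimum and maximum), the sorted center pairs are averaged
#' across replicates, and the threshold is the midpoint of the two
#' aggregated centers. Deterministic given `seed`.
#'
#' @param cts numeric vector of mutant-channel Ct values (no `NA`).
#' @param n_bootstrap number of bootstrap replicates.
#' @param min_separation minimum aggregated center separation (cycles)
#'   required to accept a two-cluster structure; below it the plate is
#'   declared carrier-free (`no_carrier_cluster`).
#' @param seed integer RNG seed.
#' @return list with `threshold`, `centers` (length-2, sorted),
#'   `separation`, and logical `no_carrier_cluster`.
#' @export
find_threshold <- function(cts, n_bootstrap = 100L, min_separation = 3,
                           seed = 1L) {
  cts <- sort(cts[!is.na(cts)])  # sample-order invariance
  if (length(unique(cts)) < 2L)
    return(list(threshold = NA_real_, centers = c(NA_real_, NA_real_),
                separation = 0, no_carrier_cluster = TRUE))
  set.seed(seed)
  centers <- matrix(NA_real_, n_bootstrap, 2)
  n <- length(cts)
  for (b in seq_len(n_bootstrap)) {
    xs <- cts[sample.int(n, n, replace = TRUE)]
    if (length(unique(xs)) < 2L) xs <- cts  # degenerate resample: fall back
    centers[b, ] <- kmeans_1d_2(xs, c(min(xs), max(xs)))
  }
  agg <- colMeans(centers)
  sep <- agg[2] - agg[1]
  if (sep < min_separation)
    return(list(threshold = NA_real_, centers = agg, separation = sep,
                no_carrier_cluster = TRUE))
  list(threshold = mean(agg), centers = agg, separation = sep,
       no_carrier_cluster = FALSE)
}

#' Fit the two-component normal calling model
#'
#' Fits one normal component to the Ct values on each side of the
#' discrimination threshold and derives the ambiguity-exclusion interval
#' as the open interval between the upper `1 - alpha_tail` quantile of
#' the carrier component and the lower `alpha_tail` quantile of the
#' non-carrier component (empty when they cross).
#'
#' @param cts numeric vector of mutant-channel Ct values.
#' @param threshold discrimination threshold (cycles).
#' @param alpha_tail per-tail exclusion fraction; 0.025 is the
#'   conservative default, 0.01 the laxer alternative.
#' @return an object of class `plate_call_model`: threshold, component
#'   means/SDs, `ambiguous_interval` (length-2 numeric, or `NULL` when
#'   empty), `alpha_tail`.
#' @export
fit_components <- function(cts, threshold, alpha_tail = 0.025) {
  cts <- cts[!is.na(cts)]
  if (alpha_tail <= 0 || alpha_tail >= 0.5)
    stop("'alpha_tail' must be in (0, 0.5)")
  lo <- cts[cts < threshold]
  hi <- cts[cts >= threshold]
  if (length(lo) < 2L || length(hi) < 2L)
    stop("need at least 2 samples on each side of the threshold")
  floor_sd <- function(s) {
    if (is.na(s) || s < 0.01) {
      warning("within-component SD floored at 0.01 cycles")
      0.01
    } else s
  }
  cm <- mean(lo); cs <- floor_sd(sd(lo))
  nm <- mean(hi); ns <- floor_sd(sd(hi))
  lower <- qnorm(1 - alpha_tail, cm, cs)
  upper <- qnorm(alpha_tail, nm, ns)
  interval <- if (lower < upper) c(lower, upper) else NULL
  structure(list(threshold = threshold, carrier_mu = cm, carrier_sigma = cs,
                 noncarrier_mu = nm, noncarrier_sigma = ns,
                 alpha_tail = alpha_tail, ambiguous_interval = interval),
            class = "plate_call_model")
}

#' Classify samples with a fitted plate model
#'
#' A Ct inside the open ambiguous interval cannot be assigned to either
#' component and is excluded; otherwise the sample is a carrier iff its
#' Ct is below the threshold. A missing mutant-channel Ct with passing
#' control means no mutant amplification at all, i.e. a non-carrier.
#'
#' @param records data.frame with `sample_id` and `ct_mutant` (QC-passed).
#' @param model a `plate_call_model`.
#' @return data.frame (sample_id, status).
#' @export
classify <- function(records, model) {
  stopifnot(inherits(model, "plate_call_model"))
  ct <- records$ct_mutant
  status <- ifelse(is.na(ct), "non_carrier",
            ifelse(ct < model$threshold, "carrier", "non_carrier"))
  iv <- model$ambiguous_interval
  if (!is.null(iv))
    status[!is.na(ct) & ct > iv[1] & ct < iv[2]] <- "excluded_ambiguous"
  data.frame(sample_id = records$sample_id, status = status,
             stringsAsFactors = FALSE)
}

call_one_plate <- function(records, control_cutoff, alpha_tail,
                           n_bootstrap, min_separation, seed) {
  qc <- qc_control(records, control_cutoff)
  fail_calls <- if (nrow(qc$failures))
    data.frame(sample_id = qc$failures$sample_id,
               status = "excluded_pcr_failure", stringsAsFactors = FALSE)
  else NULL
  pass <- qc$passing
  cts <- pass$ct_mutant[!is.na(pass$ct_mutant)]
  thr <- find_threshold(cts, n_bootstrap = n_bootstrap,
                        min_separation = min_separation, seed = seed)
  if (thr$no_carrier_cluster ||
      sum(cts < thr$threshold) < 2L || sum(cts >= thr$threshold) < 2L) {
    # carrier-free (or unsplittable) plate: everything that amplified the
    # control is a non-carrier
    calls <- data.frame(sample_id = pass$sample_id, status = "non_carrier",
                        stringsAsFactors = FALSE)
    return(list(calls = rbind(fail_calls, calls), model = NULL,
                no_carrier_cluster = TRUE))
  }
  model <- fit_components(cts, thr$threshold, alpha_tail = alpha_tail)
  calls <- classify(pass, model)
  list(calls = rbind(fail_calls, calls), model = model,
       no_carrier_cluster = FALSE)
}

#' Call carrier status across qPCR plates
#'
#' Runs the full per-plate pipeline (control QC, bagged threshold,
#' two-component fit, ambiguity exclusion), checks that any designated
#' positive-control sample is called identically on every plate, and
#' summarizes carrier frequency among called samples and the exclusion
#' fraction among all samples.
#'
#' @param records data.frame with `sample_id`, `plate_id`, `ct_mutant`,
#'   `ct_control`.
#' @param control_cutoff latest acceptable control Ct.
#' @param alpha_tail per-tail ambiguity-exclusion fraction.
#' @param n_bootstrap bagging replicates for the threshold.
#' @param min_separation minimum cluster-center separation (cycles).
#' @param positive_control_ids sample IDs of the shared positive-control
#'   sample, one per plate (optional).
#' @param seed integer RNG seed (per-plate seeds are derived from it).
#' @return list of class `plate_calls`: `calls` (sample_id, plate_id,
#'   status), `models` (per-plate `plate_call_model` or `NULL`),
#'   `flagged_plates` (no_carrier_cluster), `summary` (n, n_carrier,
#'   carrier_frequency, exclusion_rate), `positive_control_consistent`.
#' @export
call_plates <- function(records, control_cutoff = 35, alpha_tail = 0.025,
                        n_bootstrap = 100L, min_separation = 3,
                        positive_control_ids = character(), seed = 1L) {
  stopifnot(nrow(records) > 0L, "plate_id" %in% names(records))
  plates <- split(records, records$plate_id)
  models <- vector("list", length(plates))
  names(models) <- names(plates)
  flagged <- character()
  calls <- NULL
  for (i in seq_along(plates)) {
    pid <- names(plates)[i]
    res <- call_one_plate(plates[[i]], control_cutoff, alpha_tail,
                          n_bootstrap, min_separation,
                          seed = seed + i)
    res$calls$plate_id <- pid
    models[[i]] <- res$model
    if (res$no_carrier_cluster) flagged <- c(flagged, pid)
    calls <- rbind(calls, res$calls)
  }
  pc <- calls[calls$sample_id %in% positive_control_ids, , drop = FALSE]
  pc_consistent <- length(unique(pc$status)) <= 1L
  called <- calls$status %in% c("carrier", "non_carrier")
  excluded <- calls$status %in% c("excluded_ambiguous",
                                  "excluded_pcr_failure")
  summary <- data.frame(
    n = nrow(calls),
    n_carrier = sum(calls$status == "carrier"),
    carrier_frequency = if (any(called))
      sum(calls$status == "carrier") / sum(called) else NA_real_,
    exclusion_rate = mean(excluded))
  structure(list(calls = calls[, c("sample_id", "plate_id", "status")],
                 models = models, flagged_plates = flagged,
                 summary = summary,
                 positive_control_consistent = pc_consistent),
            class = "plate_calls")
}
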