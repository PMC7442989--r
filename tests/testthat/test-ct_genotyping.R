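test_that("control-channel QC routes failures and boundary cases", {
  rec <- data.frame(sample_id = c("a", "b", "c"),
                    ct_mutant = c(31, 38, 38),
                    ct_control = c(NA, 25, 36))
  qc <- qc_control(rec, control_cutoff = 35)
  expect_identical(qc$passing$sample_id, "b")
  expect_identical(sort(qc$failures$sample_id), c("a", "c"))
  expect_warning(qc_control(rec, control_cutoff = 10), "all samples")
  expect_error(qc_control(rec[0, ]), "no records")
})

test_that("bagged threshold is the midpoint for a symmetric two-point plate", {
  cts <- c(30, 30, 30, 38, 38, 38)
  thr <- find_threshold(cts, n_bootstrap = 50, seed = 4)
  expect_false(thr$no_carrier_cluster)
  expect_equal(thr$threshold, 34)
  expect_equal(thr$centers, c(30, 38))
})

test_that("threshold separates truth classes on simulated plates and is seed-deterministic", {
  for (s in 1:25) {
    sim <- simulate_ct_plate(ct_plate_params(seed = s), plate_id = "P")
    tr <- sim$truth
    ct <- sim$records$ct_mutant
    thr <- find_threshold(ct[!is.na(ct)], seed = s)
    carr_ct <- ct[tr$truth == "carrier"]
    non_ct <- ct[tr$truth == "non_carrier"]
    if (length(carr_ct)) {
      expect_gt(thr$threshold, max(carr_ct))
      expect_lt(thr$threshold, min(non_ct))
    }
  }
  cts <- simulate_ct_plate(ct_plate_params(seed = 1))$records$ct_mutant
  cts <- cts[!is.na(cts)]
  expect_identical(find_threshold(cts, seed = 5), find_threshold(cts, seed = 5))
  # permutation invariance of the data (resampling depends only on values
  # drawn, so shuffle + same seed must agree)
  expect_equal(find_threshold(sort(cts), seed = 5)$threshold,
               find_threshold(rev(sort(cts)), seed = 5)$threshold,
               tolerance = 1e-9)
})

test_that("a single tight cluster is declared carrier-free", {
  set.seed(31)
  cts <- rnorm(300, 38, 0.5)
  thr <- find_threshold(cts, seed = 2)
  expect_true(thr$no_carrier_cluster)
  expect_lt(thr$separation, 3)
  expect_true(find_threshold(rep(38, 10))$no_carrier_cluster)
})

test_that("two-component fit reproduces normal-quantile exclusion bounds", {
  cts <- exact_moment_plate(60, 31, 0.5, 300, 38.5, 0.6, seed = 6)
  m <- fit_components(cts, threshold = 34.5, alpha_tail = 0.025)
  expect_equal(m$carrier_mu, 31)
  expect_equal(m$noncarrier_sigma, 0.6)
  expect_equal(m$ambiguous_interval,
               c(31 + qnorm(0.975) * 0.5, 38.5 + qnorm(0.025) * 0.6),
               tolerance = 1e-9)
  expect_equal(m$ambiguous_interval, c(31.98, 37.32), tolerance = 1e-3)
})

test_that("the conservative 2.5% interval contains the 1% interval", {
  # smaller per-tail fraction pushes each bound toward its own component,
  # narrowing the exclusion zone: interval(0.01) is nested in interval(0.025)
  cts <- exact_moment_plate(60, 31, 0.5, 300, 38.5, 0.6, seed = 6)
  iv25 <- fit_components(cts, 34.5, alpha_tail = 0.025)$ambiguous_interval
  iv01 <- fit_components(cts, 34.5, alpha_tail = 0.01)$ambiguous_interval
  expect_lt(iv25[1], iv01[1])
  expect_gt(iv25[2], iv01[2])
})

test_that("heavily overlapping components give an empty interval", {
  cts <- exact_moment_plate(50, 33, 2, 50, 35, 2, seed = 8)
  m <- fit_components(cts, 34, alpha_tail = 0.025)
  expect_null(m$ambiguous_interval)
  calls <- classify(data.frame(sample_id = "x", ct_mutant = 34.5), m)
  expect_identical(calls$status, "non_carrier")
})

test_that("classification follows threshold, interval and no-amplification rules", {
  cts <- exact_moment_plate(60, 31, 0.5, 300, 38.5, 0.6, seed = 6)
  m <- fit_components(cts, 34.5, alpha_tail = 0.025)
  rec <- data.frame(sample_id = c("car", "amb", "non", "noamp"),
                    ct_mutant = c(30.5, 35.0, 38.6, NA))
  calls <- classify(rec, m)
  expect_identical(calls$status,
                   c("carrier", "excluded_ambiguous", "non_carrier",
                     "non_carrier"))
  # monotonicity: lowering a Ct never flips carrier -> non_carrier
  grid <- seq(29, 42, by = 0.05)
  st <- classify(data.frame(sample_id = as.character(grid),
                            ct_mutant = grid), m)$status
  carrier_idx <- which(st == "carrier")
  expect_true(all(diff(carrier_idx) == 1))  # carriers form a leftmost block
  expect_identical(st[1], "carrier")
})

test_that("plate pipeline calls simulated plates with consistent positive controls", {
  n_mis <- 0L
  for (s in 1:10) {
    sim <- simulate_ct_plate(ct_plate_params(seed = 100 + s),
                             plate_id = paste0("P", s))
    rec <- sim$records
    # shared positive-control sample, a known carrier, one well per plate
    rec <- rbind(rec, data.frame(sample_id = "PC", plate_id = paste0("P", s),
                                 ct_mutant = 30.9, ct_control = 26))
    cp <- call_plates(rec, positive_control_ids = "PC", seed = s)
    expect_true(cp$positive_control_consistent)
    tr <- merge(cp$calls, sim$truth, by = "sample_id")
    called <- tr[tr$status %in% c("carrier", "non_carrier") &
                   tr$truth %in% c("carrier", "non_carrier"), ]
    n_mis <- n_mis + sum(called$status != called$truth)
  }
  expect_identical(n_mis, 0L)
})

test_that("carrier-free plates are flagged and called all non-carrier", {
  sim <- simulate_ct_plate(ct_plate_params(carrier_frequency = 0,
                                           intermediate_rate = 0,
                                           seed = 55), plate_id = "P0")
  cp <- call_plates(sim$records, seed = 1)
  expect_identical(cp$flagged_plates, "P0")
  expect_identical(cp$summary$n_carrier, 0L)
  expect_true(all(cp$calls$status %in% c("non_carrier",
                                         "excluded_pcr_failure")))
})

test_that("re-calling the same plate yields identical calls", {
  sim <- simulate_ct_plate(ct_plate_params(seed = 77))
  a <- call_plates(sim$records, seed = 9)
  b <- call_plates(sim$records, seed = 9)
  expect_identical(a$calls, b$calls)
})
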