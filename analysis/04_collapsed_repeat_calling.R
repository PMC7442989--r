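#!/usr/bin/env Rscript
# Collapsed-repeat carrier calling on the simulated 1000G-style pileups:
# per-sample binomial calling at the 1% mutation level, coverage-tiered
# population summaries, and the minimal-coverage table behind the
# 340x/780x high-confidence presets.

library(lpakiv2)

out <- "results"
pu <- read_pileup_tsv("results/sim/pileups.tsv")
truth <- read.delim("results/sim/pileups_truth.tsv")

calls <- call_pileups(pu, level_cutoff = 0.01, error_rate = 1e-3)
tiers <- do.call(rbind, lapply(
  c("unfiltered", "coverage_340", "coverage_780"),
  function(t) population_summary(calls, tier = t)))
write.table(tiers, file.path(out, "pileup_tiers.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
for (i in seq_len(nrow(tiers)))
  message(sprintf("%s / %s: %d of %d carriers (frequency %.4f)",
                  tiers$group[i], tiers$tier[i], tiers$carriers[i],
                  tiers$individuals[i], tiers$carrier_frequency[i]))

agree <- mean(calls$status == truth$truth)
message(sprintf("agreement with simulation truth: %.2f%%", 100 * agree))

mc <- rbind(
  data.frame(method = "preset_single",
             min_coverage_table(0.01, "preset", "single")),
  data.frame(method = "preset_paired",
             min_coverage_table(0.01, "preset", "paired")),
  data.frame(method = "wald", min_coverage_table(0.01, "wald")),
  data.frame(method = "wilson", min_coverage_table(0.01, "wilson")),
  data.frame(method = "clopper-pearson",
             min_coverage_table(0.01, "clopper-pearson")))
write.table(mc, file.path(out, "min_coverage.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(paste(capture.output(print(mc, row.names = FALSE)), collapse = "\n"))
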