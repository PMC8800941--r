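#!/usr/bin/env Rscript
# Extract the 131-feature panel from every simulated scan (test-retest and
# longitudinal cohorts written by 01_simulate.R) and write feature tables
# under results/features/.

suppressPackageStartupMessages(library(petrad))

dir.create("results/features", showWarnings = FALSE, recursive = TRUE)

for (set in c("retest_day1", "retest_day2", "longitudinal")) {
  src <- file.path("results/cohorts", set)
  if (!dir.exists(src)) stop("run analysis/01_simulate.R first")
  message("Extracting ", set, " ...")
  scans <- read_cohort_nifti(src)
  tab <- extract_feature_table(scans)
  utils::write.csv(tab, file.path("results/features", paste0(set, ".csv")),
                   row.names = FALSE)
  message("  ", nrow(tab), " scans x ", length(feature_columns(tab)),
          " features")
}

manifest <- feature_manifest()
jsonlite::write_json(manifest, "results/features/manifest.json",
                     auto_unbox = TRUE)
message("Panel: ", nrow(manifest), " features (",
        sum(manifest$family == "first_order"), " first-order)")
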