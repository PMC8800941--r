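#!/usr/bin/env Rscript
# Screen the 129 non-volume features for robustness: test-retest
# reproducibility (Lin's concordance >= 0.7), redundancy (Spearman rho >=
# 0.9, P < 0.001, keep the higher-LCC member), and tumor-volume dependency
# (Spearman flag + AIC/BIC functional-form selection). Writes the report and
# a repeatability histogram under results/robustness/.

suppressPackageStartupMessages(library(petrad))

day1 <- utils::read.csv("results/features/retest_day1.csv", check.names = FALSE)
day2 <- utils::read.csv("results/features/retest_day2.csv", check.names = FALSE)
feat <- utils::read.csv("results/features/longitudinal.csv", check.names = FALSE)
bl <- feat[feat$timepoint == "BL", ]

screen <- robustness_screen(day1, day2, bl)
print(screen)

dir.create("results/robustness", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(screen$report, "results/robustness/report.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(n_screened = screen$n_screened,
       n_reproducible = sum(screen$report$lcc_pass, na.rm = TRUE),
       n_redundancy_dropped = sum(screen$report$redundancy_dropped),
       n_volume_flagged = sum(screen$report$volume_flagged),
       n_clusters = screen$n_clusters,
       robust_features = screen$robust_features),
  "results/robustness/summary.json", auto_unbox = TRUE)

# LCC histogram with cumulative percent (repeatability figure analog)
grDevices::pdf("results/robustness/lcc_histogram.pdf", width = 6, height = 4)
h <- graphics::hist(screen$report$lcc, breaks = seq(-1, 1, by = 0.1),
                    main = "Test-retest repeatability",
                    xlab = "Lin's concordance correlation", col = "grey80")
graphics::abline(v = 0.7, lty = 2)
cum <- cumsum(rev(h$counts)) / sum(h$counts) * max(h$counts)
graphics::lines(rev(h$mids), cum, type = "b", pch = 16, cex = 0.5)
grDevices::dev.off()

# correlation heatmap with dendrogram ordering
ord <- screen$clustering$order
grDevices::pdf("results/robustness/correlation_heatmap.pdf", width = 6,
               height = 6)
graphics::image(abs(screen$spearman$rho[ord, ord]), axes = FALSE,
                main = sprintf("|Spearman rho| (%d clusters)",
                               screen$n_clusters))
grDevices::dev.off()
message("Robust set: ", length(screen$robust_features), " of ",
        screen$n_screened, " screened features")
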