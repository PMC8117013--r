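#!/usr/bin/env Rscript
# Stage 4: rank year-to-year mean BAI increases and decreases per
# chronology and flag coincidences with the recorded spruce budworm window
# (1970-1978, peak 1974) and forest tent caterpillar years (1980, 2000,
# 2001).

suppressPackageStartupMessages(library(dendromix))
chron <- read.csv("results/chronologies.csv")

ranks <- do.call(rbind, lapply(unique(chron$group), function(g)
  cbind(group = g, rank_first_differences(chron[chron$group == g, ]))))
write.csv(ranks, "results/rankings.csv", row.names = FALSE)

top <- ranks[!is.na(ranks$decrease_rank) & ranks$decrease_rank <= 3, ]
cat("three largest year-over-year drops per chronology:\n")
print(top[order(top$group, top$decrease_rank),
          c("group", "year", "diff_cm2", "decrease_rank",
            "sbw_window", "ftc_year")], digits = 3, row.names = FALSE)
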