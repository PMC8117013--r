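#!/usr/bin/env Rscript
# Stage 3: bootstrapped correlation functions between each mean BAI
# chronology and monthly average temperature / total precipitation for
# January-September of the formation year, plus the April+September
# (season length) and June-August (summer heat) composites.

suppressPackageStartupMessages(library(dendromix))
climate <- read.csv("results/data/climate.csv")
chron <- read.csv("results/chronologies.csv")

tabs <- lapply(unique(chron$group), function(g) {
  ch <- chron[chron$group == g, ]
  attr(ch, "group") <- g
  correlation_function(ch, climate, n_boot = 1000,
                       seed = 100 + match(g, unique(chron$group)))
})
corr <- do.call(rbind, tabs)
write.csv(corr, "results/correlations.csv", row.names = FALSE)

sig <- corr[corr$significant, ]
cat(sprintf("%d of %d chronology x window correlations significant\n",
            nrow(sig), nrow(corr)))
cat("significant composite-window correlations:\n")
print(sig[sig$window %in% c("AprSep", "JunAug"), ], digits = 2)
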