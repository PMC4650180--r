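#!/usr/bin/env Rscript
# Classify every daytime immersion block (dry = flight, wet = resting on
# the water, intermediate = foraging) and reduce each bird-winter to
# daily activity budgets.

suppressPackageStartupMessages(library(shearwaterCOE))

imm <- read_immersion_csv("results/data/immersion.csv")
profiles <- daily_profiles(imm, thresholds = c(0.05, 0.95))

dir.create("results", showWarnings = FALSE)
write.csv(profiles, "results/daily_profiles.csv", row.names = FALSE)

cat("Daily activity budgets:\n")
cat("  ", nrow(profiles), "bird-days across",
    length(unique(profiles$bird_id)), "birds\n")
cat(sprintf("  mean daytime budget: fly %.3f, rest %.3f, forage %.3f\n",
            mean(profiles$p_fly), mean(profiles$p_rest),
            mean(profiles$p_forage)))
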