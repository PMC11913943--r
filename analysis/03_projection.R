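#!/usr/bin/env Rscript
# Projection arithmetic on the published simulated areas for 2028 and 2033:
# woody expansion as percent of the (constant) region, plus the projected
# grass losses from the published future transition flows.

suppressMessages(library(encroachr))
dir.create("results", showWarnings = FALSE)

total <- sum(bisley_class_areas(2009))
proj <- bisley_class_areas(c(2023, 2028, 2033))
pc <- change_summaries(proj, total_area = total)$percent_cover
cat("Percent cover, observed 2023 and projected 2028/2033:\n")
print(round(pc, 2))

expansion <- diff(pc["woody", ])
cat(sprintf("\nWoody expansion: %+.2f points to 2028, %+.2f points to 2033\n",
            expansion[1], expansion[2]))

fut <- bisley_transitions()
fut <- fut[fut$interval %in% c("2023-2028", "2028-2033"), ]
gl <- fut[fut$from == "grasses" & fut$to == "woody", ]
cat(sprintf("Projected grass lost to woody: %.2f ha (2023-2028), %.2f ha (2028-2033)\n",
            gl$area_ha[1], gl$area_ha[2]))

out <- data.frame(year = colnames(pc), t(pc), check.names = FALSE,
                  row.names = NULL)
write.csv(out, "results/projection.csv", row.names = FALSE)
cat("\nwrote results/projection.csv\n")
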