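#!/usr/bin/env Rscript
# Simulates telemetry from the ground-truth RSF for both study periods,
# subsamples one fix per animal-day, estimates the 99% kernel home
# ranges and builds the 1:1 used/available design tables.

library(snowrsf)

res <- run_experiment(default_run_config(1))
dir.create("results", showWarnings = FALSE)

summ <- do.call(rbind, lapply(names(res$used), function(p) {
  u <- res$used[[p]]
  d <- res$designs[[p]]
  data.frame(
    period = p,
    raw_fixes = nrow(res$relocations[[p]]),
    used_points = nrow(u),
    animals = length(unique(u$animal_id)),
    winters = length(unique(u$winter)),
    design_rows = nrow(d),
    available_points = sum(d$case == 0),
    home_range_cells = sum(res$polygons[[p]]$mask$values == 1)
  )
}))
write.csv(summ, "results/design_summary.csv", row.names = FALSE)
print(summ, row.names = FALSE)
for (p in names(res$used))
  write.csv(res$used[[p]], sprintf("results/used_%s.csv", p), row.names = FALSE)
cat("\nused:available is 1:1 by construction; ",
    "available points inherit their paired month's snow layer\n", sep = "")
cat("wrote results/design_summary.csv and results/used_*.csv\n")
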