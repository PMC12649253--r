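#!/usr/bin/env Rscript
# Stage 2: score CES-D responses and classify symptom states.
# Reads panel.csv (total-score or item-level dialect), applies the
# five-state rules (episode at total >= 12, persistence, remission,
# relapse), and writes states.csv and events.csv.

library(depstate)
cfg <- yaml::read_yaml(file.path("analysis", "config.yaml"))

panel <- read.csv(file.path(cfg$out_dir, "panel.csv"))
cls <- classify_panel(panel)

counts <- tabulate_events(cls)
cat("Classified", length(cls$sequences), "subjects\n")
cat("Observed transition events:\n")
print(counts)
cat("(episodes", counts[["12"]], "| persistence", counts[["23"]],
    "| remission", counts[["24"]] + counts[["34"]],
    "| relapse", counts[["45"]], ")\n")

write.csv(cls$states, file.path(cfg$out_dir, "states.csv"), row.names = FALSE)
write.csv(cls$events, file.path(cfg$out_dir, "events.csv"), row.names = FALSE)
cat("Wrote states.csv and events.csv\n")
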