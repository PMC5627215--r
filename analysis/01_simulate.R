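#!/usr/bin/env Rscript
# Simulate the playback experiment: 15 ambient + 15 pile-driving groups of
# four fish, two consecutive halves (silence, then playback), in paired
# random blocks. Writes the trajectory CSVs and the design table under
# results/experiment/.

suppressMessages(library(shoalnoise))

seed <- 20260924
out <- "results/experiment"

experiment <- generate_experiment(
  n_groups_per_treatment = 15,
  ambient_spec = ambient_disruption(),
  pile_spec = pile_driving_disruption(),
  base_cfg = sim_config(),
  master_seed = seed
)
write_experiment(experiment, out)

cat("Simulated", length(experiment$trials), "trials into", out, "\n")
cat("Treatments:", paste(capture.output(table(experiment$design$treatment)),
                         collapse = " "), "\n")
cat("Master seed:", seed, "\n")
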