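#!/usr/bin/env Rscript
# Step 1: generate the synthetic multi-site common-garden dataset that
# the rest of the workflow analyses, and write it as CSV under
# results/data/. The default configuration emulates a global
# compilation: 136 sites, 2-5 mono-specific stands each, mixtures at
# ~14% of sites, and a latent plant-economics-spectrum trait model.

library(soctraits)

cfg <- sim_config(seed = 1L)
d <- simulate_dataset(cfg)
write_fixture(d, "results/data")

cat("sites:      ", nrow(d$sites), "\n")
cat("stands:     ", nrow(d$stands), "\n")
cat("soil layers:", nrow(d$soil_layers), "\n")
cat("trait obs:  ", nrow(d$traits), "\n")
cat("mixtures:   ", nrow(d$mixtures), "(",
    length(unique(d$mixtures$site_id)), "sites )\n")
cat("written to results/data/\n")
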