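#!/usr/bin/env Rscript
# Generate the synthetic study region used by the downstream analyses:
# a grid road network at the published facility roster scale (44 hospitals,
# 347 health promoting hospitals, 14 with POCT today, one tertiary care
# center) and 300 typed populated places carrying default populations.

suppressMessages(library(scpath))

seed <- 1
cfg <- region_config(seed = seed)
reg <- generate_region(cfg)

dir.create("results/region", recursive = TRUE, showWarnings = FALSE)
meta <- c(seed = as.character(seed), config_hash = config_hash(unclass(cfg)))
paths <- write_layers(reg, "results/region", meta)
write_manifest("results/region/manifest.json", as.list(paths),
               unclass(cfg), seed)

message(sprintf("region: %d roads, %d places (%s)", nrow(reg$roads),
                nrow(reg$places),
                paste(capture.output(print(table(reg$places$place_type))),
                      collapse = " ")))
message(sprintf("facilities: %d, care site %s, current POCT at %d hospitals",
                nrow(reg$facilities), reg$care_site,
                length(reg$current_poct)))
message("layers written to results/region/")
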