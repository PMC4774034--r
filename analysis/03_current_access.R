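#!/usr/bin/env Rscript
# Quantify current health care access: route every populated place to its
# closest POCT-equipped hospital, then onward to the care center, and
# summarize with population weights and the 15-minute histogram.

suppressMessages(library(scpath))

layers <- read_layers(list(roads = "results/region/roads.csv",
                           places = "results/region/places.csv",
                           facilities = "results/region/facilities.csv"))
net <- read_network_csv("results/network")
current_poct <- layers$facilities$id[layers$facilities$has_poct]
care_site <- layers$facilities$id[layers$facilities$kind == "care_center"]

s <- run_scenario(net, layers$places, layers$facilities,
                  scenario_spec("current", care_site,
                                poct_sites = current_poct))
print(s)

write_scp_csv(s$paths, "results/current_care_paths.csv")
write_scp_csv(s$histogram_15min, "results/current_histogram_15min.csv")
message(sprintf(
  "current access: %.1f min to diagnosis, %.1f min to care (total %.1f); %d routes in %d 15-min bins",
  s$mean_diag_min, s$mean_care_min, s$mean_total_min, s$n_routes,
  nrow(s$histogram_15min)))
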