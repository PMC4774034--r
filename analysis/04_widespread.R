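#!/usr/bin/env Rscript
# Widespread POCT adoption: compare current access against placing POCT in
# every hospital and in every health resource facility, mirroring the
# policy-level deployment comparison.

suppressMessages(library(scpath))

layers <- read_layers(list(roads = "results/region/roads.csv",
                           places = "results/region/places.csv",
                           facilities = "results/region/facilities.csv"))
net <- read_network_csv("results/network")
current_poct <- layers$facilities$id[layers$facilities$has_poct]
care_site <- layers$facilities$id[layers$facilities$kind == "care_center"]

run <- function(name, sites = NULL, rule = "explicit") {
  run_scenario(net, layers$places, layers$facilities,
               scenario_spec(name, care_site, poct_sites = sites, rule = rule))
}
current <- run("current", sites = current_poct)
all_h <- run("all_hospitals", rule = "all_hospitals")
all_f <- run("all_facilities", rule = "all_facilities")

tb <- compare_scenarios(current, list(all_h, all_f))
write_scp_csv(tb, "results/widespread_comparison.csv")
print(tb[, c("scenario", "mean_diag_min", "pct_decrease_diag",
             "mean_total_min", "pct_decrease_total")])
message(sprintf(
  "stage-1 gap between the widespread strategies: %.1f min; total-access gap %.1f points",
  all_h$mean_diag_min - all_f$mean_diag_min,
  tb$pct_decrease_total[3] - tb$pct_decrease_total[2]))
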