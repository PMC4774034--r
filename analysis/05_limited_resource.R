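#!/usr/bin/env Rscript
# Limited-resource POCT deployment: the five location-allocation strategies
# (rearrange existing units; keep them and add 5 or 10; rearrange and add 5
# or 10), each solved as a constrained P-median over all facilities with
# population-weighted time to diagnosis as the objective.

suppressMessages(library(scpath))

seed <- 1
layers <- read_layers(list(roads = "results/region/roads.csv",
                           places = "results/region/places.csv",
                           facilities = "results/region/facilities.csv"))
net <- read_network_csv("results/network")
current_poct <- layers$facilities$id[layers$facilities$has_poct]
care_site <- layers$facilities$id[layers$facilities$kind == "care_center"]

current <- run_scenario(net, layers$places, layers$facilities,
                        scenario_spec("current", care_site,
                                      poct_sites = current_poct))

strategies <- list(
  rearrange = list(strategy = "rearrange", k_extra = 0),
  keep_plus_5 = list(strategy = "keep_plus_k", k_extra = 5),
  keep_plus_10 = list(strategy = "keep_plus_k", k_extra = 10),
  rearrange_plus_5 = list(strategy = "rearrange_plus_k", k_extra = 5),
  rearrange_plus_10 = list(strategy = "rearrange_plus_k", k_extra = 10)
)
summaries <- list()
for (nm in names(strategies)) {
  st <- strategies[[nm]]
  opt <- optimize_poct(net, layers$places, layers$facilities, st$strategy,
                       k_extra = st$k_extra, current_poct = current_poct,
                       care_site = care_site, method = "heuristic",
                       seed = seed)
  jsonlite::write_json(
    list(strategy = nm, chosen = opt$solution$chosen,
         objective = opt$solution$objective),
    sprintf("results/solution_%s.json", nm), auto_unbox = TRUE, digits = NA)
  summaries[[nm]] <- run_scenario(net, layers$places, layers$facilities,
                                  scenario_spec(nm, care_site,
                                                poct_sites = opt$sites))
  message(sprintf("%-18s objective %.0f, mean to diagnosis %.1f min",
                  nm, opt$solution$objective,
                  summaries[[nm]]$mean_diag_min))
}

tb <- compare_scenarios(current, summaries)
write_scp_csv(tb, "results/limited_resource_comparison.csv")
print(tb[, c("scenario", "mean_diag_min", "pct_decrease_diag",
             "mean_total_min", "pct_decrease_total")])
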