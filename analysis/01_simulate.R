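#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Builds a floodplain-terra firme landscape around a sinuous river channel,
# simulates a terra firme species' latent occupancy on the HAND gradient,
# records hour-scale acoustic surveys at 25 recorder sites spanning the
# gradient, and draws citizen-science checklists whose effort concentrates
# at riverside lodges. Writes the raw tables under results/.

suppressMessages(library(birdpool))
seed <- 101
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed, nrow = 50, ncol = 50,
                  occ_intercept = -6, occ_beta_hand = 6,
                  checklist_bias = 5, p_hotspot = 0.75, n_hotspots = 3,
                  hotspot_roam_m = 450,
                  vocal_rate = 0.12, false_rate = 0.02,
                  det_intercept = 0.5)
grid <- make_landscape(cfg)
message(sprintf("landscape: %d x %d cells, HAND 0-%.0f m, %d drainage cells",
                grid$nrow, grid$ncol, max(grid$layers$hand),
                sum(grid$layers$drainage)))

aru_sites <- place_aru_sites(grid, 25, seed = derive_seed(seed, "aru_sites"))
occ <- simulate_occupancy(grid, cfg, aru_sites)
message(sprintf("recorder sites: %d, occupied: %d (psi range %.2f-%.2f)",
                nrow(occ), sum(occ$z), min(occ$psi), max(occ$psi)))

sched <- recording_schedule(
  aru_sites, seq(as.Date("2021-06-01"), by = "day", length.out = 18),
  hours = 5:9)
aru <- simulate_aru_surveys(occ, sched, cfg)
message(sprintf("acoustic events: %d (%d true, %d false) over %d recorded hours",
                nrow(aru$events), sum(aru$events$label == "true"),
                sum(aru$events$label == "false"), nrow(sched)))

cl <- simulate_checklists(grid, cfg, 900)
message(sprintf("checklists: %d, raw species reports: %d",
                nrow(cl$checklists), sum(cl$checklists$species_count != "0")))

saveRDS(list(cfg = cfg, grid = grid, aru_sites = aru_sites, occ = occ,
             sched = sched, aru = aru, checklists = cl$checklists),
        "results/01_simulated.rds")
write.table(aru$events, "results/01_detections.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
write.table(cl$checklists, "results/01_checklists.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/01_simulated.rds, 01_detections.csv, 01_checklists.tsv")
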