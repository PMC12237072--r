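#!/usr/bin/env Rscript
# Stage 3: filter, zero-fill, pool and attach habitat covariates.
#
# Applies the checklist effort filters (complete, stationary/traveling,
# duration < 5 h, distance < 1 km, observers < 5, "X" recoding), recasts
# zero-filled acoustic hours as pseudo-checklists, computes multi-scale
# buffer summaries of HAND, canopy and land cover around every survey
# point, and writes the model-ready source tables.

suppressMessages(library(birdpool))
sim <- readRDS("results/01_simulated.rds")
aco <- readRDS("results/02_acoustic.rds")

flt <- filter_checklists(sim$checklists)
rej <- attr(flt, "rejections")
message(sprintf("checklists: %d of %d survive filters (%s)",
                nrow(flt), nrow(sim$checklists),
                paste(names(rej), rej, sep = "=", collapse = ", ")))

ac_tab <- make_pseudo_checklists(aco$zero_filled, sim$aru_sites)
message(sprintf("pseudo-checklists: %d hourly records, prevalence %.2f%%",
                nrow(ac_tab), 100 * mean(ac_tab$presence)))

eb_tab <- flt
eb_tab$site_id <- eb_tab$record_id
pts <- rbind(data.frame(site_id = sim$aru_sites$site_id,
                        x = sim$aru_sites$x, y = sim$aru_sites$y),
             data.frame(site_id = eb_tab$site_id, x = eb_tab$x, y = eb_tab$y))
covs <- reshape_covariates(buffer_summaries(sim$grid, pts,
                                            radii = c(150, 450)))
message(sprintf("buffer covariates: %d sites x %d columns (radii 150/450 m)",
                nrow(covs), ncol(covs) - 1))

add_covs <- function(tab) merge(tab, covs, by = "site_id", sort = FALSE)
eb <- add_covs(eb_tab); ac <- add_covs(ac_tab)
ac$date <- as.Date(ac$date)
keep <- c("site_id", "source", "x", "y", "date", "duration", "distance",
          "observers", "presence",
          grep("^(mean_|sd_|pct_|ed_)", names(eb), value = TRUE))
eb <- eb[, keep]; ac <- ac[, keep]
eb$synthetic <- FALSE; ac$synthetic <- FALSE
message(sprintf("model tables: citizen %d rows (prev %.2f%%), acoustic %d rows (prev %.2f%%)",
                nrow(eb), 100 * mean(eb$presence),
                nrow(ac), 100 * mean(ac$presence)))

saveRDS(list(eb = eb, ac = ac, covs = covs, checklists = flt),
        "results/03_tables.rds")
write.table(covs, "results/03_covariates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/03_tables.rds, 03_covariates.tsv")
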