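# The gradient-biased synthetic study system used for directional
# reproduction checks: a terra firme species on a steep HAND response,
# citizen effort concentrated at riverside lodges ("hotspots") whose trail
# networks reach only partway up the gradient, and sparse hour-scale
# acoustic detections matching field detection rates of a few percent of
# recorded hours.

directional_config <- function(seed) {
  sim_config(seed = seed, nrow = 50, ncol = 50,
             occ_intercept = -6, occ_beta_hand = 6,
             checklist_bias = 5, p_hotspot = 0.75, n_hotspots = 3,
             hotspot_roam_m = 450,
             vocal_rate = 0.12, false_rate = 0.02,
             det_intercept = 0.5)
}

# full pipeline from raw simulation to model-ready source tables
directional_tables <- function(seed, n_checklists = 900, n_aru = 25,
                               n_days = 18, radii = c(150, 450)) {
  cfg <- directional_config(seed)
  g <- make_landscape(cfg)
  aru_sites <- place_aru_sites(g, n_aru, seed = derive_seed(seed, "aru_sites"))
  occ <- simulate_occupancy(g, cfg, aru_sites)
  sched <- recording_schedule(
    aru_sites, seq(as.Date("2021-06-01"), by = "day", length.out = n_days),
    hours = 5:9)
  aru <- simulate_aru_surveys(occ, sched, cfg)
  ann <- stratified_score_sample(aru$events, cap = 30,
                                 seed = derive_seed(seed, "ann"))
  cal <- fit_score_models(ann)
  sel <- select_threshold(cal, ann, fpr_max = 0.05)
  acc <- apply_threshold(aru$events, cal, sel$threshold)
  zf <- zero_fill_acoustic(collapse_independent(acc), sched)
  ac_tab <- make_pseudo_checklists(zf, aru_sites)
  cl <- simulate_checklists(g, cfg, n_checklists)
  flt <- filter_checklists(cl$checklists)
  eb_tab <- flt
  eb_tab$site_id <- eb_tab$record_id
  pts <- rbind(data.frame(site_id = aru_sites$site_id,
                          x = aru_sites$x, y = aru_sites$y),
               data.frame(site_id = eb_tab$site_id,
                          x = eb_tab$x, y = eb_tab$y))
  covs <- reshape_covariates(buffer_summaries(g, pts, radii = radii))
  add_covs <- function(tab) merge(tab, covs, by = "site_id", sort = FALSE)
  eb <- add_covs(eb_tab); ac <- add_covs(ac_tab)
  ac$date <- as.Date(ac$date)
  keep <- c("site_id", "source", "x", "y", "date", "duration", "distance",
            "observers", "presence",
            grep("^(mean_|sd_|pct_|ed_)", names(eb), value = TRUE))
  eb <- eb[, keep]; ac <- ac[, keep]
  eb$synthetic <- FALSE; ac$synthetic <- FALSE
  list(eb = eb, ac = ac, ac_raw = ac_tab, checklists = flt, grid = g)
}

directional_predictors <- function(tabs) {
  c(grep("^(mean_|sd_)", names(tabs$eb), value = TRUE),
    "pct_floodplain_forest_150m", "pct_terra_firme_150m",
    "duration", "distance", "observers")
}

# one encounter-rate replicate: mean sensitivity and PR-AUC per class
directional_encounter <- function(seed, n_boot = 8, num_trees = 150) {
  tabs <- directional_tables(seed)
  if (sum(tabs$eb$presence) < 2 || sum(tabs$ac$presence) < 5) return(NULL)
  b <- suppressMessages(bootstrap_run(
    tabs$eb, tabs$ac, directional_predictors(tabs),
    n_boot = n_boot, num_trees = num_trees, seed = seed + 17))
  m <- summarize_bootstrap(b)
  gv <- function(cl, mt) m$mean[m$class == cl & m$metric == mt]
  list(sens_pooled = gv("pooled", "sensitivity"),
       sens_citizen = gv("citizen", "sensitivity"),
       prauc_pooled = gv("pooled", "pr_auc"),
       prauc_citizen = gv("citizen", "pr_auc"))
}

# one occupancy replicate: evaluation PR-AUC of integrated vs citizen-only
directional_occupancy <- function(seed, n_eval = 100,
                                  mcmc = list(chains = 2, iter = 800,
                                              burn = 300, thin = 2)) {
  tabs <- directional_tables(seed)
  flt <- tabs$checklists
  flt$source <- "citizen"
  cit <- transform(flt[, c("source", "x", "y", "date", "presence",
                           "observer_id", "duration", "distance",
                           "observers", "protocol", "start_time")],
                   site_id = NA, hour = NA)
  aco <- transform(tabs$ac_raw[, c("source", "x", "y", "date", "presence",
                                   "site_id")],
                   observer_id = NA, duration = 1, distance = 0,
                   observers = 1, protocol = "stationary", start_time = NA,
                   hour = as.integer(substr(tabs$ac_raw$start_time, 1, 2)))
  h <- build_histories(rbind(cit, aco), site_grouping_m = 150,
                       seed = derive_seed(seed, "hist"))
  if (nrow(h$sites) < 10) return(NULL)
  pts <- data.frame(site_id = h$sites$site_key, x = h$sites$x, y = h$sites$y)
  covs <- reshape_covariates(buffer_summaries(tabs$grid, pts,
                                              radii = c(150, 450)))
  h <- attach_site_covariates(h, covs)
  hc <- subset_histories(h, h$sites$site_key[h$sites$source == "citizen"])
  if (nrow(hc$sites) < 5 || sum(hc$sites$any_det) < 1) return(NULL)
  fc <- do.call(fit_occupancy,
                c(list(hc, ~ mean_hand_150m, ~ effort_hours,
                       seed = derive_seed(seed, "fitc")), mcmc))
  fi <- do.call(fit_integrated,
                c(list(h, ~ mean_hand_150m, ~ effort_hours,
                       seed = derive_seed(seed, "fiti")), mcmc))
  g1 <- function(f, s) {
    ev <- bootstrap_evaluate(f, h, n = n_eval, seed = derive_seed(seed, s))
    ev$summary$mean[ev$summary$metric == "pr_auc"]
  }
  list(prauc_integrated = g1(fi, "evi"), prauc_citizen = g1(fc, "evc"))
}
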