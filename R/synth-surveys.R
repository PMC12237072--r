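#' Simulate latent occupancy states
#'
#' Draws z_i ~ Bernoulli(psi_i) with
#' logit(psi_i) = intercept + beta_hand * HAND_i / hand_scale +
#' beta_canopy * (canopy_i - 20) / 10, evaluated at each site's grid cell.
#' Both z and the true psi are returned so recovery tests can compare
#' against the generative truth.
#'
#' @param grid a `land_grid`.
#' @param config a [sim_config()].
#' @param sites data.frame with `site_id`, `x`, `y` inside the grid.
#' @return `sites` with added `hand`, `canopy`, `elevation`, `psi`, `z`.
#' @export
simulate_occupancy <- function(grid, config, sites) {
  stopifnot(inherits(config, "sim_config"))
  for (nm in c("hand", "canopy", "elevation"))
    if (is.null(grid$layers[[nm]]))
      bp_stop(sprintf("grid lacks required layer '%s'", nm))
  idx <- cell_index(grid, sites$x, sites$y)
  sites$hand <- grid$layers$hand[idx]
  sites$canopy <- grid$layers$canopy[idx]
  sites$elevation <- grid$layers$elevation[idx]
  eta <- config$occ_intercept +
    config$occ_beta_hand * sites$hand / config$hand_scale +
    config$occ_beta_canopy * (sites$canopy - 20) / 10
  sites$psi <- inv_logit(eta)
  set.seed(derive_seed(config$seed, "occupancy"))
  sites$z <- stats::rbinom(nrow(sites), 1, sites$psi)
  sites
}

#' Place acoustic survey sites across the gradient
#'
#' Sites are spread on a regular transect-like lattice spanning the HAND
#' gradient (mirroring recorders deployed at set intervals along trails),
#' jittered by a fraction of a cell.
#'
#' @param grid a `land_grid`.
#' @param n_sites number of recording sites.
#' @param seed integer seed.
#' @return data.frame with `site_id`, `x`, `y`.
#' @export
place_aru_sites <- function(grid, n_sites = 30, seed = 1L) {
  set.seed(seed)
  nside <- ceiling(sqrt(n_sites))
  gx <- seq(0.1, 0.9, length.out = nside) * grid$ncol * grid$cell_size
  gy <- seq(0.1, 0.9, length.out = nside) * grid$nrow * grid$cell_size
  pts <- expand.grid(x = gx, y = gy)[seq_len(n_sites), ]
  pts$x <- pts$x + stats::runif(n_sites, -0.4, 0.4) * grid$cell_size
  pts$y <- pts$y + stats::runif(n_sites, -0.4, 0.4) * grid$cell_size
  data.frame(site_id = sprintf("ARU%02d", seq_len(n_sites)),
             x = pts$x, y = pts$y, stringsAsFactors = FALSE)
}

#' Build a recording schedule
#'
#' @param sites data.frame of acoustic sites.
#' @param dates Date vector of recording days per site.
#' @param hours integer hours of day recorded each day (diel schedule).
#' @return data.frame (site_id, date, hour) -- the recording log, one row
#'   per recorded site-hour.
#' @export
recording_schedule <- function(sites, dates, hours = 5:9) {
  expand.grid(site_id = sites$site_id, date = dates, hour = hours,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Simulate classifier detections from acoustic surveys
#'
#' For every recorded site-hour: an occupied site (z = 1) produces at least
#' one true cue event with probability 1 - exp(-vocal_rate); all sites
#' produce false detections at rate `false_rate` per hour (Poisson). Each
#' event receives a logit-scale confidence score drawn from its
#' label-conditional Gaussian (`score_mu_true` / `score_mu_false`, common
#' `score_sd`), so that with equal class frequencies
#' P(true | logit score) is logistic with slope
#' (mu_true - mu_false) / sd^2; an optional elevation drift shifts the
#' true-label mean by `score_elev_coef` per 100 m above `elev_ref_m`.
#' Scores are mapped back to (0, 1) by the inverse logit.
#'
#' @param occ output of [simulate_occupancy()] (sites with `z`).
#' @param schedule recording log from [recording_schedule()].
#' @param config a [sim_config()].
#' @param species species label attached to every event.
#' @return list with `events` (site_id, species, date, hour, start,
#'   confidence, logit_score, label, elevation) and `log` (the schedule).
#' @export
simulate_aru_surveys <- function(occ, schedule, config,
                                 species = "species_A") {
  stopifnot(inherits(config, "sim_config"))
  if (config$vocal_rate < 0 || config$false_rate < 0)
    bp_stop("rates must be non-negative")
  set.seed(derive_seed(config$seed, "aru"))
  sched <- merge(schedule, occ[, c("site_id", "z", "elevation")],
                 by = "site_id", sort = FALSE)
  p_true <- 1 - exp(-config$vocal_rate)
  n_true <- ifelse(sched$z == 1,
                   stats::rbinom(nrow(sched), 1, p_true), 0L)
  n_false <- stats::rpois(nrow(sched), config$false_rate)
  mk <- function(n_vec, label) {
    rep_rows <- rep(seq_len(nrow(sched)), n_vec)
    if (!length(rep_rows)) return(NULL)
    ev <- sched[rep_rows, c("site_id", "date", "hour", "elevation")]
    ev$label <- label
    ev
  }
  events <- rbind(mk(n_true, "true"), mk(n_false, "false"))
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(site_id = character(), species = character(),
                         date = as.Date(character()), hour = integer(),
                         start = character(), confidence = numeric(),
                         logit_score = numeric(), label = character(),
                         elevation = numeric(), stringsAsFactors = FALSE)
    return(list(events = events, log = schedule))
  }
  mu <- ifelse(events$label == "true",
               config$score_mu_true +
                 config$score_elev_coef * (events$elevation - config$elev_ref_m) / 100,
               config$score_mu_false)
  events$logit_score <- stats::rnorm(nrow(events), mu, config$score_sd)
  events$confidence <- inv_logit(events$logit_score)
  events$species <- species
  events$start <- sprintf("%sT%02d:%02d:00", events$date, events$hour,
                          sample(0:59, nrow(events), replace = TRUE))
  rownames(events) <- NULL
  list(events = events[, c("site_id", "species", "date", "hour", "start",
                           "confidence", "logit_score", "label", "elevation")],
       log = schedule)
}

#' Simulate citizen-science checklists
#'
#' Checklist locations are drawn over grid cells with density proportional
#' to exp(-checklist_bias * HAND / hand_scale) (rivers attract observers);
#' effort covariates are drawn from simple field-realistic distributions
#' (duration ~ capped lognormal hours, traveling distance < 1 km, 1-4
#' observers). Detection of the species is Bernoulli with a logit-linear
#' effort model, forced to 0 where the cell's latent z is 0. A configurable
#' fraction are flagged incomplete, and a fraction of detections are
#' recorded as "X" (present, uncounted), to exercise downstream filters.
#'
#' @param grid a `land_grid`.
#' @param config a [sim_config()].
#' @param n_checklists number of checklists (>= 1).
#' @param dates Date vector to sample checklist dates from.
#' @param z_cell optional matrix of latent occupancy per cell; if NULL it is
#'   drawn from the config's occupancy model (one draw per cell).
#' @return list with `checklists` (the eBird-like table) and `z_cell`.
#' @export
simulate_checklists <- function(grid, config, n_checklists,
                                dates = seq(as.Date("2020-01-01"),
                                            by = "day", length.out = 180),
                                z_cell = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_checklists < 1) bp_stop("n_checklists must be >= 1")
  set.seed(derive_seed(config$seed, "checklists"))
  hand <- grid$layers$hand
  if (is.null(z_cell)) {
    eta <- config$occ_intercept + config$occ_beta_hand * hand / config$hand_scale +
      config$occ_beta_canopy * (grid$layers$canopy - 20) / 10
    z_cell <- matrix(stats::rbinom(length(eta), 1, inv_logit(eta)),
                     nrow(hand), ncol(hand))
  }
  w <- exp(-config$checklist_bias * hand / config$hand_scale)
  cells <- sample(length(hand), n_checklists, replace = TRUE,
                  prob = as.vector(w))
  row <- (cells - 1L) %% grid$nrow + 1L
  col <- (cells - 1L) %/% grid$nrow + 1L
  x <- grid$origin[1] + (col - 0.5 + stats::runif(n_checklists, -0.5, 0.5)) * grid$cell_size
  y <- grid$origin[2] + (grid$nrow - row + 0.5 + stats::runif(n_checklists, -0.5, 0.5)) * grid$cell_size
  protocol <- sample(c("stationary", "traveling"), n_checklists,
                     replace = TRUE, prob = c(0.4, 0.6))
  duration <- pmin(stats::rlnorm(n_checklists, log(0.8), 0.6), 6)
  distance <- ifelse(protocol == "traveling",
                     stats::runif(n_checklists, 0.1, 1.5), 0)
  observers <- sample(1:6, n_checklists, replace = TRUE,
                      prob = c(0.55, 0.25, 0.1, 0.05, 0.03, 0.02))
  observer_id <- sprintf("obs%02d", sample(1:12, n_checklists, replace = TRUE))
  # hotspot mislocation: a fraction of checklists are reported at a shared
  # low-HAND "lodge" location while the observer actually roams the trail
  # network around it -- the species outcome comes from a cell drawn
  # uniformly within the roaming radius, so hotspot presences carry lodge
  # covariates that do not represent where the bird was found
  if (config$p_hotspot > 0 && config$n_hotspots > 0) {
    low <- order(as.vector(hand))[seq_len(max(1, round(0.02 * length(hand))))]
    hs_cells <- sample(low, config$n_hotspots, replace = length(low) < config$n_hotspots)
    hs_row <- (hs_cells - 1L) %% grid$nrow + 1L
    hs_col <- (hs_cells - 1L) %/% grid$nrow + 1L
    hs_x <- grid$origin[1] + (hs_col - 0.5) * grid$cell_size
    hs_y <- grid$origin[2] + (grid$nrow - hs_row + 0.5) * grid$cell_size
    at_hs <- which(stats::runif(n_checklists) < config$p_hotspot)
    pick <- sample(config$n_hotspots, length(at_hs), replace = TRUE)
    x[at_hs] <- hs_x[pick]
    y[at_hs] <- hs_y[pick]
    roam_cells <- config$hotspot_roam_m / grid$cell_size
    rr <- pmin(pmax(hs_row[pick] + round(stats::runif(length(at_hs), -roam_cells, roam_cells)), 1), grid$nrow)
    rc <- pmin(pmax(hs_col[pick] + round(stats::runif(length(at_hs), -roam_cells, roam_cells)), 1), grid$ncol)
    row[at_hs] <- rr
    col[at_hs] <- rc
  }
  eta_det <- config$det_intercept +
    config$det_beta_duration * duration +
    config$det_beta_distance * distance +
    config$det_beta_observers * (observers - 1)
  det <- stats::rbinom(n_checklists, 1, inv_logit(eta_det)) *
    z_cell[cbind(row, col)]
  complete <- stats::runif(n_checklists) >= config$p_incomplete
  count <- ifelse(det == 1, "1", "0")
  count[det == 1 & stats::runif(n_checklists) < config$p_x] <- "X"
  checklists <- data.frame(
    record_id = sprintf("CL%05d", seq_len(n_checklists)),
    source = "citizen",
    x = x, y = y,
    date = sample(dates, n_checklists, replace = TRUE),
    start_time = sprintf("%02d:%02d", sample(5:17, n_checklists, TRUE),
                         sample(0:59, n_checklists, TRUE)),
    protocol = protocol,
    duration = duration,
    distance = distance,
    observers = observers,
    observer_id = observer_id,
    complete = complete,
    species_count = count,
    stringsAsFactors = FALSE)
  list(checklists = checklists, z_cell = z_cell)
}
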