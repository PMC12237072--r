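#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study system: the landscape, the
#' species' occupancy process on the logit scale, the acoustic detection and
#' classifier-score process, and the citizen-science effort and detection
#' process. Defaults encode the study conditions the workflow assumes: a
#' floodplain-terra firme gradient maintained by distance from a river
#' channel, citizen effort spatially biased toward low HAND, hour-scale
#' acoustic sampling with label-dependent confidence scores, and
#' effort-dependent checklist detection.
#'
#' @param seed master integer seed; all randomness derives from it through
#'   [derive_seed()].
#' @param nrow,ncol landscape dimensions in cells (>= 10 each).
#' @param cell_size cell edge in meters.
#' @param relief_m elevation gain across the gradient (m).
#' @param noise_sd_m SD of smoothed elevation noise (m).
#' @param hand_thresholds `c(t1, t2)` in meters: floodplain forest below t1,
#'   transition forest in [t1, t2), terra firme at or above t2.
#' @param occ_intercept,occ_beta_hand,occ_beta_canopy species occupancy
#'   coefficients (logit scale); HAND enters standardized by `hand_scale`.
#' @param hand_scale divisor (m) standardizing HAND in linear predictors.
#' @param vocal_rate expected cue events per occupied site-hour.
#' @param false_rate expected false detections per site-hour (all sites).
#' @param score_mu_true,score_mu_false,score_sd label-conditional Gaussian
#'   parameters of the logit confidence score. With equal class frequencies
#'   the induced P(true | logit score) is logistic with slope
#'   `(mu_true - mu_false) / sd^2`.
#' @param score_elev_coef optional elevation effect (per 100 m above
#'   `elev_ref_m`) added to the true-label score mean, letting classifier
#'   behaviour drift along the gradient.
#' @param elev_ref_m reference elevation for the score drift.
#' @param checklist_bias strength of citizen-effort decay in HAND (per
#'   `hand_scale` meters); 0 means spatially unbiased effort.
#' @param det_intercept,det_beta_duration,det_beta_distance,det_beta_observers
#'   per-checklist detection coefficients (logit scale).
#' @param p_hotspot fraction of checklists whose reported coordinates snap
#'   to a shared "hotspot" location near the river while the species
#'   detection reflects the cell actually visited — emulating lodge and
#'   hotspot checklists whose coordinate point does not represent where
#'   the birding happened.
#' @param n_hotspots number of hotspot locations (placed at low-HAND
#'   cells).
#' @param hotspot_roam_m radius (m) of the trail network roamed from a
#'   hotspot: the visited cell that determines the species outcome is
#'   drawn uniformly within it, spanning the habitat gradient.
#' @param p_incomplete fraction of checklists flagged incomplete.
#' @param p_x fraction of complete checklists reporting "X" (present,
#'   uncounted) instead of a count when the species is detected.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       nrow = 60, ncol = 60, cell_size = 30,
                       relief_m = 60, noise_sd_m = 2,
                       hand_thresholds = c(8, 25),
                       occ_intercept = -1, occ_beta_hand = 2,
                       occ_beta_canopy = 0, hand_scale = 10,
                       vocal_rate = 0.35, false_rate = 0.05,
                       score_mu_true = 1, score_mu_false = -1,
                       score_sd = sqrt(0.5), score_elev_coef = 0,
                       elev_ref_m = 250,
                       checklist_bias = 1.5,
                       p_hotspot = 0.4, n_hotspots = 3,
                       hotspot_roam_m = 900,
                       det_intercept = -0.5, det_beta_duration = 1.2,
                       det_beta_distance = 0.2, det_beta_observers = 0.1,
                       p_incomplete = 0.1, p_x = 0.05) {
  cfg <- as.list(environment())
  if (cfg$nrow < 10 || cfg$ncol < 10)
    bp_stop("landscape must be at least 10 x 10 cells")
  if (cfg$vocal_rate < 0 || cfg$false_rate < 0)
    bp_stop("rates must be non-negative")
  if (cfg$p_incomplete < 0 || cfg$p_incomplete > 1 ||
      cfg$p_x < 0 || cfg$p_x > 1)
    bp_stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# internal: separable moving-average smoothing of a matrix (edge-replicated)
smooth_matrix <- function(m, half = 3) {
  k <- 2 * half + 1
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2 * half) - half, 1), n)
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  rs <- apply(mp, 2, function(v) stats::filter(v, rep(1 / k, k), sides = 2))
  rs <- rs[(half + 1):(half + nrow(m)), , drop = FALSE]
  cs <- t(apply(rs, 1, function(v) stats::filter(v, rep(1 / k, k), sides = 2)))
  cs[, (half + 1):(half + ncol(m)), drop = FALSE]
}

#' Generate a synthetic floodplain-terra firme landscape
#'
#' Builds a river channel running north-south as a sinuous drainage line,
#' an elevation ramp rising with distance from the channel plus smoothed
#' noise, HAND via [compute_hand()], land cover assigned by HAND thresholds
#' (floodplain forest < t1 <= transition forest < t2 <= terra firme) with
#' flooded vegetation fringing the channel, an anthropogenic "town" patch
#' (crops + built area) in the southeast corner, a "mining beach" (built +
#' bare ground) along the channel, and a canopy-height layer that is tall in
#' forest and near zero in open classes.
#'
#' @param config a [sim_config()].
#' @return a `land_grid`.
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  nr <- config$nrow; nc <- config$ncol
  # sinuous river: one drainage column per row, random-walked
  river_col <- numeric(nr)
  river_col[1] <- round(nc * 0.25)
  for (i in 2:nr)
    river_col[i] <- min(max(river_col[i - 1] + sample(-1:1, 1), 2), round(nc * 0.5))
  drainage <- matrix(FALSE, nr, nc)
  drainage[cbind(seq_len(nr), river_col)] <- TRUE
  # elevation: base 200 m + ramp away from channel + smoothed noise
  dist_cells <- matrix(0, nr, nc)
  for (i in seq_len(nr)) dist_cells[i, ] <- abs(seq_len(nc) - river_col[i])
  elev <- 200 + config$relief_m * dist_cells / nc
  if (config$noise_sd_m > 0) {
    noise <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), half = 3)
    elev <- elev + config$noise_sd_m * noise / stats::sd(noise)
  }
  for (i in seq_len(nr)) elev[i, river_col[i]] <- min(elev[i, ])
  hand <- compute_hand(elev, drainage)
  cl <- landcover_classes()
  code <- function(x) match(x, cl)
  cover <- matrix(code("terra_firme"), nr, nc)
  cover[hand < config$hand_thresholds[2]] <- code("transition_forest")
  cover[hand < config$hand_thresholds[1]] <- code("floodplain_forest")
  cover[drainage] <- code("open_water")
  # flooded vegetation fringe: non-drainage cells adjacent to the channel
  fringe <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (dc in c(-1, 1)) {
      j <- river_col[i] + dc
      if (j >= 1 && j <= nc) fringe[i, j] <- TRUE
    }
  }
  cover[fringe & !drainage] <- code("flooded_vegetation")
  # town: block in the southeast corner, split crops / built / sparse
  tr <- (nr - max(4, round(nr / 8)) + 1):nr
  tc <- (nc - max(4, round(nc / 8)) + 1):nc
  town <- as.matrix(expand.grid(row = tr, col = tc))
  lab <- sample(code(c("crops", "built_area", "sparsely_vegetated")),
                nrow(town), replace = TRUE, prob = c(0.5, 0.35, 0.15))
  cover[town] <- lab
  # mining beach: short built/bare stretch on the channel bank
  beach_rows <- sample(seq_len(nr), max(3, round(nr / 15)))
  for (i in beach_rows) {
    j <- river_col[i] + 1
    if (j <= nc) cover[i, j] <- code(sample(c("built_area", "bare_ground"), 1))
  }
  forest <- cover %in% code(c("floodplain_forest", "transition_forest",
                              "terra_firme", "flooded_vegetation"))
  canopy <- matrix(3, nr, nc)
  canopy[matrix(forest, nr, nc)] <- 28
  canopy[cover == code("open_water")] <- 0
  canopy <- canopy + abs(stats::rnorm(nr * nc, 0, 2))
  land_grid(list(elevation = elev, drainage = drainage, hand = hand,
                 cover = cover, canopy = canopy),
            cell_size = config$cell_size)
}
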