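#' Build detection histories for occupancy modeling
#'
#' Converts zero-filled observation records into site-by-visit detection
#' histories within closure periods. Citizen records are grouped by
#' (location snapped to a ~1.1 km grid, observer, closure period); groups
#' with 2-10 visits are kept, with a seeded sample of 10 when more exist.
#' Acoustic records are grouped by (site, closure period) and each
#' consecutive block of 3 recording days collapses to one visit whose
#' outcome is 1 iff any hour in the block holds a detection; effort hours =
#' recorded hours in the block, and the hour covariate is the hour of the
#' first detection (or the block's first recorded hour if none).
#'
#' @param obs pooled observation table: columns `source` ("citizen" /
#'   "acoustic"), `x`, `y`, `date`, `presence`; citizen rows additionally
#'   `observer_id`, `duration`, `distance`, `observers`, `protocol`,
#'   `start_time`; acoustic rows `site_id` and `hour`.
#' @param closure_days closure period length (default 90).
#' @param min_visits,max_visits visit bounds for citizen histories
#'   (defaults 2 and 10).
#' @param site_grouping_m location snapping distance for citizen records
#'   (default 1100 m, the metric analog of rounding coordinates to 2
#'   decimal degrees).
#' @param acoustic_block_days recording days per acoustic visit (default 3).
#' @param seed integer seed (visit subsampling).
#' @return object of class `det_histories`: list with `sites` (site_key,
#'   source, x, y, any_det) and `visits` (site_key, visit, y and visit
#'   covariates).
#' @export
build_histories <- function(obs, closure_days = 90, min_visits = 2,
                            max_visits = 10, site_grouping_m = 1100,
                            acoustic_block_days = 3, seed = 1L) {
  set.seed(seed)
  origin <- min(as.Date(obs$date))
  obs$period <- floor(as.numeric(as.Date(obs$date) - origin) / closure_days)
  sites <- list(); visits <- list(); si <- 0
  cit <- obs[obs$source == "citizen", , drop = FALSE]
  if (nrow(cit)) {
    gx <- round(cit$x / site_grouping_m) * site_grouping_m
    gy <- round(cit$y / site_grouping_m) * site_grouping_m
    grp <- paste(gx, gy, cit$observer_id, cit$period, sep = "|")
    for (g in unique(grp)) {
      ix <- which(grp == g)
      ix <- ix[order(cit$date[ix])]
      if (length(ix) < min_visits) next
      if (length(ix) > max_visits) ix <- sort(sample(ix, max_visits))
      si <- si + 1
      key <- sprintf("cit_%04d", si)
      sites[[si]] <- data.frame(
        site_key = key, source = "citizen",
        x = mean(cit$x[ix]), y = mean(cit$y[ix]),
        any_det = as.integer(any(cit$presence[ix] == 1)),
        stringsAsFactors = FALSE)
      hr <- if ("start_time" %in% names(cit))
        as.integer(substr(cit$start_time[ix], 1, 2)) else rep(NA_integer_, length(ix))
      visits[[si]] <- data.frame(
        site_key = key, visit = seq_along(ix),
        y = cit$presence[ix],
        day_of_year = as.integer(format(as.Date(cit$date[ix]), "%j")),
        hour = hr,
        effort_hours = cit$duration[ix],
        distance = cit$distance[ix],
        observers = cit$observers[ix],
        protocol = cit$protocol[ix],
        stringsAsFactors = FALSE)
    }
  }
  ac <- obs[obs$source == "acoustic", , drop = FALSE]
  if (nrow(ac)) {
    grp <- paste(ac$site_id, ac$period, sep = "|")
    for (g in unique(grp)) {
      ix <- which(grp == g)
      days <- sort(unique(as.Date(ac$date[ix])))
      n_blocks <- floor(length(days) / acoustic_block_days)
      if (n_blocks < 1) next
      vrows <- list()
      for (bk in seq_len(n_blocks)) {
        dset <- days[((bk - 1) * acoustic_block_days + 1):(bk * acoustic_block_days)]
        bix <- ix[as.Date(ac$date[ix]) %in% dset]
        det <- ac$presence[bix] == 1
        first_hr <- if (any(det)) {
          o <- order(as.Date(ac$date[bix]), ac$hour[bix])
          ac$hour[bix][o][which(det[o])[1]]
        } else min(ac$hour[bix])
        vrows[[bk]] <- data.frame(
          visit = bk, y = as.integer(any(det)),
          day_of_year = as.integer(format(dset[1], "%j")),
          hour = first_hr, effort_hours = length(bix),
          distance = 0, observers = 1L, protocol = "stationary",
          stringsAsFactors = FALSE)
      }
      si <- si + 1
      key <- sprintf("aru_%s", gsub("[^A-Za-z0-9]", "_", g))
      vr <- do.call(rbind, vrows)
      vr$site_key <- key
      sites[[si]] <- data.frame(
        site_key = key, source = "acoustic",
        x = ac$x[ix][1], y = ac$y[ix][1],
        any_det = as.integer(any(vr$y == 1)), stringsAsFactors = FALSE)
      visits[[si]] <- vr[, c("site_key", "visit", "y", "day_of_year",
                             "hour", "effort_hours", "distance",
                             "observers", "protocol")]
    }
  }
  if (si == 0) {
    warning("no detection histories could be built")
    return(structure(list(sites = data.frame(), visits = data.frame()),
                     class = "det_histories"))
  }
  structure(list(sites = do.call(rbind, sites),
                 visits = do.call(rbind, visits)),
            class = "det_histories")
}

#' Attach site covariates to detection histories
#'
#' @param hist a `det_histories`.
#' @param covs data.frame keyed by `site_id` (matched to `site_key`) or a
#'   wide covariate table from [reshape_covariates()] whose `site_id` holds
#'   the history site keys.
#' @return the histories with covariate columns merged into `$sites`.
#' @export
attach_site_covariates <- function(hist, covs) {
  names(covs)[names(covs) == "site_id"] <- "site_key"
  hist$sites <- merge(hist$sites, covs, by = "site_key", sort = FALSE)
  hist$visits <- hist$visits[hist$visits$site_key %in% hist$sites$site_key, ]
  hist
}

#' Subset detection histories by site
#'
#' @param hist a `det_histories`.
#' @param keys site keys to keep.
#' @return the subset `det_histories`.
#' @export
subset_histories <- function(hist, keys) {
  hist$sites <- hist$sites[hist$sites$site_key %in% keys, , drop = FALSE]
  hist$visits <- hist$visits[hist$visits$site_key %in% keys, , drop = FALSE]
  hist
}

#' Cumulative detectability across a site's visits
#'
#' p_i = 1 - prod_t (1 - p_it): the probability of at least one detection
#' across all visits to a site. An empty visit list gives 0.
#'
#' @param p_it per-visit detection probabilities in [0, 1].
#' @return scalar cumulative detectability.
#' @export
cumulative_detectability <- function(p_it) {
  if (length(p_it) == 0) return(0)
  if (any(p_it < 0 | p_it > 1)) bp_stop("detection probabilities must lie in [0, 1]")
  1 - prod(1 - p_it)
}
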