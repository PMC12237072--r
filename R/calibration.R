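#' Stratified sample of detections for annotation
#'
#' Draws the annotation sample for score calibration: within each elevation
#' band (default 10 m wide), up to `cap` events spanning the primary score
#' range (default 0.3-1), plus an independent second sample of up to `cap`
#' events restricted to high scores (default 0.8-1) to ensure coverage of
#' the region where false positives give way to true positives. Sampling is
#' without replacement (the second sample excludes events already chosen),
#' seeded, with ties broken by seeded uniform draws. Empty strata are
#' skipped silently.
#'
#' @param events data.frame with `confidence` and `elevation` columns.
#' @param score_range primary confidence-score range (default `c(0.3, 1)`).
#' @param high_range secondary high-score range (default `c(0.8, 1)`).
#' @param cap maximum events per band per sample (default 30).
#' @param band_width elevation band width in meters (default 10).
#' @param seed integer seed.
#' @return the sampled rows of `events`.
#' @export
stratified_score_sample <- function(events, score_range = c(0.3, 1),
                                    high_range = c(0.8, 1), cap = 30,
                                    band_width = 10, seed = 1L) {
  if (nrow(events) == 0) bp_stop("no events to sample")
  if (band_width <= 0) bp_stop("band_width must be positive")
  set.seed(seed)
  band <- floor(events$elevation / band_width)
  take <- function(pool_idx) {
    picked <- integer(0)
    for (b in unique(band[pool_idx])) {
      in_b <- pool_idx[band[pool_idx] == b]
      n <- min(cap, length(in_b))
      picked <- c(picked, if (length(in_b) == 1) in_b else sample(in_b, n))
    }
    picked
  }
  prim_pool <- which(events$confidence >= score_range[1] &
                       events$confidence <= score_range[2])
  prim <- take(prim_pool)
  high_pool <- setdiff(which(events$confidence >= high_range[1] &
                               events$confidence <= high_range[2]), prim)
  high <- take(high_pool)
  events[sort(c(prim, high)), , drop = FALSE]
}

# internal: AICc from a fitted model's logLik; k includes every estimated
# quantity (for GAMs, the total effective df)
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# internal: ridge-penalized logistic regression by IRLS; fallback when the
# annotation labels are perfectly separated in score
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit and compare candidate score-calibration models
#'
#' Fits three candidates to annotated detections: (i) an intercept-only
#' null, (ii) a logistic regression of label on logit score, and (iii) a
#' logistic GAM adding a cubic-regression-spline smooth of site elevation,
#' allowing classifier reliability to drift along the habitat gradient.
#' Candidates are compared by AICc = -2logLik + 2k + 2k(k+1)/(n-k-1) and the
#' minimizer is recorded. Perfect separation in (ii) triggers a
#' ridge-penalized refit, flagged in the output.
#'
#' @param labeled data.frame with `logit_score`, `elevation` and `label`
#'   in c("true", "false").
#' @param k_spline basis dimension for the elevation smooth (default 6).
#' @return a `score_calibration` list: `models`, `aicc` (named vector),
#'   `chosen` (one of "null", "logistic", "logistic_elev"), `separation`
#'   flag, and a `predict_prob(newdata)` closure.
#' @export
fit_score_models <- function(labeled, k_spline = 6) {
  y <- as.integer(labeled$label == "true")
  if (sum(y) < 2 || sum(1 - y) < 2)
    bp_stop("need at least 2 annotated events of each label")
  n <- length(y)
  dat <- data.frame(y = y, logit_score = labeled$logit_score,
                    elevation = labeled$elevation)
  m_null <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  separation <- FALSE
  m_log <- withCallingHandlers(
    stats::glm(y ~ logit_score, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  ridge_beta <- NULL
  if (separation || max(abs(stats::coef(m_log))) > 15) {
    separation <- TRUE
    X <- cbind(1, dat$logit_score)
    ridge_beta <- ridge_logistic(X, y)
  }
  m_gam <- NULL
  aicc_gam <- Inf
  if (length(unique(dat$elevation)) > k_spline) {
    m_gam <- try(mgcv::gam(y ~ logit_score + s(elevation, bs = "cr", k = k_spline),
                           family = stats::binomial(), data = dat,
                           method = "REML"), silent = TRUE)
    if (!inherits(m_gam, "try-error")) {
      # corrected df accounts for smoothing-parameter selection
      k_g <- attr(stats::logLik(m_gam), "df")
      aicc_gam <- aicc(as.numeric(stats::logLik(m_gam)), k_g, n)
    } else m_gam <- NULL
  }
  if (separation) {
    ll_log <- sum(y * stats::plogis(drop(cbind(1, dat$logit_score) %*% ridge_beta),
                                    log.p = TRUE) +
                  (1 - y) * stats::plogis(-drop(cbind(1, dat$logit_score) %*% ridge_beta),
                                          log.p = TRUE))
  } else ll_log <- as.numeric(stats::logLik(m_log))
  aiccs <- c(null = aicc(as.numeric(stats::logLik(m_null)), 1, n),
             logistic = aicc(ll_log, 2, n),
             logistic_elev = if (separation) Inf else aicc_gam)
  chosen <- names(which.min(aiccs))
  cal <- list(models = list(null = m_null, logistic = m_log,
                            logistic_elev = m_gam),
              ridge_beta = ridge_beta,
              aicc = aiccs, chosen = chosen, separation = separation)
  cal$predict_prob <- function(newdata) {
    switch(cal$chosen,
      null = rep(unname(inv_logit(stats::coef(m_null)[1])), nrow(newdata)),
      logistic = if (!is.null(ridge_beta))
        inv_logit(drop(cbind(1, newdata$logit_score) %*% ridge_beta))
      else unname(stats::predict(m_log, newdata, type = "response")),
      logistic_elev = unname(stats::predict(m_gam, newdata, type = "response")))
  }
  class(cal) <- "score_calibration"
  cal
}

#' Select the fpr-constrained acceptance threshold
#'
#' Scans a grid of candidate thresholds over calibrated detection
#' probability and returns the smallest (most permissive) threshold whose
#' empirical false-positive rate on the annotated sample is below
#' `fpr_max`. fpr(theta) = #(labeled false with p >= theta) /
#' #(labeled with p >= theta); thresholds accepting no events cannot be
#' evaluated and are skipped.
#'
#' @param calibration a `score_calibration` from [fit_score_models()], or
#'   NULL to use a precomputed `prob` column in `labeled`.
#' @param labeled the annotated events (with `logit_score`, `elevation`,
#'   `label`; plus `prob` when `calibration` is NULL).
#' @param fpr_max maximum tolerated false-positive rate (default 0.05).
#' @param grid_step threshold grid step (default 0.001).
#' @return list with `threshold`, `achieved_fpr`, `n_accepted`, and the
#'   evaluated `grid` (data.frame theta/fpr/n).
#' @export
select_threshold <- function(calibration, labeled, fpr_max = 0.05,
                             grid_step = 0.001) {
  if (nrow(labeled) == 0) bp_stop("no labeled events")
  p <- if (is.null(calibration)) labeled$prob else calibration$predict_prob(labeled)
  is_false <- labeled$label == "false"
  thetas <- round(seq(0, 1, by = grid_step), 10)
  # tolerance guards against binary representation of grid values
  n_acc <- vapply(thetas, function(th) sum(p >= th - 1e-9), 0)
  n_fp <- vapply(thetas, function(th) sum(is_false & p >= th - 1e-9), 0)
  fpr <- ifelse(n_acc > 0, n_fp / n_acc, NA_real_)
  ok <- !is.na(fpr) & fpr < fpr_max
  if (!any(ok))
    bp_stop(paste("no threshold satisfies the fpr constraint;",
                  "raise fpr_max or annotate more data"))
  i <- which(ok)[1]
  list(threshold = thetas[i], achieved_fpr = fpr[i], n_accepted = n_acc[i],
       grid = data.frame(theta = thetas, fpr = fpr, n = n_acc))
}

#' Apply a calibration and threshold to raw detections
#'
#' @param events raw detections with `logit_score` and `elevation`.
#' @param calibration a `score_calibration`.
#' @param threshold acceptance threshold on calibrated probability.
#' @return the accepted rows, with a `prob` column added.
#' @export
apply_threshold <- function(events, calibration, threshold) {
  events$prob <- calibration$predict_prob(events)
  events[events$prob >= threshold, , drop = FALSE]
}

#' Collapse accepted detections to independent hourly records
#'
#' Reduces event sequences to at most one detection per species per site per
#' clock hour of recording time ("independent detections").
#'
#' @param events accepted detections with `site_id`, `species`, `date`,
#'   `hour` (clock hour) columns.
#' @return one row per unique (site_id, species, date, hour).
#' @export
collapse_independent <- function(events) {
  if (nrow(events) == 0)
    return(events[, c("site_id", "species", "date", "hour"), drop = FALSE])
  unique(events[, c("site_id", "species", "date", "hour")])
}

#' Zero-fill acoustic detections against the recording log
#'
#' Every recorded site-hour becomes a row; the species column is 1 where an
#' independent detection exists and 0 otherwise. A presence at a site-hour
#' absent from the log is a data-integrity error.
#'
#' @param presences output of [collapse_independent()].
#' @param rec_log recording log (site_id, date, hour), one row per recorded
#'   hour.
#' @param species species name for the presence column.
#' @return data.frame (site_id, date, hour, presence).
#' @export
zero_fill_acoustic <- function(presences, rec_log, species = "species_A") {
  key <- function(d) paste(d$site_id, d$date, d$hour, sep = "|")
  lk <- key(rec_log)
  if (nrow(presences)) {
    miss <- !(key(presences) %in% lk)
    if (any(miss))
      bp_stop(sprintf("presence outside the recording log: %s",
                      paste(utils::head(key(presences)[miss], 3), collapse = "; ")))
  }
  out <- rec_log[, c("site_id", "date", "hour")]
  out$presence <- as.integer(lk %in% (if (nrow(presences)) key(presences) else character()))
  out$species <- species
  out
}

#' Filter events to a diel schedule
#'
#' Removes events outside the whitelisted hours of day for their season,
#' matching survey effort across recording seasons.
#'
#' @param events data.frame with `hour` and (if `by_season`) `season`.
#' @param allowed named list of integer hour vectors keyed by season label,
#'   or a single integer vector applied to all events.
#' @return the surviving rows; the number removed is reported via message.
#' @export
temporal_match_filter <- function(events, allowed) {
  if (!is.list(allowed)) {
    keep <- events$hour %in% allowed
  } else {
    if (!all(events$season %in% names(allowed)))
      bp_stop("unknown season label in events")
    keep <- mapply(function(h, s) h %in% allowed[[s]],
                   events$hour, events$season)
    keep <- as.logical(keep)
    if (!length(keep)) keep <- logical(0)
  }
  removed <- sum(!keep)
  if (removed > 0) message(sprintf("temporal filter removed %d events", removed))
  events[keep, , drop = FALSE]
}
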