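#' Filter citizen-science checklists for effort evenness
#'
#' Keeps only complete checklists submitted under the stationary or
#' traveling protocol with duration strictly less than 5 hours, effort
#' distance strictly less than 1 km, and fewer than 5 observers. Checklists
#' reporting "X" (present, uncounted) for the target species are recoded to
#' NA and dropped from that species' dataset. Counts of each rejection
#' reason are attached as an attribute and reported via message.
#'
#' @param raw eBird-like table with `protocol`, `duration`, `distance`,
#'   `observers`, `complete`, `species_count` columns.
#' @param max_duration,max_distance,max_observers strict upper bounds.
#' @return the surviving rows with an integer `presence` column; attribute
#'   `rejections` holds the per-rule counts.
#' @export
filter_checklists <- function(raw, max_duration = 5, max_distance = 1,
                              max_observers = 5) {
  if (nrow(raw) == 0) {
    raw$presence <- integer(0)
    return(raw)
  }
  ok_complete <- raw$complete %in% TRUE
  ok_protocol <- raw$protocol %in% c("stationary", "traveling")
  dur <- suppressWarnings(as.numeric(raw$duration))
  dis <- suppressWarnings(as.numeric(raw$distance))
  obs <- suppressWarnings(as.numeric(raw$observers))
  malformed <- is.na(dur) | is.na(dis) | is.na(obs)
  if (any(malformed))
    warning(sprintf("%d rows with malformed effort fields dropped", sum(malformed)))
  ok_duration <- !is.na(dur) & dur < max_duration
  ok_distance <- !is.na(dis) & dis < max_distance
  ok_observers <- !is.na(obs) & obs < max_observers
  is_x <- raw$species_count == "X"
  keep <- ok_complete & ok_protocol & ok_duration & ok_distance &
    ok_observers & !is_x & !malformed
  rej <- c(incomplete = sum(!ok_complete), protocol = sum(!ok_protocol),
           duration = sum(!ok_duration), distance = sum(!ok_distance),
           observers = sum(!ok_observers), x_recoded = sum(is_x),
           malformed = sum(malformed))
  out <- raw[keep, , drop = FALSE]
  out$presence <- as.integer(out$species_count != "0")
  attr(out, "rejections") <- rej
  out
}

#' Zero-fill species records against the full checklist universe
#'
#' @param species_ids record ids of checklists where the species was
#'   present.
#' @param checklists the full filtered checklist table (with `record_id`).
#' @return `checklists` with a 0/1 `presence` column.
#' @export
zero_fill_ebird <- function(species_ids, checklists) {
  if (!all(species_ids %in% checklists$record_id))
    bp_stop("species records reference checklist ids absent from the universe")
  checklists$presence <- as.integer(checklists$record_id %in% species_ids)
  checklists
}

# internal: ISO-8601 year-week label
iso_week <- function(date) format(as.Date(date), "%G-W%V")

#' Spatiotemporal subsampling on a 600 m weekly grid
#'
#' Within each (600 m grid cell, ISO week, presence class) stratum, retains
#' at most one citizen record, chosen uniformly at random; positive and
#' negative records are sampled separately to reduce class bias. Acoustic
#' records pass through untouched (regular recorder spacing already limits
#' spatial bias). The grid origin is anchored at the lower-left of the
#' supplied records' bounding box; cell assignment is half-open
#' [x0, x0 + cell).
#'
#' @param records table with `x`, `y`, `date`, `presence` and `source`.
#' @param cell_m grid cell size in meters (default 600).
#' @param seed integer seed.
#' @return the retained rows (original order preserved).
#' @export
spatiotemporal_subsample <- function(records, cell_m = 600, seed = 1L) {
  if (nrow(records) == 0) return(records)
  pass <- records$source == "acoustic"
  cit <- records[!pass, , drop = FALSE]
  if (nrow(cit) == 0) return(records)
  set.seed(seed)
  x0 <- min(cit$x); y0 <- min(cit$y)
  cellx <- floor((cit$x - x0) / cell_m)
  celly <- floor((cit$y - y0) / cell_m)
  stratum <- paste(cellx, celly, iso_week(cit$date), cit$presence, sep = "|")
  keep_idx <- unlist(lapply(split(seq_len(nrow(cit)), stratum), function(ix) {
    if (length(ix) == 1) ix else sample(ix, 1)
  }), use.names = FALSE)
  keep <- logical(nrow(records))
  keep[pass] <- TRUE
  keep[which(!pass)[sort(keep_idx)]] <- TRUE
  records[keep, , drop = FALSE]
}

#' Recast zero-filled acoustic hours as pseudo-checklists
#'
#' Each recorded hour becomes an observation record submitted under the
#' stationary protocol with 1 observer, 1 hour of effort, and 0 km
#' distance, so acoustic and citizen rows share one schema for pooling.
#'
#' @param zf zero-filled acoustic table from [zero_fill_acoustic()].
#' @param sites acoustic site table with `site_id`, `x`, `y`.
#' @return ObservationRecord table with `source = "acoustic"`.
#' @export
make_pseudo_checklists <- function(zf, sites) {
  m <- merge(zf, sites[, c("site_id", "x", "y")], by = "site_id", sort = FALSE)
  data.frame(
    record_id = sprintf("AC%05d", seq_len(nrow(m))),
    source = "acoustic",
    site_id = m$site_id,
    x = m$x, y = m$y,
    date = m$date,
    start_time = sprintf("%02d:00", m$hour),
    protocol = "stationary",
    duration = 1,
    distance = 0,
    observers = 1L,
    observer_id = paste0("aru_", m$site_id),
    complete = TRUE,
    presence = m$presence,
    stringsAsFactors = FALSE)
}

#' Synthetic minority-class oversampling (SMOTE)
#'
#' If the presence fraction is below `target`, adds
#' s = ceiling(target * N_abs / (1 - target) - N_pres) synthetic presence
#' rows, each interpolated between a random real presence and one of its k
#' nearest presence neighbors (Euclidean distance on predictors
#' standardized by presence-class statistics; interpolation factor
#' U(0, 1)). The resulting fraction first reaches at least `target`.
#' Non-predictor columns are copied from the seed presence row; synthetic
#' rows are flagged `synthetic = TRUE`.
#'
#' @param table data.frame with a 0/1 `presence` column.
#' @param predictors names of numeric predictor columns used for the
#'   neighbor search and interpolation.
#' @param target target presence fraction (default 0.25).
#' @param k number of nearest neighbors (default 5; lowered with a message
#'   when fewer presences exist).
#' @param seed integer seed.
#' @return the table with synthetic rows appended (and a `synthetic`
#'   column).
#' @export
smote_balance <- function(table, predictors, target = 0.25, k = 5,
                          seed = 1L) {
  if (!"synthetic" %in% names(table))
    table$synthetic <- rep(FALSE, nrow(table))
  n_pres <- sum(table$presence == 1)
  n_abs <- sum(table$presence == 0)
  if (n_pres == 0) bp_stop("cannot oversample: no presences in table")
  if (n_pres / (n_pres + n_abs) >= target) return(table)
  s <- ceiling(target * n_abs / (1 - target) - n_pres)
  if (s <= 0) return(table)
  set.seed(seed)
  pres <- table[table$presence == 1, , drop = FALSE]
  X <- as.matrix(pres[, predictors, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (k > n_pres - 1) {
    message(sprintf("SMOTE k lowered from %d to %d (available presences)", k, n_pres - 1))
    k <- n_pres - 1
  }
  if (k < 1) bp_stop("need at least 2 presences for SMOTE interpolation")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  seed_i <- sample(n_pres, s, replace = TRUE)
  nb_i <- nn[cbind(seed_i, sample(k, s, replace = TRUE))]
  u <- stats::runif(s)
  synth <- pres[seed_i, , drop = FALSE]
  synth[, predictors] <- X[seed_i, , drop = FALSE] +
    u * (X[nb_i, , drop = FALSE] - X[seed_i, , drop = FALSE])
  synth$synthetic <- TRUE
  if ("record_id" %in% names(synth))
    synth$record_id <- sprintf("SM%05d", seq_len(s))
  rownames(synth) <- NULL
  rbind(table, synth)
}

#' Equalize table sizes to the citizen table
#'
#' Subsamples each non-citizen table, class-proportionally, to the citizen
#' table's row count so that the three model classes within one bootstrap
#' iteration see equal sample sizes. Tables already at or below the target
#' size are left unchanged (with a message).
#'
#' @param ebird_table the citizen table (defines the target size).
#' @param others named list of tables to subsample.
#' @param seed integer seed.
#' @return named list of (possibly subsampled) tables.
#' @export
equalize_sample_sizes <- function(ebird_table, others, seed = 1L) {
  n_target <- nrow(ebird_table)
  set.seed(seed)
  lapply(others, function(tab) {
    if (nrow(tab) <= n_target) {
      if (nrow(tab) < n_target)
        message(sprintf("table already smaller (%d) than citizen size (%d); left unchanged",
                        nrow(tab), n_target))
      return(tab)
    }
    idx1 <- which(tab$presence == 1)
    idx0 <- which(tab$presence == 0)
    n1 <- round(n_target * length(idx1) / nrow(tab))
    n1 <- min(max(n1, 1), length(idx1))
    n0 <- n_target - n1
    keep <- sort(c(sample(idx1, n1), sample(idx0, min(n0, length(idx0)))))
    tab[keep, , drop = FALSE]
  })
}
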