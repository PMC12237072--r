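#' Logit and inverse-logit with clipping
#'
#' Classifier confidence scores live in (0, 1); before logit transformation
#' they are clipped to [1e-6, 1 - 1e-6] so that scores of exactly 0 or 1
#' (possible after rounding in upstream CSV exports) stay finite.
#'
#' @param p probabilities.
#' @return `logit_score()` returns log(p / (1 - p)) after clipping;
#'   `inv_logit()` the standard logistic function.
#' @export
logit_score <- function(p) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  log(p / (1 - p))
}

#' @rdname logit_score
#' @param x real values on the logit scale.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Hierarchical seeding
#'
#' All randomness in the simulator and the resampling stages flows from a
#' single integer seed. Sub-stages derive their own seed from the master seed
#' plus a stage name (and optional replicate index) so that changing one
#' stage's draws never perturbs another's. The derived seed is kept below
#' 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @param index optional replicate index (integer, default 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + index * 15485863) %% 2147483647)
}

#' Percentage of recorded hours with at least one independent detection
#'
#' @param n_detections integer count(s) of independent detections (at most one
#'   per species per recorded hour, so the count is also a count of hours).
#' @param total_hours total recorded hours across all sites and seasons.
#' @return percentage(s) on the 0-100 scale.
#' @export
detection_rate_pct <- function(n_detections, total_hours) {
  stopifnot(total_hours > 0, all(n_detections >= 0))
  100 * n_detections / total_hours
}

# internal: stop with a consistent error class
bp_stop <- function(msg, class = "birdpool_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
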