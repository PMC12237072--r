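#' Staged predictor selection for occupancy models
#'
#' Implements the multi-stage selection used for the occupancy component:
#' (1) drop zero-variance predictors; (2) cluster predictors whose absolute
#' pairwise correlation is at least `r_cut` (complete linkage on 1 - |r|)
#' and keep, per cluster, the member with the highest encounter-model
#' importance; (3) fit each survivor as a univariate occupancy model with
#' linear + quadratic terms and an intercept-only detection formula,
#' marking it informative when any of its 95% credible intervals excludes
#' zero; (4) fit the global model over informative predictors; (5)
#' backwards stepwise elimination, removing the predictor (its linear and
#' quadratic terms together) whose removal most improves WAIC, until no
#' removal improves it. Significance in the final model is a 95% BCI
#' excluding zero.
#'
#' @param hist a `det_histories` with site covariates attached.
#' @param candidates candidate occupancy predictor names (columns of
#'   `hist$sites`).
#' @param importances named numeric vector of encounter-model importances
#'   (used to pick cluster representatives; missing names score 0).
#' @param det_formula detection formula (fixed through selection).
#' @param r_cut correlation threshold for clustering (default 0.7).
#' @param mcmc list of MCMC settings for the selection fits (kept light by
#'   default).
#' @param seed integer seed.
#' @return list: `final_predictors`, `formula`, `final_fit`, `waic_path`,
#'   `informative`, `survivors`, `dropped_zero_var`, `intercept_only` flag.
#' @export
select_predictors <- function(hist, candidates, importances = NULL,
                              det_formula = ~ 1, r_cut = 0.7,
                              mcmc = list(chains = 2, iter = 1500,
                                          burn = 500, thin = 2),
                              seed = 1L) {
  sites <- hist$sites
  if (is.null(importances)) importances <- stats::setNames(rep(0, length(candidates)), candidates)
  # (1) zero-variance removal
  v <- vapply(candidates, function(nm) stats::var(sites[[nm]]), 0)
  dropped <- candidates[v == 0 | !is.finite(v)]
  cand <- setdiff(candidates, dropped)
  # (2) correlation clustering, keep highest-importance member
  if (length(cand) > 1) {
    R <- abs(stats::cor(sites[, cand, drop = FALSE]))
    hc <- stats::hclust(stats::as.dist(1 - R), method = "complete")
    cl <- stats::cutree(hc, h = 1 - r_cut)
    cand <- vapply(split(cand, cl), function(members) {
      sc <- importances[members]
      sc[is.na(sc)] <- 0
      members[which.max(sc)]
    }, "")
    cand <- unname(cand)
  }
  fit1 <- function(predictors, sd_off = 0) {
    f <- if (length(predictors) == 0) ~ 1 else
      stats::as.formula(paste("~", paste(
        unlist(lapply(predictors, function(p)
          c(p, sprintf("I(%s^2)", p)))), collapse = " + ")))
    do.call(fit_occupancy, c(list(hist = hist, occ_formula = f,
                                  det_formula = det_formula,
                                  seed = derive_seed(seed, "sel", sd_off)),
                             mcmc))
  }
  # (3) univariate screening
  informative <- character(0)
  for (i in seq_along(cand)) {
    f <- fit1(cand[i], sd_off = i)
    s <- summarize_fit(f)
    terms <- s[s$block == "beta" & s$term != "(Intercept)", ]
    if (any(terms$excludes_zero)) informative <- c(informative, cand[i])
  }
  if (length(informative) == 0) {
    warning("no informative predictors: returning intercept-only specification")
    final <- fit1(character(0), sd_off = 1000)
    return(list(final_predictors = character(0), formula = ~ 1,
                final_fit = final, waic_path = waic(final)$waic,
                informative = informative, survivors = cand,
                dropped_zero_var = dropped, intercept_only = TRUE))
  }
  # (4) global model, (5) backwards stepwise by WAIC
  current <- informative
  fit_cur <- fit1(current, sd_off = 2000)
  w_cur <- waic(fit_cur)$waic
  path <- w_cur
  repeat {
    if (length(current) == 0) break
    best_drop <- NULL; best_w <- w_cur; best_fit <- NULL
    for (j in seq_along(current)) {
      trial <- current[-j]
      f <- fit1(trial, sd_off = 3000 + length(path) * 100 + j)
      w <- waic(f)$waic
      if (w < best_w) { best_w <- w; best_drop <- j; best_fit <- f }
    }
    if (is.null(best_drop)) break
    current <- current[-best_drop]
    fit_cur <- best_fit
    w_cur <- best_w
    path <- c(path, w_cur)
  }
  list(final_predictors = current,
       formula = fit_cur$occ_formula,
       final_fit = fit_cur,
       waic_path = path,
       informative = informative,
       survivors = cand,
       dropped_zero_var = dropped,
       intercept_only = length(current) == 0)
}

# internal: posterior-mean per-visit detection probabilities for each site
predicted_p_by_site <- function(fit, hist) {
  des <- build_design(hist, fit$occ_formula, fit$det_formula)
  out <- stats::setNames(vector("list", des$n_sites), hist$sites$site_key)
  for (s in seq_along(des$W)) {
    src <- des$sources[s]
    a_mat <- fit$alpha[[src]]
    if (is.null(a_mat)) a_mat <- fit$alpha[[1]]
    common <- intersect(colnames(des$W[[s]]), colnames(a_mat))
    eta <- drop(des$W[[s]][, common, drop = FALSE] %*% colMeans(a_mat)[common])
    p <- inv_logit(eta)
    for (i in seq_along(p)) {
      k <- des$site[[s]][i]
      out[[k]] <- c(out[[k]], p[i])
    }
  }
  out
}

#' Filter evaluation sites by cumulative detectability
#'
#' Computes each evaluation site's cumulative detectability from the
#' relevant source's fitted detection submodel and retains only sites where
#' it exceeds `cutoff` — at retained sites an all-zero history is evidence
#' of absence rather than non-detection.
#'
#' @param eval_hist evaluation `det_histories`.
#' @param fits named list of single-source `occupancy_fit`s keyed by source
#'   ("citizen", "acoustic"), or one fit applied to all sites.
#' @param cutoff removal cutoff (default 0.9: sites with p_i <= 0.9 drop).
#' @return list with `histories` (the filtered set), `p_cum` (named vector
#'   over all input sites), `removed` (site keys).
#' @export
filter_eval_sites <- function(eval_hist, fits, cutoff = 0.9) {
  if (inherits(fits, "occupancy_fit"))
    fits <- list(citizen = fits, acoustic = fits)
  p_cum <- stats::setNames(numeric(nrow(eval_hist$sites)),
                           eval_hist$sites$site_key)
  for (src in unique(eval_hist$sites$source)) {
    keys <- eval_hist$sites$site_key[eval_hist$sites$source == src]
    sub <- subset_histories(eval_hist, keys)
    fit <- fits[[src]]
    if (is.null(fit)) bp_stop(sprintf("no fit supplied for source '%s'", src))
    pl <- predicted_p_by_site(fit, sub)
    p_cum[names(pl)] <- vapply(pl, cumulative_detectability, 0)
  }
  keep <- names(p_cum)[p_cum > cutoff]
  list(histories = subset_histories(eval_hist, keep),
       p_cum = p_cum, removed = setdiff(names(p_cum), keep))
}

# internal: posterior-mean occupancy probability for sites in a history set
predicted_psi <- function(fit, hist) {
  X <- stats::model.matrix(fit$occ_formula, hist$sites)
  # standardized with the evaluation set's own statistics, the same
  # convention applied at fitting time
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == "(Intercept)") next
    mu <- mean(X[, j]); sdv <- stats::sd(X[, j])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    X[, j] <- (X[, j] - mu) / sdv
  }
  common <- intersect(colnames(X), colnames(fit$beta))
  inv_logit(drop(X[, common, drop = FALSE] %*% colMeans(fit$beta)[common]))
}

#' Bootstrapped evaluation of occupancy fits
#'
#' Builds `n` subsamples of the evaluation set, each containing all
#' acoustic sites plus an equal number of citizen sites drawn to preserve
#' the citizen presence/absence ratio, scores site-level predicted
#' occupancy against the observed any-detection state, and reports
#' means/SDs of PR-AUC, sensitivity and specificity across subsamples.
#'
#' @param fit an `occupancy_fit` to evaluate.
#' @param eval_hist evaluation `det_histories` (typically already filtered
#'   by [filter_eval_sites()]).
#' @param n number of subsamples (default 100).
#' @param threshold decision threshold on predicted occupancy (default 0.5).
#' @param seed integer seed.
#' @return list with `summary` (mean/sd per metric) and `per_subsample`.
#' @export
bootstrap_evaluate <- function(fit, eval_hist, n = 100, threshold = 0.5,
                               seed = 1L) {
  psi <- predicted_psi(fit, eval_hist)
  truth <- eval_hist$sites$any_det
  src <- eval_hist$sites$source
  ac <- which(src == "acoustic")
  cit1 <- which(src == "citizen" & truth == 1)
  cit0 <- which(src == "citizen" & truth == 0)
  n_cit <- length(cit1) + length(cit0)
  rows <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("pr_auc", "sensitivity", "specificity")))
  set.seed(seed)
  for (b in seq_len(n)) {
    if (n_cit > 0 && length(ac) > 0) {
      m <- min(length(ac), n_cit)
      m1 <- round(m * length(cit1) / n_cit)
      m1 <- min(max(m1, if (length(cit1)) 1 else 0), length(cit1))
      m0 <- min(m - m1, length(cit0))
      pick <- c(ac,
                if (m1 > 0) sample(cit1, m1),
                if (m0 > 0) sample(cit0, m0))
    } else pick <- seq_along(truth)
    met <- suppressWarnings(compute_metrics(psi[pick], truth[pick], threshold))
    rows[b, ] <- c(met$pr_auc, met$sensitivity, met$specificity)
  }
  list(summary = data.frame(metric = colnames(rows),
                            mean = colMeans(rows, na.rm = TRUE),
                            sd = apply(rows, 2, stats::sd, na.rm = TRUE),
                            row.names = NULL),
       per_subsample = rows)
}

#' Predict occupancy surfaces
#'
#' Per masked cell: site covariates from [buffer_summaries()] around the
#' cell center, posterior-mean psi per fit, then mean and SD across the
#' supplied fits.
#'
#' @param fits list of `occupancy_fit`s (e.g., 10 bootstrap refits).
#' @param grid a `land_grid`.
#' @param mask logical matrix.
#' @param radii buffer radii for cell covariates.
#' @param cell_stride evaluate every k-th masked cell.
#' @return list of matrices `mean` and `sd` (NA outside mask).
#' @export
predict_occupancy_surface <- function(fits, grid, mask,
                                      radii = c(300, 1000),
                                      cell_stride = 1) {
  if (inherits(fits, "occupancy_fit")) fits <- list(fits)
  cc <- grid_centers(grid)
  cc <- cc[mask[cbind(cc$row, cc$col)], ]
  cc <- cc[seq(1, nrow(cc), by = cell_stride), ]
  pts <- data.frame(site_id = as.character(seq_len(nrow(cc))),
                    x = cc$x, y = cc$y)
  covs <- reshape_covariates(buffer_summaries(grid, pts, radii = radii))
  fake_hist <- list(sites = covs)
  psis <- vapply(fits, function(f) predicted_psi(f, fake_hist),
                 numeric(nrow(covs)))
  psis <- matrix(psis, nrow = nrow(covs))
  mean_m <- matrix(NA_real_, grid$nrow, grid$ncol)
  sd_m <- matrix(NA_real_, grid$nrow, grid$ncol)
  idx <- cbind(cc$row, cc$col)
  mean_m[idx] <- rowMeans(psis)
  sd_m[idx] <- if (ncol(psis) > 1) apply(psis, 1, stats::sd) else 0
  list(mean = mean_m, sd = sd_m)
}
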