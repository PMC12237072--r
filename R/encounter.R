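#' Monotone probability calibration
#'
#' Fits a non-decreasing map from raw model predictions to observed
#' outcome frequencies, the analog of the constrained monotone-GAM
#' calibration used in the encounter-rate literature. The default
#' "logistic" method is a sigmoid recalibration on the logit of the raw
#' prediction with the slope constrained non-negative: smooth and
#' low-variance, it resists the overfitting that motivates constrained
#' calibration when the map is fit on training predictions. The
#' "isotonic" method (pool-adjacent-violators with linear interpolation)
#' is the fully nonparametric alternative; its hard steps can push the
#' extremes of the training range to 0/1. Predictions outside the
#' training range are clamped. Constant predictions degenerate to the
#' identity map, flagged.
#'
#' @param raw_pred raw predicted probabilities (training data).
#' @param outcome observed 0/1 outcomes.
#' @param method "logistic" (default) or "isotonic".
#' @return list with `predict(p)` closure, `degenerate` flag, `method`,
#'   and the fitted coefficients or step coordinates.
#' @export
calibrate_monotone <- function(raw_pred, outcome,
                               method = c("logistic", "isotonic")) {
  method <- match.arg(method)
  stopifnot(length(raw_pred) == length(outcome))
  if (length(unique(raw_pred)) < 2) {
    warning("constant predictions: calibration degenerates to identity")
    return(list(predict = function(p) pmin(pmax(p, 0), 1),
                degenerate = TRUE, method = method, x = NULL, y = NULL))
  }
  rng <- range(raw_pred)
  clampr <- function(p) pmin(pmax(p, rng[1]), rng[2])
  if (method == "logistic") {
    x <- logit_score(raw_pred)
    fit <- suppressWarnings(
      stats::glm(outcome ~ x, family = stats::binomial()))
    cf <- stats::coef(fit)
    if (!is.finite(cf[2]) || cf[2] < 0) {
      # antitonic or degenerate relationship: the constraint binds and the
      # map collapses to the constant mean
      cf <- c(logit_score(mean(outcome)), 0)
    }
    return(list(predict = function(p)
      inv_logit(cf[1] + cf[2] * logit_score(clampr(p))),
      degenerate = FALSE, method = method, coef = unname(cf)))
  }
  iso <- stats::isoreg(raw_pred, outcome)
  ox <- if (is.null(iso$ord)) iso$x else iso$x[iso$ord]
  oy <- pmin(pmax(iso$yf, 0), 1)
  fx <- unique(data.frame(x = ox, y = oy))
  f <- stats::approxfun(fx$x, fx$y, method = "linear", rule = 2, ties = "ordered")
  list(predict = function(p) pmin(pmax(f(p), 0), 1),
       degenerate = FALSE, method = method, x = fx$x, y = fx$y)
}

# internal: stratified 80/20 split keeping >= 1 presence and absence in
# each part; synthetic rows are confined to the training portion
split_80_20 <- function(tab, seed) {
  set.seed(seed)
  test <- logical(nrow(tab))
  real <- !tab$synthetic
  for (cls in c(0, 1)) {
    idx <- which(tab$presence == cls & real)
    if (length(idx) < 2) next
    n_test <- max(1, round(0.2 * length(idx)))
    n_test <- min(n_test, length(idx) - 1)
    test[sample(idx, n_test)] <- TRUE
  }
  list(train = tab[!test, , drop = FALSE], test = tab[test, , drop = FALSE])
}

# internal: fit a probability forest and return model + importances
fit_encounter_rf <- function(train, predictors, num_trees, seed) {
  dat <- train[, c("presence", predictors)]
  dat$presence <- factor(dat$presence, levels = c(0, 1))
  ranger::ranger(presence ~ ., data = dat, probability = TRUE,
                 num.trees = num_trees, importance = "impurity",
                 seed = seed, num.threads = 1)
}

rf_prob <- function(model, newdata) {
  stats::predict(model, data = newdata, num.threads = 1)$predictions[, "1"]
}

#' Bootstrapped encounter-rate models
#'
#' Runs the full encounter-rate bootstrap for the three model classes
#' (citizen-only, acoustic-only, pooled). Per iteration: the citizen table
#' is spatiotemporally subsampled; each source is rebalanced by SMOTE to
#' the target presence fraction (sources treated separately, as in the
#' pooled design); non-citizen tables are subsampled to the citizen table's
#' size; a stratified 80/20 split (synthetic rows confined to training)
#' yields a shared test set containing both citizen and acoustic rows; a
#' probability random forest (Gini importance) is fitted per class,
#' calibrated on its training predictions by [calibrate_monotone()], and
#' evaluated on the shared test set at the MCC-maximizing training
#' threshold.
#'
#' @param ebird_table,acoustic_table zero-filled observation tables with
#'   `presence`, `source`, coordinates and the predictor columns.
#' @param predictors predictor column names (habitat + effort).
#' @param n_boot bootstrap iterations (default 100).
#' @param num_trees trees per forest (default 1000).
#' @param smote_target target presence fraction (default 0.25).
#' @param subsample_cell_m spatial subsampling cell (default 600).
#' @param threshold decision threshold for the binary metrics: a fixed
#'   probability (default 0.5 on the calibrated scale), or NULL to pick the
#'   MCC-maximizing threshold on each model's calibrated out-of-bag
#'   predictions.
#' @param seed integer seed.
#' @return list of per-class results: each a list of iterations holding
#'   `metrics`, `importance`, `model`, `calibration`, `threshold`.
#' @export
bootstrap_run <- function(ebird_table, acoustic_table, predictors,
                          n_boot = 100, num_trees = 1000,
                          smote_target = 0.25, subsample_cell_m = 600,
                          threshold = 0.5, seed = 1L) {
  for (tab in list(ebird_table, acoustic_table))
    if (nrow(tab) == 0 || length(unique(tab$presence)) < 2)
      bp_stop("each source table needs both presence classes")
  classes <- c("citizen", "acoustic", "pooled")
  res <- stats::setNames(vector("list", 3), classes)
  for (cl in classes) res[[cl]] <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    sd_b <- derive_seed(seed, "boot", b)
    eb <- spatiotemporal_subsample(ebird_table, cell_m = subsample_cell_m,
                                   seed = derive_seed(sd_b, "sub"))
    skip <- FALSE
    eb_s <- try(smote_balance(eb, predictors, target = smote_target,
                              seed = derive_seed(sd_b, "smote_e")), silent = TRUE)
    ac_s <- try(smote_balance(acoustic_table, predictors, target = smote_target,
                              seed = derive_seed(sd_b, "smote_a")), silent = TRUE)
    if (inherits(eb_s, "try-error") || inherits(ac_s, "try-error")) {
      message(sprintf("iteration %d skipped: a class lacks presences", b))
      next
    }
    eq <- equalize_sample_sizes(eb_s, list(acoustic = ac_s), seed = derive_seed(sd_b, "eq"))
    ac_s <- eq$acoustic
    common <- intersect(names(eb_s), names(ac_s))
    pooled <- rbind(eb_s[, common], ac_s[, common])
    eq2 <- equalize_sample_sizes(eb_s, list(pooled = pooled), seed = derive_seed(sd_b, "eq2"))
    pooled <- eq2$pooled
    sp <- split_80_20(pooled, derive_seed(sd_b, "split"))
    test <- sp$test
    if (length(unique(test$presence)) < 2 ||
        length(unique(test$source)) < 2) {
      message(sprintf("iteration %d skipped: unusable test set", b))
      next
    }
    train_tabs <- list(citizen = sp$train[sp$train$source == "citizen", ],
                       acoustic = sp$train[sp$train$source == "acoustic", ],
                       pooled = sp$train)
    for (cl in classes) {
      tr <- train_tabs[[cl]]
      if (length(unique(tr$presence)) < 2) {
        message(sprintf("iteration %d, class %s skipped: one class only", b, cl))
        next
      }
      mod <- fit_encounter_rf(tr, predictors, num_trees, derive_seed(sd_b, cl))
      # out-of-bag training predictions: in-bag ones are overfit and distort
      # both the monotone calibration and the decision threshold
      p_tr <- mod$predictions[, "1"]
      ok_oob <- !is.na(p_tr)
      calib <- calibrate_monotone(p_tr[ok_oob], tr$presence[ok_oob])
      p_tr <- p_tr[ok_oob]
      tr <- tr[ok_oob, , drop = FALSE]
      p_tr_c <- calib$predict(p_tr)
      th <- if (is.null(threshold))
        best_mcc_threshold(p_tr_c, tr$presence) else threshold
      p_te <- calib$predict(rf_prob(mod, test[, predictors]))
      met <- suppressWarnings(compute_metrics(p_te, test$presence, th))
      res[[cl]][[b]] <- list(metrics = met,
                             importance = mod$variable.importance,
                             model = mod, calibration = calib,
                             threshold = th)
    }
  }
  res
}

#' Summarize bootstrap metrics
#'
#' @param boot result of [bootstrap_run()].
#' @return data.frame with one row per model class x metric: mean and SD
#'   across completed iterations.
#' @export
summarize_bootstrap <- function(boot) {
  out <- list()
  for (cl in names(boot)) {
    done <- Filter(Negate(is.null), boot[[cl]])
    if (!length(done)) next
    mm <- do.call(rbind, lapply(done, function(it)
      unlist(it$metrics[c("kappa", "mcc", "mse", "sensitivity",
                          "specificity", "pr_auc")])))
    out[[cl]] <- data.frame(class = cl, metric = colnames(mm),
                            mean = colMeans(mm, na.rm = TRUE),
                            sd = apply(mm, 2, stats::sd, na.rm = TRUE),
                            n = nrow(mm), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Mixed-effects contrasts of predictor importances
#'
#' Fits the three contrast models comparing Gini importances across model
#' classes with species as a random intercept: (a) 300 m vs 1 km spatial
#' scale by dataset, (b) habitat vs detection covariate by dataset, (c)
#' forest-characteristic indicator (FCI) vs non-forest predictor by
#' dataset. Returns estimated marginal mean differences with standard
#' errors and p-values via emmeans. With fewer than 2 species the fit
#' degenerates to fixed effects, flagged.
#'
#' @param imp long data.frame with columns `species`, `dataset`,
#'   `predictor`, `importance`, and logical/character columns `scale`
#'   ("300m"/"1km"), `is_habitat`, `is_fci` (NA allowed where a contrast
#'   does not apply).
#' @return list of contrast tables (`scale`, `habitat`, `fci`) plus a
#'   `fixed_effects_fallback` flag.
#' @export
importance_contrasts <- function(imp) {
  fallback <- length(unique(imp$species)) < 2
  fit_one <- function(formula_mixed, formula_fixed, data, spec) {
    data <- data[stats::complete.cases(data[, all.vars(formula_fixed)]), ]
    if (fallback) {
      m <- stats::lm(formula_fixed, data = data)
    } else {
      m <- suppressMessages(lmerTest::lmer(formula_mixed, data = data))
    }
    em <- emmeans::emmeans(m, spec)
    as.data.frame(emmeans::contrast(em, method = "revpairwise", by = "dataset"))
  }
  res <- list(fixed_effects_fallback = fallback)
  res$scale <- fit_one(importance ~ scale * dataset + (1 | species),
                       importance ~ scale * dataset, imp,
                       ~ scale | dataset)
  res$habitat <- fit_one(importance ~ is_habitat * dataset + (1 | species),
                         importance ~ is_habitat * dataset, imp,
                         ~ is_habitat | dataset)
  fci_dat <- imp[imp$is_habitat %in% c(TRUE, "yes", "habitat"), ]
  res$fci <- fit_one(importance ~ is_fci * dataset + (1 | species),
                     importance ~ is_fci * dataset, fci_dat,
                     ~ is_fci | dataset)
  if (fallback) warning("fewer than 2 species: fixed-effects fallback used")
  res
}

#' Predict encounter-rate surfaces
#'
#' For every cell inside the mask: habitat covariates come from
#' [buffer_summaries()] at both radii around the cell center, effort
#' covariates are fixed at the standardized-survey values (1 h stationary
#' count, 1 observer, the species' peak activity hour), and each bootstrap
#' model's calibrated prediction is computed. Returns the per-cell mean and
#' SD across models.
#'
#' @param boot_class one class's list from [bootstrap_run()].
#' @param grid a `land_grid`.
#' @param mask logical matrix from [build_prediction_surface()].
#' @param radii buffer radii (default `c(300, 1000)`).
#' @param effort named list of fixed effort covariate values.
#' @param cell_stride evaluate every `cell_stride`-th cell (prediction
#'   resolution; default 1).
#' @return list of matrices `mean` and `sd` (NA outside the mask).
#' @export
predict_surface <- function(boot_class, grid, mask, radii = c(300, 1000),
                            effort = list(duration = 1, distance = 0,
                                          observers = 1, hour = 6,
                                          day_of_year = 180, year = 2020,
                                          speed = 0),
                            cell_stride = 1) {
  done <- Filter(Negate(is.null), boot_class)
  if (!length(done)) bp_stop("no completed bootstrap iterations")
  cc <- grid_centers(grid)
  cc <- cc[mask[cbind(cc$row, cc$col)], ]
  cc <- cc[seq(1, nrow(cc), by = cell_stride), ]
  pts <- data.frame(site_id = seq_len(nrow(cc)), x = cc$x, y = cc$y)
  covs <- buffer_summaries(grid, pts, radii = radii)
  wide <- reshape_covariates(covs)
  for (nm in names(effort)) wide[[nm]] <- effort[[nm]]
  mean_m <- matrix(NA_real_, grid$nrow, grid$ncol)
  sd_m <- matrix(NA_real_, grid$nrow, grid$ncol)
  predictors <- names(done[[1]]$model$variable.importance)
  missing_cols <- setdiff(predictors, names(wide))
  for (nm in missing_cols) wide[[nm]] <- 0
  preds <- vapply(done, function(it)
    it$calibration$predict(rf_prob(it$model, wide[, predictors])),
    numeric(nrow(wide)))
  preds <- matrix(preds, nrow = nrow(wide))
  idx <- cbind(cc$row, cc$col)
  mean_m[idx] <- rowMeans(preds)
  sd_m[idx] <- apply(preds, 1, stats::sd)
  if (length(done) == 1) sd_m[idx] <- 0
  list(mean = mean_m, sd = sd_m)
}

#' Pivot buffer summaries to one row per site
#'
#' Renames each covariate with its radius suffix (`_300m` / `_1km` style)
#' and joins radii side by side, the shape expected by model fitting.
#'
#' @param covs output of [buffer_summaries()].
#' @return data.frame, one row per `site_id`.
#' @export
reshape_covariates <- function(covs) {
  radii <- sort(unique(covs$radius_m))
  pieces <- lapply(radii, function(r) {
    sub <- covs[covs$radius_m == r, setdiff(names(covs), "radius_m")]
    suff <- if (r >= 1000) sprintf("_%gkm", r / 1000) else sprintf("_%gm", r)
    names(sub)[-1] <- paste0(names(sub)[-1], suff)
    sub
  })
  Reduce(function(a, b) merge(a, b, by = "site_id", sort = FALSE), pieces)
}
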