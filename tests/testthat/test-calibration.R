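test_that("stratified sampling caps per elevation band and is seeded", {
  set.seed(1)
  ev <- data.frame(confidence = runif(100, 0.3, 1),
                   elevation = rep(205, 100))
  s1 <- stratified_score_sample(ev, cap = 30, seed = 3)
  s2 <- stratified_score_sample(ev, cap = 30, seed = 3)
  expect_identical(s1, s2)
  # one band: 30 primary + up to 30 extra high-score events
  n_high_total <- sum(ev$confidence >= 0.8)
  n_high_in_prim <- sum(s1$confidence >= 0.8) # includes second-sample picks
  expect_gte(nrow(s1), 30)
  expect_lte(nrow(s1), 60)
  # fewer events than cap: all returned
  few <- ev[1:7, ]
  expect_equal(nrow(stratified_score_sample(few, cap = 30, seed = 1)),
               nrow(few[few$confidence >= 0.3, ]))
  # two bands are sampled independently
  ev2 <- data.frame(confidence = runif(200, 0.3, 0.79),
                    elevation = rep(c(205, 215), each = 100))
  s3 <- stratified_score_sample(ev2, cap = 30, seed = 5)
  expect_equal(unname(table(floor(s3$elevation / 10))), c(30L, 30L),
               ignore_attr = TRUE)
  expect_error(stratified_score_sample(ev[0, ], seed = 1), "no events")
})

test_that("AICc arithmetic and candidate-model comparison are correct", {
  expect_equal(birdpool:::aicc(-50, 2, 100), 104 + 12 / 97, tolerance = 1e-10)
  # labels independent of score: the null wins the clear majority of
  # seeded replicates (the flexible smooth overfits in a minority)
  wins <- 0
  for (r in 1:50) {
    set.seed(1000 + r)
    lab <- data.frame(logit_score = rnorm(120), elevation = runif(120, 200, 290),
                      label = sample(c("true", "false"), 120, replace = TRUE))
    cal <- fit_score_models(lab)
    if (cal$chosen == "null") wins <- wins + 1
  }
  expect_gte(wins, 35)
  # labels generated with an elevation effect: the smooth model wins
  set.seed(77)
  n <- 500
  ls <- rnorm(n, 0, 1.5)
  el <- runif(n, 200, 290)
  p <- plogis(2 * ls + 2.5 * sin((el - 200) / 30))
  lab <- data.frame(logit_score = ls, elevation = el,
                    label = ifelse(rbinom(n, 1, p) == 1, "true", "false"))
  cal <- fit_score_models(lab)
  expect_equal(cal$chosen, "logistic_elev")
  expect_equal(unname(which.min(cal$aicc)), 3L)
  # calibration probability non-decreasing in score at fixed elevation
  nd <- data.frame(logit_score = seq(-3, 3, 0.25), elevation = 250)
  pr <- cal$predict_prob(nd)
  expect_true(all(diff(pr) >= -1e-8))
})

test_that("perfect separation triggers a flagged penalized fallback", {
  lab <- data.frame(logit_score = c(-3, -2.5, -2, 2, 2.5, 3),
                    elevation = rep(c(210, 250), 3),
                    label = c("false", "false", "false", "true", "true", "true"))
  expect_silent(cal <- fit_score_models(lab))
  expect_true(cal$separation)
  p <- cal$predict_prob(data.frame(logit_score = c(-3, 3), elevation = c(210, 250)))
  expect_true(all(is.finite(p)))
  expect_lt(p[1], p[2])
})

test_that("the fpr-constrained threshold matches brute force and is monotone in fpr_max", {
  toy <- data.frame(prob = c(0.35, 0.5, 0.6, 0.7, 0.8, 0.9),
                    label = c("false", "false", "true", "false", "true", "true"))
  sel <- select_threshold(NULL, toy, fpr_max = 0.05, grid_step = 0.01)
  expect_equal(sel$threshold, 0.71)
  expect_equal(sel$achieved_fpr, 0)
  # brute-force check of the feasibility frontier: every smaller grid value fails
  below <- sel$grid[sel$grid$theta < sel$threshold & sel$grid$n > 0, ]
  expect_true(all(below$fpr >= 0.05))
  # all-true labels: grid minimum wins with fpr 0
  allt <- data.frame(prob = c(0.2, 0.6, 0.9), label = rep("true", 3))
  sel_t <- select_threshold(NULL, allt, fpr_max = 0.05, grid_step = 0.01)
  expect_equal(sel_t$threshold, 0)
  expect_equal(sel_t$achieved_fpr, 0)
  # raising fpr_max never increases the threshold
  lab <- make_labeled_sample(n = 250, slope = 3, seed = 41)
  cal <- fit_score_models(lab)
  th <- vapply(c(0.02, 0.05, 0.1, 0.2), function(fm)
    select_threshold(cal, lab, fpr_max = fm)$threshold, 0)
  expect_true(all(diff(th) <= 0))
  # infeasible constraint errors with guidance
  allf <- data.frame(prob = c(0.5, 0.7), label = rep("false", 2))
  expect_error(select_threshold(NULL, allf, fpr_max = 0.05), "fpr_max")
})

test_that("end-to-end calibration keeps held-out fpr near the bound", {
  ok <- 0
  for (r in 1:50) {
    lab <- make_labeled_sample(n = 560, slope = 3, seed = 5000 + r)
    train <- lab[1:260, ]; held <- lab[261:560, ]
    cal <- fit_score_models(train)
    sel <- try(select_threshold(cal, train, fpr_max = 0.05), silent = TRUE)
    if (inherits(sel, "try-error")) next
    acc <- apply_threshold(held, cal, sel$threshold)
    fpr_h <- if (nrow(acc) == 0) 0 else mean(acc$label == "false")
    if (fpr_h < 2 * 0.05) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("hourly collapse and zero-filling obey the recording log", {
  ev <- data.frame(site_id = "A", species = "sp",
                   date = as.Date("2020-01-05"),
                   hour = c(10, 10, 10, 10, 10))
  expect_equal(nrow(collapse_independent(ev)), 1)
  ev2 <- ev; ev2$hour <- c(10, 11, 10, 11, 10)
  expect_equal(nrow(collapse_independent(ev2)), 2)
  expect_equal(nrow(collapse_independent(ev[0, ])), 0)
  log10 <- data.frame(site_id = "A", date = as.Date("2020-01-05"), hour = 5:14)
  zf <- zero_fill_acoustic(collapse_independent(ev), log10)
  expect_equal(sum(zf$presence), 1)
  expect_equal(nrow(zf), 10)
  # presence at an unlogged hour is a data-integrity error naming the row
  bad <- data.frame(site_id = "A", species = "sp",
                    date = as.Date("2020-01-05"), hour = 23)
  expect_error(zero_fill_acoustic(bad, log10), "A|2020-01-05|23")
  # a species never detected yields an all-zero column
  zf0 <- zero_fill_acoustic(collapse_independent(ev[0, ]), log10)
  expect_true(all(zf0$presence == 0))
})

test_that("diel-schedule filtering keeps only whitelisted hours", {
  ev <- data.frame(hour = 0:23, season = "2024")
  expect_equal(nrow(temporal_match_filter(ev, 0:23)), 24)
  expect_equal(suppressMessages(temporal_match_filter(ev, 5:9))$hour, 5:9)
  expect_equal(nrow(suppressMessages(temporal_match_filter(ev, integer(0)))), 0)
  ev$season <- rep(c("2020", "2024"), 12)
  out <- suppressMessages(
    temporal_match_filter(ev, list("2020" = 0:23, "2024" = 5:9)))
  expect_true(all(out$hour[out$season == "2024"] %in% 5:9))
  expect_error(temporal_match_filter(ev, list("2020" = 1:3)), "season")
})
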