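test_that("HAND equals elevation minus nearest-drainage elevation, floored at zero", {
  # 1-D ridge: drainage at cell 1
  elev <- matrix(c(100, 103, 108), nrow = 1)
  dr <- matrix(c(TRUE, FALSE, FALSE), nrow = 1)
  expect_equal(compute_hand(elev, dr), matrix(c(0, 3, 8), nrow = 1))
  # flat field: HAND identically zero wherever drainage exists
  flat <- matrix(5, 6, 6)
  drf <- matrix(FALSE, 6, 6); drf[3, 2] <- TRUE
  expect_true(all(compute_hand(flat, drf) == 0))
  # cells below their nearest drainage floor at 0
  ev <- matrix(c(100, 95), nrow = 1)
  dv <- matrix(c(TRUE, FALSE), nrow = 1)
  expect_equal(compute_hand(ev, dv)[1, 2], 0)
  # brute-force agreement on random grids
  set.seed(42)
  for (rep in 1:3) {
    e <- matrix(runif(15 * 12, 100, 200), 15, 12)
    d <- matrix(runif(15 * 12) < 0.08, 15, 12)
    if (!any(d)) d[1, 1] <- TRUE
    expect_equal(compute_hand(e, d), hand_oracle(e, d), tolerance = 1e-12)
  }
  expect_error(compute_hand(flat, matrix(FALSE, 6, 6)), "empty")
})

test_that("landscapes are deterministic in the seed and structurally valid", {
  w1 <- small_world(seed = 5)
  w2 <- small_world(seed = 5)
  expect_identical(w1$grid$layers, w2$grid$layers)
  g <- w1$grid
  expect_true(all(g$layers$hand >= 0))
  expect_true(all(g$layers$hand[g$layers$drainage] == 0))
  expect_true(all(g$layers$cover %in% seq_along(landcover_classes())))
  # HAND tracks the gradient: mean HAND in the far half of each row exceeds
  # mean HAND adjacent to the channel
  near <- g$layers$hand[g$layers$hand < quantile(g$layers$hand, 0.25)]
  far <- g$layers$hand[g$layers$hand > quantile(g$layers$hand, 0.75)]
  expect_gt(mean(far), mean(near))
  # anthropogenic classes exist (town + mining beach seeded)
  codes <- match(c("crops", "built_area"), landcover_classes())
  expect_true(any(g$layers$cover %in% codes))
})

test_that("simulated occupancy follows the configured logistic model", {
  w <- small_world(seed = 9)
  # intercept-only at logit 0: mean occupancy ~= 0.5 within 3 binomial SEs
  cfg0 <- sim_config(seed = 21, occ_intercept = 0, occ_beta_hand = 0,
                     occ_beta_canopy = 0)
  n <- 1000
  set.seed(33)
  sites <- data.frame(site_id = as.character(1:n),
                      x = runif(n, 30, 1100), y = runif(n, 30, 1100))
  occ <- simulate_occupancy(w$grid, cfg0, sites)
  expect_true(all(occ$psi == 0.5))
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(occ$z) - 0.5), 3 * se)
  # saturated negative intercept: no occupied sites
  cfg_neg <- sim_config(seed = 21, occ_intercept = -20, occ_beta_hand = 0)
  occ_neg <- simulate_occupancy(w$grid, cfg_neg, sites)
  expect_true(all(occ_neg$z == 0))
  # strong positive HAND effect: top HAND quartile more occupied than bottom
  cfg_h <- sim_config(seed = 21, occ_intercept = -2, occ_beta_hand = 4)
  occ_h <- simulate_occupancy(w$grid, cfg_h, sites)
  qs <- quantile(occ_h$hand, c(0.25, 0.75))
  expect_gt(mean(occ_h$z[occ_h$hand >= qs[2]]),
            mean(occ_h$z[occ_h$hand <= qs[1]]))
})

test_that("acoustic simulation respects rates and the label-conditional score model", {
  w <- small_world(seed = 13)
  sites <- place_aru_sites(w$grid, 16, seed = 4)
  dates <- seq(as.Date("2020-02-01"), by = "day", length.out = 6)
  sched <- recording_schedule(sites, dates, hours = 5:9)
  # zero rates: empty stream
  cfg0 <- sim_config(seed = 13, vocal_rate = 0, false_rate = 0)
  occ <- simulate_occupancy(w$grid, cfg0, sites)
  expect_equal(nrow(simulate_aru_surveys(occ, sched, cfg0)$events), 0)
  # saturated vocal rate with z = 1 everywhere: every hour holds a true event
  cfg1 <- sim_config(seed = 13, occ_intercept = 20, vocal_rate = 50,
                     false_rate = 0)
  occ1 <- simulate_occupancy(w$grid, cfg1, sites)
  expect_true(all(occ1$z == 1))
  ev1 <- simulate_aru_surveys(occ1, sched, cfg1)$events
  hrs <- unique(paste(ev1$site_id, ev1$date, ev1$hour))
  expect_equal(length(hrs), nrow(sched))
  # no true detections at unoccupied sites
  cfgm <- sim_config(seed = 13, occ_intercept = 0, vocal_rate = 1,
                     false_rate = 0.3)
  occm <- simulate_occupancy(w$grid, cfgm, sites)
  evm <- simulate_aru_surveys(occm, sched, cfgm)$events
  emptyz <- occm$site_id[occm$z == 0]
  expect_true(all(evm$label[evm$site_id %in% emptyz] == "false"))
})

test_that("score labels follow the induced logistic calibration curve", {
  # equal class frequencies, mu = +-1, sd^2 = 0.5 -> slope 4, intercept 0
  w <- small_world(seed = 17)
  cfg <- sim_config(seed = 17, occ_intercept = 20, vocal_rate = 0.3,
                    false_rate = 1 - exp(-0.3),
                    score_mu_true = 1, score_mu_false = -1,
                    score_sd = sqrt(0.5))
  sites <- place_aru_sites(w$grid, 25, seed = 6)
  occ <- simulate_occupancy(w$grid, cfg, sites)
  dates <- seq(as.Date("2020-02-01"), by = "day", length.out = 40)
  sched <- recording_schedule(sites, dates, hours = 0:23)
  ev <- simulate_aru_surveys(occ, sched, cfg)$events
  bin <- ev[ev$logit_score >= 0.9 & ev$logit_score <= 1.1, ]
  phat <- mean(bin$label == "true")
  p_theory <- plogis(4 * 1)
  se <- sqrt(p_theory * (1 - p_theory) / nrow(bin))
  expect_lt(abs(phat - p_theory), 4 * se + 0.01)
})

test_that("checklist locations are biased toward low HAND only when configured", {
  w <- small_world(seed = 23)
  g <- w$grid
  cfg_b <- sim_config(seed = 23, checklist_bias = 3)
  cl_b <- simulate_checklists(g, cfg_b, 500)$checklists
  idx <- function(cl) {
    col <- floor((cl$x - 0) / g$cell_size) + 1
    row <- g$nrow - floor((cl$y - 0) / g$cell_size)
    cbind(pmin(pmax(row, 1), g$nrow), pmin(pmax(col, 1), g$ncol))
  }
  expect_lt(mean(g$layers$hand[idx(cl_b)]), mean(g$layers$hand))
  # fully unbiased effort (no river decay, no hotspot snapping)
  # reproduces the landscape HAND distribution
  cfg_u <- sim_config(seed = 29, checklist_bias = 0, p_hotspot = 0)
  cl_u <- simulate_checklists(g, cfg_u, 800)$checklists
  ks <- suppressWarnings(ks.test(g$layers$hand[idx(cl_u)],
                                 as.vector(g$layers$hand)))
  expect_gt(ks$p.value, 0.01)
  # saturated detection with full occupancy: every complete checklist records it
  cfg_d <- sim_config(seed = 31, det_intercept = 30, p_x = 0, p_incomplete = 0)
  z1 <- matrix(1L, g$nrow, g$ncol)
  cl_d <- simulate_checklists(g, cfg_d, 200, z_cell = z1)$checklists
  expect_true(all(cl_d$species_count == "1"))
})

test_that("derived seeds stay in integer range and differ across stages", {
  s <- c(derive_seed(1, "a"), derive_seed(1, "b"), derive_seed(2, "a"),
         derive_seed(1, "a", 5))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 4)
  expect_identical(derive_seed(7, "stage", 3), derive_seed(7, "stage", 3))
})
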