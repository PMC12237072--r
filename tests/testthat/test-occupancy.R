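# hand-built histories: n sites, J visits, covariate `cov`
mk_hist <- function(n = 50, J = 3, b0 = 0, b1 = 1, a0 = 0.5, a1 = 0,
                    seed = 1, source = "citizen") {
  set.seed(seed)
  x <- rnorm(n)
  z <- rbinom(n, 1, plogis(b0 + b1 * x))
  sites <- data.frame(site_key = sprintf("%s%04d", substr(source, 1, 3), 1:n),
                      source = source, x = 0, y = 0, cov = x,
                      stringsAsFactors = FALSE)
  visits <- do.call(rbind, lapply(1:n, function(i) {
    w <- rnorm(J)
    data.frame(site_key = sites$site_key[i], visit = 1:J,
               y = rbinom(J, 1, plogis(a0 + a1 * w)) * z[i], w = w)
  }))
  sites$any_det <- as.integer(tapply(visits$y, visits$site_key, max)[sites$site_key])
  structure(list(sites = sites, visits = visits, z = z),
            class = "det_histories")
}

test_that("marginal likelihood matches enumeration over latent states", {
  # worked single-site cases: psi = 0.5, p = 0.5
  X <- matrix(1, 1, 1); W <- matrix(1, 2, 1)
  r <- occupancy_loglik(0, 0, X, W, c(1, 0), c(1, 1))
  expect_equal(r$L_site, 0.125)
  expect_equal(r$loglik, log(0.125), tolerance = 1e-10)
  r0 <- occupancy_loglik(0, 0, X, W, c(0, 0), c(1, 1))
  expect_equal(r0$L_site, 0.625)
  # psi -> 1 reduces to pure Bernoulli detection likelihood
  r1 <- occupancy_loglik(20, 0, X, W, c(0, 0), c(1, 1))
  expect_equal(r1$loglik, 2 * log(0.5), tolerance = 1e-6)
  # brute-force z-enumeration on random <= 10-site instances
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    Xr <- cbind(1, rnorm(n))
    site <- rep(seq_len(n), each = 3)
    Wr <- cbind(1, rnorm(3 * n))
    yr <- rbinom(3 * n, 1, 0.4)
    beta <- rnorm(2); alpha <- rnorm(2)
    got <- occupancy_loglik(beta, alpha, Xr, Wr, yr, site)$loglik
    want <- occ_loglik_oracle(beta, alpha, Xr, Wr, yr, site)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(occupancy_loglik(c(Inf, 1), 0, X, W, c(1, 0), c(1, 1)),
               "non-finite")
})

test_that("WAIC follows its closed form on stored likelihood draws", {
  # all draws L = 0.5 at one site: lppd = log 0.5, p_waic = 0
  L <- matrix(0.5, nrow = 40, ncol = 1)
  w <- waic(L)
  expect_equal(w$lppd, log(0.5))
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * log(0.5), tolerance = 1e-10)
  expect_equal(w$waic, 1.3863, tolerance = 1e-4)
  # adding a site increases WAIC (each -2 log term is positive)
  L2 <- cbind(L, runif(40, 0.2, 0.8))
  expect_gt(waic(L2)$waic, w$waic)
  # direct recomputation from an occupancy_fit's stored draws
  h <- mk_hist(n = 40, J = 3, seed = 3)
  f <- fit_occupancy(h, ~ cov, ~ 1, chains = 2, iter = 600, burn = 200,
                     thin = 2, seed = 4)
  manual <- {
    L <- pmax(f$L_site, 1e-300)
    -2 * (sum(log(colMeans(L))) - sum(apply(log(L), 2, var)))
  }
  expect_equal(waic(f)$waic, manual, tolerance = 1e-12)
})

test_that("cumulative detectability and the removal rule behave as specified", {
  expect_equal(cumulative_detectability(c(0.5, 0.5)), 0.75)
  expect_equal(cumulative_detectability(c(0.2, 0.3, 0.4)), 0.664)
  expect_equal(cumulative_detectability(numeric(0)), 0)
  expect_equal(cumulative_detectability(c(0.95, 0.95)), 0.9975)
  expect_error(cumulative_detectability(c(0.5, 1.2)), "\\[0, 1\\]")
  # removal rule on simulated visit-level probabilities
  set.seed(3)
  p_list <- lapply(1:50, function(i) runif(sample(1:8, 1), 0.1, 0.95))
  p_cum <- vapply(p_list, cumulative_detectability, 0)
  kept <- p_cum[p_cum > 0.9]
  expect_true(all(kept >= 0.9))
  expect_true(length(kept) < 50)  # the rule actually removes some sites
})

test_that("detection histories group, cap and bin visits correctly", {
  # citizen: same observer, same snapped location, one closure period
  n <- 12
  obs <- data.frame(
    source = "citizen", x = 100 + runif(n, -50, 50), y = 200 + runif(n, -50, 50),
    date = as.Date("2021-01-01") + seq_len(n),
    presence = rep(c(1, 0), 6), observer_id = "obsA",
    duration = 1, distance = 0, observers = 1, protocol = "stationary",
    start_time = "06:30", stringsAsFactors = FALSE)
  h <- build_histories(obs, seed = 5)
  expect_equal(nrow(h$sites), 1)
  expect_equal(nrow(h$visits), 10)       # 12 visits capped at 10
  expect_equal(h$sites$any_det, 1)
  # a single visit is excluded (and an empty result warns)
  expect_warning(h1 <- build_histories(obs[1, , drop = FALSE], seed = 5),
                 "no detection histories")
  expect_equal(nrow(h1$sites), 0)
  # different observers never share a history
  obs2 <- obs; obs2$observer_id <- rep(c("a", "b"), each = 6)
  h2 <- build_histories(obs2, seed = 5)
  expect_equal(nrow(h2$sites), 2)
  # acoustic: 9 recording days, detections on day 4 only -> visits (0,1,0)
  ac <- expand.grid(date = as.Date("2021-03-01") + 0:8, hour = 5:7)
  ac$source <- "acoustic"; ac$site_id <- "ARU01"; ac$x <- 10; ac$y <- 10
  ac$presence <- as.integer(ac$date == as.Date("2021-03-04") & ac$hour == 6)
  ha <- build_histories(ac, seed = 5)
  expect_equal(nrow(ha$visits), 3)
  expect_equal(ha$visits$y, c(0, 1, 0))
  expect_equal(ha$visits$effort_hours, c(9, 9, 9))
  # hour covariate: first detection hour in the detected block
  expect_equal(ha$visits$hour[2], 6)
  expect_equal(ha$visits$hour[1], 5)
  # deterministic under the seed
  expect_identical(build_histories(obs, seed = 5), h)
})

test_that("low-detectability sites are removed from evaluation sets", {
  h <- mk_hist(n = 60, J = 2, b0 = 0.5, b1 = 0, a0 = 0, seed = 11)
  f <- fit_occupancy(h, ~ 1, ~ 1, chains = 2, iter = 600, burn = 200,
                     thin = 2, seed = 12)
  # alpha near 0 -> p ~ 0.5 per visit, p_cum ~ 0.75 < 0.9: all removed
  fl <- filter_eval_sites(h, list(citizen = f), cutoff = 0.9)
  expect_equal(nrow(fl$histories$sites), 0)
  expect_true(all(fl$p_cum < 0.9))
  # cutoff 0 retains every site
  fl0 <- filter_eval_sites(h, list(citizen = f), cutoff = 0)
  expect_equal(nrow(fl0$histories$sites), 60)
  # retained sites always exceed the cutoff
  h6 <- mk_hist(n = 60, J = 6, a0 = 1, seed = 13)
  f6 <- fit_occupancy(h6, ~ 1, ~ 1, chains = 2, iter = 600, burn = 200,
                      thin = 2, seed = 14)
  fl6 <- filter_eval_sites(h6, list(citizen = f6), cutoff = 0.9)
  expect_true(all(fl6$p_cum[fl6$histories$sites$site_key] > 0.9))
})

test_that("rank-normalized split R-hat flags stuck chains and passes mixed ones", {
  set.seed(31)
  mixed <- matrix(rnorm(4000), 1000, 4)
  expect_lt(birdpool:::rhat_rank(mixed), 1.01)
  stuck <- cbind(rnorm(1000, 0), rnorm(1000, 6))
  expect_gt(birdpool:::rhat_rank(stuck), 1.5)
  expect_equal(birdpool:::rhat_rank(matrix(1, 100, 3)), 1)
})
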