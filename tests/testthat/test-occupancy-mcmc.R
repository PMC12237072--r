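# simulate histories for one or two sources from a shared occupancy model
sim_hist <- function(n, J, b0, b1, a0, seed, source = "citizen") {
  set.seed(seed)
  x <- rnorm(n)
  z <- rbinom(n, 1, plogis(b0 + b1 * x))
  sites <- data.frame(site_key = sprintf("%s%04d", substr(source, 1, 3), 1:n),
                      source = source, x = 0, y = 0, cov = x,
                      stringsAsFactors = FALSE)
  visits <- do.call(rbind, lapply(1:n, function(i)
    data.frame(site_key = sites$site_key[i], visit = 1:J,
               y = rbinom(J, 1, plogis(a0)) * z[i])))
  sites$any_det <- as.integer(tapply(visits$y, visits$site_key, max)[sites$site_key])
  structure(list(sites = sites, visits = visits), class = "det_histories")
}

join_hist <- function(h1, h2) {
  structure(list(sites = rbind(h1$sites, h2$sites),
                 visits = rbind(h1$visits, h2$visits)),
            class = "det_histories")
}

light <- list(chains = 2, iter = 800, burn = 300, thin = 2)

test_that("the sampler is seed-deterministic and saturates correctly", {
  h <- sim_hist(50, 3, 0.5, 1, 1, seed = 2)
  f1 <- fit_occupancy(h, ~ cov, ~ 1, chains = 2, iter = 500, burn = 200,
                      thin = 2, seed = 9)
  f2 <- fit_occupancy(h, ~ cov, ~ 1, chains = 2, iter = 500, burn = 200,
                      thin = 2, seed = 9)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$alpha, f2$alpha)
  # draws count = chains x (iter - burn) / thin
  expect_equal(nrow(f1$beta), 2 * (500 - 200) / 2)
  # all-detected data with an intercept-only model: posterior psi near 1
  ha <- sim_hist(40, 4, 5, 0, 5, seed = 3)
  fa <- fit_occupancy(ha, ~ 1, ~ 1, chains = 2, iter = 600, burn = 200,
                      thin = 2, seed = 4)
  expect_gt(mean(inv_logit(fa$beta[, 1])), 0.9)
})

test_that("posterior means track generating parameters at moderate n", {
  # the full 20-replicate recovery study with interval coverage runs in
  # the end-to-end suite; this is a quick directional check
  h <- sim_hist(400, 4, 0, 1, 0.5, seed = 101)
  f <- fit_occupancy(h, ~ cov, ~ 1, chains = 3, iter = 2000, burn = 500,
                     thin = 4, seed = 201)
  truth <- c(0, sd(h$sites$cov), 0.5)
  est <- c(colMeans(f$beta), mean(f$alpha[[1]]))
  expect_true(all(abs(est - truth) < 0.35))
  expect_true(f$converged)
})

test_that("integration shares occupancy strength across detection processes", {
  # an integrated fit with only one source matches the single-source fit
  h <- sim_hist(120, 3, 0, 1, 0.5, seed = 7)
  fs <- do.call(fit_occupancy, c(list(h, ~ cov, ~ 1, seed = 5), light))
  fi <- suppressMessages(
    do.call(fit_integrated, c(list(h, ~ cov, ~ 1, seed = 5), light)))
  expect_equal(colMeans(fs$beta), colMeans(fi$beta), tolerance = 1e-12)
  # two sources from one beta: the integrated BCI for the occupancy slope
  # is narrower on average than either single-source interval
  wid <- function(f) diff(quantile(f$beta[, "cov"], c(0.025, 0.975)))
  w_int <- w_cit <- w_ac <- numeric(10)
  for (r in 1:10) {
    hc <- sim_hist(100, 3, 0, 1, 0.5, seed = 300 + r, source = "citizen")
    ha <- sim_hist(100, 3, 0, 1, 1.2, seed = 400 + r, source = "acoustic")
    fc <- do.call(fit_occupancy, c(list(hc, ~ cov, ~ 1, seed = r), light))
    fa <- do.call(fit_occupancy, c(list(ha, ~ cov, ~ 1, seed = r), light))
    fi <- do.call(fit_integrated, c(list(join_hist(hc, ha), ~ cov,
                                         ~ 1, seed = r), light))
    expect_equal(length(fi$alpha), 2)   # one detection block per source
    w_int[r] <- wid(fi); w_cit[r] <- wid(fc); w_ac[r] <- wid(fa)
  }
  expect_lt(mean(w_int), mean(w_cit))
  expect_lt(mean(w_int), mean(w_ac))
  # contradictory forced outcomes at co-located sites stay finite
  hc1 <- sim_hist(6, 2, 0, 1, 2, seed = 31, source = "citizen")
  ha1 <- sim_hist(6, 2, 0, 1, 2, seed = 32, source = "acoustic")
  ha1$sites$site_key <- hc1$sites$site_key   # exactly co-located: shared z
  ha1$visits$site_key <- rep(hc1$sites$site_key, each = 2)
  ha1$visits$y <- 0; ha1$sites$any_det <- 0
  hc1$visits$y <- 1; hc1$sites$any_det <- 1
  joined <- join_hist(hc1, ha1)
  joined$sites <- joined$sites[!duplicated(joined$sites$site_key), ]
  fz <- do.call(fit_integrated, c(list(joined, ~ 1, ~ 1, seed = 33), light))
  expect_true(all(is.finite(fz$beta)))
  expect_true(all(is.finite(waic(fz)$waic)))
})

test_that("WAIC prefers the true model over the null on strong-effect data", {
  better <- 0
  for (r in 1:20) {
    h <- sim_hist(80, 4, 0, 2, 1, seed = 600 + r)
    f_true <- fit_occupancy(h, ~ cov, ~ 1, chains = 2, iter = 700,
                            burn = 250, thin = 2, seed = r)
    f_null <- fit_occupancy(h, ~ 1, ~ 1, chains = 2, iter = 700,
                            burn = 250, thin = 2, seed = r)
    if (waic(f_true)$waic < waic(f_null)$waic) better <- better + 1
  }
  expect_gte(better, 18)
})

test_that("staged selection keeps true drivers and discards noise", {
  mk_sel_hist <- function(b1, seed, n = 200, n_noise = 3) {
    set.seed(seed)
    x <- matrix(rnorm(n * (1 + n_noise)), n)
    colnames(x) <- c("driver", sprintf("noise%d", seq_len(n_noise)))
    z <- rbinom(n, 1, plogis(0 + b1 * x[, 1]))
    sites <- data.frame(site_key = sprintf("s%04d", 1:n), source = "citizen",
                        x = 0, y = 0, stringsAsFactors = FALSE)
    sites <- cbind(sites, as.data.frame(x))
    visits <- do.call(rbind, lapply(1:n, function(i)
      data.frame(site_key = sites$site_key[i], visit = 1:4,
                 y = rbinom(4, 1, plogis(1)) * z[i])))
    sites$any_det <- as.integer(tapply(visits$y, visits$site_key,
                                       max)[sites$site_key])
    structure(list(sites = sites, visits = visits), class = "det_histories")
  }
  cands <- c("driver", "noise1", "noise2", "noise3")
  sel_mcmc <- list(chains = 2, iter = 700, burn = 250, thin = 2)
  hits <- 0
  for (r in 1:10) {
    h <- mk_sel_hist(b1 = 2, seed = 700 + r)
    s <- suppressWarnings(select_predictors(h, cands, mcmc = sel_mcmc,
                                            seed = 800 + r))
    if ("driver" %in% s$final_predictors) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # all-noise: intercept-only in most replicates
  nulls <- 0
  for (r in 1:10) {
    h <- mk_sel_hist(b1 = 0, seed = 900 + r)
    s <- suppressWarnings(select_predictors(h, cands, mcmc = sel_mcmc,
                                            seed = 1000 + r))
    if (s$intercept_only) nulls <- nulls + 1
  }
  expect_gte(nulls, 7)
  # collinear predictors collapse to one cluster representative
  h2 <- mk_sel_hist(b1 = 2, seed = 1100)
  h2$sites$driver_copy <- h2$sites$driver + rnorm(200, 0, 0.05)
  imp <- c(driver = 5, driver_copy = 1, noise1 = 0.5)
  s2 <- suppressWarnings(select_predictors(
    h2, c("driver", "driver_copy", "noise1"), importances = imp,
    mcmc = sel_mcmc, seed = 1200))
  expect_true(!("driver_copy" %in% s2$survivors))
  expect_true("driver" %in% s2$survivors)
  # zero-variance predictors are dropped before anything else
  h2$sites$flat <- 1
  s3 <- suppressWarnings(select_predictors(
    h2, c("driver", "flat"), importances = c(driver = 1, flat = 0),
    mcmc = sel_mcmc, seed = 1300))
  expect_equal(s3$dropped_zero_var, "flat")
})
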