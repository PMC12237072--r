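# Shared fixtures, built in code at test time.

small_world <- function(seed = 11, nrow = 40, ncol = 40, ...) {
  cfg <- sim_config(seed = seed, nrow = nrow, ncol = ncol, ...)
  list(cfg = cfg, grid = make_landscape(cfg))
}

# brute-force HAND: per-cell nearest drainage search
hand_oracle <- function(elev, drainage) {
  dr <- which(drainage, arr.ind = TRUE)
  out <- elev * 0
  for (i in seq_len(nrow(elev))) for (j in seq_len(ncol(elev))) {
    d <- (dr[, 1] - i)^2 + (dr[, 2] - j)^2
    out[i, j] <- max(0, elev[i, j] - elev[dr[which.min(d), 1], dr[which.min(d), 2]])
  }
  out[drainage] <- 0
  out
}

# brute-force PR-AUC: enumerate thresholds at distinct predictions
pr_auc_oracle <- function(prob, truth) {
  ths <- sort(unique(prob), decreasing = TRUE)
  rec <- 0; auc <- 0
  for (th in ths) {
    tp <- sum(prob >= th & truth == 1)
    fp <- sum(prob >= th & truth == 0)
    r <- tp / sum(truth == 1)
    p <- tp / (tp + fp)
    auc <- auc + p * (r - rec)
    rec <- r
  }
  auc
}

# brute-force occupancy likelihood: enumerate all z configurations
occ_loglik_oracle <- function(beta, alpha, X, W, y, site) {
  n <- nrow(X)
  psi <- plogis(drop(X %*% beta))
  p <- plogis(drop(W %*% alpha))
  total <- 0
  for (i in seq_len(n)) {
    yi <- y[site == i]; pi <- p[site == i]
    l1 <- psi[i] * prod(pi^yi * (1 - pi)^(1 - yi))
    l0 <- (1 - psi[i]) * as.numeric(sum(yi) == 0)
    total <- total + log(l1 + l0)
  }
  total
}

# small labeled detection sample with a logistic truth in logit score
make_labeled_sample <- function(n = 300, slope = 3, intercept = 0,
                                seed = 7, elev_range = c(200, 290)) {
  set.seed(seed)
  ls <- rnorm(n, 0, 1.3)
  lab <- rbinom(n, 1, plogis(intercept + slope * ls))
  data.frame(logit_score = ls,
             confidence = plogis(ls),
             elevation = runif(n, elev_range[1], elev_range[2]),
             label = ifelse(lab == 1, "true", "false"),
             stringsAsFactors = FALSE)
}
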