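test_that("state probabilities follow the log-linear weights", {
  u <- state_probs(0, 0, 0)
  expect_equal(unlist(u), c(psi00 = 0.25, psi10 = 0.25, psi01 = 0.25,
                            psi11 = 0.25))
  w <- state_probs(0, 0, log(3))
  expect_equal(unlist(w), c(psi00 = 1 / 6, psi10 = 1 / 6, psi01 = 1 / 6,
                            psi11 = 0.5))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # no interaction <=> independence factorization
  set.seed(5)
  for (rep in 1:5) {
    s <- state_probs(rnorm(1), rnorm(1), 0)
    expect_equal(s$psi11 * s$psi00, s$psi10 * s$psi01, tolerance = 1e-12)
  }
  # invariance under a constant shift of all four log-weights
  f <- c(1.2, -0.4, 0.7)
  for (shift in c(-5, 0, 12)) {
    lw <- c(0, f[1], f[2], f[1] + f[2] + f[3]) + shift
    manual <- exp(lw) / sum(exp(lw))
    expect_equal(unname(unlist(state_probs(f[1], f[2], f[3]))), manual,
                 tolerance = 1e-12)
  }
  big <- state_probs(800, -800, 200)        # overflow-safe
  expect_true(all(is.finite(unlist(big))))
  expect_equal(sum(big), 1, tolerance = 1e-12)
})

test_that("paired-history likelihood matches latent-state enumeration", {
  expect_equal(
    multi_site_log_likelihood(c(1, 0, 0), c(0, 0, 0),
                              c(0.25, 0.25, 0.25, 0.25), 0.5, 0.5),
    log(0.03515625), tolerance = 1e-12)
  # both species detected: only the both-present state contributes
  st <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(
    multi_site_log_likelihood(c(1, 0), c(0, 1), st, 0.6, 0.3),
    log(0.4 * (0.6 * 0.4) * (0.7 * 0.3)), tolerance = 1e-12)
  # degenerate psi11 = 1 is the product of two occupied likelihoods
  expect_equal(
    multi_site_log_likelihood(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0, 1),
                              0.4, 0.7),
    site_log_likelihood(c(1, 1, 0), 1, 0.4) +
      site_log_likelihood(c(0, 1, 1), 1, 0.7), tolerance = 1e-12)
  # randomized agreement with the enumeration oracle
  set.seed(11)
  for (rep in 1:10) {
    K <- sample(1:3, 1)
    f <- rnorm(3)
    st_r <- unlist(state_probs(f[1], f[2], f[3]))
    y1 <- rbinom(K, 1, 0.5); y2 <- rbinom(K, 1, 0.5)
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    expect_equal(exp(multi_site_log_likelihood(y1, y2, st_r, p1, p2)),
                 oracle_multi_lik(y1, y2, st_r, p1, p2), tolerance = 1e-12)
  }
})

test_that("paired-history probabilities sum to one over all outcomes", {
  set.seed(13)
  for (rep in 1:6) {
    K <- sample(1:4, 1)
    st <- unlist(state_probs(rnorm(1), rnorm(1), rnorm(1)))
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    H <- all_histories(K)
    tot <- 0
    for (i in seq_len(nrow(H))) {
      for (j in seq_len(nrow(H))) {
        tot <- tot + exp(multi_site_log_likelihood(H[i, ], H[j, ], st,
                                                   p1, p2))
      }
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("a tiny two-species optimum dominates a coarse parameter grid", {
  cfg <- simulation_config(n_sites = 8, K = 3, beta_f12 = 1, seed = 41)
  sim <- simulate_multi(cfg)
  fit <- suppressWarnings(occu_multi(sim$history1, sim$history2))
  Y1 <- as.matrix(sim$history1[, -1]); Y2 <- as.matrix(sim$history2[, -1])
  grid_ll <- function(f1, f2, f12, lp1, lp2) {
    st <- unlist(state_probs(f1, f2, f12))
    sum(vapply(seq_len(nrow(Y1)), function(i)
      multi_site_log_likelihood(Y1[i, ], Y2[i, ], st, plogis(lp1),
                                plogis(lp2)), numeric(1)))
  }
  pts <- expand.grid(f1 = c(-1, 0, 1), f2 = c(-1, 0, 1), f12 = c(-1, 0, 1),
                     lp1 = c(-1, 0, 1), lp2 = c(-1, 0, 1))
  lls <- mapply(grid_ll, pts$f1, pts$f2, pts$f12, pts$lp1, pts$lp2)
  expect_gte(fit$loglik, max(lls) - 1e-8)
})

test_that("independent species fit factorizes into the single-species fits", {
  cfg <- simulation_config(n_sites = 600, K = 3,
                           beta_f1 = 0.4, beta_f2 = -0.3, beta_f12 = 0,
                           p1 = 0.5, p2 = 0.45, seed = 47)
  sim <- simulate_multi(cfg)
  multi <- occu_multi(sim$history1, sim$history2, sim$sites,
                      "psi[1] ~ 1, psi[2] ~ 1, psi[12] ~ 0")
  f1 <- occu(sim$history1, sim$sites)
  f2 <- occu(sim$history2, sim$sites)
  expect_equal(multi$loglik, f1$loglik + f2$loglik, tolerance = 1e-4)
  expect_equal(multi$n_params, 4)
})

test_that("the interaction parameter is recovered from simulated data", {
  cfg <- simulation_config(n_sites = 1500, K = 3, beta_f12 = 1.5,
                           p1 = 0.5, p2 = 0.5, seed = 53)
  sim <- simulate_multi(cfg)
  fit <- occu_multi(sim$history1, sim$history2)
  est <- fit$coef[["f12_(Intercept)"]]
  se <- sqrt(diag(fit$vcov))[["f12_(Intercept)"]]
  expect_lt(abs(est - 1.5), 3 * se)
  # and an independent pair's interaction interval covers zero
  cfg0 <- simulation_config(n_sites = 1500, K = 3, beta_f12 = 0,
                            p1 = 0.5, p2 = 0.5, seed = 59)
  sim0 <- simulate_multi(cfg0)
  fit0 <- occu_multi(sim0$history1, sim0$history2)
  est0 <- fit0$coef[["f12_(Intercept)"]]
  se0 <- sqrt(diag(fit0$vcov))[["f12_(Intercept)"]]
  expect_lt(abs(est0), 3 * se0)
})

test_that("the headline covariate structure counts 12 parameters", {
  cfg <- simulation_config(n_sites = 250, K = 3, beta_f12 = 0.8, seed = 61)
  sim <- simulate_multi(cfg)
  spec <- paste("psi[1] ~ ecosystem,",
                "psi[2] ~ ecosystem + sqrt(numeric.add.date),",
                "psi[12] ~ ecosystem")
  fit <- suppressWarnings(occu_multi(sim$history1, sim$history2, sim$sites,
                                     spec, n_starts = 2))
  expect_equal(fit$n_params, 3 + 4 + 3 + 2)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 12)
})

test_that("conditional occupancy follows the joint state ratios", {
  expect_equal(conditional_occupancy(c(0.25, 0.25, 0.25, 0.25), 1, TRUE),
               0.5)
  expect_equal(conditional_occupancy(c(0.25, 0.25, 0.25, 0.25), 2, FALSE),
               0.5)
  st <- c(1 / 6, 1 / 6, 1 / 6, 1 / 2)
  expect_equal(conditional_occupancy(st, 1, TRUE), 0.75)
  expect_equal(conditional_occupancy(st, 1, FALSE), 0.5)
  # positive interaction implies conditional dominance, for either species
  for (f12 in c(0.3, 1, 2.5)) {
    s <- state_probs(0.4, -0.2, f12)
    expect_gt(conditional_occupancy(s, 1, TRUE),
              conditional_occupancy(s, 1, FALSE))
    expect_gt(conditional_occupancy(s, 2, TRUE),
              conditional_occupancy(s, 2, FALSE))
  }
  expect_error(conditional_occupancy(c(0.5, 0.5, 0, 0), 1, TRUE), "1e-12")
})

test_that("conditional curves are flat at 0.5 for a null fit and the two
          interval methods agree", {
  cfg <- simulation_config(n_sites = 1200, K = 3, beta_f1 = 0.3,
                           beta_f12 = 1, p1 = 0.5, p2 = 0.5, seed = 67)
  sim <- simulate_multi(cfg)
  fit <- occu_multi(sim$history1, sim$history2, sim$sites)
  # null coefficients -> flat 0.5 curves
  null_fit <- fit
  null_fit$coef[] <- 0
  null_fit$vcov[] <- 0
  grid <- tibble::tibble(latitude = seq(-60, 75, length.out = 5))
  flat <- predict_conditional_curves(null_fit, grid, n_boot = 0)
  expect_equal(flat$estimate, rep(0.5, 10))
  expect_false("lower" %in% names(flat))

  # bootstrap and delta intervals agree on a well-behaved fit
  bs <- predict_conditional_curves(fit, grid[1:2, ], n_boot = 600,
                                   method = "bootstrap", seed = 3)
  dl <- predict_conditional_curves(fit, grid[1:2, ], method = "delta")
  expect_equal(bs$estimate, dl$estimate)
  expect_lt(max(abs(bs$lower - dl$lower)), 0.05)
  expect_lt(max(abs(bs$upper - dl$upper)), 0.05)
  expect_true(all(bs$lower <= bs$estimate & bs$estimate <= bs$upper))
})

test_that("multi-fit broom methods and plots expose the fit", {
  cfg <- simulation_config(n_sites = 300, K = 3, beta_f12 = 1, seed = 71)
  sim <- simulate_multi(cfg)
  fit <- occu_multi(sim$history1, sim$history2, sim$sites)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_params)
  expect_setequal(unique(td$component), c("f1", "f2", "f12", "p1", "p2"))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  grid <- tibble::tibble(sqrt_numeric_add_date = seq(0, 60, by = 20))
  p <- autoplot(fit, grid, n_boot = 50)
  expect_s3_class(p, "ggplot")
})
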