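# Probability-model core: mean assembly, mixture likelihood, prior moments
# and input validation.

test_that("compute_mu assembles the four mean terms", {
  d <- tiny_design(J = 4, n_days = 10, seed = 1)
  st <- initial_state(d)

  # intercept-only
  st0 <- st; st0$alpha <- c(20, rep(0, length(st$alpha) - 1))
  expect_equal(compute_mu(st0, d), rep(20, length(d$y)))

  # identity bias map: g constant 1 via the slope basis's constant column
  st1 <- st; st1$alpha[] <- 0
  st1$beta <- c(1, rep(0, length(st$beta) - 1))  # column 1 of Xg basis is 1
  expect_equal(compute_mu(st1, d), d$x, tolerance = 1e-12)

  # brute-force per-observation loop oracle on a random small state
  set.seed(2)
  str <- st
  str$alpha <- rnorm(length(st$alpha), 0, 0.3)
  str$beta <- rnorm(length(st$beta), 0, 0.3)
  str$gamma <- matrix(rnorm(length(st$gamma), 0, 0.3), nrow(st$gamma))
  mu <- compute_mu(str, d)
  Bf <- d$basis_f$model_matrix; Bg <- d$basis_g$model_matrix
  for (i in sample(length(d$y), 20)) {
    j <- d$station[i]
    mi <- str$alpha[1] + sum(Bf[j, ] * str$alpha[-1]) +
      sum(Bg[j, ] * str$beta) * d$x[i] +
      sum(evaluate_basis(d$basis_h, d$x[i]) * str$gamma[j, ])
    expect_equal(mu[i], mi, tolerance = 1e-10)
  }

  # linearity: doubling beta doubles the slope contribution exactly
  st2 <- str; st2$beta <- 2 * str$beta
  expect_equal(compute_mu(st2, d) - compute_mu(str, d),
               as.numeric(d$Xg %*% str$beta), tolerance = 1e-12)

  bad <- str; bad$beta <- bad$beta[-1]
  expect_error(compute_mu(bad, d), "shape")
})

test_that("mixture likelihood marginalises z by logsumexp and collapses when pi = 1", {
  d <- tiny_design(J = 4, n_days = 10, seed = 3)
  st <- initial_state(d)
  st$pi <- rep(1, 4)
  ml <- mixture_loglik(st, d, marginal = TRUE)
  mu <- compute_mu(st, d)
  pure <- sum(dnorm(d$y, mu, sqrt(st$sigma2[d$station]), log = TRUE))
  expect_equal(ml$loglik, pure, tolerance = 1e-10)
  expect_equal(ml$deviance, -2 * pure, tolerance = 1e-10)

  # direct two-component density oracle on 5 observations
  st$pi <- c(0.9, 0.7, 0.95, 0.85)
  ml2 <- mixture_loglik(st, d, marginal = TRUE)
  pj <- st$pi[d$station]; sj <- sqrt(st$sigma2[d$station])
  direct <- sum(log(pj * dnorm(d$y, mu, sj) + (1 - pj) / 160))
  expect_equal(ml2$loglik, direct, tolerance = 1e-10)

  # per-observation marginal equals logsumexp of the weighted components
  la <- log(pj) + dnorm(d$y, mu, sj, log = TRUE)
  lb <- log(1 - pj) - log(160)
  m <- pmax(la, lb)
  expect_equal(ml2$log_density, m + log(exp(la - m) + exp(lb - m)),
               tolerance = 1e-12)

  # conditional mode follows the indicators
  st$z <- rep(1L, length(d$y)); st$z[1:3] <- 0L
  mlc <- mixture_loglik(st, d, marginal = FALSE)
  expect_equal(mlc$log_density[1:3], rep(log(1 - pj[1]) - log(160), 3))
  st$sigma2[1] <- -1
  expect_error(mixture_loglik(st, d), "domain")
})

test_that("prior moments match closed forms", {
  bm <- prior_moments("beta", shape1 = 5, shape2 = 2)
  expect_equal(round(bm$mean, 2), 0.71)
  expect_equal(round(bm$sd, 2), 0.16)
  em <- prior_moments("exp", rate = 0.1)
  expect_equal(em$mean, 10)
  expect_equal(em$variance, 100)
  um <- prior_moments("beta", shape1 = 1, shape2 = 1)
  expect_equal(um$mean, 0.5)
  expect_equal(um$sd, sqrt(1 / 12), tolerance = 1e-4)
  expect_identical(prior_moments("halfcauchy", scale = 20)$mean, "undefined")
  ig <- prior_moments("invgamma", shape = 2, rate = 10)
  expect_equal(ig$mean, 10)
  expect_identical(ig$variance, "undefined")
  expect_error(prior_moments("beta", shape1 = -1, shape2 = 2), "positive")
})

test_that("the non-linear term carries no linear trend in the covariate", {
  d <- tiny_design(J = 4, n_days = 60, seed = 4)
  set.seed(5)
  for (rep in 1:5) {
    gam <- rnorm(ncol(d$H))
    h <- as.numeric(d$H %*% gam)
    cf <- coef(lm.fit(cbind(1, d$x), h))
    expect_lt(abs(cf[2]), 1e-6)
  }
})

test_that("station input validation enforces support, keys and schema", {
  df <- data.frame(station_id = "A", name = "a", lon = 33, lat = 35,
                   elevation = 10, date = as.Date("2020-01-01") + 0:4,
                   tmax = c(20, 21, NA, 23, 24))
  ok <- validate_stations(df)
  expect_s3_class(ok, "station_data")
  df2 <- df; df2$tmax[2] <- 100
  expect_error(validate_stations(df2), "outside support")
  df3 <- rbind(df, df[1, ])
  expect_error(validate_stations(df3), "duplicate")
  expect_error(validate_stations(df[, -1]), "missing station columns")
  df4 <- df; df4$date <- as.character(df4$date); df4$date[3] <- "not-a-date"
  expect_error(validate_stations(df4), "malformed date")
})

test_that("design assembly aligns covariates and excludes missing rows", {
  field <- toy_field(n_days = 15)
  sim <- simulate_stations(field, J = 4, truth = truth_spec(missing_frac = 0.1),
                           seed = 6)
  cfg <- blend_config(h_knots = 10, seed = 1)
  d <- build_designs(sim$stations, field, cfg)
  expect_equal(length(d$y), sum(!is.na(sim$stations$tmax)))
  expect_equal(nrow(d$Xf), length(d$y))
  expect_equal(ncol(d$Xf), d$J)        # intercept + (J - 1) spatial columns
  expect_equal(ncol(d$Xg), d$J - 1L)
  expect_equal(ncol(d$H), cfg$n_gamma)
  # covariate values match an independent match_station call
  j <- 1L
  cv <- match_station(field, d$meta$lon[j], d$meta$lat[j], k = cfg$k_neighbours)
  rows <- which(d$station == j)
  expect_equal(d$x[rows],
               cv$x[match(as.Date(d$dates[rows]), as.Date(cv$times))])
})
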