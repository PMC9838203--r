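# Full-conditional correctness: every Gibbs update is checked against an
# independent analytic / numerical oracle on miniature instances, the
# Metropolis penalty sampler against a grid-integrated posterior, and the
# joint scan by determinism and a Geweke-style successive-conditional test.

test_that("indicator update uses the corrected Gaussian kernel", {
  d <- tiny_design(J = 4, n_days = 10, seed = 1)
  st <- initial_state(d)
  st$pi <- rep(0.9, 4); st$sigma2 <- rep(4, 4)
  mu <- compute_mu(st, d)

  # y exactly at the mean: p = 0.9 N(0;0,4) / (0.9 N(0;0,4) + 0.1/160)
  d_eq <- d; d_eq$y <- mu
  set.seed(1)
  p <- update_z(st, d_eq)$prob
  expect_equal(unname(p), rep(0.9 * dnorm(0, 0, 2) /
                              (0.9 * dnorm(0, 0, 2) + 0.1 / 160), length(mu)),
               tolerance = 1e-10)
  expect_equal(round(p[1], 4), 0.9965)

  # 50-sigma outliers are flagged with certainty
  d_far <- d; d_far$y <- mu + 50 * 2
  set.seed(2)
  zz <- update_z(st, d_far)
  expect_lt(max(zz$prob), 1e-100)
  expect_true(all(zz$z == 0L))

  # pi = 1 leaves no outlier mass regardless of y
  st1 <- st; st1$pi <- rep(1, 4)
  expect_equal(update_z(st1, d_far)$prob, rep(1, length(mu)))
})

test_that("pi update matches the conjugate Beta posterior", {
  d <- tiny_design(J = 4, n_days = 10, seed = 2)  # n_j = 10 each
  st <- initial_state(d)
  # station 1: 8 of 10 points kept -> Beta(5 + 8, 2 + 2) = Beta(13, 4)
  z <- rep(1L, length(d$y))
  z[which(d$station == 1)[1:2]] <- 0L
  st$z <- z
  set.seed(3)
  draws <- replicate(30000, update_pi(st, d)[1])
  m <- 13 / 17
  se <- sqrt(m * (1 - m) / (17 + 1)) / sqrt(30000)
  expect_lt(abs(mean(draws) - m), 3 * se)

  # all points kept pushes pi above its prior mean
  stA <- st; stA$z <- rep(1L, length(d$y))
  set.seed(4)
  drawsA <- replicate(5000, update_pi(stA, d)[1])
  expect_gt(mean(drawsA), 5 / 7)

  # a station with every point flagged reduces to Beta(5, 2 + n_j)
  stB <- st; stB$z <- as.integer(d$station != 2)
  set.seed(5)
  drawsB <- replicate(30000, update_pi(stB, d)[2])
  mB <- 5 / (5 + 12)
  seB <- sqrt(mB * (1 - mB) / 18) / sqrt(30000)
  expect_lt(abs(mean(drawsB) - mB), 3 * seB)

  stBad <- st; stBad$z <- rep(2L, length(d$y))
  expect_error(update_pi(stBad, d), "count inconsistency")
})

test_that("sigma2 update matches the conjugate inverse-gamma posterior", {
  d <- tiny_design(J = 4, n_days = 10, seed = 3)
  st <- initial_state(d)
  st$beta_sigma <- 10
  mu <- compute_mu(st, d)

  # station 1: four unit residuals kept -> InvGamma(2 + 2, 10 + 2) mean 4
  dd <- d; dd$y <- mu
  rows1 <- which(d$station == 1)
  dd$y[rows1[1:4]] <- mu[rows1[1:4]] + 1
  st$z <- as.integer(seq_along(d$y) %in% rows1[1:4])
  set.seed(6)
  draws <- replicate(100000, update_sigma2(st, dd, mu = mu)[1])
  expect_lt(abs(mean(draws) - 4), 3 * sqrt(8 / 100000))

  # station with everything flagged as outlier falls back to its prior,
  # InvGamma(2, 10), mean 10
  set.seed(7)
  draws0 <- replicate(100000, update_sigma2(st, dd, mu = mu)[2])
  expect_lt(abs(mean(draws0) - 10), 0.3)
})

test_that("beta_sigma update matches the conjugate Gamma posterior", {
  d <- tiny_design(J = 5, n_days = 8, seed = 4)
  st <- initial_state(d)
  st$sigma2 <- rep(5 / 2.4, 5)  # sum(1/sigma2) = 2.4
  # Gamma(1 + 5 * 2, 0.1 + 2.4) = Gamma(11, 2.5), mean 4.4
  set.seed(8)
  draws <- replicate(100000, update_beta_sigma(st, d))
  expect_lt(abs(mean(draws) - 4.4), 0.05)
})

test_that("coefficient draws match the dense-linear-algebra Gaussian oracle", {
  d <- tiny_design(J = 4, n_days = 10, seed = 5)
  st <- initial_state(d)
  st$z <- rep(1L, length(d$y))
  st$sigma2 <- c(4, 2, 3, 5)
  st$lambda <- c(f_null = 2, f_wiggly = 3, g_null = 1.5, g_wiggly = 2.5, h = 4)

  # independent oracle: Q = X' Sigma^-1 X + Omega, mean = Q^-1 b
  iv <- 1 / st$sigma2[d$station]
  Om <- prior_precisions(d, st$lambda)
  hvec <- rowSums(d$H * st$gamma[d$station, , drop = FALSE])
  W <- d$y - as.numeric(d$Xg %*% st$beta) - hvec
  Q <- t(d$Xf * iv) %*% d$Xf + Om$alpha_f
  b <- Om$alpha_f %*% c(0, rep(0, ncol(d$Xf) - 1)) + t(d$Xf) %*% (W * iv)
  mean_an <- solve(Q, b)
  cov_an <- solve(Q)

  set.seed(9)
  n_mc <- 20000
  draws <- matrix(NA_real_, n_mc, ncol(d$Xf))
  for (i in seq_len(n_mc))
    draws[i, ] <- update_coefficients(st, d, blocks = "alpha")$alpha
  se <- sqrt(diag(cov_an) / n_mc)
  expect_true(all(abs(colMeans(draws) - mean_an) < 3 * se))
  # element-wise Monte-Carlo error bound for a sample covariance
  cov_se <- sqrt((outer(diag(cov_an), diag(cov_an)) + cov_an^2) / n_mc)
  expect_true(all(abs(cov(draws) - cov_an) < 5 * cov_se))

  # infinite-penalty limit: smooth coefficients collapse to their zero prior
  stL <- st; stL$lambda[] <- 1e12
  set.seed(10)
  sL <- update_coefficients(stL, d)
  expect_lt(max(abs(sL$alpha[-1])), 1e-3)
  expect_lt(max(abs(sL$gamma)), 1e-3)
})

test_that("identical stations get identical gamma conditionals", {
  d <- tiny_design(J = 4, n_days = 20, seed = 6)
  # overwrite station 2 with station 1's data so their gamma blocks match
  r1 <- which(d$station == 1); r2 <- which(d$station == 2)
  stopifnot(length(r1) == length(r2))
  d$y[r2] <- d$y[r1]; d$x[r2] <- d$x[r1]; d$H[r2, ] <- d$H[r1, ]
  d$Xf[r2, -1] <- d$Xf[r1, -1]; d$Xg[r2, ] <- d$Xg[r1, ]
  st <- initial_state(d)
  st$sigma2[2] <- st$sigma2[1]
  # analytic conditional means coincide exactly
  Om <- prior_precisions(d, st$lambda)
  B <- d$y - as.numeric(d$Xf %*% st$alpha) - as.numeric(d$Xg %*% st$beta)
  cond <- function(j) {
    rows <- which(d$station == j)
    H <- d$H[rows, , drop = FALSE]
    Q <- crossprod(H) / st$sigma2[j] + Om$gamma
    list(mean = solve(Q, crossprod(H, B[rows]) / st$sigma2[j]),
         cov = solve(Q))
  }
  c1 <- cond(1); c2 <- cond(2)
  expect_lt(max(abs(c1$mean - c2$mean)), 1e-10)
  # and empirical means agree within Monte-Carlo error
  set.seed(11)
  n_mc <- 4000
  g1 <- g2 <- matrix(NA_real_, n_mc, ncol(d$H))
  for (i in seq_len(n_mc)) {
    s <- update_coefficients(st, d, blocks = "gamma")
    g1[i, ] <- s$gamma[1, ]; g2[i, ] <- s$gamma[2, ]
  }
  se <- sqrt((diag(c1$cov) + diag(c2$cov)) / n_mc)
  expect_true(all(abs(colMeans(g1) - colMeans(g2)) < 4 * se))
})

test_that("excluding z = 0 rows equals physically deleting them", {
  d <- tiny_design(J = 4, n_days = 15, seed = 7)
  set.seed(12)
  z <- as.integer(runif(length(d$y)) > 0.2)
  st <- initial_state(d); st$z <- z

  keep <- z == 1L
  d2 <- d
  d2$y <- d$y[keep]; d2$x <- d$x[keep]; d2$station <- d$station[keep]
  d2$dates <- d$dates[keep]
  d2$Xf <- d$Xf[keep, , drop = FALSE]; d2$Xg <- d$Xg[keep, , drop = FALSE]
  d2$H <- d$H[keep, , drop = FALSE]
  d2$n_j <- tabulate(d2$station, d2$J)
  st2 <- st; st2$z <- rep(1L, sum(keep))

  set.seed(99); a1 <- update_coefficients(st, d)
  set.seed(99); a2 <- update_coefficients(st2, d2)
  expect_identical(a1$alpha, a2$alpha)
  expect_identical(a1$beta, a2$beta)
  expect_identical(a1$gamma, a2$gamma)

  mu1 <- compute_mu(st, d); mu2 <- compute_mu(st2, d2)
  set.seed(98); s1 <- update_sigma2(st, d, mu = mu1)
  set.seed(98); s2 <- update_sigma2(st2, d2, mu = mu2)
  expect_identical(s1, s2)
})

test_that("penalty-parameter sampler matches a grid-integrated posterior", {
  d <- tiny_design(J = 4, n_days = 10, seed = 8, h_knots = 12)
  st <- initial_state(d)
  set.seed(13)
  st$gamma <- matrix(rnorm(length(st$gamma), 0, 0.5), nrow(st$gamma))

  steps <- setNames(rep(0.8, 5), names(st$lambda))
  n_mh <- 12000
  lam <- numeric(n_mh)
  set.seed(14)
  cur <- st
  for (i in seq_len(n_mh)) {
    cur <- update_lambda(cur, d, steps)$state
    lam[i] <- cur$lambda[["h"]]
  }
  lam <- lam[2001:n_mh]
  expect_true(all(lam > 0))

  # independent grid oracle for the lambda_h target:
  # prod_j N(gamma_j; 0, (lam S_h)^-1) x half-Cauchy(20), integrated on a grid
  Sh <- d$Sh
  qf <- sum(apply(st$gamma, 1, function(g) sum(g * (Sh %*% g))))
  ldSh <- determinant(Sh, logarithm = TRUE)$modulus
  p <- ncol(Sh); J <- d$J
  lgrid <- exp(seq(log(1e-4), log(5e4), length.out = 4000))
  ltar <- 0.5 * J * (p * log(lgrid) + as.numeric(ldSh)) - 0.5 * lgrid * qf +
    dcauchy(lgrid, 0, 20, log = TRUE)
  w <- exp(ltar - max(ltar)) * c(diff(lgrid), 0)
  cdf <- cumsum(w) / sum(w)
  ks <- max(abs(ecdf(lam)(lgrid) - cdf))
  expect_lt(ks, 0.05)

  # a zero step size proposes the current value: always accepted, constant
  z_steps <- steps; z_steps[] <- 0
  lu <- update_lambda(st, d, z_steps)
  expect_true(all(lu$accepted))
  expect_equal(lu$state$lambda, st$lambda)
})

test_that("the full scan is reproducible and runs the documented schedule", {
  field <- toy_field(n_days = 12)
  sim <- simulate_stations(field, J = 4, truth = truth_spec(missing_frac = 0),
                           seed = 9)
  cfg <- blend_config(chains = 2, iterations = 120, burnin = 60, thin = 2,
                      h_knots = 12, seed = 21)
  f1 <- tmax_blend(sim$stations, field, cfg)
  f2 <- tmax_blend(sim$stations, field, cfg)
  expect_identical(f1$samples$chains[[1]]$draws, f2$samples$chains[[1]]$draws)
  expect_identical(f1$z_prob, f2$z_prob)
  expect_equal(f1$samples$n_keep, 30)
  expect_equal(nrow(f1$samples$chains[[2]]$draws$alpha), 30)
  expect_true(all(pool_draws_ok(f1)))
})

test_that("Geweke-style successive-conditional simulation leaves the priors invariant", {
  # fixed coefficients; the (z, pi, sigma2, beta_sigma) cycle with data
  # resimulation must preserve the prior marginals of pi, sigma2, beta_sigma
  d <- tiny_design(J = 4, n_days = 8, seed = 10)
  cfg <- d$config
  st <- initial_state(d)
  mu <- compute_mu(st, d)
  n_it <- 10000

  set.seed(15)
  # forward (prior-only) reference sample
  fwd_bs <- rgamma(n_it, 1, 0.1)
  fwd_s2 <- 1 / rgamma(n_it, shape = 2, rate = fwd_bs)
  fwd_pi <- rbeta(n_it, 5, 2)

  # successive-conditional sampler
  set.seed(16)
  bs <- 10; s2 <- rep(4, d$J); pi_j <- rep(0.7, d$J)
  sc_bs <- sc_s2 <- sc_pi <- numeric(n_it)
  cur <- st
  for (i in seq_len(n_it)) {
    z_true <- as.integer(runif(length(mu)) < pi_j[d$station])
    y <- ifelse(z_true == 1L,
                rnorm(length(mu), mu, sqrt(s2[d$station])),
                runif(length(mu), cfg$u_min, cfg$u_max))
    dd <- d; dd$y <- y
    cur$pi <- pi_j; cur$sigma2 <- s2; cur$beta_sigma <- bs
    cur$z <- update_z(cur, dd)$z
    pi_j <- update_pi(cur, dd)
    cur$pi <- pi_j
    s2 <- update_sigma2(cur, dd, mu = mu)
    cur$sigma2 <- s2
    bs <- update_beta_sigma(cur, dd)
    sc_bs[i] <- bs; sc_s2[i] <- s2[1]; sc_pi[i] <- pi_j[1]
  }
  # the successive-conditional sampler is a Markov chain: use batch-means
  # standard errors for it, plain iid errors for the forward sample
  bm_se <- function(x, n_batch = 50) {
    bm <- colMeans(matrix(x[seq_len(n_batch * (length(x) %/% n_batch))],
                          ncol = n_batch))
    sd(bm) / sqrt(n_batch)
  }
  zscore <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(bm_se(a)^2 + var(b) / length(b))
  }
  expect_lt(abs(zscore(sc_pi, fwd_pi)), 4)
  expect_lt(abs(zscore(log(sc_s2), log(fwd_s2))), 4)
  expect_lt(abs(zscore(log(sc_bs), log(fwd_bs))), 4)
})
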