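# Gibbs sampler: full-conditional updates for every unknown, random-walk
# Metropolis on log(lambda) for the penalty parameters, and the chain driver.
# Scan order per iteration: z -> pi -> sigma2 -> alpha -> beta -> gamma ->
# beta_sigma -> lambdas (data augmentation first).

#' Update the mixture indicators z
#'
#' Each z is Bernoulli with success probability
#' `pi_j N(y; mu, sigma_j^2) / (pi_j N(y; mu, sigma_j^2) + (1 - pi_j) / (u_max - u_min))`,
#' computed on the log scale for stability.
#'
#' @param state current parameter state.
#' @param design a `blend_design`.
#' @param y response vector.
#' @return list with `z` (integer vector) and `prob` (success probabilities).
#' @export
update_z <- function(state, design, y = design$y) {
  cfg <- design$config
  mu <- compute_mu(state, design)
  sj <- sqrt(state$sigma2[design$station])
  pj <- state$pi[design$station]
  la <- log(pj) + stats::dnorm(y, mu, sj, log = TRUE)
  lb <- log1p(-pj) - log(cfg$u_max - cfg$u_min)
  prob <- 1 / (1 + exp(lb - la))
  prob[pj >= 1] <- 1
  prob[pj <= 0] <- 0
  list(z = as.integer(stats::runif(length(y)) < prob), prob = prob)
}

#' Update the non-outlier proportions pi_j
#'
#' Conjugate Beta update: `pi_j ~ Beta(alpha_pi + sum_t z, beta_pi + n_j - sum_t z)`.
#'
#' @param state current state (uses `z`).
#' @param design a `blend_design`.
#' @return numeric vector of length J.
#' @export
update_pi <- function(state, design) {
  cfg <- design$config
  sz <- as.numeric(rowsum(as.numeric(state$z), design$station,
                          reorder = TRUE))
  sz <- fill_by_station(sz, sort(unique(design$station)), design$J)
  if (any(sz > design$n_j)) stop("count inconsistency: sum(z) exceeds n_j")
  stats::rbeta(design$J, cfg$alpha_pi + sz, cfg$beta_pi + design$n_j - sz)
}

#' Update the conditional variances sigma_j^2
#'
#' Conjugate inverse-gamma update excluding outlier-flagged points:
#' `sigma_j^2 ~ InvGamma(alpha_sigma + n_j/2, beta_sigma + SS_j/2)` where
#' `n_j` and the residual sum of squares `SS_j` count only z = 1 points.
#'
#' @param state current state (uses `z`, `beta_sigma` and the coefficients).
#' @param design a `blend_design`.
#' @param mu optional precomputed mean vector.
#' @return numeric vector of length J.
#' @export
update_sigma2 <- function(state, design, mu = compute_mu(state, design)) {
  keep <- state$z == 1L
  r2 <- (design$y - mu)^2
  st <- design$station
  ssz <- rep(0, design$J); nz <- rep(0, design$J)
  if (any(keep)) {
    agg <- rowsum(cbind(r2[keep], 1), st[keep], reorder = TRUE)
    js <- as.integer(rownames(agg))
    ssz[js] <- agg[, 1]; nz[js] <- agg[, 2]
  }
  cfg <- design$config
  shape <- cfg$alpha_sigma + nz / 2
  rate <- state$beta_sigma + ssz / 2
  1 / stats::rgamma(design$J, shape = shape, rate = rate)
}

#' Update the variance hyperparameter beta_sigma
#'
#' Conjugate Gamma update: `beta_sigma ~ Gamma(c + J alpha_sigma, d + sum_j 1/sigma_j^2)`.
#'
#' @param state current state (uses `sigma2`).
#' @param design a `blend_design`.
#' @return scalar draw.
#' @export
update_beta_sigma <- function(state, design) {
  cfg <- design$config
  stats::rgamma(1, shape = cfg$c_beta_sigma + design$J * cfg$alpha_sigma,
                rate = cfg$d_beta_sigma + sum(1 / state$sigma2))
}

# canonical-form Gaussian draw: theta ~ N(Q^{-1} b, Q^{-1}) via Cholesky
draw_canonical <- function(b, Q) {
  R <- tryCatch(chol(Q), error = function(e)
    stop("numerical-conditioning error: precision not positive definite (",
         conditionMessage(e), ")"))
  mean <- backsolve(R, forwardsolve(t(R), b))
  mean + backsolve(R, stats::rnorm(length(b)))
}

#' Update the spline coefficient blocks alpha, beta and gamma
#'
#' Canonical-form Gaussian full conditionals. With rows restricted to z = 1:
#' alpha from `N_C(Omega_af mu_a0 + Xf' Sigma^-1 W, Xf' Sigma^-1 Xf + Omega_af)`
#' with `W = y - Xg beta - h`; beta from
#' `N_C(Xg' Sigma^-1 A, Xg' Sigma^-1 Xg + Omega_beta)` with
#' `A = y - Xf alpha - h`; each gamma_j from
#' `N_C(Xh_j' B_j / sigma_j^2, Xh_j' Xh_j / sigma_j^2 + Omega_gamma)` with
#' `B_j = y_j - Xf_j alpha - Xg_j beta`.
#'
#' @param state current state.
#' @param design a `blend_design`.
#' @param blocks which blocks to update (in this order).
#' @return the state with new coefficient draws.
#' @export
update_coefficients <- function(state, design, blocks = c("alpha", "beta", "gamma")) {
  cfg <- design$config
  Om <- prior_precisions(design, state$lambda)
  keep <- state$z == 1L
  y <- design$y[keep]
  st <- design$station[keep]
  Xf <- design$Xf[keep, , drop = FALSE]
  Xg <- design$Xg[keep, , drop = FALSE]
  H <- design$H[keep, , drop = FALSE]
  iv <- 1 / state$sigma2[st]

  hvec <- function() rowSums(H * state$gamma[st, , drop = FALSE])

  if ("alpha" %in% blocks) {
    W <- y - as.numeric(Xg %*% state$beta) - hvec()
    Xw <- Xf * sqrt(iv)
    Q <- crossprod(Xw) + Om$alpha_f
    b <- Om$alpha_f %*% c(cfg$mu_alpha0, rep(0, ncol(Xf) - 1L)) +
      crossprod(Xf, W * iv)
    state$alpha <- as.numeric(draw_canonical(b, Q))
  }
  if ("beta" %in% blocks) {
    A <- y - as.numeric(Xf %*% state$alpha) - hvec()
    Xw <- Xg * sqrt(iv)
    Q <- crossprod(Xw) + Om$beta
    b <- crossprod(Xg, A * iv)
    state$beta <- as.numeric(draw_canonical(b, Q))
  }
  if ("gamma" %in% blocks) {
    B <- y - as.numeric(Xf %*% state$alpha) - as.numeric(Xg %*% state$beta)
    for (j in seq_len(design$J)) {
      rows <- st == j
      if (any(rows)) {
        Hj <- H[rows, , drop = FALSE]
        Q <- crossprod(Hj) / state$sigma2[j] + Om$gamma
        b <- crossprod(Hj, B[rows]) / state$sigma2[j]
      } else {
        Q <- Om$gamma
        b <- rep(0, ncol(H))
      }
      state$gamma[j, ] <- as.numeric(draw_canonical(b, Q))
    }
  }
  state
}

# log target for one penalty parameter given its coefficient block(s):
# 0.5 * logdet(Omega) - 0.5 * coef' Omega coef  (repeated over gamma blocks)
# + half-Cauchy(scale) log prior on lambda.
lambda_log_target <- function(lam, which, state, design) {
  cfg <- design$config
  lambda <- state$lambda
  lambda[[which]] <- lam
  lp <- stats::dcauchy(lam, 0, cfg$cauchy_scale, log = TRUE) + log(2)
  if (which %in% c("f_null", "f_wiggly")) {
    Om <- lambda[["f_null"]] * design$Sf0 + lambda[["f_wiggly"]] * design$Sf1
    a <- state$alpha[-1]
    ld <- logdet_pd(Om)
    if (!is.finite(ld)) return(-Inf)
    lp + 0.5 * ld - 0.5 * sum(a * (Om %*% a))
  } else if (which %in% c("g_null", "g_wiggly")) {
    Om <- lambda[["g_null"]] * design$Sg0 + lambda[["g_wiggly"]] * design$Sg1
    ld <- logdet_pd(Om)
    if (!is.finite(ld)) return(-Inf)
    lp + 0.5 * ld - 0.5 * sum(state$beta * (Om %*% state$beta))
  } else {
    Om <- lambda[["h"]] * design$Sh
    ld <- logdet_pd(Om)
    if (!is.finite(ld)) return(-Inf)
    qf <- sum(vapply(seq_len(design$J),
                     function(j) sum(state$gamma[j, ] * (Om %*% state$gamma[j, ])),
                     numeric(1)))
    lp + 0.5 * design$J * ld - 0.5 * qf
  }
}

logdet_pd <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  2 * sum(log(diag(R)))
}

#' Random-walk Metropolis update of the penalty parameters
#'
#' Each lambda is updated by a Gaussian random walk on log(lambda) with a
#' Jacobian-corrected acceptance ratio against the product of the Gaussian
#' prior of its coefficient block (including the 0.5 log det Omega term) and
#' the half-Cauchy(scale) prior. Non-finite ratios reject with a warning.
#'
#' @param state current state.
#' @param design a `blend_design`.
#' @param step_sizes named numeric vector of log-scale proposal sds.
#' @return list with the updated `state` and a named logical `accepted`.
#' @export
update_lambda <- function(state, design, step_sizes) {
  acc <- stats::setNames(logical(length(state$lambda)), names(state$lambda))
  for (which in names(state$lambda)) {
    cur <- state$lambda[[which]]
    step <- step_sizes[[which]]
    prop <- cur * exp(stats::rnorm(1, 0, step))
    lr <- lambda_log_target(prop, which, state, design) -
      lambda_log_target(cur, which, state, design) +
      log(prop) - log(cur)
    if (is.nan(lr)) {
      warning("non-finite acceptance ratio for ", which, "; proposal rejected")
      next
    }
    if (step == 0 || log(stats::runif(1)) < lr) {
      state$lambda[[which]] <- prop
      acc[[which]] <- TRUE
    }
  }
  list(state = state, accepted = acc)
}

#' Run the Gibbs sampler
#'
#' Executes the fixed scan (z, pi, sigma2, alpha, beta, gamma, beta_sigma,
#' penalty parameters) for one or more chains, adapting the Metropolis step
#' sizes multiplicatively every `adapt_every` iterations during burn-in to
#' steer acceptance into [0.2, 0.5], then freezing them. Post-burn-in states
#' are thinned and stored; the marginal-mixture deviance is traced and the
#' posterior mean of each observation's indicator accumulated.
#'
#' @param design a `blend_design`.
#' @param config a [blend_config()]; defaults to the design's.
#' @param progress print milestone messages.
#' @return an object of class `posterior_samples`: per-chain draw matrices
#'   (`alpha`, `beta`, `gamma`, `sigma2`, `pi`, `beta_sigma`, `lambda`),
#'   deviance traces, indicator posterior means (`z_prob`), acceptance
#'   rates and sampler metadata.
#' @export
run_gibbs <- function(design, config = design$config, progress = FALSE) {
  n_iter <- config$iterations; burn <- config$burnin; thin <- config$thin
  n_keep <- floor((n_iter - burn) / thin)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    chain_seed <- config$seed + 1000L * (ch - 1L)
    state <- initial_state(design, jitter_seed = if (config$chains > 1L) chain_seed else NULL)
    set.seed(chain_seed)
    p_a <- length(state$alpha); p_b <- length(state$beta)
    p_g <- ncol(state$gamma); J <- design$J
    draws <- list(alpha = matrix(NA_real_, n_keep, p_a),
                  beta = matrix(NA_real_, n_keep, p_b),
                  gamma = matrix(NA_real_, n_keep, J * p_g),
                  sigma2 = matrix(NA_real_, n_keep, J),
                  pi = matrix(NA_real_, n_keep, J),
                  beta_sigma = numeric(n_keep),
                  lambda = matrix(NA_real_, n_keep, 5,
                                  dimnames = list(NULL, names(state$lambda))),
                  deviance = numeric(n_keep))
    zsum <- numeric(length(design$y))
    steps <- stats::setNames(rep(0.5, 5), names(state$lambda))
    acc_win <- stats::setNames(numeric(5), names(state$lambda))
    acc_tot <- stats::setNames(numeric(5), names(state$lambda))
    win_n <- 0L
    k <- 0L
    for (it in seq_len(n_iter)) {
      zz <- tryCatch(update_z(state, design), error = function(e)
        stop("iteration ", it, " [z]: ", conditionMessage(e)))
      state$z <- zz$z
      state$pi <- update_pi(state, design)
      state$sigma2 <- update_sigma2(state, design)
      state <- tryCatch(update_coefficients(state, design), error = function(e)
        stop("iteration ", it, " [coefficients]: ", conditionMessage(e)))
      state$beta_sigma <- update_beta_sigma(state, design)
      lu <- update_lambda(state, design, steps)
      state <- lu$state
      acc_win <- acc_win + lu$accepted
      acc_tot <- acc_tot + (it > burn) * lu$accepted
      win_n <- win_n + 1L
      if (it <= burn && win_n >= config$adapt_every) {
        rate <- acc_win / win_n
        steps <- steps * ifelse(rate > 0.5, 1.25, ifelse(rate < 0.2, 0.8, 1))
        acc_win[] <- 0; win_n <- 0L
      }
      if (it > burn && (it - burn) %% thin == 0L && k < n_keep) {
        k <- k + 1L
        draws$alpha[k, ] <- state$alpha
        draws$beta[k, ] <- state$beta
        draws$gamma[k, ] <- as.numeric(state$gamma)
        draws$sigma2[k, ] <- state$sigma2
        draws$pi[k, ] <- state$pi
        draws$beta_sigma[k] <- state$beta_sigma
        draws$lambda[k, ] <- state$lambda
        draws$deviance[k] <- mixture_loglik(state, design)$deviance
        zsum <- zsum + state$z
      }
      if (progress && it %% max(1L, n_iter %/% 10L) == 0L)
        message(sprintf("chain %d: iteration %d / %d", ch, it, n_iter))
    }
    chains[[ch]] <- list(draws = draws, z_prob = zsum / max(k, 1L),
                         accept_rate = acc_tot / max(n_iter - burn, 1L),
                         steps = steps, seed = chain_seed)
  }
  structure(list(chains = chains, n_keep = n_keep,
                 config = config,
                 meta = list(seed = config$seed, iterations = n_iter,
                             burnin = burn, thin = thin)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d chains x %d retained draws (iter %d, burn-in %d, thin %d)\n",
              length(x$chains), x$n_keep, x$meta$iterations, x$meta$burnin, x$meta$thin))
  invisible(x)
}

# combine a per-chain draw component across chains (row-bound)
pool_draws <- function(samples, what) {
  do.call(rbind, lapply(samples$chains, function(ch) {
    d <- ch$draws[[what]]
    if (is.null(dim(d))) matrix(d, ncol = 1) else d
  }))
}

fill_by_station <- function(vals, js, J) {
  out <- rep(0, J); out[js] <- vals; out
}
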