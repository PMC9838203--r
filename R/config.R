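#' Model and sampler configuration
#'
#' Collects every tunable of the hierarchical model and its Gibbs sampler.
#' Defaults follow the model's reference analysis: a Beta(5, 2) prior on the
#' per-station non-outlier proportion (mean 0.71, sd 0.16), a Uniform(-80, 80)
#' degC outlier component, an InvGamma(2, beta_sigma) conditional-variance
#' hierarchy with Exp(0.1) hyperprior on beta_sigma (Gamma(c = 1, d = 0.1)
#' representation), a N(0, 25) prior on the overall intercept, half-Cauchy
#' (scale 20) priors on all penalty parameters, spatial basis sizes J - 1,
#' a non-linear covariate basis of size 8 with the null space removed, and a
#' 10-nearest-neighbour inverse-distance change-of-support.
#'
#' Desk-scale sampler defaults are 3 chains x 6000 iterations with 3000
#' burn-in and thinning 3; the reference-scale run (3 x 100000 after 50000
#' burn-in) is available by overriding `iterations`, `burnin` and `thin`.
#'
#' @param alpha_pi,beta_pi Beta prior on pi_j.
#' @param u_min,u_max Uniform outlier-component bounds, degC.
#' @param alpha_sigma InvGamma shape for sigma_j^2 (fixed).
#' @param c_beta_sigma,d_beta_sigma Gamma(c, d) hyperprior on beta_sigma;
#'   the default (1, 0.1) is the Exp(0.1) prior.
#' @param mu_alpha0,var_alpha0 Normal prior on the overall intercept.
#' @param cauchy_scale half-Cauchy scale for all penalty parameters.
#' @param n_alpha,n_beta spatial basis sizes; `NULL` means J - 1.
#' @param n_gamma size of the per-station non-linear covariate basis.
#' @param h_knots number of quantile-spaced knots used to build the
#'   covariate basis before eigen-truncation.
#' @param k_neighbours,idw_power change-of-support neighbours and
#'   inverse-distance power.
#' @param outlier_threshold posterior-probability threshold below which a
#'   point is flagged as an outlier.
#' @param chains,iterations,burnin,thin,adapt_every MCMC settings;
#'   `adapt_every` is the burn-in step-size adaptation interval.
#' @param seed integer RNG seed for the fit.
#' @return an object of class `blend_config` (a validated list).
#' @export
blend_config <- function(alpha_pi = 5, beta_pi = 2,
                         u_min = -80, u_max = 80,
                         alpha_sigma = 2,
                         c_beta_sigma = 1, d_beta_sigma = 0.1,
                         mu_alpha0 = 0, var_alpha0 = 25,
                         cauchy_scale = 20,
                         n_alpha = NULL, n_beta = NULL, n_gamma = 8,
                         h_knots = 30,
                         k_neighbours = 10, idw_power = 1,
                         outlier_threshold = 0.5,
                         chains = 3, iterations = 6000, burnin = 3000,
                         thin = 3, adapt_every = 50, seed = 1L) {
  cfg <- list(alpha_pi = alpha_pi, beta_pi = beta_pi, u_min = u_min, u_max = u_max,
              alpha_sigma = alpha_sigma, c_beta_sigma = c_beta_sigma,
              d_beta_sigma = d_beta_sigma, mu_alpha0 = mu_alpha0,
              var_alpha0 = var_alpha0, cauchy_scale = cauchy_scale,
              n_alpha = n_alpha, n_beta = n_beta, n_gamma = n_gamma,
              h_knots = h_knots, k_neighbours = k_neighbours, idw_power = idw_power,
              outlier_threshold = outlier_threshold, chains = chains,
              iterations = iterations, burnin = burnin, thin = thin,
              adapt_every = adapt_every, seed = seed)
  if (cfg$u_min >= cfg$u_max) stop("config error: u_min must be < u_max")
  pos <- c("alpha_pi", "beta_pi", "alpha_sigma", "c_beta_sigma", "d_beta_sigma",
           "var_alpha0", "cauchy_scale", "n_gamma", "h_knots", "k_neighbours")
  for (nm in pos) if (cfg[[nm]] <= 0) stop("config error: ", nm, " must be > 0")
  if (cfg$outlier_threshold <= 0 || cfg$outlier_threshold >= 1)
    stop("config error: outlier_threshold must be in (0, 1)")
  if (cfg$burnin >= cfg$iterations) stop("config error: burnin must be < iterations")
  if (cfg$chains < 1 || cfg$thin < 1) stop("config error: chains and thin must be >= 1")
  structure(cfg, class = "blend_config")
}

#' @export
print.blend_config <- function(x, ...) {
  cat("tmaxblend configuration\n")
  cat(sprintf("  mixture: pi ~ Beta(%g, %g); outlier component Uniform(%g, %g) degC\n",
              x$alpha_pi, x$beta_pi, x$u_min, x$u_max))
  cat(sprintf("  variances: InvGamma(%g, beta_sigma), beta_sigma ~ Gamma(%g, %g)\n",
              x$alpha_sigma, x$c_beta_sigma, x$d_beta_sigma))
  cat(sprintf("  penalties: half-Cauchy(scale %g); bases n_alpha=%s n_beta=%s n_gamma=%d\n",
              x$cauchy_scale, x$n_alpha %||% "J-1", x$n_beta %||% "J-1", x$n_gamma))
  cat(sprintf("  change of support: %d neighbours, inverse-distance power %g\n",
              x$k_neighbours, x$idw_power))
  cat(sprintf("  MCMC: %d chains x %d iterations, burn-in %d, thin %d, seed %d\n",
              x$chains, x$iterations, x$burnin, x$thin, x$seed))
  invisible(x)
}

#' Read a configuration from YAML
#'
#' The YAML keys mirror the [blend_config()] argument names; unknown keys are
#' an error so typos are caught.
#' @param path YAML file path.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(blend_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("config error: unknown fields: ", paste(bad, collapse = ", "))
  do.call(blend_config, vals)
}

#' Closed-form prior moments
#'
#' Documents and validates the configured priors: returns the mean and
#' standard deviation (and variance) of a named distribution, or marks them
#' `undefined` where they do not exist (e.g. the half-Cauchy mean).
#'
#' @param dist one of `"beta"`, `"exp"`, `"gamma"`, `"invgamma"`,
#'   `"halfcauchy"`, `"uniform"`.
#' @param ... distribution parameters: `shape1`/`shape2` (beta), `rate`
#'   (exp), `shape`/`rate` (gamma, invgamma), `scale` (halfcauchy),
#'   `min`/`max` (uniform).
#' @return list with `mean`, `sd`, `variance`; entries are the string
#'   `"undefined"` when the moment does not exist.
#' @export
prior_moments <- function(dist, ...) {
  p <- list(...)
  chk <- function(...) if (any(unlist(list(...)) <= 0)) stop("parameters must be positive")
  und <- "undefined"
  switch(match.arg(dist, c("beta", "exp", "gamma", "invgamma", "halfcauchy", "uniform")),
    beta = {
      a <- p$shape1; b <- p$shape2; chk(a, b)
      v <- a * b / ((a + b)^2 * (a + b + 1))
      list(mean = a / (a + b), sd = sqrt(v), variance = v)
    },
    exp = {
      r <- p$rate; chk(r)
      list(mean = 1 / r, sd = 1 / r, variance = 1 / r^2)
    },
    gamma = {
      a <- p$shape; r <- p$rate; chk(a, r)
      list(mean = a / r, sd = sqrt(a) / r, variance = a / r^2)
    },
    invgamma = {
      a <- p$shape; b <- p$rate; chk(a, b)
      m <- if (a > 1) b / (a - 1) else und
      v <- if (a > 2) b^2 / ((a - 1)^2 * (a - 2)) else und
      list(mean = m, sd = if (is.character(v)) und else sqrt(v), variance = v)
    },
    halfcauchy = {
      chk(p$scale)
      list(mean = und, sd = und, variance = und)
    },
    uniform = {
      if (p$min >= p$max) stop("min must be < max")
      v <- (p$max - p$min)^2 / 12
      list(mean = (p$min + p$max) / 2, sd = sqrt(v), variance = v)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
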