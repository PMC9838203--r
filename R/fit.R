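#' Fit the station--reanalysis blending model
#'
#' The main entry point. Observations y at station j on day t follow a
#' discrete mixture: with probability pi_j a Gaussian around the bias-model
#' mean, otherwise a bounded Uniform "erroneous outlier" component:
#' \deqn{y | z=1 ~ N(mu, sigma_j^2), \quad y | z=0 ~ Unif(U_min, U_max),
#'   \quad z ~ Bern(pi_j)}
#' with mean
#' \deqn{mu = alpha_0 + f(s_j) + g(s_j) x + h_j(x)}
#' where x is the k-nearest-neighbour weighted reanalysis covariate, f and g
#' are spatial thin-plate spline surfaces (a spatially varying linear bias
#' model) and h_j is a station-specific purely non-linear penalised spline
#' deviation. All unknowns are sampled by a Gibbs scan with random-walk
#' Metropolis steps for the penalty parameters.
#'
#' @param stations station records: a `station_data` data.frame (see
#'   [read_station_csv()]) with columns station_id, lon, lat, elevation,
#'   date, tmax (missing allowed).
#' @param field a daily [reanalysis_field()] supplying the covariate, or
#'   `NULL` if `stations` has a precomputed `x` column.
#' @param config a [blend_config()].
#' @param progress print sampler milestones.
#' @return an object of class `tmax_blend` with components `design`,
#'   `samples` (a `posterior_samples`), `z_prob` (per-observation posterior
#'   non-outlier probability, averaged over chains) and `config`. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `simulate`,
#'   `predict`, `plot`.
#' @examples
#' field <- simulate_reanalysis(n_days = 60, seed = 1)
#' truth <- truth_spec()
#' sim <- simulate_stations(field, J = 4, truth = truth, seed = 1)
#' cfg <- blend_config(chains = 1, iterations = 300, burnin = 150, thin = 1,
#'                     h_knots = 15, seed = 1)
#' fit <- tmax_blend(sim$stations, field, cfg)
#' print(fit)
#' @export
tmax_blend <- function(stations, field, config = blend_config(), progress = FALSE) {
  design <- build_designs(stations, field, config)
  samples <- run_gibbs(design, config, progress = progress)
  z_prob <- Reduce(`+`, lapply(samples$chains, `[[`, "z_prob")) / length(samples$chains)
  structure(list(design = design, samples = samples, z_prob = z_prob,
                 config = config, call = match.call()),
            class = "tmax_blend")
}

# pooled posterior draws as plain matrices
draws_matrix <- function(fit, what) pool_draws(fit$samples, what)

# gamma draws for one station as a (draws x n_gamma) matrix
gamma_draws_station <- function(fit, j) {
  g <- draws_matrix(fit, "gamma")
  J <- fit$design$J; pg <- ncol(fit$design$H)
  g[, (seq_len(pg) - 1L) * J + j, drop = FALSE]
}

#' @export
print.tmax_blend <- function(x, ...) {
  d <- x$design
  cat("Bayesian station-reanalysis temperature blend\n")
  cat(sprintf("  %d stations, %d observations (%s .. %s)\n", d$J, length(d$y),
              format(min(d$dates)), format(max(d$dates))))
  cat(sprintf("  %d chains x %d retained draws\n",
              length(x$samples$chains), x$samples$n_keep))
  cat(sprintf("  posterior mean alpha_0 = %.3f; flagged outliers (p < %.2f): %d\n",
              mean(draws_matrix(x, "alpha")[, 1]), x$config$outlier_threshold,
              sum(x$z_prob < x$config$outlier_threshold)))
  invisible(x)
}

#' @export
coef.tmax_blend <- function(object, ...) {
  J <- object$design$J
  gm <- colMeans(draws_matrix(object, "gamma"))
  list(alpha0 = mean(draws_matrix(object, "alpha")[, 1]),
       alpha = colMeans(draws_matrix(object, "alpha"))[-1],
       beta = colMeans(draws_matrix(object, "beta")),
       gamma = matrix(gm, nrow = J),
       sigma2 = stats::setNames(colMeans(draws_matrix(object, "sigma2")),
                                object$design$meta$station_id),
       pi = stats::setNames(colMeans(draws_matrix(object, "pi")),
                            object$design$meta$station_id),
       beta_sigma = mean(draws_matrix(object, "beta_sigma")),
       lambda = colMeans(draws_matrix(object, "lambda")))
}

#' @export
summary.tmax_blend <- function(object, ...) {
  cf <- coef(object)
  dev <- unlist(lapply(object$samples$chains, function(ch) ch$draws$deviance))
  acc <- do.call(rbind, lapply(object$samples$chains, `[[`, "accept_rate"))
  out <- list(coef = cf,
              deviance = c(mean = mean(dev), sd = stats::sd(dev)),
              accept_rate = colMeans(acc),
              mpsrf = if (length(object$samples$chains) >= 2) mpsrf(object) else NA_real_,
              outlier_proportion = 1 - cf$pi,
              n_flagged = sum(object$z_prob < object$config$outlier_threshold))
  class(out) <- "summary.tmax_blend"
  out
}

#' @export
print.summary.tmax_blend <- function(x, ...) {
  cat("Posterior summary\n")
  cat(sprintf("  alpha_0: %.3f   beta_sigma: %.3f\n", x$coef$alpha0, x$coef$beta_sigma))
  cat("  per-station sigma_j:", paste(sprintf("%.2f", sqrt(x$coef$sigma2)), collapse = " "), "\n")
  cat("  per-station outlier proportion (1 - pi_j):",
      paste(sprintf("%.3f", x$outlier_proportion), collapse = " "), "\n")
  cat("  penalty acceptance rates:",
      paste(sprintf("%s=%.2f", names(x$accept_rate), x$accept_rate), collapse = " "), "\n")
  cat(sprintf("  deviance %.1f (sd %.1f); MPSRF %.3f; flagged outliers %d\n",
              x$deviance[["mean"]], x$deviance[["sd"]], x$mpsrf, x$n_flagged))
  invisible(x)
}

#' @export
fitted.tmax_blend <- function(object, ...) {
  d <- object$design
  al <- draws_matrix(object, "alpha"); be <- draws_matrix(object, "beta")
  mu <- as.numeric(d$Xf %*% colMeans(al)) + as.numeric(d$Xg %*% colMeans(be))
  gm <- coef(object)$gamma
  mu + rowSums(d$H * gm[d$station, , drop = FALSE])
}

#' @export
residuals.tmax_blend <- function(object, ...) object$design$y - fitted(object)

#' Posterior predictive simulation at the observed design points
#'
#' One replicate per retained posterior draw (recycled if `nsim` exceeds the
#' number of draws): y* ~ N(mu(draw), sigma_j^2(draw)) for every design row.
#'
#' @param object a `tmax_blend` fit.
#' @param nsim number of replicated datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a `length(y)` x `nsim` matrix.
#' @export
simulate.tmax_blend <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$design
  mu_d <- mu_draws_design(object)
  n_draws <- nrow(mu_d)
  sg <- draws_matrix(object, "sigma2")
  out <- matrix(NA_real_, length(d$y), nsim)
  for (s in seq_len(nsim)) {
    m <- ((s - 1L) %% n_draws) + 1L
    out[, s] <- stats::rnorm(length(d$y), mu_d[m, ], sqrt(sg[m, d$station]))
  }
  out
}

# draws x n_obs matrix of mu over the observed design
mu_draws_design <- function(fit) {
  d <- fit$design
  al <- draws_matrix(fit, "alpha"); be <- draws_matrix(fit, "beta")
  g <- draws_matrix(fit, "gamma")
  J <- d$J; pg <- ncol(d$H)
  mu <- tcrossprod(al, d$Xf) + tcrossprod(be, d$Xg)
  # h contribution: sum_k H[i,k] * gamma[draw, j_i, k]
  for (k in seq_len(pg)) {
    gk <- g[, (k - 1L) * J + d$station, drop = FALSE]  # draws x n_obs
    mu <- mu + sweep(gk, 2, d$H[, k], "*")
  }
  mu
}

#' Trace and model-fit plots
#'
#' `type = "trace"` draws the deviance trace per chain; `type = "ppc"` a
#' predicted-vs-observed scatter for non-outliers; `type = "qq"` the ranked
#' (Q-Q style) comparison for one station.
#'
#' @param x a `tmax_blend` fit.
#' @param type plot flavour.
#' @param station station id for `type = "qq"` (default first).
#' @param ... passed to the base plotting call.
#' @export
plot.tmax_blend <- function(x, type = c("trace", "ppc", "qq"), station = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    devs <- lapply(x$samples$chains, function(ch) ch$draws$deviance)
    graphics::plot(devs[[1]], type = "l", xlab = "retained draw",
                   ylab = "deviance", col = 1, ylim = range(unlist(devs)), ...)
    for (i in seq_along(devs)[-1]) graphics::lines(devs[[i]], col = i)
  } else if (type == "ppc") {
    pc <- ppc_scatter(x)
    graphics::plot(pc$observed, pc$pred_mean, xlab = "observed Tmax (degC)",
                   ylab = "PPD mean (degC)", pch = 16, cex = 0.4, ...)
    graphics::abline(0, 1, col = 2)
  } else {
    station <- station %||% x$design$meta$station_id[1]
    qq <- ppc_ranked(x, station)
    graphics::plot(qq$observed_sorted, qq$predicted_sorted,
                   xlab = "observed (sorted)", ylab = "predicted (sorted)",
                   pch = 16, cex = 0.4, ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}
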