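# Convergence diagnostics, posterior predictive checks and
# leave-one-station-out cross-validation.

#' Multivariate potential scale reduction factor (Brooks--Gelman)
#'
#' Computes the multivariate R-hat from the between- and within-chain
#' covariance matrices of a parameter subset, reported on the usual
#' scale-reduction (square-root) scale:
#' `MPSRF = sqrt((n - 1)/n + (m + 1)/m * lambda_max(W^-1 B / n))`.
#' Values near 1 indicate convergence; the reference analysis accepted 1.07
#' and the desk-scale suite requires < 1.1. A singular within-chain
#' covariance triggers a warning and a 1e-10 ridge.
#'
#' @param x a [tmax_blend()] fit, a `posterior_samples`, or a list of
#'   draw matrices (chains x (draws x parameters)).
#' @param params for fits: which columns to monitor; the default subset is
#'   `alpha_0`, the five penalty parameters, `beta_sigma` and the mean of
#'   `sigma_j^2` — one quantity per level of the hierarchy.
#' @return scalar MPSRF.
#' @export
mpsrf <- function(x, params = NULL) {
  chains <- mpsrf_chains(x, params)
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10L || any(vapply(chains, nrow, 1L) != n))
    stop("chains must have equal length >= 10")
  means <- lapply(chains, colMeans)
  grand <- Reduce(`+`, means) / m
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  Bn <- Reduce(`+`, lapply(means, function(mu) tcrossprod(mu - grand))) / (m - 1)
  ev <- tryCatch(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) 0)
  if (!is.finite(ev) || ev < 1e-12) {
    warning("within-chain covariance near-singular; adding 1e-10 ridge")
    W <- W + diag(1e-10, ncol(W))
  }
  lam1 <- max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lam1)
}

mpsrf_chains <- function(x, params = NULL) {
  if (inherits(x, "tmax_blend")) x <- x$samples
  if (inherits(x, "posterior_samples")) {
    lapply(x$chains, function(ch) {
      d <- ch$draws
      mat <- cbind(alpha0 = d$alpha[, 1], d$lambda,
                   beta_sigma = d$beta_sigma,
                   mean_sigma2 = rowMeans(d$sigma2))
      if (!is.null(params)) mat <- mat[, params, drop = FALSE]
      mat
    })
  } else {
    lapply(x, function(ch) {
      ch <- as.matrix(ch)
      if (!is.null(params)) ch <- ch[, params, drop = FALSE]
      ch
    })
  }
}

#' Posterior predictive check: predictions vs observations
#'
#' Pairs every non-flagged observation with its PPD mean and central
#' interval, and reports per-station interval coverage. Flagged outliers are
#' excluded: the Uniform component carries no information about their
#' individual values.
#'
#' @param fit a [tmax_blend()] fit.
#' @param level interval level (default 0.95).
#' @param seed RNG seed for predictive noise.
#' @return list: `pairs` (data.frame station_id, date, observed, pred_mean,
#'   lower, upper, covered), `coverage` (per-station), `observed`,
#'   `pred_mean`.
#' @export
ppc_scatter <- function(fit, level = 0.95, seed = 1L) {
  d <- fit$design
  set.seed(seed)
  keep <- fit$z_prob >= fit$config$outlier_threshold
  mu_d <- mu_draws_design(fit)[, keep, drop = FALSE]
  sg <- draws_matrix(fit, "sigma2")[, d$station[keep], drop = FALSE]
  yrep <- mu_d + matrix(stats::rnorm(length(mu_d)), nrow(mu_d)) * sqrt(sg)
  a <- (1 - level) / 2
  pm <- colMeans(yrep)
  lo <- apply(yrep, 2, stats::quantile, probs = a, names = FALSE)
  hi <- apply(yrep, 2, stats::quantile, probs = 1 - a, names = FALSE)
  obs <- d$y[keep]
  pairs <- data.frame(station_id = d$meta$station_id[d$station[keep]],
                      date = d$dates[keep], observed = obs,
                      pred_mean = pm, lower = lo, upper = hi,
                      covered = obs >= lo & obs <= hi)
  list(pairs = pairs,
       coverage = tapply(pairs$covered, pairs$station_id, mean),
       observed = obs, pred_mean = pm)
}

#' Ranked posterior predictive comparison (Q-Q style)
#'
#' Sorts a station's non-flagged observations and pairs them with the
#' sorted PPD point estimates (per-date PPD means), comparing the overall
#' distribution rather than individual days.
#'
#' @param fit a [tmax_blend()] fit.
#' @param station station id.
#' @param seed RNG seed.
#' @return list: `observed_sorted`, `predicted_sorted`, `max_gap`.
#' @export
ppc_ranked <- function(fit, station, seed = 1L) {
  d <- fit$design
  j <- match(as.character(station), d$meta$station_id)
  if (is.na(j)) stop("lookup error: unknown station id ", station)
  rows <- which(d$station == j & fit$z_prob >= fit$config$outlier_threshold)
  if (length(rows) < 10L) stop("need at least 10 non-outlier points")
  set.seed(seed)
  pr <- ppd_station(fit, station, dates = d$dates[rows])
  obs <- sort(d$y[rows])
  pred <- sort(pr$mean)
  list(observed_sorted = obs, predicted_sorted = pred,
       max_gap = max(abs(obs - pred)))
}

#' Leave-one-station-out cross-validation
#'
#' Refits the model with each station held out in turn, predicts the held
#' station's series by spatial extrapolation ([ppd_new_location()] with its
#' own covariate series), and compares the observed and predicted overall
#' mean and tail quantiles (defaults 5% and 95%; quantiles of the per-day
#' PPD means).
#'
#' @param stations a `station_data` data.frame.
#' @param field the covariate [reanalysis_field()].
#' @param config a [blend_config()] used for every fold.
#' @param probs lower/upper tail probabilities.
#' @return data.frame of class `cv_summary`, one row per station with
#'   `obs_*`, `pred_*` and `diff_* = obs - pred` for mean, lower and upper.
#' @export
loso_cv <- function(stations, field, config = blend_config(),
                    probs = c(0.05, 0.95)) {
  stations <- validate_stations(as.data.frame(stations),
                                u_min = config$u_min, u_max = config$u_max)
  ids <- sort(unique(stations$station_id))
  if (length(ids) < 5L)
    stop("need at least 5 stations so every fold retains 4 for the spatial bases")
  out <- NULL
  for (id in ids) {
    row <- tryCatch({
      train <- stations[stations$station_id != id, ]
      test <- stations[stations$station_id == id & !is.na(stations$tmax), ]
      fit <- tmax_blend(train, field, config)
      cv <- match_station(field, test$lon[1], test$lat[1],
                          k = config$k_neighbours, power = config$idw_power)
      x <- cv$x[match(test$date, as.Date(cv$times))]
      ok <- !is.na(x)
      # the held-out station's covariate can exceed the training range; the
      # basis extrapolates naturally there, which is the intended behaviour
      pr <- suppressWarnings(
        ppd_new_location(fit, test$lon[1], test$lat[1], x[ok],
                         dates = test$date[ok], seed = config$seed))
      obs <- test$tmax[ok]; pred <- pr$mean
      data.frame(station_id = id,
                 obs_mean = mean(obs), pred_mean = mean(pred),
                 obs_lower = stats::quantile(obs, probs[1], names = FALSE),
                 pred_lower = stats::quantile(pred, probs[1], names = FALSE),
                 obs_upper = stats::quantile(obs, probs[2], names = FALSE),
                 pred_upper = stats::quantile(pred, probs[2], names = FALSE))
    }, error = function(e) {
      warning("fold ", id, " failed: ", conditionMessage(e))
      NULL
    })
    out <- rbind(out, row)
  }
  if (is.null(out)) stop("all cross-validation folds failed")
  out$diff_mean <- out$obs_mean - out$pred_mean
  out$diff_lower <- out$obs_lower - out$pred_lower
  out$diff_upper <- out$obs_upper - out$pred_upper
  rownames(out) <- NULL
  class(out) <- c("cv_summary", "data.frame")
  out
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("Leave-one-station-out summary (Obs - Pred)\n")
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}
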