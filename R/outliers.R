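# Outlier flagging from posterior indicator probabilities, and the
# artificial-outlier injection sensitivity experiment.

#' Flag erroneous outliers
#'
#' A data point is flagged when its posterior non-outlier probability
#' `p(z = 1 | y)` (the mean of the retained indicator draws) falls below the
#' threshold; the default 0.5 can be made stricter, e.g. a threshold of 0.1
#' flags only points with `1 - p(z = 1 | y) > 0.9`.
#'
#' @param fit a [tmax_blend()] fit.
#' @param threshold flagging threshold in (0, 1); default the config's.
#' @return data.frame of class `outlier_report`, one row per modelled
#'   observation: station_id, date, y, p_z1, flagged; attribute
#'   `station_outlier_prop` holds the posterior mean of `1 - pi_j`.
#' @export
flag_outliers <- function(fit, threshold = fit$config$outlier_threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("config error: threshold must be in (0, 1)")
  d <- fit$design
  out <- data.frame(station_id = d$meta$station_id[d$station],
                    date = d$dates, y = d$y,
                    p_z1 = fit$z_prob,
                    flagged = fit$z_prob < threshold)
  attr(out, "station_outlier_prop") <-
    stats::setNames(1 - colMeans(draws_matrix(fit, "pi")), d$meta$station_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' Write an outlier report as CSV
#' @param report a [flag_outliers()] result.
#' @param path file path.
#' @export
write_outlier_csv <- function(report, path) {
  out <- as.data.frame(report)
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inject artificial outliers
#'
#' Corrupts `n_inject` randomly chosen eligible points by adding or
#' subtracting (sign probability 0.5) a draw from `Unif(M - 5, M + 5)`,
#' where `M = max(|y - mean(y)|)` over the non-missing, non-excluded
#' temperatures (globally by default, or per station). Corrupted values are
#' clipped inside the mixture support so they remain representable; with the
#' default (-80, 80) degC bounds the clip is almost never active.
#'
#' @param stations a `station_data` data.frame.
#' @param n_inject number of points to corrupt.
#' @param seed RNG seed.
#' @param exclude logical or integer index of rows not eligible (e.g. points
#'   already flagged by a previous fit).
#' @param m_scope `"global"` (one M over all stations) or `"per_station"`.
#' @param offset_range offsets are drawn from `Unif(M + offset_range[1],
#'   M + offset_range[2])`; the default `c(-5, 5)` gives the standard
#'   `Unif(M - 5, M + 5)` corruption, larger shifts give easier outliers.
#' @param u_min,u_max mixture support for clipping.
#' @return list: `data` (the contaminated `station_data`), `log`
#'   (data.frame: row index, station_id, date, y_original, y_injected,
#'   offset) and `M`.
#' @export
inject_outliers <- function(stations, n_inject, seed = NULL, exclude = NULL,
                            m_scope = c("global", "per_station"),
                            offset_range = c(-5, 5),
                            u_min = -80, u_max = 80) {
  m_scope <- match.arg(m_scope)
  stations <- as.data.frame(stations)
  if (!is.null(seed)) set.seed(seed)
  eligible <- which(!is.na(stations$tmax))
  if (!is.null(exclude)) {
    excl <- if (is.logical(exclude)) which(exclude) else exclude
    eligible <- setdiff(eligible, excl)
  }
  if (n_inject > length(eligible))
    stop(sprintf("n_inject = %d exceeds %d eligible observations",
                 n_inject, length(eligible)))
  if (m_scope == "global") {
    y <- stations$tmax[eligible]
    M <- max(abs(y - mean(y)))
    Mrow <- rep(M, nrow(stations))
  } else {
    Mj <- tapply(stations$tmax[eligible], stations$station_id[eligible],
                 function(y) max(abs(y - mean(y))))
    Mrow <- as.numeric(Mj[stations$station_id])
    M <- Mj
  }
  if (any(unlist(M) <= 5))
    warning("degenerate corruption: M <= 5, offsets may be small")
  if (n_inject == 0L)
    return(list(data = stations,
                log = data.frame(row = integer(), station_id = character(),
                                 date = as.Date(character()),
                                 y_original = numeric(), y_injected = numeric(),
                                 offset = numeric()),
                M = M))
  rows <- sample(eligible, n_inject)
  u <- stats::runif(n_inject, Mrow[rows] + offset_range[1],
                    Mrow[rows] + offset_range[2])
  sgn <- ifelse(stats::runif(n_inject) < 0.5, -1, 1)
  y_new <- pmin(pmax(stations$tmax[rows] + sgn * u,
                     u_min + 1e-6), u_max - 1e-6)
  log <- data.frame(row = rows, station_id = stations$station_id[rows],
                    date = stations$date[rows],
                    y_original = stations$tmax[rows],
                    y_injected = y_new, offset = y_new - stations$tmax[rows])
  stations$tmax[rows] <- y_new
  list(data = validate_stations(stations, u_min = u_min, u_max = u_max),
       log = log, M = M)
}

#' Outlier-injection sensitivity experiment
#'
#' For each trial: inject `n_inject` artificial outliers (excluding points a
#' reference fit already flags, when supplied), refit the model on the
#' contaminated data, flag, and count how many injected points are recovered
#' and how many previously clean points are falsely flagged. `refit = FALSE`
#' scores the contaminated points against an existing fit's posterior
#' (rescoring mode) instead of re-running the sampler.
#'
#' @param stations a `station_data` data.frame.
#' @param field the covariate [reanalysis_field()] (or `NULL` if `stations`
#'   carries `x`).
#' @param config a [blend_config()] for the trial fits.
#' @param n_inject points corrupted per trial.
#' @param n_trials number of trials.
#' @param seed base RNG seed; trial i uses `seed + i`.
#' @param reference_fit optional fit whose flagged points are excluded from
#'   injection.
#' @param refit logical; re-run the sampler per trial (default) or rescore.
#' @return data.frame per trial: n_injected, n_recovered, false_positives;
#'   attribute `logs` keeps the injection logs.
#' @export
outlier_sensitivity <- function(stations, field, config, n_inject, n_trials,
                                seed = 1L, reference_fit = NULL, refit = TRUE,
                                offset_range = c(-5, 5)) {
  if (n_trials == 0L)
    return(data.frame(trial = integer(), n_injected = integer(),
                      n_recovered = integer(), false_positives = integer()))
  excl <- NULL
  if (!is.null(reference_fit)) {
    rep0 <- flag_outliers(reference_fit)
    key0 <- paste(rep0$station_id, rep0$date)[rep0$flagged]
    excl <- which(paste(stations$station_id, stations$date) %in% key0)
  }
  res <- NULL; logs <- list()
  for (tr in seq_len(n_trials)) {
    inj <- inject_outliers(stations, n_inject, seed = seed + tr, exclude = excl,
                           offset_range = offset_range,
                           u_min = config$u_min, u_max = config$u_max)
    cfg <- config; cfg$seed <- as.integer(config$seed + 7L * tr)
    fit <- if (refit) {
      tmax_blend(inj$data, field, cfg)
    } else {
      stopifnot(!is.null(reference_fit))
      rescore_fit(reference_fit, inj$data, field, cfg)
    }
    rep <- flag_outliers(fit)
    key_inj <- paste(inj$log$station_id, inj$log$date)
    key_obs <- paste(rep$station_id, rep$date)
    recovered <- sum(rep$flagged[key_obs %in% key_inj])
    # false positives count only previously clean points: neither injected
    # nor already flagged by the reference fit
    prev <- if (!is.null(reference_fit)) {
      rep0 <- flag_outliers(reference_fit)
      paste(rep0$station_id, rep0$date)[rep0$flagged]
    } else character()
    fp <- sum(rep$flagged[!(key_obs %in% key_inj) & !(key_obs %in% prev)])
    res <- rbind(res, data.frame(trial = tr, n_injected = nrow(inj$log),
                                 n_recovered = recovered, false_positives = fp))
    logs[[tr]] <- inj$log
  }
  attr(res, "logs") <- logs
  res
}

# score a contaminated dataset under an existing posterior: recompute
# p(z = 1 | y) per retained draw without re-running the sampler
rescore_fit <- function(fit, stations, field, config) {
  design <- build_designs(stations, field, config)
  al <- draws_matrix(fit, "alpha"); be <- draws_matrix(fit, "beta")
  g <- draws_matrix(fit, "gamma")
  sg <- draws_matrix(fit, "sigma2"); pp <- draws_matrix(fit, "pi")
  n_draws <- nrow(al); J <- design$J; pg <- ncol(design$H)
  zsum <- numeric(length(design$y))
  for (m in seq_len(n_draws)) {
    state <- list(alpha = al[m, ], beta = be[m, ],
                  gamma = matrix(g[m, ], J, pg),
                  sigma2 = sg[m, ], pi = pp[m, ])
    mu <- compute_mu(state, design)
    sj <- sqrt(state$sigma2[design$station]); pj <- state$pi[design$station]
    la <- log(pj) + stats::dnorm(design$y, mu, sj, log = TRUE)
    lb <- log1p(-pj) - log(config$u_max - config$u_min)
    zsum <- zsum + 1 / (1 + exp(lb - la))
  }
  out <- fit
  out$design <- design
  out$z_prob <- zsum / n_draws
  out$config <- config
  out
}
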