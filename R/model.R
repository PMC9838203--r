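#' Assemble model data and design matrices
#'
#' Joins station observations with the gridded covariate (via the
#' k-nearest-neighbour change of support), builds the three spline bases and
#' returns everything the likelihood and the Gibbs sampler need:
#' \itemize{
#'   \item `Xf`: intercept design `[1, X^(f)]` where `X^(f)` is the centered
#'     spatial TPRS basis at the station coordinates (so the leading
#'     coefficient is the overall intercept alpha_0);
#'   \item `Xg`: slope design, the (uncentered) spatial basis rows multiplied
#'     by the covariate value of each observation, so `Xg %*% beta =
#'     g(s) * x`;
#'   \item `H`: the shared non-linear covariate basis (null space excluded,
#'     centered) evaluated at each observation's covariate value; station j's
#'     block uses its own coefficients gamma_j.
#' }
#' Rows with missing temperature are excluded from the design (they
#' contribute nothing to the likelihood and are imputed at prediction time).
#'
#' @param stations a `station_data` data.frame (see [read_station_csv()]).
#' @param field a daily [reanalysis_field()] providing the covariate, or
#'   `NULL` if `stations` already carries a covariate column `x`.
#' @param config a [blend_config()].
#' @return a list of class `blend_design`.
#' @export
build_designs <- function(stations, field, config = blend_config()) {
  stations <- validate_stations(as.data.frame(stations),
                                u_min = config$u_min, u_max = config$u_max)
  meta <- station_table(stations)
  J <- nrow(meta)
  if (J < 4L)
    stop("validation error: need at least 4 stations for the spatial spline bases")
  coords <- as.matrix(meta[, c("lon", "lat")])

  covariates <- NULL
  if (!is.null(field)) {
    covariates <- lapply(seq_len(J), function(j)
      match_station(field, meta$lon[j], meta$lat[j], k = config$k_neighbours,
                    power = config$idw_power, station_id = meta$station_id[j]))
    names(covariates) <- meta$station_id
    xmap <- lapply(covariates, function(cv) {
      v <- cv$x; names(v) <- format(cv$times); v
    })
    stations$x <- NA_real_
    for (j in seq_len(J)) {
      rows <- stations$station_id == meta$station_id[j]
      stations$x[rows] <- xmap[[j]][format(stations$date[rows])]
    }
  } else if (!"x" %in% names(stations)) {
    stop("either a reanalysis field or a precomputed covariate column x is required")
  }
  n_cov_missing <- sum(is.na(stations$x))
  if (n_cov_missing)
    warning(sprintf("%d observations have no covariate (outside the reanalysis period); dropped",
                    n_cov_missing))

  obs <- stations[!is.na(stations$tmax) & !is.na(stations$x), ]
  if (nrow(obs) < 10L) stop("validation error: insufficient data after matching")
  st_idx <- match(obs$station_id, meta$station_id)

  n_alpha <- config$n_alpha %||% (J - 1L)
  n_beta <- config$n_beta %||% (J - 1L)
  basis_f <- build_tprs(coords, n_basis = n_alpha, center = TRUE,
                        include_null_space = TRUE)
  basis_g <- build_tprs(coords, n_basis = n_beta, center = FALSE,
                        include_null_space = TRUE)
  xs <- obs$x
  kn <- min(config$h_knots, length(unique(xs)))
  h_knots <- unique(as.numeric(stats::quantile(unique(xs),
                                               probs = seq(0, 1, length.out = kn))))
  basis_h <- build_tprs(h_knots, n_basis = config$n_gamma, center = TRUE,
                        include_null_space = FALSE)
  # make h_j exactly trend-free over the training covariate values so the
  # non-linear deviations cannot absorb the linear bias g(s) x
  basis_h <- orthogonalize_basis(basis_h, xs)

  Bf <- basis_f$model_matrix          # J x n_alpha, rows align with meta
  Bg <- basis_g$model_matrix
  Xf <- cbind(1, Bf[st_idx, , drop = FALSE])
  Xg <- Bg[st_idx, , drop = FALSE] * xs
  H <- evaluate_basis(basis_h, xs)

  structure(list(
    y = obs$tmax, x = xs, station = st_idx,
    dates = obs$date, J = J, n_j = tabulate(st_idx, J),
    meta = meta, coords = coords, stations = stations,
    covariates = covariates,
    Xf = Xf, Xg = Xg, H = H,
    basis_f = basis_f, basis_g = basis_g, basis_h = basis_h,
    Sf0 = basis_f$penalty_null, Sf1 = basis_f$penalty_wiggly,
    Sg0 = basis_g$penalty_null, Sg1 = basis_g$penalty_wiggly,
    Sh = basis_h$penalty_wiggly,
    config = config
  ), class = "blend_design")
}

#' @export
print.blend_design <- function(x, ...) {
  cat(sprintf("blend_design: %d stations, %d observations, bases f:%d g:%d h:%d\n",
              x$J, length(x$y), ncol(x$Xf) - 1L, ncol(x$Xg), ncol(x$H)))
  invisible(x)
}

#' Prior precision matrices for the coefficient blocks
#'
#' `Omega_alpha_f` is the full intercept-block precision: 1/var_alpha0 for
#' alpha_0 and `lambda_f0 * S0 + lambda_f1 * S1` for the spatial
#' coefficients; `Omega_beta` and `Omega_gamma` are the slope-smooth and
#' non-linear-smooth precisions.
#'
#' @param design a `blend_design`.
#' @param lambda named vector `c(f_null, f_wiggly, g_null, g_wiggly, h)`.
#' @return list of precision matrices.
#' @export
prior_precisions <- function(design, lambda) {
  cfg <- design$config
  Om_a <- lambda[["f_null"]] * design$Sf0 + lambda[["f_wiggly"]] * design$Sf1
  p <- ncol(design$Xf)
  Om_af <- matrix(0, p, p)
  Om_af[1, 1] <- 1 / cfg$var_alpha0
  Om_af[-1, -1] <- Om_a
  list(alpha_f = Om_af,
       beta = lambda[["g_null"]] * design$Sg0 + lambda[["g_wiggly"]] * design$Sg1,
       gamma = lambda[["h"]] * design$Sh)
}

#' Model mean for every observation
#'
#' mu = alpha_0 + f(s_j) + g(s_j) * x + h_j(x), assembled from the design
#' matrices and the current parameter state.
#'
#' @param state parameter state list with `alpha`, `beta`, `gamma` (J x
#'   n_gamma matrix).
#' @param design a `blend_design`.
#' @return numeric vector, one mean per design row.
#' @export
compute_mu <- function(state, design) {
  if (length(state$alpha) != ncol(design$Xf) ||
      length(state$beta) != ncol(design$Xg) ||
      !all(dim(state$gamma) == c(design$J, ncol(design$H))))
    stop("shape error: state dimensions do not match design")
  as.numeric(design$Xf %*% state$alpha) +
    as.numeric(design$Xg %*% state$beta) +
    rowSums(design$H * state$gamma[design$station, , drop = FALSE])
}

#' Mixture log likelihood and deviance
#'
#' In marginal mode the latent indicators are summed out per observation:
#' `log(pi_j * N(y; mu, sigma_j^2) + (1 - pi_j) / (u_max - u_min))`,
#' evaluated by logsumexp. In conditional mode the density is evaluated
#' under the current indicators `z` (Gaussian where z = 1, bounded Uniform
#' where z = 0). Deviance is -2 times the log likelihood.
#'
#' @param state parameter state with `alpha`, `beta`, `gamma`, `sigma2`,
#'   `pi` and (for conditional mode) `z`.
#' @param design a `blend_design`.
#' @param y response vector (defaults to the design's).
#' @param marginal logical; marginalise over z.
#' @return list with `loglik`, `deviance` and per-observation `log_density`.
#' @export
mixture_loglik <- function(state, design, y = design$y, marginal = TRUE) {
  cfg <- design$config
  if (any(state$sigma2 <= 0)) stop("domain error: sigma2 must be positive")
  mu <- compute_mu(state, design)
  sj <- sqrt(state$sigma2[design$station])
  pj <- state$pi[design$station]
  if (marginal) {
    la <- log(pj) + stats::dnorm(y, mu, sj, log = TRUE)
    lb <- log1p(-pj) - log(cfg$u_max - cfg$u_min)
    m <- pmax(la, lb)
    ld <- m + log(exp(la - m) + exp(lb - m))
    ld[pj == 1] <- la[pj == 1]
    ld[pj == 0] <- lb[pj == 0]
  } else {
    z <- state$z
    ld <- ifelse(z == 1,
                 log(pj) + stats::dnorm(y, mu, sj, log = TRUE),
                 log1p(-pj) - log(cfg$u_max - cfg$u_min))
  }
  ll <- sum(ld)
  list(loglik = ll, deviance = -2 * ll, log_density = ld)
}

#' Initial parameter state
#'
#' Deterministic data-driven start: zero smooth coefficients, overall mean
#' intercept, per-station variances, pi = 0.95, all points treated as
#' non-outliers, unit penalties, beta_sigma = 10. `jitter_seed` disperses
#' chain starts with multiplicative U(0.5, 2) noise on the positive
#' parameters so multi-chain convergence diagnostics are meaningful.
#'
#' @param design a `blend_design`.
#' @param jitter_seed optional integer; `NULL` gives the undispersed start.
#' @return a parameter state list.
#' @export
initial_state <- function(design, jitter_seed = NULL) {
  J <- design$J
  sig2 <- as.numeric(tapply(design$y, design$station, stats::var))
  sig2[!is.finite(sig2) | sig2 <= 0] <- stats::var(design$y)
  st <- list(alpha = c(mean(design$y), rep(0, ncol(design$Xf) - 1L)),
             beta = rep(0, ncol(design$Xg)),
             gamma = matrix(0, J, ncol(design$H)),
             sigma2 = sig2,
             pi = rep(0.95, J),
             z = rep(1L, length(design$y)),
             beta_sigma = 10,
             lambda = c(f_null = 1, f_wiggly = 1, g_null = 1, g_wiggly = 1, h = 1))
  if (!is.null(jitter_seed)) {
    rng <- local({ set.seed(jitter_seed); function(n) stats::runif(n, 0.5, 2) })
    st$sigma2 <- st$sigma2 * rng(J)
    st$beta_sigma <- st$beta_sigma * rng(1)
    st$lambda <- st$lambda * rng(5)
    names(st$lambda) <- c("f_null", "f_wiggly", "g_null", "g_wiggly", "h")
    st$pi <- pmin(0.999, st$pi * stats::runif(J, 0.9, 1.05))
    st$alpha[1] <- st$alpha[1] * rng(1)
  }
  st
}
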