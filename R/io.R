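#' Persist posterior samples as long-format CSV
#'
#' Writes `samples.csv` (columns: parameter, chain, draw, value) and
#' `deviance.csv` (chain, draw, deviance) under `dir`. Parameter names are
#' `alpha[1]` (= alpha_0), `beta[k]`, `gamma[j,k]`, `sigma2[j]`, `pi[j]`,
#' `beta_sigma` and `lambda[name]`.
#'
#' @param fit a [tmax_blend()] fit (or a `posterior_samples`).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_samples_csv <- function(fit, dir) {
  samples <- if (inherits(fit, "tmax_blend")) fit$samples else fit
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); dev <- list()
  for (ch in seq_along(samples$chains)) {
    d <- samples$chains[[ch]]$draws
    J <- ncol(d$sigma2); pg <- ncol(d$gamma) / J
    nm <- c(sprintf("alpha[%d]", seq_len(ncol(d$alpha))),
            sprintf("beta[%d]", seq_len(ncol(d$beta))),
            sprintf("gamma[%d,%d]", rep(seq_len(J), pg),
                    rep(seq_len(pg), each = J)),
            sprintf("sigma2[%d]", seq_len(J)),
            sprintf("pi[%d]", seq_len(J)),
            "beta_sigma",
            sprintf("lambda[%s]", colnames(d$lambda)))
    mat <- cbind(d$alpha, d$beta, d$gamma, d$sigma2, d$pi, d$beta_sigma, d$lambda)
    rows[[ch]] <- data.frame(parameter = rep(nm, each = nrow(mat)),
                             chain = ch,
                             draw = rep(seq_len(nrow(mat)), times = ncol(mat)),
                             value = as.numeric(mat))
    dev[[ch]] <- data.frame(chain = ch, draw = seq_along(d$deviance),
                            deviance = d$deviance)
  }
  p1 <- file.path(dir, "samples.csv"); p2 <- file.path(dir, "deviance.csv")
  utils::write.csv(do.call(rbind, rows), p1, row.names = FALSE)
  utils::write.csv(do.call(rbind, dev), p2, row.names = FALSE, quote = FALSE)
  invisible(c(samples = p1, deviance = p2))
}

#' Write a gridded prediction as long CSV
#'
#' Columns: date, lon, lat, mean, sd.
#' @param grid a [downscale()] result.
#' @param path file path.
#' @export
write_grid_csv <- function(grid, path) {
  out <- do.call(rbind, lapply(seq_along(grid$dates), function(ti) {
    data.frame(date = format(grid$dates[ti]), lon = grid$cells$lon,
               lat = grid$cells$lat, mean = grid$mean[, ti], sd = grid$sd[, ti])
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records a reproducibility snapshot for a pipeline run: configuration,
#' seed, input file digests (file size + md5 via [tools::md5sum()]), package
#' version, per-stage timings and the output inventory. Written as JSON.
#'
#' @param config a [blend_config()].
#' @param inputs named character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @param timings named numeric vector of per-stage elapsed seconds.
#' @param path JSON output path.
#' @export
write_manifest <- function(config, inputs = character(), outputs = character(),
                           timings = numeric(), path) {
  digest <- function(f) if (file.exists(f))
    list(path = f, bytes = file.size(f), md5 = unname(tools::md5sum(f)))
  else list(path = f, bytes = NA, md5 = NA)
  man <- list(package = "tmaxblend",
              version = as.character(utils::packageVersion("tmaxblend")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed,
              config = unclass(config),
              inputs = lapply(inputs, digest),
              outputs = lapply(outputs, digest),
              timings_seconds = as.list(timings))
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out))
    warning("manifest lists outputs that do not exist: ",
            paste(missing_out, collapse = ", "))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
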