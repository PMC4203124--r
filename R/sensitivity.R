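#' Standardized-regression-coefficient sensitivity analysis
#'
#' Simulates heading date for every vector of a (possibly thinned) 3p
#' parameter grid in one environment, fits an ordinary least-squares model
#' of the simulated heading day on V_sat, P_base and TT_emhe (with
#' intercept), and attributes output variance to each parameter through
#' standardized regression coefficients
#' `SRC_i = beta_i^2 V(X_i) / V(Y)` with `V(Y) = sum_i beta_i^2 V(X_i)`,
#' so that the SRCs sum to 1 by construction whenever `V(Y) > 0`.
#'
#' Parameter vectors for which heading is not reached within the weather
#' record are excluded from the fit (a penalty date would manufacture
#' spurious linearity); the excluded fraction is reported. A parameter whose
#' grid axis is constant has undefined SRC, reported as `NA`.
#'
#' @param experiment One-row experiments data.frame (`id`, `sowing_date`,
#'   `latitude`, `season_class`).
#' @param weather Daily weather data.frame for the experiment.
#' @param spec A 3p [grid_spec()]; thinned grids (larger steps) are
#'   supported and SRC, being ratio-based, is stable under thinning.
#' @param k `model_constants`.
#' @return An `src_result` list: `experiment_id`, `season_class`, `beta0`,
#'   `beta`, `var_x`, `var_y`, `src` (named fractions), `frac_excluded`,
#'   `n_used`.
#' @export
src_analysis <- function(experiment, weather, spec = grid_spec("3p"),
                         k = model_constants()) {
  grid <- build_grid(spec, k)
  pred <- predict_grid_headings(experiment$sowing_date[1], weather,
                                experiment$latitude[1], grid, k)
  y <- as.numeric(pred)
  use <- !is.na(y)
  frac_excluded <- mean(!use)
  sc <- src_coefficients(y[use], grid[use, , drop = FALSE])
  structure(c(list(experiment_id = experiment$id[1],
                   season_class = experiment$season_class[1]),
              sc,
              list(frac_excluded = frac_excluded, n_used = sum(use))),
            class = "src_result")
}

#' SRC decomposition of a response over a factor design
#'
#' Fits `y ~ X` by ordinary least squares (with intercept) and returns
#' `SRC_i = beta_i^2 V(X_i) / sum_j beta_j^2 V(X_j)`. Columns with zero
#' variance get `NA` SRC; a constant response (`V(Y) = 0`) makes all SRCs
#' undefined.
#'
#' @param y Numeric response.
#' @param x data.frame of numeric predictors.
#' @return List `beta0, beta, var_x, var_y, src`.
#' @export
src_coefficients <- function(y, x) {
  pars <- names(x)
  varying <- vapply(pars, function(p) length(unique(x[[p]])) > 1, logical(1))
  beta <- stats::setNames(rep(NA_real_, length(pars)), pars)
  if (length(y) < 2 || stats::var(y) == 0) {
    # constant response: V(Y) = 0, every SRC undefined
    src <- stats::setNames(rep(NA_real_, length(pars)), pars)
    return(list(beta0 = if (length(y)) y[1] else NA_real_, beta = beta,
                var_x = vapply(pars, function(p) stats::var(x[[p]]),
                               numeric(1)),
                var_y = 0, src = src))
  }
  if (length(y) > sum(varying) + 1 && any(varying)) {
    fit <- stats::lm(y ~ ., data = cbind(data.frame(y = y),
                                         x[, pars[varying], drop = FALSE]))
    beta0 <- unname(stats::coef(fit)[1])
    beta[pars[varying]] <- stats::coef(fit)[-1]
  } else {
    beta0 <- if (length(y)) mean(y) else NA_real_
  }
  var_x <- vapply(pars, function(p) stats::var(x[[p]]), numeric(1))
  contrib <- ifelse(is.na(beta), 0, beta^2 * var_x)
  var_y <- sum(contrib)
  src <- if (var_y > 0) contrib / var_y
  else stats::setNames(rep(NA_real_, length(pars)), pars)
  src[!varying] <- NA_real_
  list(beta0 = beta0, beta = beta, var_x = var_x, var_y = var_y, src = src)
}

#' @export
print.src_result <- function(x, ...) {
  cat(sprintf("SRC sensitivity, experiment %s (%s):\n", x$experiment_id,
              x$season_class))
  for (p in names(x$src))
    cat(sprintf("  %-8s SRC = %s\n", p,
                ifelse(is.na(x$src[p]), "undefined",
                       sprintf("%.4f", x$src[p]))))
  cat(sprintf("  excluded (heading not reached): %.1f%%\n",
              100 * x$frac_excluded))
  invisible(x)
}

#' Aggregate SRC results by season class
#'
#' @param results List of `src_result` objects.
#' @return data.frame `season_class, parameter, min, median, max, n` of SRC
#'   fractions within each season class (empty classes give no rows).
#' @export
aggregate_src <- function(results) {
  if (length(results) == 0L)
    return(data.frame(season_class = character(), parameter = character(),
                      min = numeric(), median = numeric(), max = numeric(),
                      n = integer()))
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(season_class = r$season_class, parameter = names(r$src),
               src = unname(r$src), stringsAsFactors = FALSE)))
  df <- df[!is.na(df$src), , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, list(df$season_class, df$parameter),
                                     drop = TRUE), function(d)
    data.frame(season_class = d$season_class[1], parameter = d$parameter[1],
               min = min(d$src), median = stats::median(d$src),
               max = max(d$src), n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$season_class, out$parameter), , drop = FALSE]
}
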