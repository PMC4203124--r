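#' Parameter-grid specification for brute-force calibration
#'
#' The calibration explores the full Cartesian product of the parameter
#' ranges: P_base from 0 to 10 h in 0.1 h steps (101 values), V_sat from 0
#' to 130 days in 1 day steps (131 values) and, in the `3p` strategy,
#' TT_emhe from 400 to 800 modified degree days in steps of 10 (41 values);
#' 101 x 131 = 13,231 vectors for `2p` and 101 x 131 x 41 = 542,471 for
#' `3p`. In the `2p` strategy TT_emhe is fixed at `tt_emhe_default`.
#'
#' @param strategy `"2p"` (V_sat, P_base) or `"3p"` (+ TT_emhe).
#' @param v_sat_range,v_sat_step V_sat bounds (days, inclusive) and step.
#' @param p_base_range,p_base_step P_base bounds (hours, inclusive) and step.
#' @param tt_emhe_range,tt_emhe_step TT_emhe bounds and step (`3p` only).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(strategy = c("2p", "3p"),
                      v_sat_range = c(0, 130), v_sat_step = 1,
                      p_base_range = c(0, 10), p_base_step = 0.1,
                      tt_emhe_range = c(400, 800), tt_emhe_step = 10) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy,
                 v_sat_range = v_sat_range, v_sat_step = v_sat_step,
                 p_base_range = p_base_range, p_base_step = p_base_step,
                 tt_emhe_range = tt_emhe_range, tt_emhe_step = tt_emhe_step),
            class = "grid_spec")
}

.axis_values <- function(range, step) {
  n <- round((range[2] - range[1]) / step)
  range[1] + step * (0:n)
}

#' Build the full parameter grid
#'
#' Exact Cartesian product in deterministic order: V_sat outermost, P_base
#' inner, TT_emhe innermost. `2p` vectors carry `tt_emhe = tt_emhe_default`.
#'
#' @param spec A [grid_spec()].
#' @param k `model_constants` (for `tt_emhe_default` in the `2p` strategy).
#' @return data.frame with columns `v_sat`, `p_base`, `tt_emhe`, one row per
#'   parameter vector, with `spec` attached as an attribute.
#' @export
build_grid <- function(spec = grid_spec("2p"), k = model_constants()) {
  vs <- .axis_values(spec$v_sat_range, spec$v_sat_step)
  pb <- round(.axis_values(spec$p_base_range, spec$p_base_step), 10)
  te <- if (spec$strategy == "3p")
    .axis_values(spec$tt_emhe_range, spec$tt_emhe_step)
  else k$tt_emhe_default
  g <- expand.grid(tt_emhe = te, p_base = pb, v_sat = vs,
                   KEEP.OUT.ATTRS = FALSE)[, c("v_sat", "p_base", "tt_emhe")]
  rownames(g) <- NULL
  attr(g, "spec") <- spec
  g
}

#' Root mean square error of prediction between heading dates
#'
#' Day differences are computed by calendar-date arithmetic. Predictions of
#' `NA` (stage not reached before the weather record ends) are only allowed
#' when `nr_penalty` is supplied: they are then scored as that date (by
#' convention the day after the weather record ends), a finite monotone
#' penalty that keeps the objective ordered.
#'
#' @param obs,pred Vectors of `Date` (equal length, n >= 1).
#' @param nr_penalty Optional `Date` substituted for `NA` predictions.
#' @return RMSEP in days.
#' @export
rmsep <- function(obs, pred, nr_penalty = NULL) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) == 0L) stop("rmsep undefined for n = 0")
  obs <- as.numeric(as.Date(obs))
  pred <- as.numeric(as.Date(pred))
  if (anyNA(pred)) {
    if (is.null(nr_penalty))
      stop("NA prediction without an nr_penalty date")
    pred[is.na(pred)] <- as.numeric(as.Date(nr_penalty))
  }
  sqrt(mean((obs - pred)^2))
}

#' Predicted heading dates for every grid vector in one environment
#'
#' Heading predictions depend on the environment and the parameter vector
#' only, so one evaluation per experiment serves every genotype. The daily
#' series (TM, Tt, Veff, VDD, Ph) are computed once; vernalization and
#' photoperiod factor columns are shared across vectors with the same V_sat
#' or P_base, and in the `3p` strategy the cumulative modified thermal time
#' is shared across the TT_emhe axis (only the crossing threshold differs).
#' Results are identical (bit-for-bit) to calling [simulate_heading()]
#' vector by vector.
#'
#' @param sowing_date Sowing date.
#' @param weather Daily weather data.frame covering sowing onward.
#' @param latitude Site latitude, degrees north.
#' @param grid Parameter grid from [build_grid()].
#' @param k `model_constants`.
#' @return Integer vector (length `nrow(grid)`) of predicted heading dates
#'   as `Date`, `NA` where heading is not reached within the record.
#' @export
predict_grid_headings <- function(sowing_date, weather, latitude, grid,
                                  k = model_constants()) {
  sowing_date <- as.Date(sowing_date)
  weather <- validate_weather(weather)
  if (!(sowing_date %in% weather$date))
    stop("weather record does not contain the sowing date")
  w <- weather[weather$date > sowing_date, , drop = FALSE]
  nvec <- nrow(grid)
  none <- rep(as.Date(NA), nvec)
  if (nrow(w) == 0L) return(none)
  tm <- mean_temperature(w$tmin, w$tmax)
  tt <- daily_thermal_time(tm, k)
  vdd <- cumsum(vernalization_efficiency(tm, k))
  ph <- photoperiod(day_of_year(w$date), latitude, k$sun_angle)

  iem <- match(TRUE, cumsum(tt) >= k$tt_sow_em)
  if (is.na(iem) || iem >= nrow(w)) return(none)
  after <- seq.int(iem + 1L, nrow(w))
  tt2 <- tt[after]; vdd2 <- vdd[after]; ph2 <- ph[after]

  vs <- unique(grid$v_sat); pb <- unique(grid$p_base)
  fvm <- vapply(vs, function(v)
    vernalization_factor(vdd2, list(v_sat = v), k), numeric(length(after)))
  fpm <- vapply(pb, function(b)
    photoperiod_factor(ph2, list(p_base = b), k), numeric(length(after)))

  combo <- unique(grid[, c("v_sat", "p_base")])
  # (Tt x FV) x FP, matching the per-day arithmetic of simulate_heading
  pv <- (tt2 * fvm[, match(combo$v_sat, vs), drop = FALSE]) *
    fpm[, match(combo$p_base, pb), drop = FALSE]
  cum <- apply(pv, 2, cumsum)
  if (length(after) == 1L) cum <- matrix(cum, nrow = 1L)

  combo_of <- match(paste(grid$v_sat, grid$p_base),
                    paste(combo$v_sat, combo$p_base))
  idx <- integer(nvec)
  for (thr in unique(grid$tt_emhe)) {
    sel <- grid$tt_emhe == thr
    first <- colSums(cum < thr) + 1L   # first crossing per combo column
    idx[sel] <- first[combo_of[sel]]
  }
  out <- rep(as.Date(NA), nvec)
  ok <- idx <= length(after)
  out[ok] <- w$date[after[idx[ok]]]
  out
}

#' Predicted heading dates for every grid vector in every experiment
#'
#' @param experiments data.frame with columns `id`, `sowing_date`,
#'   `season_class` and `latitude` (see [prepare_experiments()]).
#' @param weather Named list of daily weather data.frames, one per
#'   experiment id.
#' @param grid Parameter grid from [build_grid()].
#' @param k `model_constants`.
#' @return A `grid_predictions` list: `pred` (matrix experiments x vectors
#'   of `Date` stored as integer days), `penalty` (per-experiment penalty
#'   date for not-reached predictions: last weather day + 1), `grid`.
#' @export
predict_grid_all <- function(experiments, weather, grid,
                             k = model_constants()) {
  pred <- matrix(NA_real_, nrow(experiments), nrow(grid),
                 dimnames = list(experiments$id, NULL))
  penalty <- numeric(nrow(experiments))
  for (i in seq_len(nrow(experiments))) {
    id <- experiments$id[i]
    p <- predict_grid_headings(experiments$sowing_date[i], weather[[id]],
                               experiments$latitude[i], grid, k)
    pred[i, ] <- as.numeric(p)
    penalty[i] <- max(as.numeric(weather[[id]]$date)) + 1
  }
  structure(list(pred = pred, penalty = penalty, grid = grid,
                 experiments = experiments$id),
            class = "grid_predictions")
}

#' Attach site latitude to an experiments table
#' @param experiments Experiments data.frame (`id, site, sowing_date,
#'   season_class`).
#' @param sites Sites data.frame (`name, latitude, ...`).
#' @return The experiments table with a `latitude` column.
#' @export
prepare_experiments <- function(experiments, sites) {
  i <- match(experiments$site, sites$name)
  if (anyNA(i))
    stop(sprintf("unknown site reference(s): %s",
                 paste(unique(experiments$site[is.na(i)]), collapse = ", ")))
  experiments$latitude <- sites$latitude[i]
  experiments
}

.min_tol <- 1e-9  # vectors within this of the smallest RMSEP count as ties

#' Brute-force calibration of one genotype
#'
#' Evaluates every grid vector against the genotype's observed heading
#' dates over all supplied experiments where it headed, and returns all
#' vectors attaining the minimum RMSEP (ties resolved to a representative
#' by [select_representative()]).
#'
#' @param genotype_id Genotype to calibrate.
#' @param phenotypes Phenotype table ([read_phenotypes()] layout).
#' @param experiments Experiments table with `latitude` column.
#' @param weather Named list of weather data.frames per experiment id.
#' @param spec A [grid_spec()].
#' @param k `model_constants`.
#' @param predictions Optional precomputed [predict_grid_all()] result
#'   (reused across genotypes).
#' @return A `calibration_result`: `genotype_id`, `minimizing_vectors`
#'   (data.frame of all RMSEP-minimizing parameter vectors), `min_rmsep`,
#'   `selected` (representative vector), `n_experiments_used`, `filtered`.
#' @export
optimize_genotype <- function(genotype_id, phenotypes, experiments, weather,
                              spec = grid_spec("2p"), k = model_constants(),
                              predictions = NULL) {
  obs <- phenotypes[phenotypes$genotype_id == genotype_id &
                      phenotypes$headed &
                      phenotypes$experiment_id %in% experiments$id, ,
                    drop = FALSE]
  if (nrow(obs) == 0L)
    stop(sprintf("genotype %s has no usable heading observations",
                 genotype_id))
  if (is.null(predictions)) {
    used <- experiments[experiments$id %in% obs$experiment_id, ,
                        drop = FALSE]
    predictions <- predict_grid_all(used, weather, build_grid(spec, k), k)
  }
  grid <- predictions$grid
  sq <- numeric(nrow(grid))
  for (j in seq_len(nrow(obs))) {
    e <- match(obs$experiment_id[j], predictions$experiments)
    if (is.na(e)) stop("no grid predictions for experiment ",
                       obs$experiment_id[j])
    pr <- predictions$pred[e, ]
    pr[is.na(pr)] <- predictions$penalty[e]
    sq <- sq + (as.numeric(obs$heading_date[j]) - pr)^2
  }
  rm_all <- sqrt(sq / nrow(obs))
  mn <- min(rm_all)
  win <- which(rm_all <= mn + .min_tol)
  vecs <- grid[win, , drop = FALSE]
  rownames(vecs) <- NULL
  structure(list(genotype_id = genotype_id,
                 minimizing_vectors = vecs,
                 min_rmsep = mn,
                 selected = select_representative(vecs, spec),
                 n_experiments_used = nrow(obs),
                 spec = spec,
                 filtered = FALSE),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "calibration of %s: min RMSEP %.3f d over %d experiment(s)%s\n",
    x$genotype_id, x$min_rmsep, x$n_experiments_used,
    if (x$filtered) " (winter-filtered)" else ""))
  cat(sprintf("  %d minimizing vector(s); selected v_sat=%g d, p_base=%g h, tt_emhe=%g\n",
              nrow(x$minimizing_vectors), s$v_sat, s$p_base, s$tt_emhe))
  invisible(x)
}

#' Filter winter-genotype parameter vectors using spring sowings
#'
#' A winter genotype heads in none of the spring-sown experiments, so any
#' parameter vector that predicts heading earlier than the last heading
#' date recorded in a spring experiment plus `margin_days` is inconsistent
#' with the observations and is removed. Vectors predicting that heading is
#' never reached always pass. The result is re-minimized over the
#' survivors.
#'
#' @param result A `calibration_result` from [optimize_genotype()].
#' @param experiments Experiments table with `latitude`; only rows with
#'   `season_class == "spring"` are used.
#' @param weather Named list of weather data.frames per experiment id.
#' @param phenotypes Phenotype table, used for the last recorded heading
#'   date in each spring experiment (across all genotypes).
#' @param k `model_constants`.
#' @param margin_days Days added to the last recorded heading (10).
#' @return The filtered `calibration_result` (`filtered = TRUE`).
#' @export
filter_winter_vectors <- function(result, experiments, weather, phenotypes,
                                  k = model_constants(), margin_days = 10) {
  spring <- experiments[experiments$season_class == "spring", , drop = FALSE]
  if (nrow(spring) == 0L) stop("no spring-sown experiments to filter on")
  vecs <- result$minimizing_vectors
  keep <- rep(TRUE, nrow(vecs))
  for (i in seq_len(nrow(spring))) {
    id <- spring$id[i]
    obs_he <- phenotypes$heading_date[phenotypes$experiment_id == id &
                                        phenotypes$headed]
    if (length(obs_he) == 0L) next  # nothing recorded: no constraint
    cutoff <- max(obs_he) + margin_days
    for (v in which(keep)) {
      p <- genotype_parameters(vecs$v_sat[v], vecs$p_base[v],
                               vecs$tt_emhe[v])
      hd <- simulate_heading(spring$sowing_date[i], weather[[id]],
                             spring$latitude[i], p, k)$heading_date
      if (!is.na(hd) && hd < cutoff) keep[v] <- FALSE
    }
  }
  if (!any(keep))
    stop(sprintf("genotype %s: all minimizing vectors removed by the winter filter",
                 result$genotype_id))
  vecs <- vecs[keep, , drop = FALSE]
  rownames(vecs) <- NULL
  result$minimizing_vectors <- vecs
  result$selected <- select_representative(vecs,
                                           result$spec %||% grid_spec("2p"))
  result$filtered <- TRUE
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Representative vector among RMSEP ties
#'
#' When several parameter vectors minimize the RMSEP, the representative is
#' the member closest (Euclidean distance, each axis scaled by its grid
#' step) to the component-wise median of the tied vectors. Exact distance
#' ties break deterministically to the lowest V_sat, then P_base, then
#' TT_emhe.
#'
#' @param vectors data.frame of tied parameter vectors (`v_sat`, `p_base`,
#'   `tt_emhe`).
#' @param spec The [grid_spec()] (for axis steps).
#' @return One-row list (`v_sat`, `p_base`, `tt_emhe`).
#' @export
select_representative <- function(vectors, spec = grid_spec("2p")) {
  if (nrow(vectors) == 0L) stop("no vectors to select from")
  d <- ((vectors$v_sat - stats::median(vectors$v_sat)) / spec$v_sat_step)^2 +
    ((vectors$p_base - stats::median(vectors$p_base)) / spec$p_base_step)^2
  if (spec$strategy == "3p")
    d <- d + ((vectors$tt_emhe - stats::median(vectors$tt_emhe)) /
                spec$tt_emhe_step)^2
  i <- order(d, vectors$v_sat, vectors$p_base, vectors$tt_emhe)[1]
  list(v_sat = vectors$v_sat[i], p_base = vectors$p_base[i],
       tt_emhe = vectors$tt_emhe[i])
}

#' Robustness of the optimized parameters to the experiment set
#'
#' Repeats the calibration on random subsets of the genotype's
#' experiments, drawing (without replacement) `n_spring - 1` of its
#' spring-sown and `n_autumn - 1` of its autumn-sown experiments for each
#' repeat, and reports the spread of the selected parameters.
#'
#' @inheritParams optimize_genotype
#' @param n_repeats Number of random experiment sets (10).
#' @param seed RNG seed.
#' @return List: `repeats` (data.frame of selected `v_sat`, `p_base`,
#'   `tt_emhe` per repeat), `sd_v_sat` (days), `sd_p_base` (hours).
#' @export
resample_robustness <- function(genotype_id, phenotypes, experiments,
                                weather, spec = grid_spec("2p"),
                                k = model_constants(), n_repeats = 10,
                                seed = 1) {
  tested <- phenotypes$experiment_id[phenotypes$genotype_id == genotype_id &
                                       phenotypes$headed]
  ex <- experiments[experiments$id %in% tested, , drop = FALSE]
  n_aut <- sum(ex$season_class == "autumn")
  n_spr <- sum(ex$season_class == "spring")
  if (max(n_aut, n_spr) < 2L)
    stop("robustness resampling needs >= 2 experiments in a season class")
  grid <- build_grid(spec, k)
  predictions <- predict_grid_all(ex, weather, grid, k)
  rng <- .seeded_rng(seed)
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    pick <- function(ids) {
      if (length(ids) < 2L) return(ids)
      ids[.rng_sample(rng, length(ids), length(ids) - 1L)]
    }
    sub <- c(pick(ex$id[ex$season_class == "autumn"]),
             pick(ex$id[ex$season_class == "spring"]))
    res <- optimize_genotype(genotype_id, phenotypes,
                             ex[ex$id %in% sub, , drop = FALSE], weather,
                             spec, k, predictions = list(
                               pred = predictions$pred,
                               penalty = predictions$penalty,
                               grid = grid,
                               experiments = predictions$experiments))
    out[[r]] <- as.data.frame(res$selected)
  }
  rep_df <- do.call(rbind, out)
  list(repeats = rep_df,
       sd_v_sat = stats::sd(rep_df$v_sat),
       sd_p_base = stats::sd(rep_df$p_base))
}

# Local RNG helpers: isolate seeded draws from the global RNG state.
.seeded_rng <- function(seed) {
  e <- new.env()
  e$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  e
}

.rng_sample <- function(rng, n, size) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  out <- sample.int(n, size)
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  out
}

#' Calibrate every genotype of a panel
#'
#' Classifies each genotype as winter (observed in at least one spring-sown
#' experiment and headed in none of them) or spring. Spring genotypes are
#' optimized over all experiments where they headed; winter genotypes over
#' their autumn-sown experiments, followed by the spring-sowing consistency
#' filter ([filter_winter_vectors()]).
#'
#' @inheritParams optimize_genotype
#' @param margin_days Winter-filter margin (10 days).
#' @param verbose Print progress.
#' @return data.frame `genotype_id, v_sat, p_base, tt_emhe, min_rmsep,
#'   n_vectors, n_experiments, winter, filtered`.
#' @export
calibrate_panel <- function(phenotypes, experiments, weather,
                            spec = grid_spec("2p"), k = model_constants(),
                            margin_days = 10, verbose = FALSE) {
  grid <- build_grid(spec, k)
  predictions <- predict_grid_all(experiments, weather, grid, k)
  genos <- unique(phenotypes$genotype_id)
  rows <- vector("list", length(genos))
  for (gi in seq_along(genos)) {
    g <- genos[gi]
    ph_g <- phenotypes[phenotypes$genotype_id == g, , drop = FALSE]
    spring_ids <- experiments$id[experiments$season_class == "spring"]
    in_spring <- ph_g$experiment_id %in% spring_ids
    winter <- any(in_spring) && !any(ph_g$headed[in_spring])
    ex_use <- if (winter)
      experiments[experiments$season_class == "autumn", , drop = FALSE]
    else experiments
    res <- optimize_genotype(g, phenotypes, ex_use, weather, spec, k,
                             predictions = predictions)
    if (winter)
      res <- tryCatch(
        filter_winter_vectors(res, experiments, weather, phenotypes, k,
                              margin_days),
        error = function(e) { warning(conditionMessage(e)); res })
    if (verbose) print(res)
    rows[[gi]] <- data.frame(
      genotype_id = g, v_sat = res$selected$v_sat,
      p_base = res$selected$p_base, tt_emhe = res$selected$tt_emhe,
      min_rmsep = res$min_rmsep, n_vectors = nrow(res$minimizing_vectors),
      n_experiments = res$n_experiments_used, winter = winter,
      filtered = res$filtered, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
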