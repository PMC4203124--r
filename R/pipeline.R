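#' Evaluate predicted against observed heading dates
#'
#' Computes the RMSEP (root mean square error of prediction, days) and R2
#' between observed and predicted heading dates, pooled and optionally per
#' group. R2 is the squared Pearson correlation of observed and predicted
#' dates (the variance-explained convention for obs~pred relationships),
#' recorded in the report metadata. Dates are compared as calendar dates;
#' day-of-year is display only, so autumn sowings heading the following
#' year evaluate without year-wrap artifacts. Pairs where the prediction
#' did not reach heading are counted separately, never silently dropped.
#'
#' @param observations Phenotype data.frame (`genotype_id, experiment_id,
#'   heading_date, headed`).
#' @param predictions data.frame (`genotype_id, experiment_id,
#'   heading_date`) with `NA` for not-reached predictions.
#' @param by Grouping scope: `"pooled"`, `"experiment"`, or `"season"`
#'   (the latter needs `experiments`).
#' @param experiments Experiments table (for `by = "season"`).
#' @return data.frame `scope, group, n, mean, min, max, rmsep, r2` (mean,
#'   min and max are observed heading day-of-year), with attributes
#'   `n_not_reached`, `median_rmsep`, `median_r2` (medians across groups)
#'   and `r2_convention`.
#' @export
evaluate_predictions <- function(observations, predictions,
                                 by = c("pooled", "experiment", "season"),
                                 experiments = NULL) {
  by <- match.arg(by)
  obs <- observations[observations$headed, , drop = FALSE]
  key <- function(d) paste(d$genotype_id, d$experiment_id)
  i <- match(key(obs), key(predictions))
  obs <- obs[!is.na(i), , drop = FALSE]
  pred_date <- predictions$heading_date[i[!is.na(i)]]
  nr <- is.na(pred_date)
  group <- switch(by,
                  pooled = rep("all", nrow(obs)),
                  experiment = obs$experiment_id,
                  season = {
                    if (is.null(experiments))
                      stop("by = 'season' needs the experiments table")
                    experiments$season_class[
                      match(obs$experiment_id, experiments$id)]
                  })
  rows <- lapply(split(seq_len(nrow(obs)), group), function(idx) {
    o <- obs$heading_date[idx]; p <- pred_date[idx]
    use <- !is.na(p)
    r2 <- if (sum(use) >= 3 &&
              stats::sd(as.numeric(o[use])) > 0 &&
              stats::sd(as.numeric(p[use])) > 0)
      stats::cor(as.numeric(o[use]), as.numeric(p[use]))^2
    else NA_real_
    data.frame(scope = by, group = group[idx][1], n = sum(use),
               mean = round(mean(day_of_year(o))),
               min = min(day_of_year(o)), max = max(day_of_year(o)),
               rmsep = if (any(use)) rmsep(o[use], p[use]) else NA_real_,
               r2 = r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_not_reached") <- sum(nr)
  attr(out, "median_rmsep") <- stats::median(out$rmsep, na.rm = TRUE)
  attr(out, "median_r2") <- stats::median(out$r2, na.rm = TRUE)
  attr(out, "r2_convention") <- "squared Pearson correlation of obs~pred"
  out
}

#' Fit marker models for the calibrated parameters
#'
#' The marker-model half of the pipeline: mask rare allele classes, impute
#' missing calls, discard unreliably imputed markers (PFC filter), run the
#' structure-corrected association scan per trait, keep markers associated
#' at `alpha`, collapse collinear markers to one representative per LD
#' block, and fit the final multiple-marker model by backward elimination.
#'
#' @param params Calibration table (`genotype_id, v_sat, p_base, tt_emhe`),
#'   e.g. from [calibrate_panel()].
#' @param genotypes A [genotype_matrix()].
#' @param structure Structure table (`genotype_id, g1..g4`).
#' @param traits Traits to model (default `v_sat` and `p_base`).
#' @param B Permutations for adjusted p-values; with `B = 0` the raw
#'   p-values gate candidacy.
#' @param alpha Association and retention threshold (0.05).
#' @param min_freq Rare-class masking threshold (0.05).
#' @param max_pfc Imputation-reliability threshold (0.2).
#' @param r_threshold LD-block collinearity threshold (0.8).
#' @param seed RNG seed (imputation forests and permutations).
#' @param n_trees,max_iter Imputation forest size and iteration cap.
#' @return List per trait of `marker_linear_model`, with attributes
#'   `associations` (per-trait scan tables) and `imputation` (PFC report).
#' @export
fit_parameter_models <- function(params, genotypes, structure,
                                 traits = c("v_sat", "p_base"),
                                 B = 1000, alpha = 0.05, min_freq = 0.05,
                                 max_pfc = 0.2, r_threshold = 0.8,
                                 seed = 1, n_trees = 100, max_iter = 10) {
  g <- mask_rare(genotypes, min_freq)
  imp <- impute_genotypes(g, seed = seed, n_trees = n_trees,
                          max_iter = max_iter)
  g <- pfc_filter(imp$matrix, imp$report, max_pfc)
  models <- list()
  assoc_tables <- list()
  for (tr in traits) {
    y <- stats::setNames(params[[tr]], params$genotype_id)
    assoc <- associate(y, g, structure, B = B, seed = seed, trait = tr)
    assoc_tables[[tr]] <- assoc
    pcol <- if (B > 0) assoc$adjusted_p else assoc$raw_p
    cand <- assoc$marker[!is.na(pcol) & pcol < alpha]
    if (length(cand) > 1) {
      lb <- ld_blocks(g[, cand, drop = FALSE], r_threshold)
      cand <- lb$representatives
    }
    models[[tr]] <- if (length(cand))
      backward_eliminate(y, cand, g, alpha = alpha, trait = tr)
    else marker_linear_model(tr, mean(y), list(), r2_fit = 0)
  }
  attr(models, "associations") <- assoc_tables
  attr(models, "imputation") <- imp$report
  models
}

#' Predict genotype parameters from marker models
#'
#' Applies the per-trait marker models to every genotype of a matrix.
#' Predictions are clamped to the biologically admissible parameter ranges
#' (V_sat >= 0 days, 0 <= P_base < p_opt, TT_emhe > 0); traits without a
#' model fall back to `defaults`.
#'
#' @param models Named list of `marker_linear_model` (from
#'   [fit_parameter_models()] or [bundled_marker_model()]).
#' @param genotypes A [genotype_matrix()] (imputed, or at least complete
#'   at the model markers).
#' @param defaults Parameter values for unmodelled traits.
#' @param k `model_constants`.
#' @return List: `params` (data.frame `genotype_id, v_sat, p_base,
#'   tt_emhe`), `exclusions` (genotypes lacking usable calls, with
#'   reasons).
#' @export
predict_parameters <- function(models, genotypes,
                               defaults = list(v_sat = 0, p_base = 0,
                                               tt_emhe = 500),
                               k = model_constants()) {
  ids <- rownames(genotypes)
  out <- data.frame(genotype_id = ids, stringsAsFactors = FALSE)
  excl <- list()
  clamp <- list(
    v_sat = function(v) pmax(0, v),
    p_base = function(v) pmin(k$p_opt - 1e-6, pmax(0, v)),
    tt_emhe = function(v) pmax(1, v))
  for (tr in c("v_sat", "p_base", "tt_emhe")) {
    if (!is.null(models[[tr]])) {
      pr <- predict_parameter_all(models[[tr]], genotypes)
      out[[tr]] <- clamp[[tr]](unname(pr$values[ids]))
      if (nrow(pr$exclusions)) excl[[tr]] <-
          cbind(trait = tr, pr$exclusions)
    } else out[[tr]] <- defaults[[tr]]
  }
  list(params = out,
       exclusions = if (length(excl)) do.call(rbind, excl)
       else data.frame(trait = character(), genotype_id = character(),
                       reason = character()))
}

#' Simulate heading dates for a parameter table
#'
#' @param params data.frame `genotype_id, v_sat, p_base, tt_emhe` (rows
#'   with any `NA` parameter are skipped).
#' @param experiments Experiments table with `latitude`.
#' @param weather Named list of weather data.frames per experiment id.
#' @param k `model_constants`.
#' @return data.frame `genotype_id, experiment_id, heading_date` (`NA`
#'   when heading is not reached within the record).
#' @export
predict_headings <- function(params, experiments, weather,
                             k = model_constants()) {
  ok <- stats::complete.cases(params[, c("v_sat", "p_base", "tt_emhe")])
  params <- params[ok, , drop = FALSE]
  combos <- unique(params[, c("v_sat", "p_base", "tt_emhe")])
  pred <- matrix(NA_real_, nrow(experiments), nrow(combos))
  for (e in seq_len(nrow(experiments))) {
    id <- experiments$id[e]
    for (c_i in seq_len(nrow(combos))) {
      p <- genotype_parameters(combos$v_sat[c_i], combos$p_base[c_i],
                               combos$tt_emhe[c_i])
      pred[e, c_i] <- as.numeric(
        simulate_heading(experiments$sowing_date[e], weather[[id]],
                         experiments$latitude[e], p, k)$heading_date)
    }
  }
  key <- function(d) paste(d$v_sat, d$p_base, d$tt_emhe)
  ci <- match(key(params), key(combos))
  rows <- expand.grid(g = seq_len(nrow(params)),
                      e = seq_len(nrow(experiments)))
  data.frame(genotype_id = params$genotype_id[rows$g],
             experiment_id = experiments$id[rows$e],
             heading_date = as.Date(pred[cbind(rows$e, ci[rows$g])],
                                    origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

#' Read a pipeline configuration file
#'
#' YAML with paths (`sites, experiments, weather_dir, phenotypes,
#' genotypes, structure`), grid settings (`strategy, margin_days`),
#' marker-model settings (`B, alpha, seed`) and an output directory.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

.load_study_files <- function(cfg) {
  sites <- read_sites(cfg$sites)
  experiments <- prepare_experiments(
    read_experiments(cfg$experiments, sites), sites)
  weather <- list()
  for (id in experiments$id)
    weather[[id]] <- read_weather(
      file.path(cfg$weather_dir, sprintf("weather_%s.csv", id)))
  phen <- read_phenotypes(cfg$phenotypes, experiments)
  list(sites = sites, experiments = experiments, weather = weather,
       phenotypes = phen)
}

#' File-driven pipeline stages
#'
#' Thin orchestration over the in-memory API, driven by a [read_config()]
#' list: `run_calibration` calibrates the panel and writes
#' `calibration.csv`; `run_marker_fit` fits the marker models and writes
#' one JSON per trait; `run_prediction` predicts parameters and heading
#' dates for the genotype matrix and writes `predicted_params.csv` and
#' `predicted_headings.csv`. Each stage logs its input counts.
#'
#' @param cfg Config list (see [read_config()]).
#' @return The stage's main table or model list, invisibly written to
#'   `cfg$outdir`.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
run_calibration <- function(cfg) {
  d <- .load_study_files(cfg)
  message(sprintf("calibration: %d genotypes, %d experiments, strategy %s",
                  length(unique(d$phenotypes$genotype_id)),
                  nrow(d$experiments), cfg$strategy %||% "2p"))
  calib <- calibrate_panel(d$phenotypes, d$experiments, d$weather,
                           grid_spec(cfg$strategy %||% "2p"),
                           margin_days = cfg$margin_days %||% 10)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(calib, file.path(cfg$outdir, "calibration.csv"),
                   row.names = FALSE)
  calib
}

#' @rdname pipeline_stages
#' @export
run_marker_fit <- function(cfg) {
  calib <- utils::read.csv(file.path(cfg$outdir, "calibration.csv"),
                           stringsAsFactors = FALSE)
  genotypes <- read_genotypes(cfg$genotypes)
  structure <- read_structure(cfg$structure)
  message(sprintf("marker fit: %d genotypes, %d markers",
                  nrow(genotypes), ncol(genotypes)))
  models <- fit_parameter_models(calib, genotypes, structure,
                                 B = cfg$B %||% 1000,
                                 alpha = cfg$alpha %||% 0.05,
                                 seed = cfg$seed %||% 1)
  for (tr in names(models))
    write_marker_model(models[[tr]],
                       file.path(cfg$outdir,
                                 sprintf("marker_model_%s.json", tr)))
  models
}

#' @rdname pipeline_stages
#' @export
run_prediction <- function(cfg) {
  d <- .load_study_files(cfg)
  genotypes <- read_genotypes(cfg$genotypes)
  models <- list()
  for (tr in c("v_sat", "p_base", "tt_emhe")) {
    f <- file.path(cfg$outdir, sprintf("marker_model_%s.json", tr))
    if (file.exists(f)) models[[tr]] <- read_marker_model(f)
  }
  pp <- predict_parameters(models, genotypes)
  if (nrow(pp$exclusions))
    message(sprintf("%d genotype x trait exclusions (missing calls)",
                    nrow(pp$exclusions)))
  heads <- predict_headings(pp$params, d$experiments, d$weather)
  utils::write.csv(pp$params,
                   file.path(cfg$outdir, "predicted_params.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(heads[, 1:2],
               heading_date = ifelse(is.na(heads$heading_date), "NR",
                                     as.character(heads$heading_date))),
    file.path(cfg$outdir, "predicted_headings.csv"), row.names = FALSE)
  list(params = pp$params, headings = heads, exclusions = pp$exclusions)
}
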