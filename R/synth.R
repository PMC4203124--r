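#' Configuration of the synthetic study generator
#'
#' Defines a seeded synthetic analogue of a multi-environment wheat
#' phenology study: two temperate French-latitude sites, autumn and spring
#' sowings, and a panel mixing spring genotypes with winter genotypes whose
#' obligate vernalization requirement (high V_sat) prevents heading after
#' spring sowing. Marker effects are planted additively on V_sat and
#' P_base at disjoint marker sets, giving both parameters the multimodal,
#' major-gene distributions seen in real panels.
#'
#' Defaults scale the design to desk size: 60 genotypes, 300 markers,
#' 3 autumn + 2 spring experiments, 1.5 days of observation noise on
#' heading dates, 3% missing genotype calls, and a winter fraction of 0.25.
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param n_genotypes,n_markers Panel size.
#' @param winter_fraction Carrier frequency of the major winter allele
#'   (which is also the fraction of obligate-winter genotypes).
#' @param v_sat_intercept,v_sat_effects Baseline V_sat (days) and planted
#'   allelic effects (days); the first effect is the major winter allele.
#' @param p_base_intercept,p_base_effects Baseline P_base (hours) and
#'   planted allelic effects (hours); the first effect is the major one.
#' @param minor_carrier_freq Carrier frequency of non-major effect alleles.
#' @param dev_sd_v_sat,dev_sd_p_base SD of the residual (polygenic)
#'   deviation added to each parameter before rounding to the grid.
#' @param noise_sd_days SD of observation noise on heading dates (days).
#' @param missing_rate Probability that a call is missing within a marker
#'   that carries missing data.
#' @param missing_marker_fraction Fraction of (non-effect) markers that
#'   carry missing data at all; most markers of a typical panel are
#'   complete.
#' @param sites data.frame `name, latitude` of the simulated sites.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_genotypes = 60, n_markers = 300,
                         winter_fraction = 0.25,
                         v_sat_intercept = 15,
                         v_sat_effects = c(100, 12, 6),
                         p_base_intercept = 1.5,
                         p_base_effects = c(3, 1),
                         minor_carrier_freq = 0.3,
                         dev_sd_v_sat = 2, dev_sd_p_base = 0.3,
                         noise_sd_days = 1.5,
                         missing_rate = 0.05,
                         missing_marker_fraction = 0.05,
                         sites = data.frame(
                           name = c("clermont", "moulon"),
                           latitude = c(45.77, 48.70),
                           stringsAsFactors = FALSE)) {
  stopifnot(winter_fraction >= 0, winter_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate daily weather for a site
#'
#' Sinusoidal annual mean-temperature cycle (coldest mid-January, mean
#' level decreasing with latitude) plus seeded AR(1) noise; the daily
#' minimum and maximum are the mean plus/minus half a positive daily
#' range, so `tmin <= tmax` always. Winters at the default latitudes hold
#' sustained mean temperatures in the vernalizing 3-10 degC plateau.
#'
#' @param latitude Site latitude, degrees north.
#' @param start,end First and last date of the record.
#' @param seed RNG seed.
#' @param amplitude Annual half-amplitude of the mean cycle, degC.
#' @param noise_sd Innovation SD of the AR(1) day-to-day noise, degC.
#' @param ar Autocorrelation of the noise.
#' @return Daily weather data.frame (`date`, `tmin`, `tmax`), gap-free.
#' @export
gen_weather <- function(latitude, start, end, seed = 1,
                        amplitude = 8.5, noise_sd = 2.0, ar = 0.6) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  n <- length(dates)
  doy <- day_of_year(dates)
  level <- 23.5 - 0.26 * latitude
  season <- level + amplitude * cos(2 * pi * (doy - 197) / 365.25)
  .with_seed(seed, {
    e <- stats::filter(stats::rnorm(n, 0, noise_sd), ar,
                       method = "recursive")
    dr <- pmax(1, stats::rnorm(n, 8, 2))
  })
  tm <- season + as.numeric(e)
  data.frame(date = dates, tmin = tm - dr / 2, tmax = tm + dr / 2)
}

#' Default experiment layout of the synthetic study
#'
#' Three autumn sowings and two spring sowings over two seasons at the two
#' configured sites, each with its observation window; `extra = TRUE` adds
#' two held-out autumn environments for validation designs (validation
#' sets in this kind of study are autumn-sown, the agronomically usual
#' practice).
#' The spring sowings sit at the late end of the feasible window, where
#' post-emergence vernalizing temperatures are marginal: that is what makes
#' the spring environment discriminate V_sat day by day (and what keeps
#' obligate-winter genotypes from heading there), while the autumn sowings
#' carry the photoperiod information for P_base.
#'
#' @param config A [synth_config()].
#' @param extra Add the two held-out environments.
#' @return Experiments data.frame (`id, site, sowing_date, end_date,
#'   season_class, latitude`).
#' @export
gen_experiments <- function(config = synth_config(), extra = FALSE) {
  ex <- data.frame(
    id = c("aut1", "aut2", "aut3", "spr1", "spr2"),
    site = c("moulon", "clermont", "moulon", "moulon", "clermont"),
    sowing_date = as.Date(c("2001-10-20", "2001-10-27", "2002-10-20",
                            "2002-05-02", "2002-05-06")),
    end_date = as.Date(c("2002-07-31", "2002-07-31", "2003-07-31",
                         "2002-09-15", "2002-09-15")),
    season_class = c("autumn", "autumn", "autumn", "spring", "spring"),
    stringsAsFactors = FALSE)
  if (extra)
    ex <- rbind(ex, data.frame(
      id = c("aut4", "aut5"),
      site = c("clermont", "moulon"),
      sowing_date = as.Date(c("2002-11-05", "2002-10-28")),
      end_date = as.Date(c("2003-07-31", "2003-07-31")),
      season_class = c("autumn", "autumn"),
      stringsAsFactors = FALSE))
  prepare_experiments(ex, config$sites)
}

#' Generate the genotype panel with planted marker effects
#'
#' True parameters are built additively: `v_sat = intercept + planted
#' allelic effects + N(0, dev_sd)`, rounded to the 1-day grid and clamped
#' to \[0, 130\]; `p_base` likewise on the 0.1 h grid, clamped to
#' \[0, 9\]. The first V_sat effect allele is the major winter allele
#' (carrier frequency `winter_fraction`); its carriers are the obligate
#' winter genotypes. Effect markers for the two traits are disjoint.
#' Non-effect markers are biallelic with group-dependent allele
#' frequencies driven by a 4-group population structure; calls go missing
#' at `missing_rate`.
#'
#' @param config A [synth_config()].
#' @return List: `genotypes` (a [genotype_matrix()]), `structure`
#'   (`genotype_id, g1..g4`), `truth` (`genotype_id, v_sat, p_base,
#'   tt_emhe, winter`), `effects` (data.frame of planted effects:
#'   `marker, trait, allele, effect`).
#' @export
gen_panel <- function(config = synth_config()) {
  cf <- config
  n <- cf$n_genotypes
  ids <- sprintf("G%03d", seq_len(n))
  nv <- length(cf$v_sat_effects)
  np <- length(cf$p_base_effects)
  stopifnot(cf$n_markers >= nv + np + 1)
  mk <- sprintf("M%04d", seq_len(cf$n_markers))
  v_mk <- mk[seq_len(nv)]
  p_mk <- mk[nv + seq_len(np)]
  .with_seed(cf$seed + 101L, {
    # structure: each genotype mostly from one of 4 ancestral groups
    grp <- sample.int(4, n, replace = TRUE)
    gmat <- matrix(stats::rgamma(4 * n, 0.5), n, 4)
    gmat[cbind(seq_len(n), grp)] <- stats::rgamma(n, 6)
    gmat <- gmat / rowSums(gmat)

    calls <- matrix(NA_character_, n, cf$n_markers,
                    dimnames = list(ids, mk))
    carrier <- function(freq) stats::runif(n) < freq
    eff_rows <- list()
    v_true <- rep(cf$v_sat_intercept, n)
    p_true <- rep(cf$p_base_intercept, n)
    winter <- rep(FALSE, n)
    for (i in seq_len(nv)) {
      freq <- if (i == 1) cf$winter_fraction else cf$minor_carrier_freq
      carry <- carrier(freq)
      calls[, v_mk[i]] <- ifelse(carry, "22", "11")
      v_true <- v_true + cf$v_sat_effects[i] * carry
      if (i == 1) winter <- carry
      eff_rows[[length(eff_rows) + 1L]] <- data.frame(
        marker = v_mk[i], trait = "v_sat", allele = "22",
        effect = cf$v_sat_effects[i], stringsAsFactors = FALSE)
    }
    for (i in seq_len(np)) {
      carry <- carrier(cf$minor_carrier_freq)
      calls[, p_mk[i]] <- ifelse(carry, "22", "11")
      p_true <- p_true + cf$p_base_effects[i] * carry
      eff_rows[[length(eff_rows) + 1L]] <- data.frame(
        marker = p_mk[i], trait = "p_base", allele = "22",
        effect = cf$p_base_effects[i], stringsAsFactors = FALSE)
    }
    # null markers with structure-dependent allele frequencies
    null_mk <- setdiff(mk, c(v_mk, p_mk))
    base_f <- stats::rbeta(length(null_mk), 2, 2)
    for (j in seq_along(null_mk)) {
      gf <- pmin(0.95, pmax(0.05,
                            base_f[j] + stats::rnorm(4, 0, 0.15)))
      calls[, null_mk[j]] <- ifelse(stats::runif(n) < gf[grp], "22", "11")
    }
    v_true <- pmin(130, pmax(0, round(
      v_true + stats::rnorm(n, 0, cf$dev_sd_v_sat))))
    p_true <- pmin(9, pmax(0, round(
      p_true + stats::rnorm(n, 0, cf$dev_sd_p_base), 1)))
    # Missing calls hit a small fraction of the markers (the typical
    # panel pattern), and only null markers: with no LD in the generator
    # an effect marker with missing data would be unimputable by
    # construction, which would measure the generator's lack of LD, not
    # the pipeline.
    n_miss_mk <- round(cf$missing_marker_fraction * length(null_mk))
    if (cf$missing_rate > 0 && n_miss_mk > 0) {
      miss_mk <- sample(null_mk, n_miss_mk)
      for (mm in miss_mk)
        calls[stats::runif(n) < cf$missing_rate, mm] <- NA_character_
    }
  })
  list(genotypes = genotype_matrix(calls),
       structure = data.frame(genotype_id = ids, g1 = gmat[, 1],
                              g2 = gmat[, 2], g3 = gmat[, 3],
                              g4 = gmat[, 4], stringsAsFactors = FALSE),
       truth = data.frame(genotype_id = ids, v_sat = v_true,
                          p_base = p_true, tt_emhe = 500, winter = winter,
                          stringsAsFactors = FALSE),
       effects = do.call(rbind, eff_rows))
}

#' Forward-simulate heading observations from true parameters
#'
#' Each genotype x experiment heading date is the phenology simulator's
#' prediction under the genotype's true parameters plus rounded normal
#' observation noise; when the simulator does not reach heading within the
#' experiment's record the observation is `NH` (not headed).
#'
#' @param truth Truth table from [gen_panel()].
#' @param experiments Experiments table with `latitude`.
#' @param weather Named list of weather data.frames per experiment id.
#' @param noise_sd_days Observation noise SD (days); 0 reproduces the
#'   simulator output exactly.
#' @param seed RNG seed for the noise.
#' @param k `model_constants`.
#' @return Phenotype data.frame (`genotype_id, experiment_id,
#'   heading_date, headed`).
#' @export
gen_phenotypes <- function(truth, experiments, weather,
                           noise_sd_days = 1.5, seed = 1,
                           k = model_constants()) {
  combos <- unique(truth[, c("v_sat", "p_base", "tt_emhe")])
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
  ci <- match(key(truth), key(combos))
  rows <- expand.grid(g = seq_len(nrow(truth)),
                      e = seq_len(nrow(experiments)))
  hd <- pred[cbind(rows$e, ci[rows$g])]
  noise <- if (noise_sd_days > 0)
    .with_seed(seed + 202L,
               round(stats::rnorm(nrow(rows), 0, noise_sd_days)))
  else rep(0, nrow(rows))
  headed <- !is.na(hd)
  data.frame(genotype_id = truth$genotype_id[rows$g],
             experiment_id = experiments$id[rows$e],
             heading_date = as.Date(ifelse(headed, hd + noise, NA),
                                    origin = "1970-01-01"),
             headed = headed, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Weather for both sites, the experiment layout, the genotype panel with
#' planted effects, and forward-simulated heading observations, all from
#' one master seed.
#'
#' @param config A [synth_config()].
#' @param extra_experiments Include the two held-out environments.
#' @param k `model_constants`.
#' @return List: `config`, `sites`, `experiments`, `weather` (named list
#'   per experiment id), `panel` (from [gen_panel()]), `phenotypes`.
#' @export
gen_study <- function(config = synth_config(), extra_experiments = FALSE,
                      k = model_constants()) {
  experiments <- gen_experiments(config, extra = extra_experiments)
  site_weather <- list()
  for (s in seq_len(nrow(config$sites)))
    site_weather[[config$sites$name[s]]] <-
      gen_weather(config$sites$latitude[s], "2001-09-01", "2003-08-31",
                  seed = config$seed + 300L + s)
  weather <- list()
  for (e in seq_len(nrow(experiments))) {
    w <- site_weather[[experiments$site[e]]]
    weather[[experiments$id[e]]] <-
      w[w$date >= experiments$sowing_date[e] &
          w$date <= experiments$end_date[e], , drop = FALSE]
  }
  panel <- gen_panel(config)
  phen <- gen_phenotypes(panel$truth, experiments, weather,
                         noise_sd_days = config$noise_sd_days,
                         seed = config$seed, k = k)
  list(config = config, sites = config$sites, experiments = experiments,
       weather = weather, panel = panel, phenotypes = phen)
}

#' Write a synthetic study to CSV fixtures
#'
#' Writes all tables of a [gen_study()] result in the package CSV
#' dialects, plus `truth.csv` with the planted parameters and
#' `effects.csv` with the planted marker effects.
#'
#' @param study A [gen_study()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synth_fixtures <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  utils::write.csv(study$sites, p("sites.csv"), row.names = FALSE,
                   quote = FALSE)
  ex <- study$experiments
  utils::write.csv(
    data.frame(id = ex$id, site = ex$site,
               sowing_date = as.character(ex$sowing_date),
               season_class = ex$season_class),
    p("experiments.csv"), row.names = FALSE, quote = FALSE)
  for (id in names(study$weather))
    write_weather(study$weather[[id]], p(sprintf("weather_%s.csv", id)))
  write_phenotypes(study$phenotypes, p("phenotypes.csv"))
  write_genotypes(study$panel$genotypes, p("genotypes.csv"))
  write_structure(study$panel$structure, p("structure.csv"))
  utils::write.csv(study$panel$truth, p("truth.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$panel$effects, p("effects.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(outdir)
}
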