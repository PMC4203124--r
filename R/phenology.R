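#' Fixed constants of the heading-date model
#'
#' The day-step model accumulates thermal time modified by vernalization and
#' photoperiod factors. Its non-genetic constants are fixed panel-wide:
#' cardinal temperatures of the thermal response (`t_base`, `t_opt`,
#' `t_card_max`; the cardinal maximum is named `t_card_max` to avoid
#' collision with daily maximum temperature), cardinal vernalizing
#' temperatures (`v_t1`..`v_t4`), the base vernalizing-day requirement
#' `v_base`, the optimum photoperiod `p_opt`, the sowing-to-emergence phase
#' duration `tt_sow_em` (modified degree days), the default
#' emergence-to-heading duration `tt_emhe_default`, and the twilight sun
#' angle used for photoperiod.
#'
#' @param t_base,t_opt,t_card_max Cardinal temperatures, deg C (1, 26, 37).
#' @param v_t1,v_t2,v_t3,v_t4 Cardinal vernalizing temperatures, deg C
#'   (-4, 3, 10, 17).
#' @param v_base Vernalizing days at which vernalization starts to count
#'   (0 days).
#' @param p_opt Photoperiod at which development is unconstrained (20 h).
#' @param tt_sow_em Sowing-to-emergence duration, modified degree days (148).
#' @param tt_emhe_default Emergence-to-heading duration used when TT_emhe is
#'   not a free genotype parameter (500 modified degree days).
#' @param sun_angle Sun depression angle for photoperiod, degrees (6).
#' @return A `model_constants` list.
#' @export
model_constants <- function(t_base = 1, t_opt = 26, t_card_max = 37,
                            v_t1 = -4, v_t2 = 3, v_t3 = 10, v_t4 = 17,
                            v_base = 0, p_opt = 20,
                            tt_sow_em = 148, tt_emhe_default = 500,
                            sun_angle = 6) {
  if (!(t_base < t_opt && t_opt < t_card_max))
    stop("cardinal temperatures must satisfy t_base < t_opt < t_card_max")
  if (!(v_t1 <= v_t2 && v_t2 <= v_t3 && v_t3 <= v_t4))
    stop("vernalizing temperatures must satisfy v_t1 <= v_t2 <= v_t3 <= v_t4")
  if (tt_sow_em <= 0) stop("tt_sow_em must be positive")
  structure(list(t_base = t_base, t_opt = t_opt, t_card_max = t_card_max,
                 v_t1 = v_t1, v_t2 = v_t2, v_t3 = v_t3, v_t4 = v_t4,
                 v_base = v_base, p_opt = p_opt, tt_sow_em = tt_sow_em,
                 tt_emhe_default = tt_emhe_default, sun_angle = sun_angle),
            class = "model_constants")
}

#' Genotype parameters of the heading-date model
#'
#' The genetic parameters: `v_sat` (vernalizing days needed for full
#' vernalization), `p_base` (base photoperiod below which development
#' stops), and `tt_emhe` (emergence-to-heading duration in modified degree
#' days, an earliness-per-se proxy).
#'
#' @param v_sat Vernalization requirement, days (>= 0).
#' @param p_base Base photoperiod, hours (>= 0, below `p_opt`).
#' @param tt_emhe Emergence-to-heading duration, modified degree days (> 0).
#' @return A `genotype_parameters` list.
#' @export
genotype_parameters <- function(v_sat, p_base, tt_emhe = 500) {
  if (v_sat < 0) stop("v_sat must be >= 0")
  if (p_base < 0) stop("p_base must be >= 0")
  if (tt_emhe <= 0) stop("tt_emhe must be > 0")
  structure(list(v_sat = v_sat, p_base = p_base, tt_emhe = tt_emhe),
            class = "genotype_parameters")
}

#' Daily mean temperature
#' @param tmin,tmax Daily minimum and maximum temperature, deg C.
#' @return `(tmin + tmax) / 2`.
#' @export
mean_temperature <- function(tmin, tmax) {
  if (any(tmin > tmax)) stop("tmin > tmax")
  (tmin + tmax) / 2
}

#' Thermal response factor FT
#'
#' Bilinear response of development rate to daily mean temperature: 0 at or
#' below `t_base` and at or above `t_card_max`, 1 at `t_opt`, linear in
#' between.
#'
#' @param tm Daily mean temperature, deg C. Vectorised.
#' @param k `model_constants`.
#' @return FT in \[0, 1\].
#' @export
thermal_factor <- function(tm, k = model_constants()) {
  ft <- ifelse(tm <= k$t_opt,
               (tm - k$t_base) / (k$t_opt - k$t_base),
               (k$t_card_max - tm) / (k$t_card_max - k$t_opt))
  pmin(1, pmax(0, ft))
}

#' Daily thermal time Tt = FT x t_opt
#' @inheritParams thermal_factor
#' @return Thermal time in deg C days, in \[0, t_opt\].
#' @export
daily_thermal_time <- function(tm, k = model_constants()) {
  thermal_factor(tm, k) * k$t_opt
}

#' Daily vernalization efficiency Veff
#'
#' Trapezoidal response to daily mean temperature: 0 outside
#' \[`v_t1`, `v_t4`\], 1 on the \[`v_t2`, `v_t3`\] plateau, linear flanks.
#' Summing Veff over days gives the accumulated vernalizing days VDD.
#'
#' @inheritParams thermal_factor
#' @return Veff in \[0, 1\].
#' @export
vernalization_efficiency <- function(tm, k = model_constants()) {
  v <- ifelse(tm < k$v_t2,
              (tm - k$v_t1) / (k$v_t2 - k$v_t1),
              ifelse(tm <= k$v_t3, 1,
                     (k$v_t4 - tm) / (k$v_t4 - k$v_t3)))
  v[tm < k$v_t1 | tm > k$v_t4] <- 0
  pmin(1, pmax(0, v))
}

#' Vernalization factor FV
#'
#' Linear progress of vernalization from `v_base` to `v_sat` accumulated
#' vernalizing days, clamped to \[0, 1\]. When `v_sat <= v_base` (fully
#' spring genotype) FV is 1 for any VDD: spring wheats with `v_sat` close to
#' zero reach full vernalization essentially immediately.
#'
#' @param vdd Accumulated vernalizing days (>= 0). Vectorised.
#' @param p `genotype_parameters` (uses `v_sat`).
#' @param k `model_constants` (uses `v_base`).
#' @return FV in \[0, 1\].
#' @export
vernalization_factor <- function(vdd, p, k = model_constants()) {
  if (p$v_sat <= k$v_base) return(rep(1, length(vdd)))
  pmin(1, pmax(0, (vdd - k$v_base) / (p$v_sat - k$v_base)))
}

#' Photoperiod factor FP
#'
#' Linear response of development rate to daily photoperiod between
#' `p_base` (FP = 0) and `p_opt` (FP = 1), clamped to \[0, 1\].
#'
#' @param ph Daily photoperiod, hours. Vectorised.
#' @param p `genotype_parameters` (uses `p_base`).
#' @param k `model_constants` (uses `p_opt`).
#' @return FP in \[0, 1\].
#' @export
photoperiod_factor <- function(ph, p, k = model_constants()) {
  if (p$p_base >= k$p_opt) stop("p_base must be below p_opt")
  pmin(1, pmax(0, (ph - p$p_base) / (k$p_opt - p$p_base)))
}

#' Simulate development from sowing to heading
#'
#' Day-step simulation. From the day after sowing, plain thermal time Tt
#' accumulates until it reaches `tt_sow_em` (emergence; vernalization and
#' photoperiod do not limit pre-emergence development). Vernalizing days VDD
#' accumulate from sowing. From the day after emergence, modified thermal
#' time PVTt = Tt x FV x FP accumulates until it reaches the genotype's
#' `tt_emhe` (heading), FV continuing to modify thermal time until heading.
#' A stage is assigned to the first day its accumulator meets or exceeds the
#' phase duration; the accumulator resets at emergence (surplus discarded).
#'
#' @param sowing_date Sowing date (`Date` or ISO string).
#' @param weather Daily weather data.frame (`date`, `tmin`, `tmax`) covering
#'   the sowing date onward, gap-free.
#' @param latitude Site latitude, degrees north.
#' @param p `genotype_parameters`.
#' @param k `model_constants`.
#' @return A `phenology_sim` list: `trace` (per-day data.frame with date,
#'   TM, FT, Tt, Veff, VDD, FV, Ph, FP, PVTt, phase), `emergence_date` and
#'   `heading_date` (`Date`, `NA` when the weather record ends before the
#'   stage is reached).
#' @export
simulate_heading <- function(sowing_date, weather, latitude, p,
                             k = model_constants()) {
  sowing_date <- as.Date(sowing_date)
  weather <- validate_weather(weather)
  if (!(sowing_date %in% weather$date))
    stop("weather record does not contain the sowing date")
  w <- weather[weather$date > sowing_date, , drop = FALSE]
  if (nrow(w) == 0L)
    return(structure(list(trace = NULL, emergence_date = as.Date(NA),
                          heading_date = as.Date(NA)),
                     class = "phenology_sim"))
  tm <- mean_temperature(w$tmin, w$tmax)
  tt <- daily_thermal_time(tm, k)
  veff <- vernalization_efficiency(tm, k)
  vdd <- cumsum(veff)
  fv <- vernalization_factor(vdd, p, k)
  ph <- photoperiod(day_of_year(w$date), latitude, k$sun_angle)
  fp <- photoperiod_factor(ph, p, k)
  pvtt <- tt * fv * fp

  cum1 <- cumsum(tt)
  iem <- match(TRUE, cum1 >= k$tt_sow_em)
  emergence <- if (is.na(iem)) as.Date(NA) else w$date[iem]
  heading <- as.Date(NA)
  ihe <- NA_integer_
  if (!is.na(iem) && iem < nrow(w)) {
    after <- seq.int(iem + 1L, nrow(w))
    cum2 <- cumsum(pvtt[after])
    j <- match(TRUE, cum2 >= p$tt_emhe)
    if (!is.na(j)) {
      ihe <- after[j]
      heading <- w$date[ihe]
    }
  }
  phase <- rep("done", nrow(w))
  if (is.na(iem)) phase[] <- "sow_em"
  else {
    phase[seq_len(iem)] <- "sow_em"
    if (is.na(ihe)) {
      if (iem < nrow(w)) phase[seq.int(iem + 1L, nrow(w))] <- "em_he"
    } else {
      phase[seq.int(iem + 1L, ihe)] <- "em_he"
    }
  }
  trace <- data.frame(date = w$date, TM = tm, FT = thermal_factor(tm, k),
                      Tt = tt, Veff = veff, VDD = vdd, FV = fv, Ph = ph,
                      FP = fp, PVTt = pvtt, phase = phase,
                      stringsAsFactors = FALSE)
  structure(list(trace = trace, emergence_date = emergence,
                 heading_date = heading),
            class = "phenology_sim")
}

#' @export
print.phenology_sim <- function(x, ...) {
  fmt <- function(d) if (is.na(d)) "not reached" else as.character(d)
  cat("phenology simulation\n",
      "  emergence: ", fmt(x$emergence_date), "\n",
      "  heading:   ", fmt(x$heading_date), "\n", sep = "")
  invisible(x)
}
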