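# Shared fixtures, built in code. Heavyweight synthetic studies are
# memoized so several test files can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

const_weather <- function(start, end, tmin, tmax) {
  d <- seq(as.Date(start), as.Date(end), by = "day")
  data.frame(date = d, tmin = tmin, tmax = tmax)
}

# Constant 26 degC under polar day (lat 68, May-Aug): FT = 1, FP = 1 for
# any p_base, Veff = 0 (TM above the vernalizing range). An analytically
# transparent environment for phase arithmetic.
polar_summer <- function() const_weather("2020-05-01", "2020-08-31", 26, 26)

cached_study <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# default synthetic study, noiseless
study0 <- function() cached_study("study0", function()
  gen_study(synth_config(seed = 7, noise_sd_days = 0)))

# default synthetic study with observation noise
study_noisy <- function() cached_study("study_noisy", function()
  gen_study(synth_config(seed = 7)))

# 2 autumn + 1 spring experiment subset, plus cached full-grid predictions
study0_grid <- function() cached_study("study0_grid", function() {
  st <- study0()
  ex <- st$experiments[st$experiments$id %in% c("aut1", "aut2", "spr1"), ]
  grid <- build_grid(grid_spec("2p"))
  list(st = st, ex = ex, grid = grid,
       pred = predict_grid_all(ex, st$weather, grid))
})

# Independent day-length oracle: minute-stepped solar altitude with the
# Spencer (1971) Fourier-series declination -- a different formula and a
# different integration path than the implementation.
oracle_daylength <- function(doy, lat, angle) {
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)   # radians
  phi <- lat * pi / 180
  minutes <- seq(0, 1439.5, by = 0.5)
  ha <- (minutes / 4 - 180) * pi / 180             # hour angle, radians
  alt <- asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha))
  sum(alt > -angle * pi / 180) * 0.5 / 60
}
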