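k0 <- model_constants()

test_that("daily mean temperature is the midpoint", {
  expect_equal(mean_temperature(0, 10), 5)
  expect_equal(mean_temperature(-5, 5), 0)
  expect_equal(mean_temperature(12.3, 19.7), 16.0)
  expect_error(mean_temperature(5, 0), "tmin > tmax")
})

test_that("thermal response is bilinear with the cardinal temperatures", {
  expect_equal(thermal_factor(26, k0), 1)     # optimum
  expect_equal(thermal_factor(1, k0), 0)      # base
  expect_equal(thermal_factor(37, k0), 0)     # cardinal maximum
  expect_equal(thermal_factor(13.5, k0), 0.5) # (13.5-1)/(26-1)
  expect_equal(thermal_factor(31.5, k0), 0.5) # (37-31.5)/(37-26)
  tm <- seq(-10, 45, by = 0.5)
  expect_true(all(thermal_factor(tm, k0) >= 0 &
                    thermal_factor(tm, k0) <= 1))
})

test_that("daily thermal time is FT x t_opt", {
  expect_equal(daily_thermal_time(26, k0), 26)
  expect_equal(daily_thermal_time(0, k0), 0)
  expect_equal(daily_thermal_time(13.5, k0), 13.0)
})

test_that("vernalization efficiency is trapezoidal", {
  expect_equal(vernalization_efficiency(5, k0), 1)     # plateau
  expect_equal(vernalization_efficiency(17.1, k0), 0)  # beyond T4
  expect_equal(vernalization_efficiency(-4.1, k0), 0)  # below T1
  expect_equal(vernalization_efficiency(-0.5, k0), 0.5) # (-0.5+4)/7
  expect_equal(vernalization_efficiency(13.5, k0), 0.5) # (17-13.5)/7
  expect_equal(vernalization_efficiency(c(-4, 3, 10, 17), k0),
               c(0, 1, 1, 0))
})

test_that("vernalization factor saturates at v_sat and handles v_sat = 0", {
  p <- genotype_parameters(v_sat = 40, p_base = 2)
  expect_equal(vernalization_factor(40, p, k0), 1)
  expect_equal(vernalization_factor(0, p, k0), 0)
  expect_equal(vernalization_factor(20, p, k0), 0.5)
  expect_equal(vernalization_factor(100, p, k0), 1)  # clamped
  p0 <- genotype_parameters(v_sat = 0, p_base = 2)
  expect_equal(vernalization_factor(c(0, 5, 200), p0, k0), c(1, 1, 1))
})

test_that("photoperiod factor is linear between p_base and p_opt", {
  p <- genotype_parameters(v_sat = 0, p_base = 8)
  expect_equal(photoperiod_factor(20, p, k0), 1)   # p_opt
  expect_equal(photoperiod_factor(8, p, k0), 0)    # p_base
  expect_equal(photoperiod_factor(14, p, k0), 0.5) # (14-8)/(20-8)
  expect_equal(photoperiod_factor(23, p, k0), 1)   # clamped above p_opt
  expect_error(photoperiod_factor(12, genotype_parameters(0, 25), k0),
               "p_base")
})

test_that("phase arithmetic under constant optimum temperature", {
  # polar day, constant TM = 26: Tt = 26/day, FP = 1, and v_sat = 0 gives
  # FV = 1. Emergence needs ceiling(148/26) = 6 days, heading a further
  # ceiling(500/26) = 20 days.
  s <- simulate_heading("2020-05-10", polar_summer(), 68,
                        genotype_parameters(0, 0, 500))
  expect_equal(as.numeric(s$emergence_date - as.Date("2020-05-10")), 6)
  expect_equal(as.numeric(s$heading_date - s$emergence_date), 20)
  # plain thermal-time bracketing across the emergence-to-heading phase
  tr <- s$trace
  emhe <- tr$phase == "em_he"
  expect_lt(sum(tr$Tt[emhe]) - tr$Tt[which(emhe)[sum(emhe)]], 500)
  expect_gte(sum(tr$Tt[emhe]), 500)
})

test_that("unsatisfiable vernalization leaves heading not reached", {
  # TM = 26 accumulates no vernalizing days, so any v_sat > 0 pins FV at 0
  s <- simulate_heading("2020-05-10", polar_summer(), 68,
                        genotype_parameters(130, 0, 500))
  expect_true(is.na(s$heading_date))
  expect_false(is.na(s$emergence_date))
})

test_that("trace invariants hold on realistic weather", {
  w <- gen_weather(48.7, "2001-09-01", "2002-08-31", seed = 3)
  s <- simulate_heading("2001-10-20", w, 48.7,
                        genotype_parameters(30, 2, 500))
  tr <- s$trace
  for (col in c("FT", "Veff", "FV", "FP"))
    expect_true(all(tr[[col]] >= 0 & tr[[col]] <= 1), label = col)
  expect_true(all(tr$Tt >= 0 & tr$Tt <= k0$t_opt))
  expect_true(all(tr$PVTt <= tr$Tt + 1e-12))
  expect_true(all(diff(tr$VDD) >= 0))
  expect_lte(s$emergence_date, s$heading_date)
  # deterministic
  s2 <- simulate_heading("2001-10-20", w, 48.7,
                         genotype_parameters(30, 2, 500))
  expect_identical(s, s2)
})

test_that("heading date is monotone in v_sat, p_base and tt_emhe", {
  for (seed in 1:3) {
    w <- gen_weather(47 + seed, "2001-09-01", "2002-09-15", seed = seed)
    hd <- function(v, pb, te)
      simulate_heading("2001-10-25", w, 47 + seed,
                       genotype_parameters(v, pb, te))$heading_date
    h_v <- c(hd(0, 2, 500), hd(25, 2, 500), hd(60, 2, 500))
    h_p <- c(hd(20, 0, 500), hd(20, 5, 500), hd(20, 9, 500))
    h_t <- c(hd(20, 2, 400), hd(20, 2, 600), hd(20, 2, 800))
    for (h in list(h_v, h_p, h_t)) {
      h <- h[!is.na(h)]
      if (length(h) > 1) expect_true(all(diff(as.numeric(h)) >= 0))
    }
  }
})

test_that("sowing date must be covered by the weather record", {
  expect_error(simulate_heading("2019-01-01", polar_summer(), 68,
                                genotype_parameters(0, 0)),
               "sowing date")
})

test_that("constructors enforce parameter invariants", {
  expect_error(genotype_parameters(-1, 0), "v_sat")
  expect_error(genotype_parameters(0, -1), "p_base")
  expect_error(genotype_parameters(0, 0, 0), "tt_emhe")
  expect_error(model_constants(t_base = 30), "cardinal")
  expect_error(model_constants(v_t2 = -10), "vernalizing")
})
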