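test_that("the parameter grid has the exact published cardinalities", {
  expect_identical(nrow(build_grid(grid_spec("2p"))), 13231L)
  expect_identical(nrow(build_grid(grid_spec("3p"))), 542471L)
  one <- grid_spec("2p", v_sat_range = c(10, 10), p_base_range = c(2, 2))
  expect_identical(nrow(build_grid(one)), 1L)
})

test_that("the grid is an exact Cartesian product in deterministic order", {
  g <- build_grid(grid_spec("2p"))
  # v_sat outermost, p_base inner; 2p carries the default TT_emhe
  expect_equal(g$v_sat[1:202], rep(c(0, 1), each = 101))
  expect_equal(g$p_base[1:3], c(0, 0.1, 0.2))
  expect_true(all(g$tt_emhe == 500))
  expect_equal(nrow(unique(g)), nrow(g))
  g3 <- build_grid(grid_spec("3p",
                             v_sat_range = c(0, 1), p_base_range = c(0, 0.1),
                             tt_emhe_range = c(400, 410)))
  expect_equal(g3$tt_emhe[1:2], c(400, 410))  # tt_emhe innermost
  expect_equal(nrow(g3), 8L)
})

test_that("rmsep matches hand arithmetic on calendar dates", {
  d <- function(doy) as.Date(doy - 1, origin = "2020-01-01")
  expect_equal(rmsep(d(c(100, 110)), d(c(100, 110))), 0)
  expect_equal(rmsep(d(c(100, 110)), d(c(103, 106))), sqrt((9 + 16) / 2))
  expect_equal(rmsep(d(150), d(157)), 7)
  expect_error(rmsep(as.Date(character()), as.Date(character())), "n = 0")
  expect_error(rmsep(d(100), as.Date(NA)), "penalty")
  # not-reached scored as the penalty date
  expect_equal(rmsep(d(100), as.Date(NA), nr_penalty = d(110)), 10)
})

test_that("grid calibration equals naive per-vector re-simulation", {
  st <- study0()
  ex <- st$experiments[st$experiments$id %in% c("aut1", "spr1"), ]
  spec <- grid_spec("2p", v_sat_range = c(0, 40), v_sat_step = 10,
                    p_base_range = c(0, 4), p_base_step = 1)
  grid <- build_grid(spec)
  g <- st$panel$truth$genotype_id[!st$panel$truth$winter][1]
  obs <- st$phenotypes[st$phenotypes$genotype_id == g &
                         st$phenotypes$experiment_id %in% ex$id, ]
  # naive oracle: one full simulation per vector per experiment
  r_naive <- vapply(seq_len(nrow(grid)), function(v) {
    p <- genotype_parameters(grid$v_sat[v], grid$p_base[v],
                             grid$tt_emhe[v])
    prd <- vapply(obs$experiment_id, function(e) {
      i <- match(e, ex$id)
      h <- as.numeric(simulate_heading(ex$sowing_date[i],
                                       st$weather[[e]], ex$latitude[i],
                                       p)$heading_date)
      # per-experiment penalty: day after the record ends
      if (is.na(h)) max(as.numeric(st$weather[[e]]$date)) + 1 else h
    }, numeric(1))
    rmsep(obs$heading_date, as.Date(prd, origin = "1970-01-01"))
  }, numeric(1))
  res <- optimize_genotype(g, st$phenotypes, ex, st$weather, spec)
  expect_identical(res$min_rmsep, min(r_naive))
  naive_win <- grid[r_naive <= min(r_naive) + 1e-9, , drop = FALSE]
  rownames(naive_win) <- NULL
  expect_identical(res$minimizing_vectors[, c("v_sat", "p_base")],
                   naive_win[, c("v_sat", "p_base")])
})

test_that("naive NR penalty differs per experiment in the oracle", {
  # the penalty in optimize_genotype is per experiment (last weather day
  # + 1); check one NR-heavy genotype against a per-experiment oracle
  st <- study0()
  ex <- st$experiments[st$experiments$id == "spr1", ]
  spec <- grid_spec("2p", v_sat_range = c(100, 130), v_sat_step = 15,
                    p_base_range = c(0, 2), p_base_step = 1)
  grid <- build_grid(spec)
  g <- st$panel$truth$genotype_id[!st$panel$truth$winter][2]
  obs <- st$phenotypes[st$phenotypes$genotype_id == g &
                         st$phenotypes$experiment_id == "spr1", ]
  pen <- as.Date(max(as.numeric(st$weather[["spr1"]]$date)) + 1,
                 origin = "1970-01-01")
  r_naive <- vapply(seq_len(nrow(grid)), function(v) {
    p <- genotype_parameters(grid$v_sat[v], grid$p_base[v])
    prd <- simulate_heading(ex$sowing_date, st$weather[["spr1"]],
                            ex$latitude, p)$heading_date
    rmsep(obs$heading_date, prd, nr_penalty = pen)
  }, numeric(1))
  res <- optimize_genotype(g, st$phenotypes, ex, st$weather, spec)
  expect_identical(res$min_rmsep, min(r_naive))
})

test_that("noiseless forward-simulated genotypes are recovered in-set", {
  sg <- study0_grid()
  tr <- sg$st$panel$truth
  spring <- tr[!tr$winter, ][1:10, ]
  for (r in seq_len(nrow(spring))) {
    res <- optimize_genotype(spring$genotype_id[r], sg$st$phenotypes,
                             sg$ex, sg$st$weather, grid_spec("2p"),
                             predictions = sg$pred)
    expect_identical(res$min_rmsep, 0)
    expect_true(any(res$minimizing_vectors$v_sat == spring$v_sat[r] &
                      abs(res$minimizing_vectors$p_base -
                            spring$p_base[r]) < 1e-9))
  }
})

test_that("a single autumn sowing leaves v_sat unidentified", {
  sg <- study0_grid()
  tr <- sg$st$panel$truth
  g <- tr$genotype_id[!tr$winter][1]
  ex1 <- sg$ex[sg$ex$id == "aut1", ]
  res <- optimize_genotype(g, sg$st$phenotypes, ex1, sg$st$weather,
                           grid_spec("2p"), predictions = sg$pred)
  expect_gt(nrow(res$minimizing_vectors), 1)
  expect_gt(length(unique(res$minimizing_vectors$v_sat)), 1)
})

test_that("genotypes without usable observations are rejected", {
  sg <- study0_grid()
  tr <- sg$st$panel$truth
  wint <- tr$genotype_id[tr$winter][1]
  spr_only <- sg$ex[sg$ex$season_class == "spring", ]
  expect_error(optimize_genotype(wint, sg$st$phenotypes, spr_only,
                                 sg$st$weather, grid_spec("2p")),
               "no usable")
})

test_that("minimal total squared error is monotone in the experiment set", {
  # removing an experiment never increases the minimal SUM of squared
  # errors (the mean-based RMSEP is not monotone)
  sg <- study0_grid()
  stn <- study_noisy()
  predn <- cached_study("noisy_grid3", function()
    predict_grid_all(sg$ex, stn$weather, sg$grid))
  tr <- stn$panel$truth
  for (g in tr$genotype_id[!tr$winter][1:5]) {
    res3 <- optimize_genotype(g, stn$phenotypes, sg$ex, stn$weather,
                              grid_spec("2p"), predictions = predn)
    sse3 <- res3$min_rmsep^2 * res3$n_experiments_used
    for (drop in sg$ex$id) {
      ex2 <- sg$ex[sg$ex$id != drop, ]
      res2 <- optimize_genotype(g, stn$phenotypes, ex2, stn$weather,
                                grid_spec("2p"), predictions = predn)
      sse2 <- res2$min_rmsep^2 * res2$n_experiments_used
      expect_lte(sse2, sse3 + 1e-9)
    }
  }
})

test_that("winter filter applies the strict 'earlier than' boundary", {
  # polar-summer spring experiment: v_sat = 0 vectors head exactly 26
  # days after sowing; v_sat > 0 vectors never head (no vernalizing days
  # at TM = 26)
  sow <- as.Date("2020-05-10")
  ex <- data.frame(id = "sprX", site = "polar", sowing_date = sow,
                   season_class = "spring", latitude = 68,
                   stringsAsFactors = FALSE)
  weather <- list(sprX = polar_summer())
  phen <- data.frame(genotype_id = "other", experiment_id = "sprX",
                     heading_date = sow + 26, headed = TRUE,
                     stringsAsFactors = FALSE)
  vecs <- data.frame(v_sat = c(0, 50), p_base = c(0, 0),
                     tt_emhe = c(500, 500))
  res <- structure(list(genotype_id = "wg", minimizing_vectors = vecs,
                        min_rmsep = 0, selected = NULL,
                        n_experiments_used = 1, spec = grid_spec("2p"),
                        filtered = FALSE),
                   class = "calibration_result")
  # margin 0: prediction equals the latest observed heading -> retained
  f0 <- filter_winter_vectors(res, ex, weather, phen, margin_days = 0)
  expect_equal(nrow(f0$minimizing_vectors), 2)
  # margin 10: the day-26 prediction is now too early -> removed;
  # the never-heading vector always passes
  f10 <- filter_winter_vectors(res, ex, weather, phen, margin_days = 10)
  expect_equal(f10$minimizing_vectors$v_sat, 50)
  expect_true(f10$filtered)
  # all vectors removed -> unfilterable
  res$minimizing_vectors <- vecs[1, , drop = FALSE]
  expect_error(filter_winter_vectors(res, ex, weather, phen,
                                     margin_days = 10),
               "removed by the winter filter")
})

test_that("representative selection is the median-closest member", {
  spec <- grid_spec("2p")
  v1 <- data.frame(v_sat = 42, p_base = 3.1, tt_emhe = 500)
  expect_equal(select_representative(v1, spec)$v_sat, 42)
  v3 <- data.frame(v_sat = c(10, 20, 30), p_base = 2, tt_emhe = 500)
  expect_equal(select_representative(v3, spec)$v_sat, 20)
  # equidistant from the median: deterministic tie-break to lowest v_sat
  v2 <- data.frame(v_sat = c(10, 30), p_base = 2, tt_emhe = 500)
  expect_equal(select_representative(v2, spec)$v_sat, 10)
})

test_that("robustness resampling is seeded and matches subset enumeration", {
  # G003 in the noiseless default study is identifiable under every
  # admissible subset (2 of 3 autumn x 1 of 2 spring experiments; all six
  # were enumerated with the optimizer), so its resampled SDs are zero
  st <- study0()
  r1 <- resample_robustness("G003", st$phenotypes, st$experiments,
                            st$weather, n_repeats = 4, seed = 11)
  r2 <- resample_robustness("G003", st$phenotypes, st$experiments,
                            st$weather, n_repeats = 4, seed = 11)
  expect_identical(r1, r2)
  expect_identical(r1$sd_v_sat, 0)
  expect_identical(r1$sd_p_base, 0)
  tr <- st$panel$truth
  expect_equal(r1$repeats$v_sat[1], tr$v_sat[tr$genotype_id == "G003"])
  # needs two experiments in some season class
  ph1 <- st$phenotypes[st$phenotypes$experiment_id == "aut1", ]
  expect_error(resample_robustness("G003", ph1, st$experiments,
                                   st$weather),
               ">= 2 experiments")
})

test_that("panel calibration classifies winter genotypes and filters them", {
  st <- study0()
  tr <- st$panel$truth
  sub <- c(tr$genotype_id[tr$winter][1:2], tr$genotype_id[!tr$winter][1:4])
  ph <- st$phenotypes[st$phenotypes$genotype_id %in% sub, ]
  calib <- suppressWarnings(
    calibrate_panel(ph, st$experiments, st$weather, grid_spec("2p")))
  expect_equal(sort(calib$genotype_id), sort(sub))
  i <- match(calib$genotype_id, tr$genotype_id)
  expect_equal(calib$winter, tr$winter[i])
  # spring genotypes recovered exactly at zero noise with the full design
  spring_rows <- !calib$winter
  expect_true(all(calib$min_rmsep[spring_rows] == 0))
  # winter genotypes keep a high vernalization requirement after filtering
  expect_true(all(calib$v_sat[calib$winter] >
                    max(tr$v_sat[i][!tr$winter[i]])))
})
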