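# small synthetic association panel with known structure
assoc_panel <- function(n = 60, n_markers = 40, seed = 19) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  grp <- sample.int(4, n, replace = TRUE)
  gm <- matrix(stats::rgamma(4 * n, 0.5), n, 4)
  gm[cbind(seq_len(n), grp)] <- stats::rgamma(n, 6)
  gm <- gm / rowSums(gm)
  calls <- matrix(sample(c("11", "22"), n * n_markers, replace = TRUE),
                  n, n_markers,
                  dimnames = list(ids, sprintf("m%03d", seq_len(n_markers))))
  structure_df <- data.frame(genotype_id = ids, g1 = gm[, 1], g2 = gm[, 2],
                             g3 = gm[, 3], g4 = gm[, 4],
                             stringsAsFactors = FALSE)
  list(g = genotype_matrix(calls), s = structure_df, grp = grp, ids = ids)
}

test_that("null raw p-values are uniform under the structure model", {
  p <- assoc_panel(n = 80, n_markers = 500, seed = 23)
  set.seed(1)
  y <- stats::setNames(6 * p$s$g1 - 4 * p$s$g2 + stats::rnorm(80, 0, 2),
                       p$ids)
  a <- associate(y, p$g, p$s, B = 0)
  expect_true(all(is.na(a$adjusted_p)))       # B = 0: raw only
  ks <- stats::ks.test(a$raw_p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation-adjusted p-values are bounded and reproducible", {
  p <- assoc_panel()
  set.seed(2)
  y <- stats::setNames(stats::rnorm(60), p$ids)
  a1 <- associate(y, p$g, p$s, B = 99, seed = 7)
  a2 <- associate(y, p$g, p$s, B = 99, seed = 7)
  expect_identical(a1$adjusted_p, a2$adjusted_p)
  expect_true(all(a1$adjusted_p >= 1 / 100 & a1$adjusted_p <= 1))
  expect_identical(attr(a1, "perm_scheme"), "trait_shuffle")
  a3 <- associate(y, p$g, p$s, B = 99, seed = 8)
  expect_false(identical(a1$adjusted_p, a3$adjusted_p))
})

test_that("a planted additive effect attains the smallest adjusted p", {
  p <- assoc_panel(seed = 29)
  set.seed(3)
  carrier <- unclass(p$g)[, "m001"] == "22"
  y <- stats::setNames(10 * carrier + stats::rnorm(60, 0, 1), p$ids)
  a <- associate(y, p$g, p$s, B = 199, seed = 7)
  expect_equal(a$marker[which.min(a$adjusted_p)], "m001")
  expect_gt(a$r2[a$marker == "m001"], 0.5)
})

test_that("monomorphic markers are skipped with a notice", {
  p <- assoc_panel(n_markers = 3)
  m <- unclass(p$g)
  m[, 2] <- "11"
  g <- genotype_matrix(m)
  set.seed(4)
  y <- stats::setNames(stats::rnorm(60), p$ids)
  expect_message(a <- associate(y, g, p$s, B = 0), "monomorphic")
  expect_equal(nrow(a), 2)
})

test_that("LD blocks group collinear markers with the right representative", {
  p <- assoc_panel(n = 200, n_markers = 12, seed = 31)
  m <- unclass(p$g)
  m[, "m002"] <- m[, "m001"]                   # exact duplicate
  flip <- sample(200, 6)
  m[, "m003"] <- m[, "m001"]
  m[flip, "m003"] <- ifelse(m[flip, "m003"] == "11", "22", "11")
  g <- genotype_matrix(m, n_missing_raw = stats::setNames(
    c(3L, 0L, 5L, rep(0L, 9)), colnames(m)))
  lb <- ld_blocks(g, 0.8)
  triple <- lb$blocks[[which(vapply(lb$blocks, length, 1L) == 3)]]
  expect_setequal(triple, c("m001", "m002", "m003"))
  # the member with the fewest pre-imputation missing calls represents it
  expect_true("m002" %in% lb$representatives)
  # everything else is a singleton
  expect_equal(sort(vapply(lb$blocks, length, 1L)),
               c(rep(1L, 9), 3L))
})

test_that("backward elimination keeps the planted marker, drops noise", {
  p <- assoc_panel(n = 80, n_markers = 6, seed = 37)
  set.seed(5)
  carrier <- unclass(p$g)[, "m004"] == "22"
  y <- stats::setNames(8 * carrier + stats::rnorm(80, 0, 1), p$ids)
  mod <- backward_eliminate(y, colnames(p$g), p$g, alpha = 0.05,
                            trait = "v_sat")
  kept <- vapply(mod$terms, `[[`, "", "marker")
  expect_true("m004" %in% kept)
  expect_equal(mod$terms[[match("m004", kept)]]$effects[["22"]], 8,
               tolerance = 0.15)
  # alpha = 1 keeps every candidate
  mod_all <- backward_eliminate(y, colnames(p$g), p$g, alpha = 1)
  expect_equal(length(mod_all$terms), 6)
  # a single useless candidate gives an intercept-only model
  set.seed(6)
  y0 <- stats::setNames(stats::rnorm(80), p$ids)
  mod0 <- backward_eliminate(y0, "m001", p$g, alpha = 1e-6)
  expect_equal(length(mod0$terms), 0)
  expect_equal(mod0$intercept, mean(y0))
})

test_that("rank deficiency is reported with the offending count", {
  p <- assoc_panel(n = 10, n_markers = 15, seed = 41)
  set.seed(7)
  y <- stats::setNames(stats::rnorm(10), p$ids)
  expect_error(backward_eliminate(y, colnames(p$g), p$g),
               "rank deficiency: 16 coefficients for 10 genotypes")
})

test_that("fitted marker models have mean-zero residuals on fitting data", {
  p <- assoc_panel(n = 80, n_markers = 6, seed = 37)
  set.seed(8)
  carrier <- unclass(p$g)[, "m004"] == "22"
  y <- stats::setNames(8 * carrier + stats::rnorm(80, 0, 1), p$ids)
  mod <- backward_eliminate(y, colnames(p$g), p$g, alpha = 1)
  pred <- predict_parameter_all(mod, p$g)$values
  expect_equal(mean(y - pred[p$ids]), 0, tolerance = 1e-10)
})

test_that("major-gene models restrict the candidate set", {
  p <- assoc_panel(n = 80, n_markers = 6, seed = 37)
  set.seed(9)
  carrier <- unclass(p$g)[, "m004"] == "22"
  y <- stats::setNames(8 * carrier + stats::rnorm(80, 0, 1), p$ids)
  mg <- major_gene_model(y, p$g, "m004")
  expect_equal(vapply(mg$terms, `[[`, "", "marker"), "m004")
  # empty gene list: intercept only
  m0 <- major_gene_model(y, p$g, character())
  expect_equal(length(m0$terms), 0)
  # full candidate list: identical to plain backward elimination
  expect_equal(major_gene_model(y, p$g, colnames(p$g)),
               backward_eliminate(y, colnames(p$g), p$g))
})
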