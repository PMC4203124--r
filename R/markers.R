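#' Mask rare allele classes as missing
#'
#' For each marker, allele classes with frequency below `min_freq` among
#' the non-missing calls are set to missing, so that rare classes do not
#' enter association models as poorly estimated levels.
#'
#' @param x A [genotype_matrix()].
#' @param min_freq Frequency threshold (0.05); classes strictly below it
#'   are masked. `min_freq = 0` is the identity.
#' @return The masked `genotype_matrix` (metadata unchanged;
#'   `n_missing_raw` stays frozen at its pre-masking value).
#' @export
mask_rare <- function(x, min_freq = 0.05) {
  info <- marker_info(x)
  m <- unclass(x)
  attr(m, "marker_info") <- NULL
  for (j in seq_len(ncol(m))) {
    calls <- m[, j]
    tab <- table(calls[!is.na(calls)])
    if (!length(tab)) next
    rare <- names(tab)[tab / sum(tab) < min_freq]
    if (length(rare)) m[m[, j] %in% rare, j] <- NA_character_
  }
  genotype_matrix(m, chromosome = info$chromosome,
                  n_missing_raw = info$n_missing_raw)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.marker_mode <- function(calls) {
  tab <- table(calls[!is.na(calls)])
  names(tab)[which.max(tab)]  # ties: first in sorted class order
}

#' Iterative random-forest genotype imputation
#'
#' Fills missing calls by iterative random-forest classification: each
#' marker with missing data is regressed (as a categorical response) on all
#' other markers, missing entries are replaced by the forest predictions,
#' and the cycle repeats until the proportion of imputed entries that
#' change between iterations stops decreasing or `max_iter` is reached
#' (the previous iteration's values are kept when the criterion first
#' increases). The out-of-bag misclassification rate of each marker's
#' forest estimates its proportion of falsely classified entries (PFC).
#'
#' @param x A [genotype_matrix()].
#' @param seed RNG seed for the forests.
#' @param n_trees Trees per forest (100).
#' @param max_iter Iteration cap (10).
#' @return List: `matrix` (the imputed `genotype_matrix`, no missing cells)
#'   and `report` (data.frame `marker, pfc, n_imputed`; one row per marker
#'   that had missing calls, empty when there was nothing to impute), plus
#'   `iterations` and `converged` attributes on the report.
#' @export
impute_genotypes <- function(x, seed = 1, n_trees = 100, max_iter = 10) {
  info <- marker_info(x)
  m <- unclass(x)
  attr(m, "marker_info") <- NULL
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing))
    stop(sprintf("marker(s) missing in all genotypes, unimputable: %s",
                 paste(colnames(m)[all_missing], collapse = ", ")))
  miss <- is.na(m)
  targets <- which(colSums(miss) > 0L)
  report <- data.frame(marker = character(), pfc = numeric(),
                       n_imputed = integer(), stringsAsFactors = FALSE)
  if (length(targets) == 0L) {
    attr(report, "iterations") <- 0L
    attr(report, "converged") <- TRUE
    return(list(matrix = x, report = report))
  }
  if (ncol(m) < 2L) stop("imputation needs >= 2 markers")
  # initialize missing cells with the per-marker modal class
  for (j in targets) m[miss[, j], j] <- .marker_mode(x[, j])
  targets <- targets[order(colSums(miss)[targets])]
  pfc <- stats::setNames(rep(NA_real_, length(targets)),
                         colnames(m)[targets])
  .with_seed(seed, {
    prev_diff <- Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      m_prev <- m
      pfc_prev <- pfc
      for (j in targets) {
        y_obs <- factor(m[!miss[, j], j])
        pred_df <- as.data.frame(m[, -j, drop = FALSE],
                                 stringsAsFactors = TRUE)
        if (nlevels(y_obs) < 2L) {
          m[miss[, j], j] <- as.character(levels(y_obs))
          pfc[colnames(m)[j]] <- 0
          next
        }
        fit <- randomForest::randomForest(
          x = pred_df[!miss[, j], , drop = FALSE], y = y_obs,
          ntree = n_trees)
        pfc[colnames(m)[j]] <- unname(fit$err.rate[n_trees, "OOB"])
        m[miss[, j], j] <-
          as.character(stats::predict(fit,
                                      pred_df[miss[, j], , drop = FALSE]))
      }
      diff <- sum(m[miss] != m_prev[miss]) / sum(miss)
      if (diff > prev_diff) {      # criterion rose: keep previous fill
        m <- m_prev
        pfc <- pfc_prev
        converged <- TRUE
        break
      }
      if (diff == 0) { converged <- TRUE; break }
      prev_diff <- diff
    }
    report <- data.frame(marker = names(pfc), pfc = unname(pfc),
                          n_imputed = colSums(miss)[names(pfc)],
                          stringsAsFactors = FALSE)
    attr(report, "iterations") <- iter
    attr(report, "converged") <- converged
  })
  rownames(report) <- NULL
  out <- genotype_matrix(m, chromosome = info$chromosome,
                         n_missing_raw = info$n_missing_raw)
  list(matrix = out, report = report)
}

#' Discard markers with unreliable imputation
#'
#' Markers whose imputation PFC (out-of-bag proportion of falsely
#' classified entries) exceeds `max_pfc` are removed; the comparison is
#' strictly greater, so a marker at exactly `max_pfc` is retained.
#'
#' @param x A [genotype_matrix()].
#' @param report Imputation report from [impute_genotypes()].
#' @param max_pfc PFC threshold (0.2).
#' @return The filtered `genotype_matrix` (survivors keep their original
#'   metadata). An empty report is the identity.
#' @export
pfc_filter <- function(x, report, max_pfc = 0.2) {
  if (nrow(report) == 0L) return(x)
  drop <- report$marker[report$pfc > max_pfc]
  if (!length(drop)) return(x)
  keep <- setdiff(colnames(x), drop)
  info <- marker_info(x)
  genotype_matrix(unclass(x)[, keep, drop = FALSE],
                  chromosome = stats::setNames(info$chromosome, info$marker)[keep],
                  n_missing_raw = stats::setNames(info$n_missing_raw,
                                                  info$marker)[keep])
}
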