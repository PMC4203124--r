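#' Structure-corrected marker-trait association scan
#'
#' For each marker, fits an ordinary least-squares model of the trait on
#' the marker's allele class (categorical) plus the ancestral-group
#' contributions, `y = m_k + g1 + g2 + g3 + g4 + e`. The four group
#' contributions sum to 1, so the fitted design uses an intercept plus
#' three of the four columns (equivalent fit, avoids singularity). The raw
#' p-value is the marker term's partial F-test over the structure-only
#' model; the adjusted p-value is a permutation p-value,
#' `(1 + #\{permutations with p_perm <= p_obs\}) / (B + 1)`, obtained by
#' permuting trait values across genotypes with the covariates fixed
#' (`perm_scheme = "trait_shuffle"`; the same `B` permutations are applied
#' to every marker). The marker r2 is the marker term's incremental sum of
#' squares as a fraction of the total trait sum of squares.
#'
#' @param trait_values Named numeric vector of trait values (names =
#'   genotype ids), e.g. optimized V_sat per genotype.
#' @param x A [genotype_matrix()] (typically masked and imputed).
#' @param structure Structure data.frame (`genotype_id, g1..g4`).
#' @param B Number of permutations (1000). `B = 0` skips the adjustment
#'   (adjusted p reported as `NA`).
#' @param seed RNG seed for the permutations.
#' @param trait Label recorded in the output (e.g. `"v_sat"`).
#' @return data.frame `marker, trait, raw_p, adjusted_p, r2, n` with
#'   attribute `perm_scheme`. Markers monomorphic after masking are skipped
#'   with a message.
#' @export
associate <- function(trait_values, x, structure, B = 1000, seed = 1,
                      trait = "trait") {
  ids <- intersect(names(trait_values),
                   intersect(rownames(x), structure$genotype_id))
  if (length(ids) < 8L) stop("too few genotypes shared across inputs")
  y <- trait_values[ids]
  g <- structure[match(ids, structure$genotype_id), c("g1", "g2", "g3"),
                 drop = FALSE]
  m <- unclass(x)[ids, , drop = FALSE]
  z <- cbind(1, as.matrix(g))                      # reduced design
  n <- length(y)
  ymat <- matrix(y, n, 1)
  if (B > 0) {
    perm <- .with_seed(seed, replicate(B, sample.int(n)))
    ymat <- cbind(ymat, matrix(y[perm], n, B))
  }
  qr_red <- qr(z)
  rss_red_all <- colSums(qr.resid(qr_red, ymat)^2)
  rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    calls <- m[, j]
    ok <- !is.na(calls)
    f <- factor(calls[ok])
    if (nlevels(f) < 2L) {
      message("marker ", colnames(m)[j],
              " is monomorphic after masking; skipped")
      next
    }
    d <- cbind(z[ok, , drop = FALSE],
               stats::model.matrix(~f)[, -1, drop = FALSE])
    qr_full <- qr(d)
    ysub <- ymat[ok, , drop = FALSE]
    rss_red <- if (all(ok)) rss_red_all
    else colSums(qr.resid(qr(z[ok, , drop = FALSE]), ysub)^2)
    rss_full <- colSums(qr.resid(qr_full, ysub)^2)
    df1 <- qr_full$rank - qr(z[ok, , drop = FALSE])$rank
    df2 <- sum(ok) - qr_full$rank
    if (df1 < 1L || df2 < 1L) next
    fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    yc <- ymat[ok, 1]
    tss <- sum((yc - mean(yc))^2)
    rows[[j]] <- data.frame(
      marker = colnames(m)[j], trait = trait, raw_p = p[1],
      adjusted_p = if (B > 0) (1 + sum(p[-1] <= p[1])) / (B + 1)
      else NA_real_,
      r2 = if (tss > 0) (rss_red[1] - rss_full[1]) / tss else NA_real_,
      n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker = character(), trait = character(),
                      raw_p = numeric(), adjusted_p = numeric(),
                      r2 = numeric(), n = integer())
  rownames(out) <- NULL
  attr(out, "perm_scheme") <- "trait_shuffle"
  attr(out, "B") <- B
  out
}

#' Linkage-disequilibrium blocks of collinear markers
#'
#' Pairwise collinearity `r_LD` between (possibly multi-allelic) markers is
#' the maximum absolute Pearson correlation over all pairs of allele-class
#' indicator columns, computed on genotypes observed for both markers.
#' Markers with `r_LD >= r_threshold` are connected; blocks are the
#' connected components of that graph. Each block is represented by its
#' member with the fewest missing calls before imputation (ties break by
#' marker id).
#'
#' @param x A [genotype_matrix()].
#' @param r_threshold Collinearity threshold (0.8).
#' @return List: `blocks` (list of character vectors of marker ids),
#'   `representatives` (character vector, one per block).
#' @export
ld_blocks <- function(x, r_threshold = 0.8) {
  m <- unclass(x)
  info <- marker_info(x)
  markers <- colnames(m)
  ind <- lapply(seq_along(markers), function(j) {
    f <- factor(m[, j])
    sapply(levels(f), function(l) as.numeric(f == l))
  })
  edges <- list()
  for (a in seq_along(markers)) for (b in seq_len(a - 1L)) {
    r <- suppressWarnings(stats::cor(ind[[a]], ind[[b]],
                                     use = "pairwise.complete.obs"))
    r <- max(abs(r), na.rm = TRUE)
    if (is.finite(r) && r >= r_threshold)
      edges[[length(edges) + 1L]] <- c(markers[a], markers[b])
  }
  gr <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges)
    else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = markers))
  comp <- igraph::components(gr)$membership
  blocks <- split(names(comp), comp)
  names(blocks) <- NULL
  nm_raw <- stats::setNames(info$n_missing_raw, info$marker)
  reps <- vapply(blocks, function(b)
    b[order(nm_raw[b], b)][1], character(1))
  list(blocks = blocks, representatives = unname(reps))
}

#' Backward-elimination multiple-marker linear model
#'
#' Starts from all candidate markers as categorical terms, iteratively
#' removes the whole marker term with the largest partial-F p-value above
#' `alpha` (one at a time, refitting after each removal), and stops when
#' every remaining term is at or below `alpha`. The result is returned as
#' a [marker_linear_model()]: intercept plus per-allele effects relative
#' to each marker's reference allele (the first class in sorted order).
#'
#' @param trait_values Named numeric vector (names = genotype ids).
#' @param candidate_markers Character vector of marker ids to start from.
#' @param x A [genotype_matrix()] with no missing calls at the candidates
#'   (impute first).
#' @param alpha Retention threshold (0.05); `alpha = 1` keeps all
#'   candidates.
#' @param trait Trait label stored in the model.
#' @return A `marker_linear_model`; intercept-only when no candidate
#'   survives.
#' @export
backward_eliminate <- function(trait_values, candidate_markers, x,
                               alpha = 0.05, trait = "trait") {
  ids <- intersect(names(trait_values), rownames(x))
  y <- trait_values[ids]
  m <- unclass(x)[ids, candidate_markers, drop = FALSE]
  df <- data.frame(lapply(as.data.frame(m, stringsAsFactors = FALSE),
                          factor), check.names = FALSE)
  keep <- candidate_markers[vapply(df, nlevels, integer(1)) >= 2L]
  n_coef <- 1L + sum(vapply(df[keep], nlevels, integer(1)) - 1L)
  if (n_coef > length(y))
    stop(sprintf("rank deficiency: %d coefficients for %d genotypes",
                 n_coef, length(y)))
  repeat {
    if (!length(keep)) {
      fit <- stats::lm(y ~ 1)
      break
    }
    dat <- cbind(data.frame(y = y), df[, keep, drop = FALSE])
    fit <- stats::lm(y ~ ., data = dat)
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    names(pv) <- rownames(dr)[-1]
    if (all(pv <= alpha, na.rm = TRUE) && !anyNA(pv)) break
    # aliased terms (NA p) are removed first, then the largest p
    worst <- names(pv)[order(ifelse(is.na(pv), Inf, pv),
                             decreasing = TRUE)[1]]
    keep <- setdiff(keep, .unbacktick(worst))
  }
  .model_from_fit(fit, keep, df, trait)
}

.unbacktick <- function(s) gsub("^`|`$", "", s)

.model_from_fit <- function(fit, keep, df, trait) {
  cf <- stats::coef(fit)
  terms <- lapply(keep, function(mk) {
    lv <- levels(df[[mk]])
    eff <- stats::setNames(vapply(lv[-1], function(l) {
      nm <- paste0(mk, l)
      nm2 <- paste0("`", mk, "`", l)
      if (nm %in% names(cf)) unname(cf[nm])
      else if (nm2 %in% names(cf)) unname(cf[nm2])
      else NA_real_
    }, numeric(1)), lv[-1])
    list(marker = mk, reference = lv[1], effects = eff)
  })
  marker_linear_model(trait = trait, intercept = unname(cf[1]),
                      terms = terms,
                      r2_fit = summary(fit)$r.squared)
}

#' Marker model restricted to known major genes
#'
#' Runs [backward_eliminate()] with the candidate set restricted to a
#' supplied list of major-gene markers, quantifying how much of the
#' parameter variation the major genes alone explain.
#'
#' @inheritParams backward_eliminate
#' @param gene_marker_list Character vector of major-gene marker ids (an
#'   empty list gives the intercept-only model).
#' @return A `marker_linear_model`.
#' @export
major_gene_model <- function(trait_values, x, gene_marker_list,
                             alpha = 0.05, trait = "trait") {
  if (!length(gene_marker_list)) {
    ids <- intersect(names(trait_values), rownames(x))
    return(marker_linear_model(trait = trait,
                               intercept = mean(trait_values[ids]),
                               terms = list(), r2_fit = 0))
  }
  backward_eliminate(trait_values, gene_marker_list, x, alpha, trait)
}
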