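#' Marker-based linear model for a genotype parameter
#'
#' A multiple-linear marker model maps allele classes at a small set of
#' markers to a genotype-parameter value: prediction = intercept + the sum
#' of the allelic effects carried at each model marker, where each marker's
#' reference allele has an implicit effect of 0.
#'
#' @param trait Trait label (`"v_sat"`, `"p_base"`, `"tt_emhe"`).
#' @param intercept Intercept, in trait units (days for V_sat, hours for
#'   P_base).
#' @param terms List of terms, each `list(marker, reference,
#'   effects = c(allele = coefficient), chromosome = NULL)`.
#' @param r2_fit Fraction of trait variance explained at fit time
#'   (optional).
#' @return A `marker_linear_model`.
#' @export
marker_linear_model <- function(trait, intercept, terms, r2_fit = NA_real_) {
  for (t in terms) {
    if (is.null(t$marker) || is.null(t$reference) || is.null(t$effects))
      stop("each term needs marker, reference and effects")
    if (t$reference %in% names(t$effects))
      stop("reference allele must not appear among the effects")
  }
  structure(list(trait = trait, intercept = intercept, terms = terms,
                 r2_fit = r2_fit),
            class = "marker_linear_model")
}

#' @export
print.marker_linear_model <- function(x, ...) {
  cat(sprintf("marker model for %s: intercept %g, %d marker term(s)",
              x$trait, x$intercept, length(x$terms)))
  if (!is.na(x$r2_fit)) cat(sprintf(", fit R2 = %.2f", x$r2_fit))
  cat("\n")
  for (t in x$terms)
    cat(sprintf("  %s (ref %s): %s\n", t$marker, t$reference,
                paste(sprintf("%s %+g", names(t$effects), t$effects),
                      collapse = ", ")))
  invisible(x)
}

#' Predict a genotype parameter from marker calls
#'
#' Evaluates a [marker_linear_model()] for one genotype: intercept plus the
#' effect of the carried allele at each model marker (0 for the reference
#' allele). A missing call or an allele class unknown to the model is an
#' explicit error — never a silent zero.
#'
#' @param model A `marker_linear_model`.
#' @param genotype_calls Named character vector (or one row of a
#'   [genotype_matrix()]) of allele classes; must cover every model marker.
#' @return Predicted trait value (numeric scalar).
#' @export
predict_parameter <- function(model, genotype_calls) {
  val <- model$intercept
  for (t in model$terms) {
    if (!(t$marker %in% names(genotype_calls)))
      stop(sprintf("no call at model marker %s", t$marker))
    a <- genotype_calls[[t$marker]]
    if (is.na(a))
      stop(sprintf("missing call at model marker %s", t$marker))
    if (a == t$reference) next
    if (!(a %in% names(t$effects)))
      stop(sprintf("unknown allele class '%s' at marker %s", a, t$marker))
    val <- val + unname(t$effects[[a]])
  }
  val
}

#' Predict a genotype parameter for every genotype of a matrix
#'
#' Matrix-level wrapper around [predict_parameter()]; genotypes lacking a
#' usable call at any model marker are not silently dropped but listed in
#' an exclusions report.
#'
#' @param model A `marker_linear_model`.
#' @param x A [genotype_matrix()].
#' @return List: `values` (named numeric, `NA` for excluded genotypes) and
#'   `exclusions` (data.frame `genotype_id, reason`).
#' @export
predict_parameter_all <- function(model, x) {
  vals <- stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
  excl <- list()
  for (g in rownames(x)) {
    r <- tryCatch(predict_parameter(model, unclass(x)[g, ]),
                  error = function(e) e)
    if (inherits(r, "error"))
      excl[[g]] <- data.frame(genotype_id = g,
                              reason = conditionMessage(r),
                              stringsAsFactors = FALSE)
    else vals[g] <- r
  }
  list(values = vals,
       exclusions = if (length(excl)) do.call(rbind, excl)
       else data.frame(genotype_id = character(), reason = character()))
}

#' Read / write marker models as JSON
#'
#' Format: `{trait, intercept, r2_fit, terms: [{marker, chromosome,
#' reference, effects: {allele: coefficient}}]}`.
#'
#' @param path JSON file path.
#' @param model A `marker_linear_model` (for writing).
#' @return `read_marker_model` returns a `marker_linear_model`.
#' @export
read_marker_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(j$terms, function(t)
    list(marker = t$marker, reference = as.character(t$reference),
         effects = stats::setNames(vapply(t$effects, as.numeric,
                                          numeric(1)),
                                   names(t$effects)),
         chromosome = t$chromosome %||% NA_character_))
  marker_linear_model(trait = j$trait, intercept = as.numeric(j$intercept),
                      terms = terms,
                      r2_fit = as.numeric(j$r2_fit %||% NA))
}

#' @rdname read_marker_model
#' @export
write_marker_model <- function(model, path) {
  j <- list(trait = model$trait, intercept = model$intercept,
            r2_fit = model$r2_fit,
            terms = lapply(model$terms, function(t)
              list(marker = t$marker,
                   chromosome = t$chromosome %||% NA_character_,
                   reference = t$reference,
                   effects = as.list(t$effects))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Bundled reference marker models for V_sat and P_base
#'
#' The package ships the published multiple-linear marker models fitted on
#' a 210-genotype bread-wheat association panel: 11 markers for V_sat
#' (intercept 53.9 days; major terms at the Vrn-A1 and Vrn-B1 vernalization
#' genes) and 12 markers for P_base (intercept 4.85 h; major term at the
#' Ppd-D1 photoperiod gene). Effects are per allele class relative to each
#' marker's reference allele.
#'
#' @param trait `"v_sat"` or `"p_base"`.
#' @return A `marker_linear_model`.
#' @examples
#' m <- bundled_marker_model("v_sat")
#' # a genotype carrying the reference allele at every model marker:
#' refs <- stats::setNames(vapply(m$terms, `[[`, "", "reference"),
#'                         vapply(m$terms, `[[`, "", "marker"))
#' predict_parameter(m, refs)   # the intercept, 53.9 days
#' @export
bundled_marker_model <- function(trait = c("v_sat", "p_base")) {
  trait <- match.arg(trait)
  path <- system.file("extdata",
                      sprintf("marker_model_%s.json", trait),
                      package = "headcast", mustWork = TRUE)
  read_marker_model(path)
}
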