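#' @name env_io
#' @title Reading and writing weather, phenotype, genotype and structure tables
#'
#' @description
#' All tables are plain CSV. Dialects:
#' \itemize{
#'   \item weather: `date` (ISO-8601), `tmin`, `tmax` (deg C)
#'   \item sites: `name, latitude, longitude, elevation`
#'   \item experiments: `id, site, sowing_date, season_class` with
#'     `season_class` one of `autumn`, `spring` (declared, never inferred)
#'   \item phenotypes: `genotype_id, experiment_id, heading_date` with the
#'     literal token `NH` for genotypes that did not head
#'   \item genotypes: rows = genotypes (first column `genotype_id`), columns =
#'     markers, cells = allele-class strings (e.g. `11`, `22`, `ins`, `del`),
#'     empty = missing
#'   \item structure: `genotype_id, g1, g2, g3, g4` ancestral-group
#'     contributions
#' }
#' Weather records must be gap-free: silent interpolation of missing days
#' would bias thermal-time sums, so a gap is an error naming the date.
NULL

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("malformed %s table: missing column(s) %s",
                 what, paste(miss, collapse = ", ")))
}

#' Read a daily weather table
#'
#' @param path Path to a weather CSV (`date`, `tmin`, `tmax`).
#' @return A data.frame with columns `date` (Date), `tmin`, `tmax`, ordered
#'   by date, validated to be gap-free with `tmin <= tmax`.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("date", "tmin", "tmax"), "weather")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("malformed weather table: unparseable date(s)")
  if (anyNA(df$tmin) || anyNA(df$tmax))
    stop("malformed weather table: missing temperature value(s)")
  validate_weather(df)
}

#' Validate a daily weather record
#'
#' @param weather data.frame with `date`, `tmin`, `tmax`.
#' @return The record, ordered by date, invisibly checked.
#' @export
validate_weather <- function(weather) {
  weather <- weather[order(weather$date), , drop = FALSE]
  if (anyDuplicated(weather$date))
    stop(sprintf("duplicate weather date(s): %s",
                 paste(unique(weather$date[duplicated(weather$date)]),
                       collapse = ", ")))
  bad <- weather$tmin > weather$tmax
  if (any(bad))
    stop(sprintf("tmin > tmax on %s",
                 paste(weather$date[bad], collapse = ", ")))
  d <- diff(as.integer(weather$date))
  if (any(d != 1L)) {
    gap_after <- weather$date[which(d != 1L)[1]]
    stop(sprintf("weather record has a gap after %s", gap_after))
  }
  rownames(weather) <- NULL
  weather
}

#' Read a sites table
#' @param path Path to a sites CSV.
#' @return data.frame `name, latitude, longitude, elevation`.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("name", "latitude"), "sites")
  if (anyDuplicated(df$name))
    stop("duplicate site name(s)")
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("site latitude out of [-90, 90]")
  df
}

#' Read an experiments table
#' @param path Path to an experiments CSV.
#' @param sites Optional sites table; site references are checked against it.
#' @return data.frame `id, site, sowing_date (Date), season_class`.
#' @export
read_experiments <- function(path, sites = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "site", "sowing_date", "season_class"),
                "experiments")
  df$sowing_date <- as.Date(df$sowing_date)
  if (anyNA(df$sowing_date))
    stop("malformed experiments table: unparseable sowing_date(s)")
  if (anyDuplicated(df$id)) stop("duplicate experiment id(s)")
  if (!all(df$season_class %in% c("autumn", "spring")))
    stop("season_class must be 'autumn' or 'spring'")
  if (!is.null(sites) && !all(df$site %in% sites$name))
    stop(sprintf("unknown site reference(s): %s",
                 paste(setdiff(df$site, sites$name), collapse = ", ")))
  df
}

#' Read a heading-date phenotype table
#'
#' The literal token `NH` marks a genotype that did not head in an
#' experiment; it is parsed to `NA` in `heading_date` with `headed = FALSE`.
#'
#' @param path Path to a phenotypes CSV.
#' @param experiments Optional experiments table; experiment references and
#'   the `heading >= sowing` invariant are then checked.
#' @return data.frame `genotype_id, experiment_id, heading_date (Date),
#'   headed (logical)`.
#' @export
read_phenotypes <- function(path, experiments = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(heading_date = "character"))
  .require_cols(df, c("genotype_id", "experiment_id", "heading_date"),
                "phenotypes")
  headed <- df$heading_date != "NH"
  hd <- as.Date(ifelse(headed, df$heading_date, NA))
  if (anyNA(hd[headed]))
    stop("malformed phenotypes table: unparseable heading_date(s)")
  out <- data.frame(genotype_id = df$genotype_id,
                    experiment_id = df$experiment_id,
                    heading_date = hd, headed = headed,
                    stringsAsFactors = FALSE)
  key <- paste(out$genotype_id, out$experiment_id)
  if (anyDuplicated(key))
    stop(sprintf("duplicate phenotype record(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (!is.null(experiments)) {
    unknown <- setdiff(out$experiment_id, experiments$id)
    if (length(unknown))
      stop(sprintf("unknown experiment reference(s): %s",
                   paste(unknown, collapse = ", ")))
    sow <- experiments$sowing_date[match(out$experiment_id, experiments$id)]
    bad <- out$headed & out$heading_date < sow
    if (any(bad))
      stop("heading_date earlier than sowing date for: ",
           paste(key[bad], collapse = "; "))
  }
  out
}

#' Read a genotype matrix
#'
#' @param path Path to a genotypes CSV (first column `genotype_id`, remaining
#'   columns markers; empty cells are missing calls).
#' @param chromosome Optional named character vector of marker chromosomes.
#' @return A `genotype_matrix`: character matrix (genotypes x markers, `NA`
#'   for missing) with a `marker_info` attribute recording `chromosome` and
#'   `n_missing_raw` (missing-call counts frozen before any imputation).
#' @export
read_genotypes <- function(path, chromosome = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "genotype_id")
    stop("malformed genotypes table: first column must be genotype_id")
  if (anyDuplicated(df$genotype_id)) stop("duplicate genotype id(s)")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genotype_id
  m[m == ""] <- NA_character_
  genotype_matrix(m, chromosome = chromosome)
}

#' Construct a genotype matrix object
#'
#' @param calls Character matrix, genotypes x markers, `NA` = missing call.
#' @param chromosome Optional character vector (or named vector) of
#'   chromosome labels per marker; `NA` where unknown.
#' @param n_missing_raw Optional integer vector of per-marker missing counts
#'   before imputation; defaults to the current missing counts.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, chromosome = NULL, n_missing_raw = NULL) {
  stopifnot(is.matrix(calls), is.character(calls))
  if (is.null(colnames(calls))) stop("markers must be named")
  if (is.null(chromosome)) chromosome <- rep(NA_character_, ncol(calls))
  if (!is.null(names(chromosome)))
    chromosome <- unname(chromosome[colnames(calls)])
  if (is.null(n_missing_raw)) n_missing_raw <- colSums(is.na(calls))
  attr(calls, "marker_info") <- data.frame(
    marker = colnames(calls),
    chromosome = as.character(chromosome),
    n_missing_raw = as.integer(n_missing_raw),
    stringsAsFactors = FALSE)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' Per-marker metadata of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return data.frame `marker, chromosome, n_missing_raw`.
#' @export
marker_info <- function(x) attr(x, "marker_info")

#' @export
`[.genotype_matrix` <- function(x, i, j, drop = FALSE) {
  info <- marker_info(x)
  m <- unclass(x)
  attr(m, "marker_info") <- NULL
  out <- m[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  genotype_matrix(out,
                  chromosome = stats::setNames(info$chromosome,
                                               info$marker)[colnames(out)],
                  n_missing_raw = stats::setNames(info$n_missing_raw,
                                                  info$marker)[colnames(out)])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d genotypes x %d markers (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a population-structure table
#' @param path Path to a structure CSV (`genotype_id, g1, g2, g3, g4`).
#' @return data.frame of ancestral-group contributions.
#' @export
read_structure <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("genotype_id", "g1", "g2", "g3", "g4"), "structure")
  if (anyDuplicated(df$genotype_id)) stop("duplicate genotype id(s)")
  df
}

#' Write tables in the package CSV dialects
#'
#' Counterparts of the `read_*` functions; a write followed by a read
#' reproduces the records exactly.
#'
#' @param x The table to write.
#' @param path Output path.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_weather <- function(x, path) {
  utils::write.csv(data.frame(date = as.character(x$date),
                              tmin = x$tmin, tmax = x$tmax),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_tables
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(data.frame(
    genotype_id = x$genotype_id, experiment_id = x$experiment_id,
    heading_date = ifelse(x$headed, as.character(x$heading_date), "NH")),
    path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_tables
#' @export
write_genotypes <- function(x, path) {
  m <- unclass(x)
  attr(m, "marker_info") <- NULL
  m[is.na(m)] <- ""
  utils::write.csv(data.frame(genotype_id = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_tables
#' @export
write_structure <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}
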