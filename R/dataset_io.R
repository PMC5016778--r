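# Canonical column set for a scored site table. Order matters: it is the order
# in which columns are written out and validated.
.STUDY_COLUMNS <- c(
  "site_id", "island",
  "status_local", "status_10km", "status_60km",
  "dist_port_km", "dist_freshwater", "dist_pollution",
  "algae_cover", "wave_exposure", "traffic", "substrate", "aquaculture",
  "nis_prop", "n_native", "richness", "simpson"
)

.NUMERIC_COLUMNS <- setdiff(.STUDY_COLUMNS, c("site_id", "island"))

# Default per-column scale declaration. "likert" columns are bounded ordinal
# scores, "proportion" columns live in [0,1], everything else is a raw
# measurement (km, counts, index values).
.DEFAULT_SCALES <- c(
  status_local = "likert", status_10km = "raw", status_60km = "raw",
  dist_port_km = "raw", dist_freshwater = "raw", dist_pollution = "raw",
  algae_cover = "proportion", wave_exposure = "likert", traffic = "likert",
  substrate = "likert", aquaculture = "likert",
  nis_prop = "proportion", n_native = "raw", richness = "raw",
  simpson = "proportion"
)

#' Construct a validated study dataset
#'
#' A study dataset is a data frame of scored coastal sites, one row per site,
#' carrying the protective-status scores at three spatial scales, the
#' invasion-vector and habitat covariates, and the community response
#' variables (NIS proportion, native species count, diversity indices).
#' Row order is preserved and significant: the Durbin-Watson diagnostic
#' depends on it.
#'
#' @param df data frame with the canonical columns (see Details).
#' @param scales optional named character vector declaring the measurement
#'   scale of each numeric column (`"raw"`, `"likert"` or `"proportion"`);
#'   defaults are supplied for the canonical columns.
#'
#' @details Required columns: `site_id`, `island`, `status_local`,
#'   `status_10km`, `status_60km`, `dist_port_km`, `dist_freshwater`,
#'   `dist_pollution`, `algae_cover`, `wave_exposure`, `traffic`,
#'   `substrate`, `aquaculture`, `nis_prop`, `n_native`, `richness`,
#'   `simpson`. Local protective status must be one of the four tier values
#'   1, 2, 3 or 5; proportions must lie in [0,1]; `site_id` must be unique;
#'   missing cells are rejected rather than imputed.
#'
#' @return an object of class `study_dataset` (a data frame).
#' @seealso [read_dataset()], [packaged_table1()]
#' @export
study_dataset <- function(df, scales = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("study dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .STUDY_COLUMNS]
  for (cn in .NUMERIC_COLUMNS) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) &
                     !is.na(df[[cn]]))
      stop(sprintf("column '%s' is not numeric (first bad row: %s)",
                   cn, if (length(bad)) bad[1] else "?"), call. = FALSE)
    }
  }
  sc <- .DEFAULT_SCALES
  if (!is.null(scales)) sc[names(scales)] <- scales
  x <- structure(df, scales = sc, class = c("study_dataset", "data.frame"))
  validate_study_dataset(x)
  x
}

#' Validate a study dataset
#'
#' Checks the structural invariants of a [study_dataset()]; called by all
#' constructors and readers.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_study_dataset <- function(x) {
  stopifnot(inherits(x, "study_dataset"))
  if (nrow(x) == 0L) stop("study dataset has no rows", call. = FALSE)
  if (anyNA(x[.NUMERIC_COLUMNS])) {
    bad <- which(rowSums(is.na(x[.NUMERIC_COLUMNS])) > 0)[1]
    stop("missing value in row ", bad,
         "; datasets with missing cells are rejected, not imputed",
         call. = FALSE)
  }
  if (anyDuplicated(x$site_id)) {
    dup <- unique(x$site_id[duplicated(x$site_id)])
    stop("duplicated site_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(x$status_local %in% c(1, 2, 3, 5))) {
    stop("status_local must be one of the protection tiers 1, 2, 3, 5",
         call. = FALSE)
  }
  if (any(x$nis_prop < 0 | x$nis_prop > 1)) {
    stop("nis_prop must lie in [0, 1]", call. = FALSE)
  }
  if (any(x$simpson < 0 | x$simpson >= 1)) {
    stop("simpson must lie in [0, 1)", call. = FALSE)
  }
  if (any(x$n_native < 0)) stop("n_native must be nonnegative", call. = FALSE)
  invisible(x)
}

#' Read a scored site table from CSV
#'
#' Reads a UTF-8 CSV with a header row into a validated [study_dataset()].
#' Non-canonical column names can be mapped through `dialect`; row order in
#' the file is preserved.
#'
#' @param path path to a CSV file.
#' @param dialect optional column mapping: either a named character vector
#'   (`c(canonical = "file_column", ...)`) or the path to a YAML file whose
#'   top-level `columns:` mapping has the same shape. Optionally the YAML may
#'   carry a `scales:` mapping overriding per-column scale declarations.
#' @return a [study_dataset()].
#' @export
read_dataset <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) <= 1L && all(dim(raw) == c(0L, 0L))) {
    stop("empty dataset file: ", path, call. = FALSE)
  }
  scales <- NULL
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect)) &&
      file.exists(dialect)) {
    cfg <- yaml::read_yaml(dialect)
    scales <- unlist(cfg$scales)
    dialect <- unlist(cfg$columns)
  }
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("dialect maps '", canon, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (nrow(raw) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  study_dataset(raw, scales = scales)
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_dataset()]: numeric cells are written with full precision
#' so that a read/write round trip is lossless at the printed precision.
#'
#' @param x a [study_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  validate_study_dataset(x)
  df <- as.data.frame(x)
  for (cn in .NUMERIC_COLUMNS) df[[cn]] <- format(df[[cn]], digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged 30-site two-island reference dataset
#'
#' The scored site table for the 30 coastal sites of the two-island Pacific
#' survey the package reproduces: 16 sites on Moorea (French Polynesia) and
#' 14 on Vancouver Island (Canada), the latter split 8 east-coast / 6
#' west-coast sites. Columns are the local, 10-km and 60-km protective
#' status, distances to port/freshwater/pollution, algae cover, wave
#' exposure, maritime traffic, substrate artificiality and aquaculture
#' scores, and the response block (NIS species proportion, native species
#' count, Margalef richness, Simpson index). Values are transcribed at
#' printed precision; row order follows the printed table and is significant
#' for the autocorrelation diagnostics.
#'
#' @return a [study_dataset()] with 30 rows.
#' @examples
#' d <- packaged_table1()
#' nrow(d)                      # 30
#' d[d$site_id == "M-Ti", "aquaculture"]
#' @export
packaged_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "mpanis")
  read_dataset(path)
}

#' Regional subset of a study dataset
#'
#' Restricts a dataset to one or more island/coast labels, preserving row
#' order. Used for the regional robustness re-analysis.
#'
#' @param x a [study_dataset()].
#' @param islands character vector of island labels (e.g. `"Moorea"`,
#'   `"VancouverEast"`, `"VancouverWest"`).
#' @param ... ignored.
#' @return a [study_dataset()] with the matching rows.
#' @export
subset.study_dataset <- function(x, islands, ...) {
  stopifnot(length(islands) >= 1L)
  keep <- x$island %in% islands
  if (!any(keep)) {
    stop("empty subset: no site has island in {",
         paste(islands, collapse = ", "), "}", call. = FALSE)
  }
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  study_dataset(out, scales = attr(x, "scales"))
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study dataset: %d sites (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$island)),
                            as.integer(table(x$island))), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}
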