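#' Write a survey dataset, STI table and station series as CSV tables
#'
#' Tables are UTF-8, comma-delimited with a header row: occurrences
#' (`square_id`, `survey`, `year`, `species_id`), squares (`square_id`,
#' `altitude_m`, `altitudinal_range_m`, `year_survey1`, `year_survey2`),
#' sti (`species_id`, `group`, `sti`), stations (`station_id`, `altitude_m`,
#' `year`, `month`, `mean_temp_c`).
#'
#' @param dir Output directory (created if missing).
#' @param dataset A `survey_dataset`, or `NULL`.
#' @param sti An STI table, or `NULL`.
#' @param stations A `station_series`, or `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(dir, dataset = NULL, sti = NULL, stations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths[[name]] <<- path
  }
  if (!is.null(dataset)) {
    wr(dataset$occurrences, "occurrences")
    wr(dataset$squares, "squares")
  }
  if (!is.null(sti)) wr(sti, "sti")
  if (!is.null(stations)) wr(as.data.frame(stations), "stations")
  invisible(paths)
}

.check_schema <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", file, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.check_numeric <- function(df, cols, file) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop("file ", file, ", column ", col, ": non-numeric value at row ",
           bad[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Read survey, STI and station tables from CSV files
#'
#' Validates the documented schemas, coerces numeric columns (with the
#' offending row number on failure), and deduplicates repeated occurrence
#' rows with a warning.
#'
#' @param occurrences,squares,sti,stations Paths to the respective CSV
#'   files; `sti` and `stations` may be `NULL`.
#' @return A list with `dataset` (a `survey_dataset`), `sti`, `stations`
#'   (or `NULL` where not supplied).
#' @export
read_tables <- function(occurrences, squares, sti = NULL, stations = NULL) {
  occ <- utils::read.csv(occurrences, stringsAsFactors = FALSE)
  .check_schema(occ, c("square_id", "survey", "year", "species_id"),
                occurrences)
  occ <- .check_numeric(occ, c("survey", "year"), occurrences)
  dup <- duplicated(occ)
  if (any(dup)) {
    warning(sum(dup), " duplicated occurrence row(s) removed", call. = FALSE)
    occ <- occ[!dup, , drop = FALSE]
  }

  sq <- utils::read.csv(squares, stringsAsFactors = FALSE)
  .check_schema(sq, c("square_id", "altitude_m", "altitudinal_range_m",
                      "year_survey1"), squares)
  sq <- .check_numeric(sq, c("altitude_m", "altitudinal_range_m"), squares)
  if (!"year_survey2" %in% names(sq)) sq$year_survey2 <- sq$year_survey1 + 5L

  sti_df <- NULL
  if (!is.null(sti)) {
    sti_df <- utils::read.csv(sti, stringsAsFactors = FALSE)
    .check_schema(sti_df, c("species_id", "group", "sti"), sti)
    sti_df <- .check_numeric(sti_df, "sti", sti)
  }
  stations_df <- NULL
  if (!is.null(stations)) {
    stations_df <- utils::read.csv(stations, stringsAsFactors = FALSE)
    .check_schema(stations_df, c("station_id", "altitude_m", "year", "month",
                                 "mean_temp_c"), stations)
    stations_df <- .check_numeric(stations_df,
                                  c("altitude_m", "year", "month",
                                    "mean_temp_c"), stations)
    class(stations_df) <- c("station_series", "data.frame")
  }
  dataset <- structure(list(occurrences = occ, squares = sq),
                       class = "survey_dataset")
  list(dataset = dataset, sti = sti_df, stations = stations_df)
}
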