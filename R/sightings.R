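# Sighting-record data model: schema, CSV reader/writer, season-year rule,
# occasion calendars and the results-report writer.

# Permitted values for the five Urian-style quality components.
QUALITY_LEVELS <- list(
  focus    = c(2L, 4L, 9L),
  contrast = c(1L, 3L),
  angle    = c(1L, 2L, 8L),
  partial  = c(1L, 8L),
  frame    = c(1L, 5L)
)

SIDE_LEVELS <- c("left", "right", "unknown")
DIST_LEVELS <- c("D1", "D2", "D3", "unknown")
AGE_LEVELS <- c("adult", "juvenile", "calf")

#' Default sighting-record CSV schema
#'
#' Maps the internal field names to the column headers expected in a
#' sightings CSV. Supply `col_map` to [read_sightings()] to ingest files
#' whose headers differ (third-party exports).
#'
#' @return named character vector (internal field -> expected header).
#' @export
sighting_schema <- function() {
  fields <- c("image_id", "timestamp", "individual_id", "side",
              "focus", "contrast", "angle", "partial", "frame",
              "distinctiveness", "age_class", "mother_id",
              "photographer", "vessel", "latitude", "longitude")
  stats::setNames(fields, fields)
}

MANDATORY_FIELDS <- c("image_id", "timestamp", "focus", "contrast",
                      "angle", "partial", "frame")

#' Read and validate photo-identification sighting records
#'
#' Reads a UTF-8 CSV of one row per identified (or unidentified) animal per
#' image, validates timestamps and the five quality-component scores against
#' their permitted values, and returns the clean rows. Malformed rows are not
#' fatal: they are dropped and reported, with their line numbers, in the
#' `rejections` attribute.
#'
#' @param path path to the CSV file.
#' @param col_map optional named character vector mapping internal field
#'   names (see [sighting_schema()]) to the file's headers.
#' @param tz timezone in which timestamps are interpreted (default "UTC";
#'   timestamps are treated as local civil time).
#' @return a `data.frame` of validated records, row order preserved, with an
#'   attribute `rejections` (data.frame: line, reason).
#' @export
read_sightings <- function(path, col_map = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  schema <- sighting_schema()
  if (!is.null(col_map)) schema[names(col_map)] <- col_map
  missing_cols <- setdiff(schema[MANDATORY_FIELDS], names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   matrix(nrow = nrow(raw), ncol = 0))
  for (f in names(schema)) {
    df[[f]] <- if (schema[[f]] %in% names(raw)) raw[[schema[[f]]]] else NA_character_
  }
  validate_sightings(df, tz = tz)
}

# element-wise timestamp parsing over a cascade of ISO 8601 formats
# (longest first, so a date-only format never truncates a date-time)
parse_timestamps <- function(x, tz = "UTC") {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  res <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (f in fmts) {
    need <- is.na(res) & !is.na(x) & x != ""
    if (!any(need)) break
    res[need] <- as.POSIXct(strptime(x[need], f, tz = tz))
  }
  res
}

#' Validate a raw sightings data frame
#'
#' @param df data.frame with character columns named as in [sighting_schema()].
#' @param tz timezone for timestamp parsing.
#' @return validated records with a `rejections` attribute.
#' @export
validate_sightings <- function(df, tz = "UTC") {
  n <- nrow(df)
  reasons <- character(n)
  ts <- parse_timestamps(df$timestamp, tz)
  reasons[is.na(ts)] <- "unparseable timestamp"
  for (comp in names(QUALITY_LEVELS)) {
    v <- suppressWarnings(as.integer(df[[comp]]))
    bad <- !is.na(df[[comp]]) & df[[comp]] != "" & !(v %in% QUALITY_LEVELS[[comp]])
    bad <- bad | is.na(v)
    reasons[bad & reasons == ""] <-
      sprintf("invalid %s score (permitted: %s)", comp,
              paste(QUALITY_LEVELS[[comp]], collapse = ","))
    df[[comp]] <- v
  }
  blank_to_na <- function(x) { x[!is.na(x) & x == ""] <- NA_character_; x }
  for (f in c("individual_id", "mother_id", "photographer", "vessel")) {
    df[[f]] <- blank_to_na(df[[f]])
  }
  df$side <- tolower(blank_to_na(df$side))
  df$side[is.na(df$side)] <- "unknown"
  bad_side <- !(df$side %in% SIDE_LEVELS)
  reasons[bad_side & reasons == ""] <- "invalid side"
  df$distinctiveness <- blank_to_na(df$distinctiveness)
  df$distinctiveness[is.na(df$distinctiveness)] <- "unknown"
  bad_d <- !(df$distinctiveness %in% DIST_LEVELS)
  reasons[bad_d & reasons == ""] <- "invalid distinctiveness (D1/D2/D3)"
  df$age_class <- blank_to_na(df$age_class)
  df$age_class[is.na(df$age_class)] <- "adult"
  bad_a <- !(df$age_class %in% AGE_LEVELS)
  reasons[bad_a & reasons == ""] <- "invalid age_class"
  for (f in c("latitude", "longitude")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  df$timestamp <- ts
  df$date <- as.Date(ts, tz = tz)

  keep <- reasons == ""
  rejections <- data.frame(line = which(!keep) + 1L,  # +1 for the header row
                           reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  if (nrow(rejections)) {
    warning(sprintf("%d row(s) rejected during validation", nrow(rejections)))
  }
  out
}

#' Write sighting records to CSV
#'
#' Inverse of [read_sightings()]: `read_sightings(write_sightings(x, f))`
#' reproduces all field values.
#'
#' @param records validated sighting records.
#' @param path output CSV path.
#' @export
write_sightings <- function(records, path) {
  out <- records
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%S")
  out$date <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign the season-year of an austral spring--autumn field season
#'
#' Field seasons span the austral spring to autumn (October--April) and are
#' labelled by the calendar year in which the spring falls: October--December
#' dates keep their own year, January--April dates belong to the previous
#' year's season. Dates in May--September fall outside any season and are
#' returned as `NA` with a warning.
#'
#' @param dates a `Date` vector (or anything coercible via `as.Date`).
#' @return integer vector of season-years (`NA` = out of season).
#' @export
assign_season_year <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  out <- ifelse(m >= 10L, y, ifelse(m <= 4L, y - 1L, NA_integer_))
  if (any(!is.na(dates) & is.na(out))) {
    warning(sum(!is.na(dates) & is.na(out)),
            " date(s) fall in May-September, outside any field season")
  }
  as.integer(out)
}

#' Build a robust-design occasion calendar
#'
#' A calendar lists the primary occasions (season-years) and, within each,
#' the secondary occasions (calendar months). A month given as 11 or 12
#' falls in the season-year itself; months 1--4 fall in the following
#' calendar year.
#'
#' @param months named list: one element per season-year (names are the
#'   years), each an integer vector of months in chronological order within
#'   the season (e.g. `c(11, 12, 1, 2, 3)`).
#' @return an object of class `occasion_calendar`.
#' @export
occasion_calendar <- function(months) {
  years <- as.integer(names(months))
  if (any(is.na(years)) || is.unsorted(years, strictly = TRUE)) {
    stop("`months` must be named by strictly increasing season-years")
  }
  prim <- lapply(seq_along(years), function(i) {
    mo <- as.integer(months[[i]])
    if (!length(mo)) stop("primary ", years[i], " has zero secondary occasions")
    if (!all(mo %in% c(10:12, 1:4))) {
      stop("secondary months must lie within the October-April season window")
    }
    cal_year <- ifelse(mo >= 10L, years[i], years[i] + 1L)
    ord <- cal_year * 12L + mo
    if (is.unsorted(ord, strictly = TRUE)) {
      stop("secondary months within primary ", years[i],
           " must be strictly increasing in time")
    }
    data.frame(season_year = years[i], month = mo, cal_year = cal_year)
  })
  structure(list(years = years, primaries = prim), class = "occasion_calendar")
}

#' Default study calendar: ten season-years of November--March months
#'
#' Mirrors a decade-long ecotour photo-ID design: five monthly secondary
#' occasions (November--March) per season-year, with a single season
#' (2020) shifted to January--April after an effort disruption.
#'
#' @param years integer vector of season-years (default 2012--2021).
#' @param shifted_years years whose window is January--April instead.
#' @return an `occasion_calendar`.
#' @export
default_calendar <- function(years = 2012:2021, shifted_years = 2020L) {
  months <- lapply(years, function(y) {
    if (y %in% shifted_years) c(1L, 2L, 3L, 4L) else c(11L, 12L, 1L, 2L, 3L)
  })
  names(months) <- years
  occasion_calendar(months)
}

#' @export
print.occasion_calendar <- function(x, ...) {
  cat("Occasion calendar:", length(x$years), "primary occasions\n")
  for (p in x$primaries) {
    cat(sprintf("  %d: %s\n", p$season_year[1],
                paste(month.abb[p$month], collapse = "-")))
  }
  invisible(x)
}

n_secondaries <- function(calendar) {
  vapply(calendar$primaries, nrow, integer(1))
}

#' Write a machine- and human-readable results report
#'
#' Each data.frame in `results` is written as `<name>.csv`; scalar/vector
#' elements are collected into `summary.json`; a plain-text `summary.txt`
#' restates the bundle. Output is deterministic given identical inputs.
#'
#' @param results named list of data.frames and/or scalar summaries.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!length(results)) warning("empty results bundle: writing empty report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create report directory: ", dir)
  paths <- character(0)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE, na = "")
      paths <- c(paths, p)
    } else {
      scalars[[nm]] <- x
    }
  }
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(scalars, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tp <- file.path(dir, "summary.txt")
  lines <- c("photopop results report",
             paste0("tables: ", paste(setdiff(names(results), names(scalars)),
                                      collapse = ", ")),
             vapply(names(scalars), function(k) {
               paste0(k, ": ", paste(format(scalars[[k]]), collapse = " "))
             }, character(1)))
  writeLines(lines, tp)
  invisible(c(paths, jp, tp))
}

#' Read a structured plain-text configuration file
#'
#' YAML file holding occasion windows, thresholds (group gap minutes,
#' minimum sighting counts, permutation schedules) and seeds. Values are
#' returned as a plain list; missing keys fall back to package defaults at
#' the point of use.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
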