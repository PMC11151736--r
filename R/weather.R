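#' Read a daily weather table
#'
#' Expects a CSV with columns `date` (ISO-8601), `precip_mm` and `tavg_c`.
#' Dates must be consecutive calendar days with no gaps or duplicates;
#' precipitation must be non-negative.
#'
#' @param path path to the CSV file.
#' @return A `weather_series` data frame (`date`, `precip_mm`, `tavg_c`).
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "precip_mm", "tavg_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date in weather CSV", call. = FALSE)
  weather_series(df$date, df$precip_mm, df$tavg_c)
}

#' Construct and validate a daily weather series
#'
#' @param dates `Date` vector of consecutive calendar days.
#' @param precip_mm daily precipitation depth, mm (>= 0).
#' @param tavg_c daily mean air temperature, deg C.
#' @return A `weather_series` data frame.
#' @export
weather_series <- function(dates, precip_mm, tavg_c) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (length(precip_mm) != n || length(tavg_c) != n)
    stop("dates, precip_mm and tavg_c must have equal length", call. = FALSE)
  if (anyDuplicated(dates))
    stop("duplicate date(s) in weather series: ",
         paste(unique(dates[duplicated(dates)]), collapse = ", "),
         call. = FALSE)
  full <- seq(min(dates), max(dates), by = "day")
  if (length(full) != n || any(sort(dates) != full)) {
    missing_days <- setdiff(as.character(full), as.character(dates))
    stop("weather series has date gap(s); missing: ",
         paste(missing_days, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(precip_mm)) || any(precip_mm < 0))
    stop("precip_mm must be finite and non-negative", call. = FALSE)
  ord <- order(dates)
  structure(
    data.frame(date = dates[ord], precip_mm = as.numeric(precip_mm[ord]),
               tavg_c = as.numeric(tavg_c[ord])),
    class = c("weather_series", "data.frame"))
}

#' Write a weather series to CSV
#' @param weather a `weather_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(as.data.frame(weather), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Is a date in the Pacific-Northwest dry season (June-September)?
#' @param dates `Date` vector.
#' @return logical vector.
#' @export
is_dry_season <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  m >= 6L & m <= 9L
}
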