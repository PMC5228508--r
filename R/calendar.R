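#' Seasonal period calendar
#'
#' Builds the quarterly calendar used throughout the analysis. Each calendar
#' year is divided into four seasons: winter (January--March), spring
#' (April--June), summer (July--September) and autumn (October--December).
#' Periods are numbered consecutively from 1 starting at the winter of
#' \code{first_year}.
#'
#' @param first_year,last_year integer calendar years spanned by the study
#'   (inclusive).
#' @return A data frame of class \code{"period_calendar"} with one row per
#'   seasonal period and columns \code{period}, \code{year}, \code{season}
#'   (factor with levels winter, spring, summer, autumn), \code{start} and
#'   \code{end} (Dates, closed range).
#' @examples
#' cal <- period_calendar(2008, 2013)
#' head(cal)
#' @export
period_calendar <- function(first_year, last_year) {
  stopifnot(is.numeric(first_year), is.numeric(last_year),
            last_year >= first_year)
  years <- seq(as.integer(first_year), as.integer(last_year))
  seasons <- c("winter", "spring", "summer", "autumn")
  grid <- expand.grid(season = seasons, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  start_month <- c(winter = 1L, spring = 4L, summer = 7L, autumn = 10L)
  end_month <- c(winter = 3L, spring = 6L, summer = 9L, autumn = 12L)
  start <- as.Date(sprintf("%d-%02d-01", grid$year, start_month[grid$season]))
  # last day of the closing month
  end <- as.Date(sprintf("%d-%02d-01", grid$year, end_month[grid$season]))
  end <- seq_dates_month_end(end)
  cal <- data.frame(period = seq_len(nrow(grid)), year = grid$year,
                    season = factor(grid$season, levels = seasons),
                    start = start, end = end)
  class(cal) <- c("period_calendar", "data.frame")
  cal
}

# last day of the month containing each date
seq_dates_month_end <- function(first_of_month) {
  nxt <- as.POSIXlt(first_of_month)
  nxt$mon <- nxt$mon + 1L
  as.Date(nxt) - 1L
}

#' Locate dates in the period calendar
#'
#' @param dates a Date vector.
#' @param calendar a \code{\link{period_calendar}}.
#' @return Integer vector of period indices (\code{NA} for dates outside the
#'   calendar).
#' @export
date_to_period <- function(dates, calendar) {
  dates <- as.Date(dates)
  idx <- findInterval(as.integer(dates), as.integer(calendar$start))
  idx[idx == 0L] <- NA_integer_
  out <- calendar$period[idx]
  out[!is.na(dates) & dates > max(calendar$end)] <- NA_integer_
  out
}

#' Spawn-season flag for a species
#'
#' Bull Trout spawn during the summer period (July--September hiatus window);
#' Rainbow Trout during the spring period (April--May migration window).
#'
#' @param calendar a \code{\link{period_calendar}}.
#' @param species \code{"BullTrout"} or \code{"RainbowTrout"}.
#' @return Logical vector along calendar rows: is each period the species'
#'   spawning season?
#' @export
spawn_season_periods <- function(calendar, species) {
  species <- match.arg(species, c("BullTrout", "RainbowTrout"))
  target <- if (species == "BullTrout") "summer" else "spring"
  calendar$season == target
}
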