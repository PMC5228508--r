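#' Filter raw hourly detections
#'
#' Applies the two detection-level quality rules used before any aggregation:
#' records with two or fewer detections of a transmitter at a receiver within
#' an hour are treated as spurious and discarded, and detections recorded
#' after a transmitter's expected tag life are artifacts and discarded.
#'
#' @param detections data frame with columns \code{fish_id},
#'   \code{receiver_id}, \code{hour} (POSIXct, or a string parseable as one;
#'   timestamps are truncated to the hour, interpreted as the half-open
#'   interval \[h, h+1)) and \code{n_detections}.
#' @param captures data frame with at least \code{fish_id},
#'   \code{capture_date} (Date) and \code{tag_life_days} (\code{NA} for fish
#'   carrying anchor tags only).
#' @param min_detections minimum hourly detection count retained (default 3,
#'   i.e. records with 2 or fewer are dropped).
#' @return The surviving rows of \code{detections}, hours truncated.
#' @export
filter_hourly <- function(detections, captures, min_detections = 3L) {
  detections <- as.data.frame(detections)
  captures <- as.data.frame(captures)
  req_cols(detections, c("fish_id", "receiver_id", "hour", "n_detections"),
           "detections")
  req_cols(captures, c("fish_id", "capture_date", "tag_life_days"), "captures")
  if (nrow(detections) == 0L) return(detections)

  unknown <- setdiff(detections$fish_id, captures$fish_id)
  if (length(unknown))
    stop("detections reference unknown fish: ",
         paste(unique(unknown), collapse = ", "))

  hour <- as.POSIXct(detections$hour, tz = "UTC")
  hour <- trunc(hour, units = "hours")
  detections$hour <- as.POSIXct(hour, tz = "UTC")

  i <- match(detections$fish_id, captures$fish_id)
  tag_life <- captures$tag_life_days[i]
  if (anyNA(tag_life))
    stop("detections recorded for fish without an acoustic transmitter: ",
         paste(unique(detections$fish_id[is.na(tag_life)]), collapse = ", "))
  release <- as.POSIXct(as.Date(captures$capture_date[i]), tz = "UTC")
  if (any(detections$hour < release))
    stop("detections dated before capture for fish: ",
         paste(unique(detections$fish_id[detections$hour < release]),
               collapse = ", "))
  expiry <- release + tag_life * 86400
  keep <- detections$n_detections >= min_detections & detections$hour <= expiry
  detections[keep, , drop = FALSE]
}

#' Assign each fish-day to a single lake section
#'
#' Detections of the same fish in more than one section on the same day are
#' resolved in favour of the section with the most detections; ties are
#' broken by the section with the fewest receivers, and remaining ties by the
#' smallest sectional area (areas are unique, so the cascade always resolves).
#'
#' @param detections filtered hourly detections (see
#'   \code{\link{filter_hourly}}).
#' @param sections data frame with \code{section_id}, \code{n_receivers},
#'   \code{area_ha} (unique) and any zone-flag columns.
#' @param receivers optional data frame mapping \code{receiver_id} to
#'   \code{section_id}; if \code{NULL}, receiver ids are taken to be section
#'   ids.
#' @return data frame \code{fish_id}, \code{date}, \code{section_id}: at most
#'   one row per fish-day.
#' @export
assign_daily_sections <- function(detections, sections, receivers = NULL) {
  detections <- as.data.frame(detections)
  sections <- as.data.frame(sections)
  req_cols(sections, c("section_id", "n_receivers", "area_ha"), "sections")
  if (anyDuplicated(sections$area_ha))
    stop("sectional areas must be unique (tie-break cascade requires it)")
  if (nrow(detections) == 0L)
    return(data.frame(fish_id = character(), date = as.Date(character()),
                      section_id = character()))
  if (is.null(receivers)) {
    section <- detections$receiver_id
  } else {
    section <- receivers$section_id[match(detections$receiver_id,
                                          receivers$receiver_id)]
  }
  if (any(!section %in% sections$section_id))
    stop("receivers map to unknown sections: ",
         paste(unique(section[!section %in% sections$section_id]),
               collapse = ", "))
  date <- as.Date(as.POSIXct(detections$hour, tz = "UTC"), tz = "UTC")
  tally <- aggregate(detections$n_detections,
                     by = list(fish_id = detections$fish_id, date = date,
                               section_id = section),
                     FUN = sum)
  names(tally)[4] <- "n"
  j <- match(tally$section_id, sections$section_id)
  tally$n_receivers <- sections$n_receivers[j]
  tally$area_ha <- sections$area_ha[j]
  # cascade: most detections, fewest receivers, smallest area
  o <- order(tally$fish_id, tally$date, -tally$n, tally$n_receivers,
             tally$area_ha)
  tally <- tally[o, , drop = FALSE]
  first <- !duplicated(tally[c("fish_id", "date")])
  out <- tally[first, c("fish_id", "date", "section_id")]
  rownames(out) <- NULL
  out[order(out$fish_id, out$date), , drop = FALSE]
}

#' Classify post-release mortalities
#'
#' Acoustically tagged fish that 30 days after release are no longer being
#' detected, or whose entire detection record is confined to a single
#' section, are classified as post-release mortalities (death attributable to
#' capture, handling and surgery) and are excluded from survival analysis.
#' Fish carrying anchor tags only cannot be assessed and are always retained.
#'
#' @param daily daily sectional assignments from
#'   \code{\link{assign_daily_sections}}.
#' @param captures capture records (\code{fish_id}, \code{capture_date},
#'   \code{tag_life_days}).
#' @param window_days length of the post-release assessment window.
#' @return data frame \code{fish_id}, \code{status} with status one of
#'   \code{"retained"} or \code{"post_release_mortality"}.
#' @export
classify_post_release <- function(daily, captures, window_days = 30) {
  captures <- as.data.frame(captures)
  daily <- as.data.frame(daily)
  status <- character(nrow(captures))
  for (k in seq_len(nrow(captures))) {
    if (is.na(captures$tag_life_days[k])) {
      status[k] <- "retained"
      next
    }
    asg <- daily[daily$fish_id == captures$fish_id[k], , drop = FALSE]
    cutoff <- as.Date(captures$capture_date[k]) + window_days
    silent <- !any(asg$date > cutoff)
    single <- length(unique(asg$section_id)) <= 1L
    status[k] <- if (silent || single) "post_release_mortality" else "retained"
  }
  data.frame(fish_id = captures$fish_id, status = status)
}

#' Infer spawning from detection hiatuses and spawning-ground visits
#'
#' Bull Trout leave the main lake to spawn in tributaries, so a spawning
#' event is inferred from a hiatus in detections of at least four weeks
#' overlapping August--September, bracketed by detections. Rainbow Trout
#' spawn at the outflow of Trout Lake: a spawning event is inferred from
#' either a detection at a Trout Lake outflow section during April--May, or a
#' hiatus of three or more weeks overlapping April--May whose bracketing
#' detections both lie in the uppermost sections of the lake.
#'
#' A fish-year is only assessed when the transmitter was active for the whole
#' spawning-season period of that year; otherwise the flag is missing
#' (\code{NA}), not 0.
#'
#' @param daily daily sectional assignments.
#' @param captures capture records (supplies \code{species},
#'   \code{capture_date}, \code{tag_life_days}).
#' @param calendar a \code{\link{period_calendar}}.
#' @param sections section table with logical zone-flag columns
#'   \code{trout_lake_outflow} and \code{upper_north}.
#' @param bt_gap_days,rt_gap_days minimum hiatus lengths (days) for Bull
#'   Trout and Rainbow Trout.
#' @param strict_containment if \code{FALSE} (default) a qualifying hiatus
#'   need only intersect the spawn window; if \code{TRUE} the detection-free
#'   days falling inside the window must themselves reach the threshold.
#' @return data frame \code{fish_id}, \code{year}, \code{spawn} (0, 1 or
#'   \code{NA}) covering every (monitorable fish) x (calendar year).
#' @export
infer_spawning <- function(daily, captures, calendar, sections,
                           bt_gap_days = 28L, rt_gap_days = 21L,
                           strict_containment = FALSE) {
  daily <- as.data.frame(daily)
  captures <- as.data.frame(captures)
  req_cols(sections, c("section_id", "trout_lake_outflow", "upper_north"),
           "sections")
  out <- list()
  years <- sort(unique(calendar$year))
  for (k in seq_len(nrow(captures))) {
    fid <- captures$fish_id[k]
    species <- captures$species[k]
    asg <- daily[daily$fish_id == fid, , drop = FALSE]
    asg <- asg[order(asg$date), , drop = FALSE]
    for (yr in years) {
      sp_period <- calendar[spawn_season_periods(calendar, species) &
                              calendar$year == yr, , drop = FALSE]
      monitored <- !is.na(captures$tag_life_days[k]) &&
        as.Date(captures$capture_date[k]) <= sp_period$start &&
        as.Date(captures$capture_date[k]) + captures$tag_life_days[k] >=
          sp_period$end
      if (!monitored) {
        out[[length(out) + 1L]] <- data.frame(fish_id = fid, year = yr,
                                              spawn = NA_integer_)
        next
      }
      if (species == "BullTrout") {
        win <- c(as.Date(sprintf("%d-08-01", yr)),
                 as.Date(sprintf("%d-09-30", yr)))
        flag <- has_hiatus(asg, win, bt_gap_days, strict_containment)
      } else {
        win <- c(as.Date(sprintf("%d-04-01", yr)),
                 as.Date(sprintf("%d-05-31", yr)))
        outflow <- sections$section_id[sections$trout_lake_outflow]
        visit <- any(asg$section_id %in% outflow &
                       asg$date >= win[1] & asg$date <= win[2])
        upper <- sections$section_id[sections$upper_north]
        flag <- visit || has_hiatus(asg, win, rt_gap_days,
                                    strict_containment, flank = upper)
      }
      out[[length(out) + 1L]] <- data.frame(fish_id = fid, year = yr,
                                            spawn = as.integer(flag))
    }
  }
  do.call(rbind, out)
}

# gap = detection-free days between consecutive assignment dates; qualifies
# if long enough and overlapping the window (optionally: the overlap itself
# must reach the threshold), with both flanking assignments in `flank`
# sections when given
has_hiatus <- function(asg, window, min_days, strict, flank = NULL) {
  if (nrow(asg) < 2L) return(FALSE)
  d <- asg$date
  gap <- as.integer(diff(d)) - 1L
  lo <- d[-length(d)] + 1L   # first detection-free day
  hi <- d[-1L] - 1L          # last detection-free day
  overlap <- pmin(as.integer(hi), as.integer(window[2])) -
    pmax(as.integer(lo), as.integer(window[1])) + 1L
  ok <- if (strict) overlap >= min_days else gap >= min_days & overlap >= 1L
  if (!is.null(flank)) {
    s <- asg$section_id
    ok <- ok & s[-length(s)] %in% flank & s[-1L] %in% flank
  }
  any(ok)
}

#' Build seasonal encounter histories
#'
#' Reduces the per-fish daily record to the seasonal logical matrices the
#' survival model consumes: for every retained fish and every seasonal period
#' from first capture to censoring, whether the fish was monitored (active
#' transmitter for the whole period), moved (detected in two or more
#' sections), was reported recaptured, and its (possibly missing) spawning
#' state, together with its calculated fork length and the standardized year.
#' Periods after a reported recapture are censored: the fish is removed from
#' the analysis from the following period on.
#'
#' @param daily daily sectional assignments.
#' @param captures capture records.
#' @param recaptures data frame \code{fish_id}, \code{date} of reported
#'   angler recaptures.
#' @param statuses output of \code{\link{classify_post_release}}.
#' @param spawn_flags output of \code{\link{infer_spawning}}.
#' @param calendar a \code{\link{period_calendar}}.
#' @param growth named list of \code{\link{growth_params}} per species.
#' @return A long-format data frame of class \code{"encounter_data"} with
#'   columns \code{fish_id}, \code{species}, \code{period}, \code{year},
#'   \code{season}, \code{monitored} (T), \code{moved} (m, \code{NA} when not
#'   monitored), \code{reported} (y), \code{spawned} (x, \code{NA} when
#'   unobserved), \code{spawn_season} (S), \code{length_mm} (calculated fork
#'   length) and \code{year_std} (Y).
#' @export
build_encounter_data <- function(daily, captures, recaptures, statuses,
                                 spawn_flags, calendar,
                                 growth = list(
                                   BullTrout = growth_params("BullTrout"),
                                   RainbowTrout = growth_params("RainbowTrout"))) {
  daily <- as.data.frame(daily)
  captures <- as.data.frame(captures)
  recaptures <- as.data.frame(recaptures)
  retained <- statuses$fish_id[statuses$status == "retained"]
  captures <- captures[captures$fish_id %in% retained, , drop = FALSE]
  K <- max(calendar$period)
  Y <- standardize_year(calendar)
  rows <- list()
  for (k in seq_len(nrow(captures))) {
    fid <- captures$fish_id[k]
    species <- captures$species[k]
    cap_date <- as.Date(captures$capture_date[k])
    f <- date_to_period(cap_date, calendar)
    if (is.na(f)) stop("capture date outside calendar for fish ", fid)
    rec <- recaptures[recaptures$fish_id == fid, , drop = FALSE]
    y_period <- NA_integer_
    if (nrow(rec)) {
      rdate <- min(as.Date(rec$date))
      if (rdate < cap_date)
        stop("recapture before capture for fish ", fid)
      y_period <- date_to_period(rdate, calendar)
      if (is.na(y_period)) y_period <- K  # reported after study end: ignore
    }
    l <- if (!is.na(y_period)) min(y_period, K) else K
    tt <- f:l
    cal_t <- calendar[tt, , drop = FALSE]
    tag_life <- captures$tag_life_days[k]
    monitored <- if (is.na(tag_life)) rep(0L, length(tt)) else
      as.integer(cap_date <= cal_t$start & cap_date + tag_life >= cal_t$end)
    asg <- daily[daily$fish_id == fid, , drop = FALSE]
    asg_period <- date_to_period(asg$date, calendar)
    moved <- vapply(seq_along(tt), function(j) {
      if (!monitored[j]) return(NA_integer_)
      secs <- unique(asg$section_id[!is.na(asg_period) & asg_period == tt[j]])
      as.integer(length(secs) >= 2L)
    }, integer(1))
    reported <- as.integer(!is.na(y_period) & tt == y_period)
    S <- as.integer(spawn_season_periods(calendar, species)[tt])
    x_obs <- rep(NA_integer_, length(tt))
    in_spawn <- S == 1L & monitored == 1L
    if (any(in_spawn)) {
      sf <- spawn_flags[spawn_flags$fish_id == fid, , drop = FALSE]
      x_obs[in_spawn] <- sf$spawn[match(cal_t$year[in_spawn], sf$year)]
    }
    gp <- growth[[species]]
    L_mm <- vb_length(captures$fork_length_mm[k], f, tt, gp)
    rows[[length(rows) + 1L]] <- data.frame(
      fish_id = fid, species = species, period = tt, year = cal_t$year,
      season = cal_t$season, monitored = monitored, moved = moved,
      reported = reported, spawned = x_obs, spawn_season = S,
      length_mm = L_mm, year_std = Y[tt])
  }
  enc <- do.call(rbind, rows)
  rownames(enc) <- NULL
  class(enc) <- c("encounter_data", "data.frame")
  enc
}

#' Audit possible emigration from last-detection patterns
#'
#' Tabulates, by final section and season, the acoustically tagged fish whose
#' last detection precedes the expiry of their transmitter by at least
#' \code{min_remaining_days} and who were never reported recaptured. Fish
#' disappearing well before their transmitter died, at the edges of the
#' receiver array, are candidate emigrants.
#'
#' @param daily daily sectional assignments.
#' @param captures capture records.
#' @param recaptures reported recaptures.
#' @param calendar a \code{\link{period_calendar}}.
#' @param min_remaining_days minimum transmitter life remaining at last
#'   detection.
#' @return data frame with one row per section that had qualifying fish and
#'   columns \code{section_id}, \code{winter}, \code{spring}, \code{summer},
#'   \code{autumn} (counts).
#' @export
emigration_audit <- function(daily, captures, recaptures, calendar,
                             min_remaining_days = 120) {
  daily <- as.data.frame(daily)
  captures <- as.data.frame(captures)
  acoustic <- captures[!is.na(captures$tag_life_days), , drop = FALSE]
  seasons <- c("winter", "spring", "summer", "autumn")
  hits <- list()
  for (k in seq_len(nrow(acoustic))) {
    fid <- acoustic$fish_id[k]
    if (fid %in% recaptures$fish_id) next
    asg <- daily[daily$fish_id == fid, , drop = FALSE]
    if (!nrow(asg)) next
    last <- asg[which.max(asg$date), , drop = FALSE]
    expiry <- as.Date(acoustic$capture_date[k]) + acoustic$tag_life_days[k]
    if (as.integer(expiry - last$date) < min_remaining_days) next
    p <- date_to_period(last$date, calendar)
    hits[[length(hits) + 1L]] <- data.frame(
      section_id = last$section_id,
      season = as.character(calendar$season[match(p, calendar$period)]))
  }
  if (!length(hits)) {
    out <- data.frame(section_id = character())
    out[seasons] <- integer(0)
    return(out)
  }
  hits <- do.call(rbind, hits)
  tab <- table(hits$section_id, factor(hits$season, levels = seasons))
  out <- data.frame(section_id = rownames(tab),
                    as.data.frame.matrix(tab), row.names = NULL)
  names(out) <- c("section_id", seasons)
  out
}

req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
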