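#' Simulation design
#'
#' Describes a synthetic tag-telemetry study with the structure the analysis
#' assumes: multi-year releases of large fish, acoustic transmitters with
#' finite tag lives in the early years and anchor-tag-only cohorts in the
#' final two, quarterly seasonal periods, species-specific spawning seasons,
#' and known generating coefficients. Defaults mirror the study conditions:
#' releases 2008--2013 (Bull Trout 0/22/26/21/13/6, Rainbow Trout
#' 18/31/29/36/26/9 per year), transmitter lives of 455 days in the pilot
#' year and 830 or 1,239 days afterwards, anchor tags only in 2012--2013,
#' and coefficient values of the magnitude reported for the study
#' populations.
#'
#' @param species \code{"BullTrout"} or \code{"RainbowTrout"}.
#' @param years release/calendar years.
#' @param n_per_year releases per year (recycled to \code{length(years)}).
#' @param acoustic_years years whose releases carry transmitters.
#' @param tag_life_days candidate transmitter lives (days) for non-pilot
#'   years; the pilot (first) year always uses 455 days. A single large
#'   value keeps fish monitored throughout.
#' @param beta true coefficients (named as \code{\link{cjs_coef_names}}).
#' @param gamma true indicators (named as \code{\link{cjs_indicator_names}});
#'   coefficients with indicator 0 are zeroed in the generative model.
#' @param p_post_release fraction of acoustically tagged fish planted as
#'   post-release mortalities (raw-telemetry level only). Defaults to the
#'   observed 7% (Bull Trout) or 25% (Rainbow Trout).
#' @param p_spawn_planted probability a monitored fish-year is planted as a
#'   spawning event in the raw-telemetry generator.
#' @param n_sections number of lake sections.
#' @param n_noise spurious detection rows (hourly counts of 1--2) added to
#'   the raw bundle.
#' @param n_late detection rows dated past transmitter life added to the raw
#'   bundle.
#' @return list of class \code{"sim_design"}, including the
#'   \code{\link{period_calendar}} and a section table.
#' @export
sim_design <- function(species = c("BullTrout", "RainbowTrout"),
                       years = 2008:2013,
                       n_per_year = NULL,
                       acoustic_years = 2008:2011,
                       tag_life_days = c(1239, 830),
                       beta = NULL, gamma = NULL,
                       p_post_release = NULL,
                       p_spawn_planted = 0.5,
                       n_sections = 30L,
                       n_noise = 200L, n_late = 20L) {
  species <- match.arg(species)
  if (is.null(n_per_year))
    n_per_year <- if (species == "BullTrout") c(0, 22, 26, 21, 13, 6)
                  else c(18, 31, 29, 36, 26, 9)
  n_per_year <- rep_len(n_per_year, length(years))
  if (is.null(beta))
    beta <- if (species == "BullTrout")
      c(beta_phi0 = 2.728, beta_phix = 0.33, beta_phiY = -0.982,
        beta_rho0 = -3.065, beta_rhoY = 0,
        beta_delta0 = 2.358, beta_deltaS = -2.399, beta_deltaY = -0.373,
        beta_kappa0 = 2.429, beta_kappaL = 1.147, beta_kappaY = 0)
    else
      c(beta_phi0 = 2.697, beta_phix = -2.671, beta_phiY = -0.468,
        beta_rho0 = -3.289, beta_rhoY = 0,
        beta_delta0 = 2.975, beta_deltaS = 0, beta_deltaY = 0,
        beta_kappa0 = 0.16, beta_kappaL = 4.457, beta_kappaY = -2.153)
  if (is.null(gamma))
    gamma <- if (species == "BullTrout")
      c(gamma_phix = 0, gamma_phiY = 1, gamma_rhoY = 0,
        gamma_deltaS = 1, gamma_deltaY = 1, gamma_kappaL = 1,
        gamma_kappaY = 0)
    else
      c(gamma_phix = 1, gamma_phiY = 1, gamma_rhoY = 0,
        gamma_deltaS = 0, gamma_deltaY = 0, gamma_kappaL = 1,
        gamma_kappaY = 1)
  if (is.null(p_post_release))
    p_post_release <- if (species == "BullTrout") 0.07 else 0.25
  calendar <- period_calendar(min(years), max(years))
  structure(list(species = species, years = years, n_per_year = n_per_year,
                 acoustic_years = acoustic_years,
                 tag_life_days = tag_life_days,
                 beta = check_beta(beta), gamma = check_gamma(gamma),
                 growth = growth_params(species),
                 p_post_release = p_post_release,
                 p_spawn_planted = p_spawn_planted,
                 calendar = calendar,
                 sections = default_sections(n_sections),
                 n_noise = n_noise, n_late = n_late),
            class = "sim_design")
}

# 30 sections: S02 is the Trout Lake outflow, S07-S09 the top of the lake,
# the rest the main lake; receiver counts 1-3, unique areas
default_sections <- function(n_sections = 30L) {
  ids <- sprintf("S%02d", seq_len(n_sections) + 1L)  # S02..S31
  data.frame(section_id = ids,
             n_receivers = rep_len(c(1L, 2L, 3L), n_sections),
             area_ha = 1000 + 17 * seq_len(n_sections),
             trout_lake_outflow = ids == "S02",
             upper_north = ids %in% c("S07", "S08", "S09"))
}

main_lake_sections <- function(sections) {
  sections$section_id[!sections$trout_lake_outflow & !sections$upper_north]
}

# capture attributes shared by both generators
sim_captures <- function(design) {
  rows <- list()
  fish <- 0L
  for (k in seq_along(design$years)) {
    nk <- design$n_per_year[k]
    if (nk == 0) next
    yr <- design$years[k]
    acoustic <- yr %in% design$acoustic_years
    for (j in seq_len(nk)) {
      fish <- fish + 1L
      cap <- as.Date(sprintf("%d-01-01", yr)) +
        sample.int(270L, 1L)  # Jan-Sep release
      tl <- if (!acoustic) NA_integer_ else if (k == 1L) 455L else
        sample(rep_len(as.integer(design$tag_life_days), 2L), 1L)
      rows[[fish]] <- data.frame(
        fish_id = sprintf("%s%03d", substr(design$species, 1, 2), fish),
        species = design$species, capture_date = cap,
        fork_length_mm = round(stats::runif(1, 500, 850)),
        tag_life_days = tl, reward1 = 100, reward2 = 10,
        release_section = sample(main_lake_sections(design$sections), 1L))
    }
  }
  do.call(rbind, rows)
}

#' Simulate seasonal encounter histories from the generative model
#'
#' Draws latent alive states, spawning states, movement detections and
#' angler recaptures period by period from the model's Bernoulli structure
#' (coefficients with indicator 0 contribute nothing), applies recapture
#' censoring, and returns both the encounter data and the generating truth.
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed integer seed.
#' @return An \code{encounter_data} data frame with attribute \code{"truth"}
#'   (list with the generating \code{beta}, \code{gamma}, and the per-fish
#'   alive matrix \code{z}).
#' @export
simulate_encounters <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(as.integer(seed))
  caps <- sim_captures(design)
  cal <- design$calendar
  K <- max(cal$period)
  Ystd <- standardize_year(cal)
  Sflag <- spawn_season_periods(cal, design$species)
  beta <- design$beta
  beta[cjs_indicator_map()] <- beta[cjs_indicator_map()] * design$gamma
  rows <- list()
  zmat <- matrix(NA_integer_, nrow(caps), K, dimnames = list(caps$fish_id,
                                                             NULL))
  for (i in seq_len(nrow(caps))) {
    f <- date_to_period(caps$capture_date[i], cal)
    tl <- caps$tag_life_days[i]
    mon <- if (is.na(tl)) rep(0L, K) else
      as.integer(caps$capture_date[i] <= cal$start &
                   caps$capture_date[i] + tl >= cal$end)
    FL <- vb_length(caps$fork_length_mm[i], f, f:K, design$growth)
    z <- 1L
    for (t in f:K) {
      zmat[i, t] <- z
      p <- linear_predictors(beta, L = length_covariate(FL[t - f + 1]),
                             Y = Ystd[t], S = as.numeric(Sflag[t]), x = 0)
      # observation layers and the spawning process start after release
      x <- if (Sflag[t] && t > f) stats::rbinom(1, 1, z * p$kappa) else 0L
      if (x == 1L)  # spawning-season survival uses the spawning state
        p$phi <- stats::plogis(stats::qlogis(p$phi) + beta["beta_phix"])
      y <- if (t > f) stats::rbinom(1, 1, z * p$rho) else 0L
      m <- if (mon[t] == 1L && t > f) stats::rbinom(1, 1, z * p$delta)
           else NA_integer_
      x_obs <- if (Sflag[t] && mon[t] == 1L && t > f) as.integer(x)
               else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = caps$fish_id[i], species = design$species, period = t,
        year = cal$year[t], season = cal$season[t], monitored = mon[t],
        moved = m, reported = y, spawned = x_obs,
        spawn_season = as.integer(Sflag[t]), length_mm = FL[t - f + 1],
        year_std = Ystd[t])
      if (y == 1L) break  # censored after a reported recapture
      if (t < K) z <- stats::rbinom(1, 1, z * p$phi)
    }
  }
  enc <- do.call(rbind, rows)
  rownames(enc) <- NULL
  class(enc) <- c("encounter_data", "data.frame")
  attr(enc, "truth") <- list(beta = beta, gamma = design$gamma, z = zmat,
                             captures = caps)
  enc
}

# redraw observations for an existing design (posterior-predictive use)
simulate_from_design <- function(data, beta) {
  data <- as_cjs_data(data)
  beta <- check_beta(beta)
  rows <- list()
  for (i in seq_len(data$n)) {
    f <- data$first[i]; l <- data$last[i]
    z <- 1L
    for (t in f:data$K) {
      if (t > l && is.na(data$S[i, t])) break  # outside original record
      if (t > l) break
      S <- data$S[i, t]
      p <- linear_predictors(beta, L = data$L[i, t], Y = data$Y[i, t],
                             S = S, x = 0)
      x <- if (S == 1L && t > f) stats::rbinom(1, 1, z * p$kappa) else 0L
      if (x == 1L)
        p$phi <- stats::plogis(stats::qlogis(p$phi) + beta["beta_phix"])
      y <- if (t > f) stats::rbinom(1, 1, z * p$rho) else 0L
      mon <- data$Tmat[i, t]
      m <- if (mon == 1L && t > f) stats::rbinom(1, 1, z * p$delta)
           else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = data$fish_id[i], period = t, monitored = mon, moved = m,
        reported = y,
        spawned = if (S == 1L && mon == 1L && t > f) as.integer(x)
                  else NA_integer_,
        spawn_season = S, length_mm = data$L[i, t] * 100 + 600,
        year_std = data$Y[i, t])
      if (y == 1L) break
      if (t < l) z <- stats::rbinom(1, 1, z * p$phi)
    }
  }
  enc <- do.call(rbind, rows)
  rownames(enc) <- NULL
  class(enc) <- c("encounter_data", "data.frame")
  enc
}

#' Simulate a raw telemetry bundle
#'
#' Emulates the study at the raw-data level: daily section occupancy with
#' period-level movement, hourly detection counts while alive and within
#' transmitter life, planted post-release failures (silent or
#' single-section from day 0), planted species-specific spawning signatures
#' (a four-week August--September hiatus for Bull Trout; a Trout Lake
#' outflow visit or a bracketed three-week April--May hiatus for Rainbow
#' Trout), spurious rows with hourly counts of 1--2, and detections dated
#' past transmitter life. The bundle is exactly what the reduction pipeline
#' reads; a ground-truth sidecar carries the planted labels and the true
#' seasonal matrices for round-trip testing.
#'
#' Natural deaths are kept clear of the 30-day post-release window and every
#' healthy fish moves in its first full period, so the planted post-release
#' labels are unambiguous.
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed integer seed.
#' @return list with data frames \code{detections}, \code{captures},
#'   \code{recaptures}, \code{sections}, \code{receivers} and a
#'   \code{truth} list (per-fish \code{status}, \code{spawn} flags by year,
#'   and the true \code{encounters} matrices in long format).
#' @export
simulate_telemetry <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(as.integer(seed))
  caps <- sim_captures(design)
  cal <- design$calendar
  K <- max(cal$period)
  sections <- design$sections
  lake <- main_lake_sections(sections)
  receivers <- do.call(rbind, lapply(seq_len(nrow(sections)), function(s)
    data.frame(receiver_id = sprintf("%s_R%d", sections$section_id[s],
                                     seq_len(sections$n_receivers[s])),
               section_id = sections$section_id[s])))
  Sflag <- spawn_season_periods(cal, design$species)
  beta <- design$beta
  beta[cjs_indicator_map()] <- beta[cjs_indicator_map()] * design$gamma
  Ystd <- standardize_year(cal)

  det <- list(); recap <- list(); truth_enc <- list()
  status <- character(nrow(caps)); spawn_truth <- list()
  study_end <- max(cal$end)

  for (i in seq_len(nrow(caps))) {
    fid <- caps$fish_id[i]
    cap_date <- caps$capture_date[i]
    tl <- caps$tag_life_days[i]
    acoustic <- !is.na(tl)
    f <- date_to_period(cap_date, cal)
    expiry <- if (acoustic) cap_date + tl else study_end

    # planted post-release failure (acoustic fish only)
    fail <- acoustic && stats::runif(1) < design$p_post_release
    if (fail) {
      status[i] <- "post_release_mortality"
      if (stats::runif(1) < 0.5) {  # single-section trickle, then silence
        home <- caps$release_section[i]
        days <- cap_date + sort(sample.int(25L, 8L))
        days <- days[days < expiry & days <= study_end]
        for (dd in days)
          det[[length(det) + 1L]] <- emit_day(fid, as.Date(dd, origin = "1970-01-01"),
                                              home, receivers)
      }  # else silent: no detections at all
      next
    }
    status[i] <- "retained"

    # period-level truth: death, recapture, movement, spawning
    FL <- vb_length(caps$fork_length_mm[i], f, f:K, design$growth)
    death_period <- K + 1L
    y_period <- NA_integer_
    moved_t <- rep(FALSE, K)
    spawn_yr <- list()
    for (t in f:K) {
      p <- linear_predictors(beta, L = length_covariate(FL[t - f + 1]),
                             Y = Ystd[t], S = as.numeric(Sflag[t]), x = 0)
      mon_full <- acoustic && cap_date <= cal$start[t] && expiry >= cal$end[t]
      x <- 0L
      if (Sflag[t] && mon_full) {
        x <- stats::rbinom(1, 1, design$p_spawn_planted)
        spawn_yr[[length(spawn_yr) + 1L]] <-
          data.frame(fish_id = fid, year = cal$year[t], spawn = x)
      }
      if (x == 1L)
        p$phi <- stats::plogis(stats::qlogis(p$phi) + beta["beta_phix"])
      moved_t[t] <- stats::rbinom(1, 1, p$delta) == 1L
      # the first two record periods always show movement, so planted
      # post-release labels stay unambiguous under the 30-day rule
      if (t <= f + 1L) moved_t[t] <- TRUE
      # no recaptures during the release period or while away spawning
      if (t > f && x == 0L && stats::rbinom(1, 1, p$rho) == 1L) {
        y_period <- t
        break
      }
      # natural deaths never occur in the first transition, keeping them
      # clear of the post-release assessment window
      if (t < K && t > f && stats::rbinom(1, 1, p$phi) == 0L) {
        death_period <- t + 1L
        break
      }
    }
    l <- if (!is.na(y_period)) y_period else min(death_period - 1L, K)

    # daily plan: home section per period, with a mid-period switch on moves
    end_date <- if (!is.na(y_period)) {
      d1r <- max(cal$start[y_period], cap_date + 45L)
      d1r + sample.int(max(as.integer(cal$end[y_period] - d1r), 1L), 1L) - 1L
    } else if (death_period <= K) {
      dper <- death_period
      d0 <- max(cal$start[dper], cap_date + 45L)  # clear of the 30-day window
      d0 + sample.int(max(as.integer(cal$end[dper] - d0), 1L), 1L) - 1L
    } else study_end
    home <- caps$release_section[i]
    plan <- list()
    for (t in f:l) {
      d1 <- max(cal$start[t], cap_date + 1L)
      d2 <- min(cal$end[t], end_date)
      if (d1 > d2) next
      days <- seq(d1, d2, by = "day")
      sec <- rep(home, length(days))
      if (isTRUE(moved_t[t]) && length(days) >= 2L) {
        other <- sample(setdiff(lake, home), 1L)
        cut <- sample.int(length(days) - 1L, 1L)
        sec[(cut + 1L):length(days)] <- other
        home <- other
      }
      plan[[length(plan) + 1L]] <- data.frame(date = days, section = sec,
                                              period = t)
    }
    plan <- do.call(rbind, plan)

    # plant the spawning signature
    if (length(spawn_yr)) {
      sp <- do.call(rbind, spawn_yr)
      for (r in seq_len(nrow(sp))) {
        if (sp$spawn[r] != 1L) next
        yr <- sp$year[r]
        if (design$species == "BullTrout") {
          gap <- c(as.Date(sprintf("%d-08-05", yr)),
                   as.Date(sprintf("%d-09-12", yr)))  # 39 detection-free days
          plan <- plan[!(plan$date >= gap[1] & plan$date <= gap[2]), ,
                       drop = FALSE]
        } else if (stats::runif(1) < 0.5) {  # outflow visit route
          visit <- as.Date(sprintf("%d-05-03", yr))
          plan$section[plan$date >= visit & plan$date <= visit + 2] <- "S02"
        } else {  # bracketed hiatus route
          gap <- c(as.Date(sprintf("%d-04-20", yr)),
                   as.Date(sprintf("%d-05-18", yr)))  # 27 detection-free days
          plan$section[plan$date %in% (gap + c(-1L, 1L))] <- "S08"
          plan <- plan[!(plan$date >= gap[1] & plan$date <= gap[2]), ,
                       drop = FALSE]
        }
      }
      spawn_truth[[length(spawn_truth) + 1L]] <- sp
    }

    # emissions (only while the transmitter lives; the expiry day itself is
    # excluded so every emitted hour precedes the tag-life cutoff)
    if (acoustic && nrow(plan)) {
      emit <- plan[plan$date < expiry, , drop = FALSE]
      for (r in seq_len(nrow(emit)))
        det[[length(det) + 1L]] <- emit_day(fid, emit$date[r],
                                            emit$section[r], receivers)
    }

    if (!is.na(y_period))
      recap[[length(recap) + 1L]] <- data.frame(
        fish_id = fid, date = end_date, tags_returned = "100;10")

    # true seasonal matrices (same definitions the builder applies)
    t_hi <- if (!is.na(y_period)) y_period else K
    for (t in f:t_hi) {
      mon_full <- acoustic && cap_date <= cal$start[t] && expiry >= cal$end[t]
      secs <- unique(plan$section[plan$period == t & plan$date < expiry])
      truth_enc[[length(truth_enc) + 1L]] <- data.frame(
        fish_id = fid, period = t,
        monitored = as.integer(mon_full),
        moved = if (mon_full) as.integer(length(secs) >= 2L) else NA_integer_,
        reported = as.integer(!is.na(y_period) && t == y_period))
    }
  }

  detections <- do.call(rbind, det)
  # spurious sub-threshold rows, within each fish's valid window
  if (design$n_noise > 0 && nrow(caps)) {
    ac <- caps[!is.na(caps$tag_life_days), , drop = FALSE]
    if (nrow(ac)) {
      pick <- sample.int(nrow(ac), design$n_noise, replace = TRUE)
      offs <- vapply(pick, function(k)
        sample.int(min(ac$tag_life_days[k],
                       as.integer(study_end - ac$capture_date[k]) + 1L), 1L),
        integer(1))
      noise <- data.frame(
        fish_id = ac$fish_id[pick],
        receiver_id = sample(receivers$receiver_id, design$n_noise,
                             replace = TRUE),
        hour = as.POSIXct(ac$capture_date[pick], tz = "UTC") +
          offs * 86400 + sample(0:23, design$n_noise, replace = TRUE) * 3600,
        n_detections = sample(1:2, design$n_noise, replace = TRUE))
      detections <- rbind(detections, noise)
    }
  }
  # detections dated past transmitter life (to be filtered)
  if (design$n_late > 0) {
    ac <- caps[!is.na(caps$tag_life_days), , drop = FALSE]
    if (nrow(ac)) {
      pick <- sample.int(nrow(ac), design$n_late, replace = TRUE)
      late <- data.frame(
        fish_id = ac$fish_id[pick],
        receiver_id = sample(receivers$receiver_id, design$n_late,
                             replace = TRUE),
        hour = as.POSIXct(ac$capture_date[pick] + ac$tag_life_days[pick],
                          tz = "UTC") + sample(86400 * (2:30), design$n_late,
                                               replace = TRUE),
        n_detections = 3L + stats::rpois(design$n_late, 4))
      detections <- rbind(detections, late)
    }
  }
  rownames(detections) <- NULL
  list(detections = detections, captures = caps,
       recaptures = if (length(recap)) do.call(rbind, recap) else
         data.frame(fish_id = character(), date = as.Date(character()),
                    tags_returned = character()),
       sections = sections, receivers = receivers,
       truth = list(
         status = data.frame(fish_id = caps$fish_id, status = status),
         spawn = if (length(spawn_truth)) do.call(rbind, spawn_truth) else
           NULL,
         encounters = do.call(rbind, truth_enc)))
}

# one day's worth of hourly detection rows for a fish in a section
emit_day <- function(fish_id, date, section, receivers) {
  rec <- receivers$receiver_id[receivers$section_id == section]
  hours <- sort(sample(0:23, sample(2:4, 1L)))
  data.frame(fish_id = fish_id,
             receiver_id = sample(rec, length(hours), replace = TRUE),
             hour = as.POSIXct(date, tz = "UTC") + hours * 3600,
             n_detections = 3L + stats::rpois(length(hours), 4))
}
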