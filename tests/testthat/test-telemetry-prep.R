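captures_fixture <- function() {
  data.frame(fish_id = c("F1", "F2", "F3"),
             species = "BullTrout",
             capture_date = as.Date(c("2009-05-01", "2009-06-15",
                                      "2010-04-01")),
             fork_length_mm = c(620, 700, 550),
             tag_life_days = c(455L, 1239L, NA),
             reward1 = 100, reward2 = 10,
             release_section = c("S10", "S11", "S12"))
}

sections_fixture <- function() {
  data.frame(section_id = c("S02", "S08", "S10", "S11", "S12"),
             n_receivers = c(1L, 2L, 2L, 1L, 1L),
             area_ha = c(100, 400, 900, 800, 700),
             trout_lake_outflow = c(TRUE, FALSE, FALSE, FALSE, FALSE),
             upper_north = c(FALSE, TRUE, FALSE, FALSE, FALSE))
}

det_row <- function(fish, rec, hour, n) {
  data.frame(fish_id = fish, receiver_id = rec,
             hour = as.POSIXct(hour, tz = "UTC"), n_detections = n)
}

test_that("hourly filtering drops sparse and post-tag-life records", {
  caps <- captures_fixture()
  det <- rbind(
    det_row("F1", "S10", "2009-05-02 01:00:00", 2),   # sparse
    det_row("F1", "S10", "2009-05-02 02:00:00", 1),   # sparse
    det_row("F2", "S11", "2009-06-16 03:00:00", 2),   # sparse
    det_row("F1", "S10", "2011-05-02 04:00:00", 9),   # past 455 d tag life
    det_row("F1", "S10", "2009-05-03 05:00:00", 3),
    det_row("F1", "S11", "2009-05-04 06:00:00", 7),
    det_row("F2", "S11", "2009-06-17 07:00:00", 3),
    det_row("F2", "S10", "2009-06-18 08:00:00", 12),
    det_row("F2", "S11", "2009-06-19 09:00:00", 4),
    det_row("F1", "S10", "2009-05-05 10:00:00", 5))
  out <- filter_hourly(det, caps)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$n_detections >= 3))
  # a record with exactly two detections is discarded
  expect_false(any(out$hour == as.POSIXct("2009-05-02 01:00:00",
                                          tz = "UTC")))
  # empty input is the identity
  expect_equal(nrow(filter_hourly(det[0, ], caps)), 0L)
})

test_that("hourly filtering rejects malformed inputs", {
  caps <- captures_fixture()
  expect_error(filter_hourly(det_row("NOPE", "S10",
                                     "2009-05-02 01:00:00", 5), caps),
               "unknown fish.*NOPE")
  expect_error(filter_hourly(det_row("F1", "S10",
                                     "2009-04-01 01:00:00", 5), caps),
               "before capture")
  # detections of a fish without a transmitter are impossible
  expect_error(filter_hourly(det_row("F3", "S10",
                                     "2010-05-01 01:00:00", 5), caps),
               "without an acoustic transmitter")
})

test_that("daily assignment resolves multi-section days by the cascade", {
  secs <- sections_fixture()
  # most detections wins
  det <- rbind(det_row("F1", "S10", "2009-05-02 01:00:00", 5),
               det_row("F1", "S11", "2009-05-02 02:00:00", 3))
  out <- assign_daily_sections(det, secs)
  expect_equal(out$section_id, "S10")
  # tie on detections: fewest receivers wins (S11 has 1 vs S10's 2)
  det <- rbind(det_row("F1", "S10", "2009-05-02 01:00:00", 4),
               det_row("F1", "S11", "2009-05-02 02:00:00", 4))
  expect_equal(assign_daily_sections(det, secs)$section_id, "S11")
  # tie on both: smallest area wins (S12 700 < S11 800)
  det <- rbind(det_row("F1", "S12", "2009-05-02 01:00:00", 4),
               det_row("F1", "S11", "2009-05-02 02:00:00", 4))
  expect_equal(assign_daily_sections(det, secs)$section_id, "S12")
  # single-section day is that section; one assignment per fish-day
  det <- rbind(det_row("F1", "S10", "2009-05-02 01:00:00", 3),
               det_row("F1", "S10", "2009-05-03 01:00:00", 3),
               det_row("F2", "S11", "2009-05-02 01:00:00", 3))
  out <- assign_daily_sections(det, secs)
  expect_equal(nrow(out), 3L)
  expect_equal(anyDuplicated(out[c("fish_id", "date")]), 0L)
  # duplicated areas break the cascade guarantee
  bad <- secs
  bad$area_ha[2] <- bad$area_ha[1]
  expect_error(assign_daily_sections(det, bad), "unique")
})

test_that("receiver table maps receivers to sections", {
  secs <- sections_fixture()
  recv <- data.frame(receiver_id = c("R1", "R2"),
                     section_id = c("S10", "S11"))
  det <- rbind(det_row("F1", "R1", "2009-05-02 01:00:00", 5),
               det_row("F1", "R2", "2009-05-02 02:00:00", 3))
  expect_equal(assign_daily_sections(det, secs, recv)$section_id, "S10")
  expect_error(assign_daily_sections(det_row("F1", "RX",
                                             "2009-05-02 01:00:00", 5),
                                     secs, recv), "unknown sections")
})

test_that("post-release classification applies both clauses", {
  caps <- captures_fixture()
  daily <- data.frame(
    fish_id = c(rep("F1", 3), rep("F2", 3)),
    date = as.Date(c("2009-05-10", "2009-06-20", "2009-07-29",  # 3 sections
                     "2009-06-20", "2009-07-25", "2009-08-30")),
    section_id = c("S10", "S11", "S12", "S11", "S11", "S11"))
  st <- classify_post_release(daily, caps)
  expect_equal(st$status[st$fish_id == "F1"], "retained")
  # F2 detected well past 30 days but only ever in one section
  expect_equal(st$status[st$fish_id == "F2"], "post_release_mortality")
  # anchor-only fish cannot be assessed and are retained
  expect_equal(st$status[st$fish_id == "F3"], "retained")
  # a silent fish (no assignments at all) is a mortality
  st2 <- classify_post_release(daily[daily$fish_id == "F2", ],
                               caps[caps$fish_id == "F1", ])
  expect_equal(st2$status, "post_release_mortality")
})

test_that("spawning inference detects hiatuses and outflow visits", {
  cal <- period_calendar(2009, 2009)
  secs <- sections_fixture()
  bt_cap <- data.frame(fish_id = "B1", species = "BullTrout",
                       capture_date = as.Date("2009-03-01"),
                       fork_length_mm = 650, tag_life_days = 1239L)
  # detected daily all summer: no spawning
  daily <- data.frame(fish_id = "B1",
                      date = seq(as.Date("2009-03-02"),
                                 as.Date("2009-10-30"), by = "day"),
                      section_id = "S10")
  sp <- infer_spawning(daily, bt_cap, cal, secs)
  expect_equal(sp$spawn[sp$year == 2009], 0L)
  # a 30-day August hiatus with bracketing detections is a spawning event
  gap <- daily$date >= as.Date("2009-08-05") & daily$date <=
    as.Date("2009-09-05")
  sp <- infer_spawning(daily[!gap, ], bt_cap, cal, secs)
  expect_equal(sp$spawn[sp$year == 2009], 1L)
  # Rainbow Trout: a single outflow (S02) visit in May flags spawning
  rt_cap <- bt_cap
  rt_cap$species <- "RainbowTrout"
  visit <- daily
  visit$section_id[visit$date == as.Date("2009-05-03")] <- "S02"
  sp <- infer_spawning(visit, rt_cap, cal, secs)
  expect_equal(sp$spawn[sp$year == 2009], 1L)
  # Rainbow Trout hiatus route requires upper-lake flanking detections
  gap_rt <- daily$date >= as.Date("2009-04-20") & daily$date <=
    as.Date("2009-05-18")
  flanked <- daily[!gap_rt, ]
  sp <- infer_spawning(flanked, rt_cap, cal, secs)
  expect_equal(sp$spawn[sp$year == 2009], 0L)  # flanks in main lake
  flanked$section_id[flanked$date %in% as.Date(c("2009-04-19",
                                                 "2009-05-19"))] <- "S08"
  sp <- infer_spawning(flanked, rt_cap, cal, secs)
  expect_equal(sp$spawn[sp$year == 2009], 1L)
  # unmonitored fish-years are missing, not 0
  short_cap <- bt_cap
  short_cap$tag_life_days <- 30L
  sp <- infer_spawning(daily, short_cap, cal, secs)
  expect_true(is.na(sp$spawn[sp$year == 2009]))
})

test_that("encounter building censors, detects movement and errors", {
  cal <- period_calendar(2009, 2010)
  caps <- captures_fixture()[1:2, ]
  caps$capture_date <- as.Date(c("2009-01-01", "2009-05-01"))
  caps$tag_life_days <- c(4000L, 4000L)
  daily <- data.frame(
    fish_id = c("F1", "F1", "F1", "F2", "F2"),
    date = as.Date(c("2009-03-01", "2009-05-10", "2009-05-20",
                     "2009-08-10", "2009-08-20")),
    section_id = c("S10", "S10", "S11", "S11", "S11"))
  recaps <- data.frame(fish_id = "F1", date = as.Date("2009-08-15"),
                       tags_returned = "100;10")
  st <- data.frame(fish_id = c("F1", "F2"), status = "retained")
  sp <- data.frame(fish_id = character(), year = integer(),
                   spawn = integer())
  enc <- build_encounter_data(daily, caps, recaps, st, sp, cal)
  f1 <- enc[enc$fish_id == "F1", ]
  # recaptured in period 3 (summer 2009): rows end there, y = 1 there only
  expect_equal(f1$period, 1:3)
  expect_equal(f1$reported, c(0L, 0L, 1L))
  # moved in spring (two sections), not in winter
  expect_equal(f1$moved[f1$period == 2], 1L)
  expect_equal(f1$moved[f1$period == 1], 0L)
  # uncensored fish runs to the end of the calendar
  f2 <- enc[enc$fish_id == "F2", ]
  expect_equal(max(f2$period), max(cal$period))
  expect_equal(f2$moved[f2$period == 3], 0L)  # one section visited
  # monitored only in periods fully covered by the transmitter
  expect_equal(f2$monitored[f2$period == 2], 0L)  # released mid-period
  expect_equal(f2$monitored[f2$period == 3], 1L)
  # recapture before capture is rejected
  bad <- recaps
  bad$date <- as.Date("2008-12-20")
  expect_error(build_encounter_data(daily, caps, bad, st, sp, cal),
               "recapture before capture")
  # post-release mortalities are excluded
  st2 <- st
  st2$status[1] <- "post_release_mortality"
  enc2 <- build_encounter_data(daily, caps, recaps, st2, sp, cal)
  expect_false("F1" %in% enc2$fish_id)
})

test_that("emigration audit counts early disappearances only", {
  cal <- period_calendar(2009, 2010)
  caps <- data.frame(fish_id = c("E1", "E2", "E3"),
                     species = "BullTrout",
                     capture_date = as.Date("2009-02-01"),
                     fork_length_mm = 650,
                     tag_life_days = c(455L, 455L, 455L))
  daily <- data.frame(
    fish_id = c("E1", "E2", "E3"),
    date = as.Date(c("2009-05-10",   # 455-d tag dies 2010-05-01: >120 d left
                     "2010-04-25",   # only 6 days of tag life left
                     "2009-06-10")), # early, but recaptured afterwards
    section_id = c("S08", "S10", "S10"))
  recaps <- data.frame(fish_id = "E3", date = as.Date("2009-07-01"),
                       tags_returned = "100")
  aud <- emigration_audit(daily, caps, recaps, cal)
  expect_equal(sum(aud[c("winter", "spring", "summer", "autumn")]), 1L)
  expect_equal(aud$section_id, "S08")
  expect_equal(aud$spring, 1L)
})
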