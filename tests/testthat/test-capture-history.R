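test_that("effort counts trap-days with half-open daily bins and no double counting", {
  intervals <- tibble::tibble(
    site_id = "B04",
    start_date = as.Date("2011-01-01"),
    end_date = as.Date("2011-01-10"))
  bins <- make_time_bins("2011-01-01", "2011-01-10", by = "day")
  eff <- build_effort(intervals, bins)
  expect_equal(nrow(eff), 10L)
  expect_true(all(eff$trap_days == 1L))

  # two overlapping intervals on one site count each day once
  overlap <- tibble::tibble(
    site_id = "B04",
    start_date = as.Date(c("2011-01-01", "2011-01-05")),
    end_date = as.Date(c("2011-01-07", "2011-01-10")))
  eff2 <- build_effort(overlap, bins)
  expect_equal(sum(eff2$trap_days), 10L)

  # effort is invariant under splitting an interval into contiguous pieces
  split_iv <- tibble::tibble(
    site_id = "B04",
    start_date = as.Date(c("2011-01-01", "2011-01-06")),
    end_date = as.Date(c("2011-01-05", "2011-01-10")))
  monthly <- make_time_bins("2011-01-01", "2011-01-31", by = "month")
  expect_equal(build_effort(split_iv, monthly)$trap_days,
               build_effort(intervals, monthly)$trap_days)
})

test_that("a 225-site survey yields one effort row per site and bin", {
  sites <- sprintf("S%03d", 1:225)
  intervals <- tibble::tibble(
    site_id = sites,
    start_date = as.Date("2012-01-01"),
    end_date = as.Date("2012-03-31"))
  eff <- build_effort(intervals,
                      make_time_bins("2012-01-01", "2012-03-31", "month"))
  expect_equal(length(unique(eff$site_id)), 225L)
  expect_equal(nrow(eff), 225L * 3L)
  expect_equal(unique(eff$trap_days[eff$bin_id == "2012-02-01"]), 29L)
})

history_fixture <- function() {
  scenes <- generate_scenes(40, sim_config(blank_fraction = 0), seed = 12)
  pool <- volunteer_profiles(20, accuracy = 1, blank_propensity = 0,
                             count_slip = 0, behaviour_error = 0)
  raw <- generate_classifications(scenes, pool, per_event_n = 8, seed = 13,
                                  config = sim_config(blank_fraction = 0,
                                                      pareidolia = 0))
  cons <- aggregate_classifications(raw, scene_metadata(scenes))
  list(scenes = scenes, cons = cons)
}

test_that("detection histories conserve events and flag zero-effort cells", {
  fx <- history_fixture()
  cons <- fx$cons
  sp <- names(sort(table(cons$species), decreasing = TRUE))[1]
  rec <- cons[cons$species == sp, ]

  bins <- make_time_bins(min(as.Date(cons$datetime)),
                         max(as.Date(cons$datetime)), by = "month")
  intervals <- tibble::tibble(
    site_id = unique(cons$site_id),
    start_date = min(as.Date(cons$datetime)),
    end_date = max(as.Date(cons$datetime)))
  eff <- build_effort(intervals, bins)

  counts <- build_history(cons, eff, sp, mode = "counts")
  expect_equal(sum(counts$value), nrow(rec))  # conservation
  pres <- build_history(cons, eff, sp, mode = "presence")
  expect_true(all(pres$value %in% 0:1))
  expect_true(all(pres$value[counts$value > 0] == 1L))
  expect_false(any(counts$flagged))

  # a record at a site with no effort is flagged, not dropped
  drop_site <- rec$site_id[1]
  eff_partial <- build_effort(intervals[intervals$site_id != drop_site, ],
                              bins)
  expect_warning(flagged <- build_history(cons, eff_partial, sp,
                                          mode = "counts"),
                 "zero search effort")
  expect_equal(sum(flagged$value), nrow(rec))
  expect_true(any(flagged$flagged))

  # no records of an absent species -> all-zero history
  absent <- setdiff(species_vocabulary(), cons$species)[1]
  zero <- build_history(cons, eff, absent, mode = "counts")
  expect_true(all(zero$value == 0L))
  expect_error(build_history(cons, eff, "unicorn"), "unknown species")
})

test_that("relative abundance is events per 100 trap-days and scales with effort", {
  bins <- make_time_bins("2011-01-01", "2011-04-10", by = "day")
  intervals <- tibble::tibble(site_id = "A01",
                              start_date = as.Date("2011-01-01"),
                              end_date = as.Date("2011-04-10"))  # 100 days
  eff <- build_effort(intervals, bins)
  expect_equal(sum(eff$trap_days), 100L)

  cons <- aggregate_classifications(
    dplyr::bind_rows(lapply(1:5, function(i) {
      make_raw(replicate(3, "zebra", simplify = FALSE),
               event = paste0("Z", i))
    })))
  cons$site_id <- "A01"
  cons$datetime <- as.POSIXct("2011-02-01 12:00:00", tz = "Etc/GMT-3") +
    (seq_len(nrow(cons)) - 1) * 86400
  hist <- build_history(cons, eff, "zebra", mode = "counts")
  rai <- relative_abundance(hist, eff)
  expect_equal(rai$rai, 5.0)  # 5 events / 100 trap-days * 100

  # doubled effort halves the rate
  iv2 <- tibble::tibble(site_id = "A01",
                        start_date = as.Date("2011-01-01"),
                        end_date = as.Date("2011-07-19"))  # 200 days
  bins2 <- make_time_bins("2011-01-01", "2011-07-19", by = "day")
  eff2 <- build_effort(iv2, bins2)
  rai2 <- relative_abundance(build_history(cons, eff2, "zebra",
                                           mode = "counts"), eff2)
  expect_equal(rai2$rai, 2.5)

  # zero events is rate zero; presence mode is rejected; zero effort errors
  none <- build_history(cons, eff, "eland", mode = "counts")
  expect_equal(relative_abundance(none, eff)$rai, 0)
  pres <- build_history(cons, eff, "zebra", mode = "presence")
  expect_error(relative_abundance(pres, eff), "counts-mode")
  eff0 <- eff
  eff0$trap_days <- 0L
  expect_warning(h0 <- build_history(cons, eff0, "zebra", mode = "counts"))
  expect_error(relative_abundance(h0, eff0), "zero")
})
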