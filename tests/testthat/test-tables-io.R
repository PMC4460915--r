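test_that("raw classification tables group rows and round-trip", {
  raw <- worked_example_raw()
  # the giraffe stream: 10 classifications, one annotation each
  gir <- raw[raw$capture_event_id == "ASG0010cz5", ]
  expect_equal(nrow(gir), 10L)
  expect_equal(length(unique(gir$classification_id)), 10L)
  expect_true(all(gir$species == "giraffe"))
  expect_true(all(as.character(gir$count) == "1"))
  # blanks carry no species and no payload
  blanks <- raw[raw$is_blank, ]
  expect_equal(nrow(blanks), 3L)
  expect_true(all(is.na(blanks$species)))
  expect_true(all(is.na(blanks$count)))

  # round trip
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_raw_classifications(raw, tmp)
  expect_equal(read_raw_classifications(tmp), raw)
})

test_that("grouping conserves rows: raw rows = sum over events of max(1, annotations)", {
  raw <- random_raw(n_events = 10, seed = 3)
  per_cls <- table(raw$classification_id)
  expect_equal(nrow(raw), sum(pmax(1L, as.integer(per_cls))))
  # blank classifications contribute exactly one row each
  expect_true(all(as.integer(per_cls[unique(raw$classification_id[raw$is_blank])]) == 1L))
})

test_that("raw parser rejects schema violations and strange labels", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies",
               "E1,C1,u1,unicorn,1,0,0,1,0,0,0"), tmp)
  expect_error(read_raw_classifications(tmp), "unknown species.*unicorn")

  writeLines(c("CaptureEventID,Species", "E1,zebra"), tmp)
  expect_error(read_raw_classifications(tmp), "missing required column")

  # a blank row carrying payload is ignored with a warning
  writeLines(c("CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies",
               "E1,C1,u1,blank,3,1,0,0,0,0,0"), tmp)
  expect_warning(raw <- read_raw_classifications(tmp), "blank row")
  expect_true(raw$is_blank[1] && is.na(raw$count[1]))

  # empty table with valid header is an empty stream
  writeLines("CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies",
             tmp)
  expect_equal(nrow(read_raw_classifications(tmp)), 0L)

  # Y/N flags (as printed in publications) parse like 0/1
  writeLines(c("CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies",
               "E1,C1,u1,zebra,2,Y,N,Y,N,N,N"), tmp)
  raw <- read_raw_classifications(tmp)
  expect_true(raw$standing && raw$moving && !raw$resting)
})

test_that("two rows sharing a ClassificationID form one two-species classification", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies",
               "E1,C1,u1,zebra,2,1,0,0,0,0,0",
               "E1,C1,u1,wildebeest,5,1,0,0,0,0,0"), tmp)
  raw <- read_raw_classifications(tmp)
  expect_equal(nrow(raw), 2L)
  expect_equal(length(unique(raw$classification_id)), 1L)
  expect_setequal(raw$species, c("zebra", "wildebeest"))
})

test_that("consensus tables round-trip including diagnostics", {
  raw <- worked_example_raw()
  cons <- aggregate_classifications(raw, worked_example_metadata())
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_consensus(cons, tmp, diagnostics = TRUE)
  header <- strsplit(readLines(tmp, n = 1), ",")[[1]]
  expect_equal(header[1:19],
               c("CaptureEventID", "NumImages", "DateTime", "SiteID",
                 "LocationX", "LocationY", "NumSpecies", "Species", "Count",
                 "Standing", "Resting", "Moving", "Eating", "Interacting",
                 "Babies", "NumClassifications", "NumVotes", "NumBlanks",
                 "Evenness"))
  back <- read_consensus(tmp)
  expect_equal(as.data.frame(back), as.data.frame(cons), tolerance = 1e-12)

  # without diagnostics the file is strictly 19 columns
  write_consensus(cons, tmp)
  expect_length(strsplit(readLines(tmp, n = 1), ",")[[1]], 19L)

  expect_error(write_consensus(cons[, -2], tmp), "missing field")

  # empty list -> header-only file
  write_consensus(cons[0, ], tmp)
  expect_length(readLines(tmp), 1L)
})

test_that("gold, effort and image-index tables parse and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  gold <- tibble::tibble(
    capture_event_id = c("E1", "E2", "E2", "E3"),
    num_species = c(1L, 2L, 2L, 1L),
    species = c("giraffe", "zebra", "wildebeest", "impossible"),
    count = count_bin(c("2", "11-50", "51+", NA)))
  write_gold(gold, tmp)
  expect_equal(read_gold(tmp), gold)

  # impossible must be the only record for its event
  bad <- gold
  bad$capture_event_id[4] <- "E2"
  write_gold(bad, tmp)
  expect_error(read_gold(tmp), "impossible")

  effort <- tibble::tibble(
    site_id = c("B04", "B04", "C07"),
    start_date = as.Date(c("2010-07-01", "2010-09-20", "2010-07-05")),
    end_date = as.Date(c("2010-09-19", "2010-12-01", "2010-08-30")))
  write_effort(effort, tmp)
  expect_equal(read_effort(tmp), effort)
  expect_equal(strsplit(readLines(tmp, n = 1), ",")[[1]],
               c("Site ID", "Start date", "End date"))

  # interval with end before start is rejected
  writeLines(c("Site ID,Start date,End date", "B04,2011-01-10,2011-01-02"),
             tmp)
  expect_error(read_effort(tmp), "end date before start")

  imgs <- tibble::tibble(
    capture_event_id = "ASG000001",
    url_info = "S1/B04/B04_R1/S1_B04_R1_PICT0012.JPG")
  write_image_index(imgs, tmp)
  back <- read_image_index(tmp)
  expect_identical(back$url_info, imgs$url_info)
})

test_that("randomized raw tables round-trip through disk", {
  for (seed in 1:3) {
    raw <- random_raw(n_events = 6, seed = seed)
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_raw_classifications(raw, tmp, provenance = c("tool test", "seed x"))
    expect_equal(read_raw_classifications(tmp), raw)
  }
})
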