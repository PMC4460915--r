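test_that("median species richness uses the lower-middle rule, floored at 1", {
  sets <- function(ns) make_raw(lapply(ns, function(k) species_vocabulary()[seq_len(k)]))
  expect_equal(median_species_richness(sets(c(1, 1, 2, 2, 2))), 2L)
  expect_equal(median_species_richness(sets(c(1, 1, 2, 2))), 1L)  # 1.5 -> 1
  expect_equal(median_species_richness(sets(c(1, 1, 1))), 1L)
  expect_error(median_species_richness(make_raw(list(character()))),
               "undefined")
})

test_that("plurality selection ranks by votes then label and flags ties", {
  tally <- vote_tally(make_raw(c(replicate(10, "spotted hyena", simplify = FALSE),
                                 replicate(2, "warthog", simplify = FALSE),
                                 list("jackal", "wildcat"))))
  expect_equal(tally$n_classifications, 14L)
  expect_equal(tally$n_blanks, 0L)
  pick <- plurality_species(tally, 1L)
  expect_equal(pick$species, "spotted hyena")
  expect_false(pick$tie)

  # a three-way tie at the cut is flagged and broken alphabetically
  tie_tally <- vote_tally(make_raw(c(
    replicate(5, "impala", simplify = FALSE),
    replicate(5, "Grant's gazelle", simplify = FALSE),
    replicate(5, "dik dik", simplify = FALSE))))
  pick <- plurality_species(tie_tally, 1L)
  expect_true(pick$tie)
  expect_equal(pick$species, "dik dik")

  # unanimity is trivially untied
  single <- plurality_species(vote_tally(make_raw(list("eland"))), 1L)
  expect_equal(single$species, "eland")
  expect_false(single$tie)
})

test_that("median counts and behaviour proportions condition on the species", {
  raw <- make_raw(list("giraffe", "giraffe", c("giraffe", "zebra")),
                  counts = list("2", "4", c("3", "11-50")))
  expect_equal(as.character(median_count(raw, "giraffe")), "3")
  expect_equal(as.character(median_count(raw, "zebra")), "11-50")
  expect_error(median_count(raw, "topi"), "does not occur")
  # even-length medians take the lower middle bin
  raw2 <- make_raw(list("zebra", "zebra"), counts = list("10", "11-50"))
  expect_equal(as.character(median_count(raw2, "zebra")), "10")

  raw$standing[1] <- TRUE
  props <- behaviour_proportions(raw, "giraffe")
  expect_equal(unname(props["standing"]), 1 / 3)
  expect_equal(unname(props["moving"]), 1)
  expect_equal(unname(props["eating"]), 0)
})

test_that("Pielou evenness matches its definition and the boundary cases", {
  expect_equal(pielou_evenness(c(giraffe = 10)), 0)
  expect_equal(pielou_evenness(c(a = 5, b = 5)), 1)
  # the 14-classification worked example: votes {10, 2, 1, 1}
  v <- c(10, 2, 1, 1)
  p <- v / sum(v)
  expect_equal(pielou_evenness(v), -sum(p * log(p)) / log(4))
  expect_equal(round(pielou_evenness(v), 3), 0.646)
  expect_error(pielou_evenness(integer()), "undefined")
})

test_that("evenness agrees with an independent diversity oracle on random tallies", {
  skip_if_not_installed("vegan")
  set.seed(99)
  for (i in 1:300) {
    s <- sample(1:8, 1)
    votes <- sample(1:40, s, replace = TRUE)
    got <- pielou_evenness(votes)
    want <- if (s == 1) 0 else {
      unname(vegan::diversity(votes, index = "shannon") / log(s))
    }
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1 + 1e-12)
    expect_identical(got == 0, s == 1L)
  }
})

test_that("percent support divides by all classifications including blanks", {
  raw <- make_raw(c(replicate(10, "spotted hyena", simplify = FALSE),
                    replicate(2, "warthog", simplify = FALSE),
                    list("jackal", "wildcat")))
  tally <- vote_tally(raw)
  expect_equal(percent_support(tally, "spotted hyena"), 10 / 14)
  with_blanks <- make_raw(c(replicate(5, "impala", simplify = FALSE),
                            replicate(3, character(), simplify = FALSE)))
  expect_equal(percent_support(vote_tally(with_blanks), "impala"), 5 / 8)
  expect_error(percent_support(tally, "topi"), "no votes")
})

test_that("aggregation reproduces the published worked examples", {
  raw <- worked_example_raw()
  cons <- aggregate_classifications(raw, worked_example_metadata())

  gir <- cons[cons$capture_event_id == "ASG0010cz5", ]
  expect_equal(gir$species, "giraffe")
  expect_equal(as.character(gir$count), "1")
  expect_equal(gir$evenness, 0)
  expect_equal(gir$num_species, 1L)
  expect_equal(gir$num_votes, 10L)
  expect_equal(gir$moving, 0.9)
  expect_equal(gir$standing, 0.1)
  expect_equal(gir$site_id, "B04")

  hy <- cons[cons$capture_event_id == "ASG0000009", ]
  expect_equal(hy$species, "spotted hyena")
  expect_equal(round(hy$evenness, 3), 0.646)
  expect_equal(hy$percent_support, 10 / 14)

  # the 25-classification sample tallies to a three-way tie: flagged,
  # not asserted away
  cmp <- cons[cons$capture_event_id == "ASG000xzxd", ]
  expect_true(cmp$tie)
  expect_equal(cmp$num_blanks, 3L)
  expect_equal(cmp$num_classifications, 25L)
  expect_equal(cmp$percent_support, 0.2)
})

test_that("all-blank events are excluded; two-species events share event fields", {
  all_blank <- make_raw(replicate(6, character(), simplify = FALSE))
  expect_equal(nrow(aggregate_classifications(all_blank)), 0L)
  expect_equal(nrow(aggregate_capture_event(all_blank)), 0L)

  two <- make_raw(c(replicate(12, c("wildebeest", "zebra"), simplify = FALSE),
                    replicate(2, "zebra", simplify = FALSE)))
  cons <- aggregate_classifications(two)
  expect_equal(nrow(cons), 2L)
  expect_equal(unique(cons$num_species), 2L)
  expect_equal(cons$species, c("zebra", "wildebeest"))
  expect_equal(cons$num_votes, c(14L, 12L))
  expect_equal(length(unique(cons$evenness)), 1L)
})

test_that("the vectorized aggregator equals the per-event reference", {
  raw <- random_raw(n_events = 12, seed = 21)
  norm <- merge_duplicate_species(raw)
  ref <- dplyr::bind_rows(lapply(
    split(norm, factor(norm$capture_event_id,
                       levels = unique(norm$capture_event_id))),
    aggregate_capture_event))
  fast <- aggregate_classifications(raw)
  expect_equal(as.data.frame(fast), as.data.frame(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("aggregation is permutation invariant and vote-conserving", {
  raw <- random_raw(n_events = 6, seed = 31)
  cons <- aggregate_classifications(raw)
  set.seed(1)
  # shuffle classifications within the table
  cls_order <- sample(unique(raw$classification_id))
  shuffled <- raw[order(match(raw$classification_id, cls_order)), ]
  cons2 <- aggregate_classifications(shuffled)
  key <- function(x) x[order(x$capture_event_id, x$species),
                       setdiff(names(x), "tie")]
  expect_equal(as.data.frame(key(cons2)), as.data.frame(key(cons)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # emitted votes never exceed the species mentions in the classifications
  norm <- merge_duplicate_species(raw)
  for (ev in unique(cons$capture_event_id)) {
    emitted <- sum(cons$num_votes[cons$capture_event_id == ev])
    named <- sum(!is.na(norm$species[norm$capture_event_id == ev]))
    expect_lte(emitted, named)
  }

  # adding one more vote for the current winner never changes the winner
  one <- make_raw(c(replicate(4, "impala", simplify = FALSE),
                    replicate(3, "topi", simplify = FALSE)))
  w1 <- aggregate_classifications(one)$species[1]
  more <- make_raw(c(replicate(5, "impala", simplify = FALSE),
                     replicate(3, "topi", simplify = FALSE)))
  expect_equal(aggregate_classifications(more)$species[1], w1)
})
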