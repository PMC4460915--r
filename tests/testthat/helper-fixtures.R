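# Shared fixture builders. Everything is constructed in code (or read from
# the package's small worked-example CSVs); nothing binary.

# Quick raw-classification constructor: one classification per element of
# `species_sets` (a list of character vectors; empty vector = blank answer).
make_raw <- function(species_sets, event = "EV1", counts = NULL,
                     user_prefix = "u") {
  rows <- list()
  for (i in seq_along(species_sets)) {
    sps <- species_sets[[i]]
    cid <- sprintf("%s_c%03d", event, i)
    uid <- sprintf("%s%03d", user_prefix, i)
    if (!length(sps)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        capture_event_id = event, classification_id = cid, user_id = uid,
        species = NA_character_, count = count_bin(NA_character_),
        standing = NA, resting = NA, moving = NA, eating = NA,
        interacting = NA, babies = NA, is_blank = TRUE)
    } else {
      cnt <- if (is.null(counts)) rep("1", length(sps)) else counts[[i]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        capture_event_id = event, classification_id = cid, user_id = uid,
        species = sps, count = count_bin(cnt),
        standing = FALSE, resting = FALSE, moving = TRUE, eating = FALSE,
        interacting = FALSE, babies = FALSE, is_blank = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

worked_example_raw <- function() {
  read_raw_classifications(
    system.file("extdata", "worked_example_raw.csv", package = "trapvote"))
}

worked_example_metadata <- function() {
  read_capture_metadata(
    system.file("extdata", "worked_example_metadata.csv", package = "trapvote"))
}

# Randomized raw table spanning several events, for round-trip and
# conservation properties.
random_raw <- function(n_events = 8, seed = 1) {
  set.seed(seed)
  vocab <- species_vocabulary()
  events <- lapply(seq_len(n_events), function(i) {
    n_cls <- sample(1:12, 1)
    sets <- lapply(seq_len(n_cls), function(j) {
      if (stats::runif(1) < 0.25) return(character())
      sample(vocab, sample(1:3, 1))
    })
    counts <- lapply(sets, function(s) {
      sample(count_bin_labels(), length(s), replace = TRUE)
    })
    raw <- make_raw(sets, event = sprintf("EV%03d", i), counts = counts)
    nb <- !raw$is_blank
    raw$standing[nb] <- stats::runif(sum(nb)) < 0.5
    raw$resting[nb] <- stats::runif(sum(nb)) < 0.3
    raw$moving[nb] <- stats::runif(sum(nb)) < 0.5
    raw$eating[nb] <- stats::runif(sum(nb)) < 0.3
    raw$interacting[nb] <- stats::runif(sum(nb)) < 0.1
    raw$babies[nb] <- stats::runif(sum(nb)) < 0.1
    raw
  })
  dplyr::bind_rows(events)
}
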