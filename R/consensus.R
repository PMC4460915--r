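# Plurality consensus. For each capture event: species richness is the median
# number of distinct species named per classification; the top-voted species
# fill that many slots; each chosen species gets the ordinal median of its
# reported counts and the proportion of its classifications flagging each
# behaviour; certainty comes from Pielou evenness over the vote shares,
# NumBlanks, and percent support.

#' Tally votes for one capture event
#'
#' Counts, over one capture event's classifications, how many volunteers
#' named each species (`votes`), how many classified the event at all
#' (`n_classifications`, blanks included) and how many answered "nothing
#' here" (`n_blanks`).
#'
#' @param event Normalized classification tibble for a single capture event
#'   (rows of [read_raw_classifications()] output, after
#'   [merge_duplicate_species()]).
#' @return A `vote_tally` list with fields `votes` (named integer vector),
#'   `n_classifications` and `n_blanks`.
#' @export
vote_tally <- function(event) {
  n_cls <- length(unique(event$classification_id))
  blanks <- length(unique(event$classification_id[event$is_blank]))
  sp <- event$species[!event$is_blank]
  votes <- if (length(sp)) {
    tab <- table(sp)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer()
  }
  structure(list(votes = votes, n_classifications = n_cls, n_blanks = blanks),
            class = "vote_tally")
}

#' Median species richness of a capture event
#'
#' The aggregated number of species in an image set is the median, across
#' non-blank classifications, of the number of distinct species each names.
#' Half-integer medians (even numbers of classifications) are rounded down,
#' never below 1: the deployed algorithm was conservative, and validation
#' showed missed second species to be far more common than invented ones.
#'
#' @param event Normalized classification tibble for one capture event.
#' @return Integer richness (>= 1).
#' @export
median_species_richness <- function(event) {
  nb <- event[!event$is_blank, ]
  if (!nrow(nb)) {
    stop("species richness is undefined without non-blank classifications",
         call. = FALSE)
  }
  k <- sort(as.integer(table(nb$classification_id)))
  max(1L, k[floor((length(k) + 1L) / 2L)])
}

#' Select the plurality species
#'
#' Returns the `s_star` species with the most votes. Ties at the final slot
#' are broken deterministically (more votes first, then alphabetical label)
#' and flagged, so downstream analyses can exclude tied records.
#'
#' @param tally A [vote_tally()].
#' @param s_star Number of species slots (usually
#'   [median_species_richness()]).
#' @return List with `species` (character vector of winners, in vote order)
#'   and `tie` (logical: the cut passed through a tied vote count).
#' @export
plurality_species <- function(tally, s_star) {
  votes <- tally$votes
  if (!length(votes)) stop("no species votes to rank", call. = FALSE)
  # locale-independent alphabetical tie-break (case-folded, then raw)
  ord <- order(-votes, tolower(names(votes)), names(votes), method = "radix")
  votes <- votes[ord]
  s_star <- min(s_star, length(votes))
  tie <- length(votes) > s_star && votes[[s_star]] == votes[[s_star + 1L]]
  list(species = names(votes)[seq_len(s_star)], tie = tie)
}

#' Ordinal median count for a species
#'
#' The consensus count for a species is the median, on the 12-level bin
#' scale, of the counts reported by the classifications that named the
#' species. Even-length medians take the lower of the two middle bins.
#'
#' @param event Normalized classification tibble for one capture event.
#' @param species Canonical species label.
#' @return A single count bin.
#' @export
median_count <- function(event, species) {
  x <- event$count[!event$is_blank & !is.na(event$species) &
                     event$species == species]
  if (!length(x)) {
    stop(sprintf("species '%s' does not occur in this capture event", species),
         call. = FALSE)
  }
  median_count_bin(x)
}

#' Behaviour and young proportions for a species
#'
#' For each of the five behaviours and the young flag: the proportion of
#' classifications naming the species that set the flag. The denominator is
#' per-species (classifications that named the species), matching the
#' per-species rows of the consensus schema.
#'
#' @param event Normalized classification tibble for one capture event.
#' @param species Canonical species label.
#' @return Named numeric vector `standing`, `resting`, `moving`, `eating`,
#'   `interacting`, `babies`, each in `[0, 1]`.
#' @export
behaviour_proportions <- function(event, species) {
  rows <- event[!event$is_blank & !is.na(event$species) &
                  event$species == species, ]
  if (!nrow(rows)) {
    stop(sprintf("species '%s' does not occur in this capture event", species),
         call. = FALSE)
  }
  vapply(.behaviour_flags, function(f) mean(rows[[f]], na.rm = TRUE),
         numeric(1))
}

#' Pielou evenness of a vote tally
#'
#' Certainty metric over the non-blank votes of a capture event: with `S`
#' the number of distinct species voted and `p_i` the share of votes for
#' species `i`, evenness is `-(sum_i p_i log p_i) / log S`. When all
#' classifications agree (`S = 1`) the value is 0 by definition: 0 means
#' unanimity (high certainty), 1 a maximally split vote (low certainty).
#' Blank classifications never enter the tally.
#'
#' @param tally A [vote_tally()], or a (named) numeric vector of votes.
#' @return Evenness in `[0, 1]`.
#' @export
#' @examples
#' pielou_evenness(c(giraffe = 10))            # 0
#' pielou_evenness(c(zebra = 5, impala = 5))   # 1
pielou_evenness <- function(tally) {
  votes <- if (inherits(tally, "vote_tally")) tally$votes else tally
  votes <- votes[!is.na(votes) & votes > 0]
  if (!length(votes)) {
    stop("evenness is undefined without non-blank votes", call. = FALSE)
  }
  s <- length(votes)
  if (s == 1L) return(0)
  p <- votes / sum(votes)
  -sum(p * log(p)) / log(s)
}

#' Percent support for a species
#'
#' `NumVotes / NumClassifications`: the proportion of all volunteers who
#' classified the event (blanks included in the denominator) that named the
#' species. High values indicate high certainty.
#'
#' @param tally A [vote_tally()].
#' @param species Canonical species label present in the tally.
#' @return Proportion in `[0, 1]`.
#' @export
percent_support <- function(tally, species) {
  if (!species %in% names(tally$votes)) {
    stop(sprintf("species '%s' received no votes", species), call. = FALSE)
  }
  unname(tally$votes[[species]] / tally$n_classifications)
}

.empty_consensus <- function() {
  tibble::tibble(
    capture_event_id = character(), num_images = integer(),
    datetime = as.POSIXct(character(), tz = .camera_tz),
    site_id = character(), location_x = numeric(), location_y = numeric(),
    num_species = integer(), species = character(),
    count = count_bin(character()),
    standing = numeric(), resting = numeric(), moving = numeric(),
    eating = numeric(), interacting = numeric(), babies = numeric(),
    num_classifications = integer(), num_votes = integer(),
    num_blanks = integer(), evenness = numeric(),
    tie = logical(), percent_support = numeric()
  )
}

#' Aggregate one capture event
#'
#' Runs the full plurality algorithm on one capture event's normalized
#' classifications. Events whose classifications are all blank produce no
#' records (the consensus dataset excludes blank-retired image sets).
#' Otherwise one record per selected species is emitted, with the event-level
#' evenness shared across records. Output is independent of classification
#' order.
#'
#' @param event Normalized classification tibble for one capture event.
#' @param metadata Optional single-row tibble with `num_images`, `datetime`,
#'   `site_id`, `location_x`, `location_y` for the event; missing metadata is
#'   `NA`.
#' @return Consensus tibble (zero or more rows); includes the diagnostic
#'   columns `tie` and `percent_support`.
#' @export
aggregate_capture_event <- function(event, metadata = NULL) {
  if (!nrow(event)) stop("no classifications supplied", call. = FALSE)
  if (all(event$is_blank)) return(.empty_consensus())

  tally <- vote_tally(event)
  s_star <- median_species_richness(event)
  pick <- plurality_species(tally, s_star)
  evenness <- pielou_evenness(tally)
  n_species <- length(pick$species)

  nb <- event[!event$is_blank, ]
  sp_rows <- lapply(pick$species, function(sp) {
    rows <- nb[nb$species == sp, ]
    props <- vapply(.behaviour_flags, function(f) mean(rows[[f]], na.rm = TRUE),
                    numeric(1))
    tibble::tibble(
      species = sp,
      count = median_count_bin(rows$count),
      standing = props[["standing"]], resting = props[["resting"]],
      moving = props[["moving"]], eating = props[["eating"]],
      interacting = props[["interacting"]], babies = props[["babies"]],
      num_votes = as.integer(tally$votes[[sp]]),
      percent_support = tally$votes[[sp]] / tally$n_classifications
    )
  })
  body <- dplyr::bind_rows(sp_rows)

  meta <- list(num_images = NA_integer_,
               datetime = as.POSIXct(NA, tz = .camera_tz),
               site_id = NA_character_,
               location_x = NA_real_, location_y = NA_real_)
  if (!is.null(metadata) && nrow(metadata)) {
    for (f in names(meta)) {
      if (f %in% names(metadata)) meta[[f]] <- metadata[[f]][[1]]
    }
  }

  tibble::tibble(
    capture_event_id = event$capture_event_id[[1]],
    num_images = as.integer(meta$num_images),
    datetime = meta$datetime,
    site_id = meta$site_id,
    location_x = meta$location_x, location_y = meta$location_y,
    num_species = as.integer(n_species),
    body,
    num_classifications = as.integer(tally$n_classifications),
    num_blanks = as.integer(tally$n_blanks),
    evenness = evenness,
    tie = pick$tie
  )[names(.empty_consensus())]
}

#' Aggregate a raw classification table into consensus records
#'
#' Applies [merge_duplicate_species()] (unless `normalize = FALSE`) and then
#' [aggregate_capture_event()] to every capture event in the table, joining
#' capture metadata when provided. Capture events are emitted in file order;
#' events whose classifications are all blank are dropped.
#'
#' @param raw Raw classification tibble ([read_raw_classifications()]).
#' @param metadata Optional metadata tibble ([read_capture_metadata()]).
#' @param normalize Merge duplicate species within classifications first.
#' @return Consensus tibble, one row per (capture event, species), with the
#'   diagnostic columns `tie` and `percent_support` (dropped on disk unless
#'   requested in [write_consensus()]).
#' @export
aggregate_classifications <- function(raw, metadata = NULL, normalize = TRUE) {
  if (!nrow(raw)) return(.empty_consensus())
  if (normalize) raw <- merge_duplicate_species(raw)
  nb <- raw[!raw$is_blank, ]
  if (!nrow(nb)) return(.empty_consensus())
  ev_levels <- unique(raw$capture_event_id)

  # per-event classification and blank counts (one row per classification)
  cls <- raw[!duplicated(paste(raw$capture_event_id, raw$classification_id,
                               sep = "\r")), ]
  ev_f <- factor(cls$capture_event_id, levels = ev_levels)
  n_cls <- as.integer(table(ev_f))
  n_blank <- as.integer(table(ev_f[cls$is_blank]))
  names(n_cls) <- names(n_blank) <- ev_levels

  # median species richness: distinct species per non-blank classification
  rich <- dplyr::count(nb, .data$capture_event_id, .data$classification_id)
  s_star <- vapply(split(rich$n, factor(rich$capture_event_id,
                                        levels = ev_levels)),
                   function(k) {
                     if (!length(k)) return(NA_integer_)
                     k <- sort(k)
                     max(1L, k[floor((length(k) + 1L) / 2L)])
                   }, integer(1))

  # vote tallies and plurality selection per event
  vt <- dplyr::count(nb, .data$capture_event_id, .data$species,
                     name = "num_votes")
  vt_split <- split(seq_len(nrow(vt)),
                    factor(vt$capture_event_id, levels = ev_levels))
  sel_rows <- integer(0)
  sel_rank <- integer(0)
  tie_by_ev <- logical(length(ev_levels))
  evenness_by_ev <- rep(NA_real_, length(ev_levels))
  names(tie_by_ev) <- names(evenness_by_ev) <- ev_levels
  for (i in seq_along(ev_levels)) {
    rows <- vt_split[[i]]
    if (!length(rows)) next
    votes <- vt$num_votes[rows]
    labs <- vt$species[rows]
    ord <- order(-votes, tolower(labs), labs, method = "radix")
    k <- min(s_star[[i]], length(rows))
    tie_by_ev[i] <- length(rows) > k && votes[ord[k]] == votes[ord[k + 1L]]
    evenness_by_ev[i] <- pielou_evenness(votes)
    sel_rows <- c(sel_rows, rows[ord[seq_len(k)]])
    sel_rank <- c(sel_rank, seq_len(k))
  }
  sel <- vt[sel_rows, ]
  sel$.rank <- sel_rank
  n_species <- as.integer(table(factor(sel$capture_event_id,
                                       levels = ev_levels)))
  names(n_species) <- ev_levels

  # per selected (event, species): ordinal count median, flag proportions
  lower_median <- function(lv) {
    lv <- sort(lv)
    lv[floor((length(lv) + 1L) / 2L)]
  }
  stats <- nb |>
    dplyr::semi_join(sel, by = c("capture_event_id", "species")) |>
    dplyr::group_by(.data$capture_event_id, .data$species) |>
    dplyr::summarise(
      count_level = lower_median(as.integer(.data$count)),
      standing = mean(.data$standing, na.rm = TRUE),
      resting = mean(.data$resting, na.rm = TRUE),
      moving = mean(.data$moving, na.rm = TRUE),
      eating = mean(.data$eating, na.rm = TRUE),
      interacting = mean(.data$interacting, na.rm = TRUE),
      babies = mean(.data$babies, na.rm = TRUE),
      .groups = "drop")
  body <- dplyr::left_join(sel, stats, by = c("capture_event_id", "species"))

  meta <- tibble::tibble(capture_event_id = ev_levels)
  meta_fields <- c("num_images", "datetime", "site_id", "location_x",
                   "location_y")
  if (!is.null(metadata)) {
    meta <- dplyr::left_join(
      meta, metadata[c("capture_event_id",
                       intersect(meta_fields, names(metadata)))],
      by = "capture_event_id")
  }
  if (!"num_images" %in% names(meta)) meta$num_images <- NA_integer_
  if (!"datetime" %in% names(meta)) {
    meta$datetime <- as.POSIXct(NA, tz = .camera_tz)
  }
  if (!"site_id" %in% names(meta)) meta$site_id <- NA_character_
  if (!"location_x" %in% names(meta)) meta$location_x <- NA_real_
  if (!"location_y" %in% names(meta)) meta$location_y <- NA_real_

  id <- body$capture_event_id
  mrow <- match(id, meta$capture_event_id)
  out <- tibble::tibble(
    capture_event_id = id,
    num_images = as.integer(meta$num_images[mrow]),
    datetime = meta$datetime[mrow],
    site_id = meta$site_id[mrow],
    location_x = meta$location_x[mrow],
    location_y = meta$location_y[mrow],
    num_species = unname(n_species[id]),
    species = body$species,
    count = .bin_from_level(body$count_level),
    standing = body$standing, resting = body$resting, moving = body$moving,
    eating = body$eating, interacting = body$interacting,
    babies = body$babies,
    num_classifications = unname(n_cls[id]),
    num_votes = as.integer(body$num_votes),
    num_blanks = unname(n_blank[id]),
    evenness = unname(evenness_by_ev[id]),
    tie = unname(tie_by_ev[id]),
    percent_support = unname(body$num_votes / n_cls[id])
  )
  ord <- order(match(id, ev_levels), body$.rank)
  out <- out[ord, ]
  out$num_species <- as.integer(out$num_species)
  out$num_blanks <- as.integer(out$num_blanks)
  tibble::remove_rownames(out)
}
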