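# Streaming retirement engine. Capture events circulate until one of four
# stopping rules fires, checked in order after every incoming classification:
#   Blank            - the first `blank_run` (5) classifications are all blank
#   Blank_Consensus  - `blank_total` (10) blank classifications in total
#   Consensus        - `consensus_votes` (10) matching classifications of the
#                      same species set ("lion" and "lion-zebra" are distinct
#                      combinations; one never advances the other's tally)
#   Complete         - `complete_total` (25) classifications in total
# Retirement is absorbing: once a status other than "active" is reached it
# never changes, and further classifications are counted as post-retirement.

#' Retirement rule configuration
#'
#' Thresholds default to the deployed values of the Serengeti survey. Note on
#' the Complete rule: the survey's description of the rule mentions non-blank
#' classifications, but its own worked example (an image set retired as
#' Complete after being viewed by 25 people, 3 of whom answered blank) counts
#' every classification. The default follows the worked example; set
#' `complete_counts_blanks = FALSE` for the literal non-blank reading.
#'
#' @param blank_run Consecutive leading blanks that retire an event as Blank.
#' @param blank_total Total blanks that retire an event as Blank_Consensus.
#' @param consensus_votes Matching classifications (identical species sets)
#'   that retire an event as Consensus.
#' @param complete_total Classifications that retire an event as Complete.
#' @param complete_counts_blanks Whether blanks count toward `complete_total`.
#' @return A `retire_config` list.
#' @export
retire_config <- function(blank_run = 5L, blank_total = 10L,
                          consensus_votes = 10L, complete_total = 25L,
                          complete_counts_blanks = TRUE) {
  thr <- c(blank_run = blank_run, blank_total = blank_total,
           consensus_votes = consensus_votes, complete_total = complete_total)
  if (any(thr < 1L) || any(thr != floor(thr))) {
    stop("retirement thresholds must be positive integers", call. = FALSE)
  }
  structure(list(blank_run = as.integer(blank_run),
                 blank_total = as.integer(blank_total),
                 consensus_votes = as.integer(consensus_votes),
                 complete_total = as.integer(complete_total),
                 complete_counts_blanks = isTRUE(complete_counts_blanks)),
            class = "retire_config")
}

#' Fresh retirement state for one capture event
#'
#' @param config A [retire_config()].
#' @return A `retirement_state` list with counters at zero and status
#'   `"active"`.
#' @export
retirement_state <- function(config = retire_config()) {
  stopifnot(inherits(config, "retire_config"))
  structure(list(n_total = 0L, n_blank = 0L, n_nonblank = 0L,
                 leading_blank_run = TRUE, votes = integer(),
                 status = "active", winning_set = NA_character_,
                 config = config),
            class = "retirement_state")
}

#' Ingest one classification into a retirement state
#'
#' Updates the counters for a single classification and applies the stopping
#' rules in the order Blank, Blank_Consensus, Consensus, Complete. Ingesting
#' into an already-retired state is a contract violation.
#'
#' @param state A `retirement_state`.
#' @param species Character vector of species named by the classification
#'   (the normalized species set); an empty vector is a blank ("nothing
#'   here") answer.
#' @return The updated `retirement_state`; `state$status` is one of
#'   `"active"`, `"Blank"`, `"Blank_Consensus"`, `"Consensus"`, `"Complete"`.
#' @export
retire_ingest <- function(state, species = character()) {
  stopifnot(inherits(state, "retirement_state"))
  if (state$status != "active") {
    stop("cannot ingest into a retired state (status '", state$status, "')",
         call. = FALSE)
  }
  species <- species[!is.na(species)]
  blank <- length(species) == 0L
  cfg <- state$config

  state$n_total <- state$n_total + 1L
  if (blank) {
    state$n_blank <- state$n_blank + 1L
  } else {
    state$leading_blank_run <- FALSE
    state$n_nonblank <- state$n_nonblank + 1L
    key <- paste(sort(unique(species)), collapse = " + ")
    state$votes[key] <- (if (key %in% names(state$votes)) state$votes[[key]] else 0L) + 1L
  }

  complete_n <- if (cfg$complete_counts_blanks) state$n_total else state$n_nonblank
  if (state$leading_blank_run && state$n_blank >= cfg$blank_run) {
    state$status <- "Blank"
  } else if (state$n_blank >= cfg$blank_total) {
    state$status <- "Blank_Consensus"
  } else if (length(state$votes) && max(state$votes) >= cfg$consensus_votes) {
    state$status <- "Consensus"
    state$winning_set <- names(state$votes)[which.max(state$votes)]
  } else if (complete_n >= cfg$complete_total) {
    state$status <- "Complete"
  }
  state
}

# Species sets per classification, in file order, for one capture event's rows.
.classification_sets <- function(rows) {
  ids <- unique(rows$classification_id)
  lapply(ids, function(cid) {
    sp <- rows$species[rows$classification_id == cid]
    unique(sp[!is.na(sp)])
  })
}

#' Replay a classification stream through the retirement engine
#'
#' Groups a raw classification table by capture event (file order preserved
#' within each event, as classifications are ordered by time in the raw
#' data), replays each event's classifications through [retire_ingest()],
#' and reports when and why each event retired. Classifications arriving
#' after retirement are not ingested but counted separately: in the real
#' deployment image sets were re-circulated, so the number of classifications
#' generally exceeds the retirement threshold.
#'
#' @param raw Raw classification tibble ([read_raw_classifications()]).
#' @param config A [retire_config()].
#' @return Tibble with one row per capture event: `capture_event_id`,
#'   `status`, `n_consumed` (classifications ingested up to and including the
#'   retiring one), `n_post_retirement`, and `winning_set` (the retiring
#'   species combination for Consensus retirements, else `NA`).
#' @export
run_retirement <- function(raw, config = retire_config()) {
  if (!nrow(raw)) {
    return(tibble::tibble(capture_event_id = character(), status = character(),
                          n_consumed = integer(), n_post_retirement = integer(),
                          winning_set = character()))
  }
  ev_ids <- unique(raw$capture_event_id)
  idx <- split(seq_len(nrow(raw)),
               factor(raw$capture_event_id, levels = ev_ids))
  res <- lapply(ev_ids, function(ev) {
    rows <- raw[idx[[ev]], ]
    sets <- .classification_sets(rows)
    state <- retirement_state(config)
    consumed <- 0L
    post <- 0L
    for (sp in sets) {
      if (state$status == "active") {
        state <- retire_ingest(state, sp)
        consumed <- consumed + 1L
      } else {
        post <- post + 1L
      }
    }
    tibble::tibble(capture_event_id = ev, status = state$status,
                   n_consumed = consumed, n_post_retirement = post,
                   winning_set = state$winning_set)
  })
  dplyr::bind_rows(res)
}
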