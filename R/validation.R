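# Validation of consensus output against expert gold-standard labels:
# mismatch taxonomy (correct / impossible / missed_species / extra_species /
# wrong_species), per-species accuracy, ordinal count-bin agreement, and the
# evenness separation between correct and incorrect answers.

.match_categories <- c("correct", "impossible", "missed_species",
                       "extra_species", "wrong_species")

#' Classify one consensus-vs-gold comparison
#'
#' Compares the species set the plurality algorithm produced for a capture
#' event with the expert species set. Gold `"impossible"` events are their
#' own category and always count as incorrect (volunteers cannot answer
#' "impossible"). Otherwise: `correct` for equal sets, `missed_species` when
#' the consensus set is a proper subset of the expert set (including an empty
#' consensus), `extra_species` for a proper superset, and `wrong_species` for
#' any other disagreement.
#'
#' @param consensus_species Character vector of consensus species for the
#'   event (may be empty).
#' @param gold_species Character vector of expert species, or
#'   `"impossible"`.
#' @return One of `"correct"`, `"impossible"`, `"missed_species"`,
#'   `"extra_species"`, `"wrong_species"`.
#' @export
match_event <- function(consensus_species, gold_species) {
  cons <- unique(consensus_species[!is.na(consensus_species)])
  gold <- unique(gold_species[!is.na(gold_species)])
  if (!length(gold)) stop("gold does not cover this event", call. = FALSE)
  if ("impossible" %in% gold) return("impossible")
  if (setequal(cons, gold)) return("correct")
  if (all(cons %in% gold)) return("missed_species")
  if (all(gold %in% cons)) return("extra_species")
  "wrong_species"
}

#' Match all gold-covered capture events
#'
#' Applies [match_event()] to every capture event in the gold table, looking
#' up the consensus species set (empty when the event produced no consensus
#' records, e.g. all-blank events). Events in the consensus table without
#' gold coverage are ignored.
#'
#' @param consensus Consensus tibble ([aggregate_classifications()]).
#' @param gold Gold-standard tibble ([read_gold()]).
#' @return Tibble of match outcomes: `capture_event_id`, `category`,
#'   `correct` (logical; impossible counts as incorrect), `evenness` (of the
#'   consensus, `NA` when absent).
#' @export
match_events <- function(consensus, gold) {
  ids <- unique(gold$capture_event_id)
  cons_split <- split(consensus$species, consensus$capture_event_id)
  even_by_ev <- tapply(consensus$evenness, consensus$capture_event_id,
                       function(x) x[[1]])
  gold_split <- split(gold$species, gold$capture_event_id)
  category <- vapply(ids, function(id) {
    match_event(cons_split[[id]] %||% character(), gold_split[[id]])
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    capture_event_id = ids,
    category = category,
    correct = category == "correct",
    evenness = unname(even_by_ev[ids])
  )
}

#' Per-species accuracy against the gold standard
#'
#' For each species in the gold standard: the number of gold-covered capture
#' events containing it, how many of those the plurality algorithm got fully
#' correct, and the proportion. Impossible events are excluded (they contain
#' no identifiable species).
#'
#' @param outcomes Match-outcome tibble from [match_events()].
#' @param gold Gold-standard tibble.
#' @return Tibble `species`, `n_correct`, `n_total`, `proportion`, sorted by
#'   decreasing `n_total`.
#' @export
accuracy_by_species <- function(outcomes, gold) {
  g <- gold[gold$species != "impossible", ]
  g <- g[g$capture_event_id %in%
           outcomes$capture_event_id[outcomes$category != "impossible"], ]
  if (!nrow(g)) {
    return(tibble::tibble(species = character(), n_correct = integer(),
                          n_total = integer(), proportion = numeric()))
  }
  ok <- stats::setNames(outcomes$correct, outcomes$capture_event_id)
  g |>
    dplyr::mutate(correct = unname(ok[.data$capture_event_id])) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_correct = sum(.data$correct),
                     n_total = dplyr::n(),
                     proportion = mean(.data$correct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_total), .data$species)
}

#' Count-bin agreement with the gold standard
#'
#' For capture events where the plurality algorithm captured all or a subset
#' of the species present (categories `correct` and `missed_species`),
#' compares the consensus count bin against the expert count bin for every
#' species both agree on. "Within +/-1 bin" is ordinal adjacency on the
#' 12-level scale, so `10` and `11-50` are adjacent.
#'
#' @param consensus Consensus tibble.
#' @param gold Gold-standard tibble.
#' @param by_bin Summarise per expert count bin (`TRUE`) or overall.
#' @param single_species_only Restrict to capture events where the experts
#'   saw exactly one species.
#' @return With `by_bin = TRUE`: tibble `gold_count`, `n`, `prop_exact`,
#'   `prop_within_1`. Otherwise a one-row tibble `n`, `prop_exact`,
#'   `prop_within_1`.
#' @export
count_agreement <- function(consensus, gold, by_bin = TRUE,
                            single_species_only = FALSE) {
  outcomes <- match_events(consensus, gold)
  keep <- outcomes$capture_event_id[outcomes$category %in%
                                      c("correct", "missed_species")]
  g <- gold[gold$capture_event_id %in% keep & gold$species != "impossible", ]
  if (single_species_only) {
    n_sp <- table(gold$capture_event_id[gold$species != "impossible"])
    g <- g[n_sp[g$capture_event_id] == 1L, ]
  }
  pairs <- dplyr::inner_join(
    dplyr::select(g, "capture_event_id", "species", gold_count = "count"),
    dplyr::select(consensus, "capture_event_id", "species",
                  consensus_count = "count"),
    by = c("capture_event_id", "species")
  )
  pairs$dist <- count_bin_distance(pairs$consensus_count, pairs$gold_count)
  if (!by_bin) {
    return(tibble::tibble(n = nrow(pairs),
                          prop_exact = mean(pairs$dist == 0L),
                          prop_within_1 = mean(pairs$dist <= 1L)))
  }
  pairs |>
    dplyr::group_by(gold_count = .data$gold_count) |>
    dplyr::summarise(n = dplyr::n(),
                     prop_exact = mean(.data$dist == 0L),
                     prop_within_1 = mean(.data$dist <= 1L),
                     .groups = "drop") |>
    dplyr::arrange(.data$gold_count)
}

#' Evenness separation between correct and incorrect answers
#'
#' Mean and standard error of the consensus evenness score, grouped by
#' whether the consensus agreed with the experts (impossible events count as
#' incorrect). In the original validation, incorrect answers had markedly
#' higher evenness than correct ones, making evenness a usable certainty
#' threshold.
#'
#' @param outcomes Match-outcome tibble from [match_events()].
#' @return Tibble with rows `correct` and `incorrect`: `n`, `mean_evenness`,
#'   `se_evenness` (`NA` for empty groups).
#' @export
evenness_separation <- function(outcomes) {
  grp <- ifelse(outcomes$correct, "correct", "incorrect")
  ev <- outcomes$evenness
  one <- function(g) {
    x <- ev[grp == g & !is.na(ev)]
    tibble::tibble(group = g, n = length(x),
                   mean_evenness = if (length(x)) mean(x) else NA_real_,
                   se_evenness = if (length(x) > 1L) {
                     stats::sd(x) / sqrt(length(x))
                   } else {
                     NA_real_
                   })
  }
  dplyr::bind_rows(one("correct"), one("incorrect"))
}

#' Full validation report
#'
#' Runs the whole gold-standard comparison: mismatch taxonomy, overall
#' accuracy, per-species accuracy, count-bin agreement (both pooled and
#' restricted to single-species events) and evenness separation.
#'
#' @param consensus Consensus tibble.
#' @param gold Gold-standard tibble.
#' @return A `trapvote_validation` list with elements `outcomes`,
#'   `category_counts`, `overall_accuracy`, `accuracy_by_species`,
#'   `count_agreement`, `count_agreement_overall`,
#'   `count_agreement_single_species`, `evenness_separation`.
#' @export
validate_consensus <- function(consensus, gold) {
  outcomes <- match_events(consensus, gold)
  counts <- table(factor(outcomes$category, levels = .match_categories))
  structure(list(
    outcomes = outcomes,
    category_counts = counts,
    overall_accuracy = mean(outcomes$correct),
    accuracy_by_species = accuracy_by_species(outcomes, gold),
    count_agreement = count_agreement(consensus, gold),
    count_agreement_overall = count_agreement(consensus, gold, by_bin = FALSE),
    count_agreement_single_species =
      count_agreement(consensus, gold, by_bin = FALSE,
                      single_species_only = TRUE),
    evenness_separation = evenness_separation(outcomes)
  ), class = "trapvote_validation")
}

#' @export
print.trapvote_validation <- function(x, ...) {
  cat("Gold-standard validation\n")
  cat(sprintf("  events compared:   %d\n", nrow(x$outcomes)))
  cat(sprintf("  overall accuracy:  %.3f\n", x$overall_accuracy))
  cat("  mismatch taxonomy:\n")
  for (nm in names(x$category_counts)) {
    cat(sprintf("    %-15s %d\n", nm, x$category_counts[[nm]]))
  }
  co <- x$count_agreement_overall
  if (nrow(co) && co$n[1] > 0) {
    cat(sprintf("  count agreement:   %.3f exact, %.3f within +/-1 bin (n=%d)\n",
                co$prop_exact, co$prop_within_1, co$n))
  }
  es <- x$evenness_separation
  cat(sprintf("  evenness: correct %.3f (n=%d) vs incorrect %.3f (n=%d)\n",
              es$mean_evenness[1], es$n[1], es$mean_evenness[2], es$n[2]))
  invisible(x)
}
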