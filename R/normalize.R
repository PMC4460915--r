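# Canonicalization of classifications before aggregation. Volunteers sometimes
# list the same species twice within one classification to express different
# behaviours ("1 zebra standing" + "1 zebra moving"); those rows are merged
# into a single annotation ("2 zebras, standing and moving") before voting.

#' Merge repeated species within a classification
#'
#' Within each `ClassificationID`, annotations of the same species are merged
#' into one: counts are combined on the ordinal scale with
#' [combine_counts()], and behaviour flags (including the young flag) are
#' OR-ed. Merging never crosses classification boundaries, so each
#' volunteer's answer stays separate. The operation is idempotent and
#' preserves row order (a merged annotation takes the position of its first
#' occurrence).
#'
#' @param raw Raw classification tibble from [read_raw_classifications()].
#' @return Tibble in the same format with each species appearing at most once
#'   per classification.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   capture_event_id = "E1", classification_id = "C1", user_id = "u1",
#'   species = c("zebra", "zebra"), count = count_bin(c(1, 1)),
#'   standing = c(TRUE, FALSE), resting = FALSE, moving = c(FALSE, TRUE),
#'   eating = FALSE, interacting = FALSE, babies = FALSE, is_blank = FALSE)
#' merge_duplicate_species(raw)  # one row: 2 zebras, standing and moving
merge_duplicate_species <- function(raw) {
  if (!nrow(raw)) return(raw)
  key <- paste(raw$classification_id, raw$species, sep = "\r")
  if (!anyDuplicated(key[!raw$is_blank])) return(raw)

  raw$.row <- seq_len(nrow(raw))
  nb <- raw[!raw$is_blank, ]
  merged <- nb |>
    dplyr::group_by(.data$capture_event_id, .data$classification_id,
                    .data$user_id, .data$species) |>
    dplyr::summarise(
      count = .bin_from_level(Reduce(.combine_levels, as.integer(.data$count))),
      standing = any(.data$standing), resting = any(.data$resting),
      moving = any(.data$moving), eating = any(.data$eating),
      interacting = any(.data$interacting), babies = any(.data$babies),
      is_blank = FALSE, .row = min(.data$.row), .groups = "drop"
    )
  out <- dplyr::bind_rows(merged, raw[raw$is_blank, ])
  out <- out[order(out$.row), ]
  out$.row <- NULL
  out[names(raw)[names(raw) != ".row"]]
}
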