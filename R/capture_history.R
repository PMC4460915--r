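# Ecological re-use: aggregate camera operation dates into search effort
# (trap-days per site and time bin) and consensus records into
# species-specific detection histories for occupancy and relative-abundance
# analyses. Time bins are half-open [start, end) calendar-day multiples in
# the camera's local zone (UTC+3, no daylight saving), so a midnight event
# belongs to exactly one bin.

#' Build a time-binning specification
#'
#' Half-open calendar bins `[start, end)` covering `[from, to]`.
#'
#' @param from,to First and last dates to cover.
#' @param by Bin width: `"day"`, `"week"`, `"month"` or an integer number of
#'   days.
#' @return Tibble with `bin_id` (label of the bin start), `bin_start`,
#'   `bin_end` (`Date`; exclusive).
#' @export
make_time_bins <- function(from, to, by = "month") {
  from <- as.Date(from)
  to <- as.Date(to)
  stopifnot(from <= to)
  if (is.numeric(by)) by <- paste(as.integer(by), "days")
  starts <- seq(from, to, by = by)
  ends <- c(starts[-1], seq(starts[length(starts)], by = by,
                            length.out = 2)[2])
  tibble::tibble(bin_id = format(starts, "%Y-%m-%d"),
                 bin_start = starts, bin_end = ends)
}

.assign_bin <- function(dates, bins) {
  i <- findInterval(as.numeric(dates), as.numeric(bins$bin_start))
  i[i > 0 & as.numeric(dates) >= as.numeric(bins$bin_end)[pmax(i, 1L)]] <- 0L
  ifelse(i == 0L, NA_integer_, i)
}

#' Aggregate operation intervals into a search-effort matrix
#'
#' For every site and time bin, the number of trap-days: calendar days
#' covered by at least one operation interval for that site. Overlapping
#' intervals (e.g. consecutive SD cards with overlapping valid dates) count
#' each day once, so effort is invariant under splitting an interval into
#' contiguous sub-intervals.
#'
#' @param intervals Operation-interval tibble ([read_effort()]).
#' @param bins Time bins from [make_time_bins()]; defaults to monthly bins
#'   spanning the intervals.
#' @return Long tibble `site_id`, `bin_id`, `trap_days` covering every
#'   site-by-bin combination, with the bins as attribute `"bins"`.
#' @export
build_effort <- function(intervals, bins = NULL) {
  if (is.null(bins)) {
    bins <- make_time_bins(min(intervals$start_date),
                           max(intervals$end_date), by = "month")
  }
  sites <- unique(intervals$site_id)
  days <- lapply(sites, function(s) {
    iv <- intervals[intervals$site_id == s, ]
    unique(as.Date(unlist(Map(function(a, b) seq(a, b, by = "day"),
                              iv$start_date, iv$end_date)),
                   origin = "1970-01-01"))
  })
  grid <- tidyr::expand_grid(site_id = sites, bin_id = bins$bin_id)
  counts <- dplyr::bind_rows(Map(function(s, d) {
    b <- .assign_bin(d, bins)
    b <- b[!is.na(b)]
    if (!length(b)) {
      return(tibble::tibble(site_id = character(), bin_id = character(),
                            trap_days = integer()))
    }
    tab <- table(b)
    tibble::tibble(site_id = s, bin_id = bins$bin_id[as.integer(names(tab))],
                   trap_days = as.integer(tab))
  }, sites, days))
  out <- dplyr::left_join(grid, counts, by = c("site_id", "bin_id"))
  out$trap_days[is.na(out$trap_days)] <- 0L
  attr(out, "bins") <- bins
  class(out) <- c("effort_matrix", class(out))
  out
}

#' Species detection history over sites and time bins
#'
#' Converts consensus records of one species into a site-by-bin detection
#' history: presence/absence indicators (`mode = "presence"`) or capture
#' event counts (`mode = "counts"`). Records falling in site/bin cells with
#' zero search effort are kept but flagged (`flagged = TRUE`) with a
#' warning, never silently dropped. Records outside the bin range are
#' dropped with a warning.
#'
#' @param consensus Consensus tibble with `site_id` and `datetime` metadata.
#' @param effort Effort matrix from [build_effort()] (supplies the bins and
#'   the site list).
#' @param species Canonical species label.
#' @param mode `"presence"` or `"counts"`.
#' @param filter An optional certainty pre-filter: a function taking the
#'   consensus tibble and returning a logical keep-vector (e.g. thresholds
#'   on `percent_support`, `evenness` or `num_blanks`). Off by default; the
#'   original survey presents such thresholds as analyst-chosen.
#' @return Long tibble `site_id`, `bin_id`, `value`, `flagged`, with
#'   attributes `"species"`, `"mode"` and `"bins"`.
#' @export
build_history <- function(consensus, effort, species,
                          mode = c("presence", "counts"), filter = NULL) {
  mode <- match.arg(mode)
  species <- normalize_species(species, allow_blank = FALSE)
  if (!species %in% species_vocabulary()) {
    stop("unknown species: ", species, call. = FALSE)
  }
  bins <- attr(effort, "bins")
  if (!is.null(filter)) consensus <- consensus[filter(consensus), ]
  rec <- consensus[consensus$species == species, ]
  rec <- rec[!is.na(rec$site_id) & !is.na(rec$datetime), ]
  day <- as.Date(format(rec$datetime, "%Y-%m-%d", tz = .camera_tz))
  b <- .assign_bin(day, bins)
  if (any(is.na(b)) && nrow(rec)) {
    warning(sprintf("%d record(s) outside the binned period were dropped",
                    sum(is.na(b))), call. = FALSE)
  }
  rec <- rec[!is.na(b), ]
  b <- b[!is.na(b)]
  counts <- dplyr::count(
    tibble::tibble(site_id = rec$site_id, bin_id = bins$bin_id[b]),
    .data$site_id, .data$bin_id, name = "n_events")

  out <- dplyr::left_join(
    effort[c("site_id", "bin_id", "trap_days")], counts,
    by = c("site_id", "bin_id"))
  out$n_events[is.na(out$n_events)] <- 0L
  missing_site <- !counts$site_id %in% effort$site_id
  if (any(missing_site)) {
    extra <- counts[missing_site, ]
    extra$trap_days <- 0L
    out <- dplyr::bind_rows(out, extra)
  }
  out$flagged <- out$n_events > 0L & out$trap_days == 0L
  if (any(out$flagged)) {
    warning(sprintf("%d detection cell(s) have zero search effort",
                    sum(out$flagged)), call. = FALSE)
  }
  out$value <- if (mode == "presence") as.integer(out$n_events > 0L) else {
    as.integer(out$n_events)
  }
  out <- out[c("site_id", "bin_id", "value", "flagged")]
  attr(out, "bins") <- bins
  attr(out, "species") <- species
  attr(out, "mode") <- mode
  out
}

#' Pivot a long effort or history table to a wide site-by-bin matrix
#'
#' @param x Long tibble from [build_effort()] or [build_history()].
#' @param value Column to spread (`"trap_days"` or `"value"`).
#' @return Wide tibble, one row per site, one column per bin.
#' @export
history_wide <- function(x, value = intersect(c("trap_days", "value"),
                                              names(x))[1]) {
  tidyr::pivot_wider(x[c("site_id", "bin_id", value)],
                     names_from = "bin_id",
                     values_from = tidyr::all_of(value),
                     values_fill = 0L)
}

#' Relative abundance index per site
#'
#' Capture events per 100 trap-days per site, the standard camera-trap
#' relative abundance index (RAI).
#'
#' @param history A counts-mode history from [build_history()].
#' @param effort Matching effort matrix.
#' @return Tibble `site_id`, `n_events`, `trap_days`, `rai`; sites with zero
#'   effort get `NA` (and only appear if they recorded events).
#' @export
relative_abundance <- function(history, effort) {
  if (!identical(attr(history, "mode"), "counts")) {
    stop("relative abundance needs a counts-mode history", call. = FALSE)
  }
  ev <- history |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_events = sum(.data$value), .groups = "drop")
  eff <- effort |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(trap_days = sum(.data$trap_days), .groups = "drop")
  out <- dplyr::left_join(ev, eff, by = "site_id")
  out$trap_days[is.na(out$trap_days)] <- 0L
  if (all(out$trap_days == 0L)) {
    stop("total search effort is zero", call. = FALSE)
  }
  out$rai <- ifelse(out$trap_days > 0, 100 * out$n_events / out$trap_days,
                    NA_real_)
  out
}
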