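# Readers and writers for the five table schemas of the public dataset:
# raw_data.csv, consensus_data.csv, gold_standard_data.csv, search_effort.csv
# and all_images.csv. Column names and encodings mirror the published files;
# an optional provenance header of '#'-prefixed comment lines is tolerated on
# input and can be emitted on output.

.raw_cols <- c("CaptureEventID", "ClassificationID", "UserID", "Species",
               "Count", "Standing", "Resting", "Moving", "Eating",
               "Interacting", "Babies")

.consensus_cols <- c("CaptureEventID", "NumImages", "DateTime", "SiteID",
                     "LocationX", "LocationY", "NumSpecies", "Species",
                     "Count", "Standing", "Resting", "Moving", "Eating",
                     "Interacting", "Babies", "NumClassifications",
                     "NumVotes", "NumBlanks", "Evenness")

.gold_cols <- c("CaptureEventID", "NumSpecies", "Species", "Count")

.effort_cols <- c("Site ID", "Start date", "End date")

.images_cols <- c("CaptureEventID", "URL_Info")

.behaviour_flags <- c("standing", "resting", "moving", "eating", "interacting",
                      "babies")

# Camera timestamps are UTC+3 year-round (no daylight saving).
.camera_tz <- "Etc/GMT-3"

.check_columns <- function(df, expected, what, aliases = NULL) {
  nms <- names(df)
  if (!is.null(aliases)) {
    hit <- match(.norm_key(nms), .norm_key(names(aliases)))
    nms[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
    names(df) <- nms
  }
  missing <- setdiff(expected, nms)
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[expected]
}

.read_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  comment = "#", na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

.write_table <- function(df, path, provenance = NULL) {
  if (!is.null(provenance) && length(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE, na = "",
                     progress = FALSE)
  } else {
    readr::write_csv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

.parse_flag <- function(x, what) {
  key <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[key %in% c("1", "Y", "YES", "TRUE", "T")] <- TRUE
  out[key %in% c("0", "N", "NO", "FALSE", "F")] <- FALSE
  bad <- which(!is.na(key) & key != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: invalid binary indicator '%s' (row %d)", what,
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

.format_flag <- function(x) {
  ifelse(is.na(x), "", ifelse(x, "1", "0"))
}

#' Read a raw volunteer classification table
#'
#' Parses a `raw_data.csv`-schema file: one row per unique user, capture event
#' and species, with rows sharing a `ClassificationID` belonging to the same
#' classification (one volunteer's complete answer). A `Species` value of
#' `"blank"` records a "nothing here" answer; any count or behaviour values on
#' such a row are ignored with a warning. File row order is preserved.
#'
#' @param path Path to a CSV file with the `raw_data.csv` header.
#' @return A tibble with one row per annotation (or one row per blank
#'   classification) and columns `capture_event_id`, `classification_id`,
#'   `user_id`, `species` (canonical label, `NA` for blanks), `count`
#'   (ordered count-bin factor), logical behaviour flags `standing`,
#'   `resting`, `moving`, `eating`, `interacting`, `babies`, and `is_blank`.
#' @export
read_raw_classifications <- function(path) {
  df <- .check_columns(.read_table(path), .raw_cols, "raw classification table")
  if (!nrow(df)) return(.empty_raw())

  species <- normalize_species(df$Species, allow_blank = TRUE,
                               allow_impossible = FALSE)
  is_blank <- species == "blank"

  payload <- df[c("Count", "Standing", "Resting", "Moving", "Eating",
                  "Interacting", "Babies")]
  stray <- is_blank & Reduce(`|`, lapply(payload, function(col) trimws(col) != ""))
  if (any(stray)) {
    warning(sprintf(
      "ignoring count/behaviour values on %d blank row(s) (first at data row %d)",
      sum(stray), which(stray)[1]), call. = FALSE)
  }

  count_chr <- ifelse(is_blank, NA_character_, df$Count)
  if (any(!is_blank & trimws(df$Count) == "")) {
    bad <- which(!is_blank & trimws(df$Count) == "")[1]
    stop(sprintf("raw classification table: missing Count on non-blank row %d",
                 bad), call. = FALSE)
  }
  flags <- lapply(c(Standing = "Standing", Resting = "Resting",
                    Moving = "Moving", Eating = "Eating",
                    Interacting = "Interacting", Babies = "Babies"),
                  function(nm) {
                    f <- .parse_flag(ifelse(is_blank, NA_character_, df[[nm]]), nm)
                    f[!is_blank & is.na(f)] <- FALSE
                    f
                  })

  tibble::tibble(
    capture_event_id = df$CaptureEventID,
    classification_id = df$ClassificationID,
    user_id = df$UserID,
    species = ifelse(is_blank, NA_character_, species),
    count = count_bin(count_chr),
    standing = flags$Standing, resting = flags$Resting, moving = flags$Moving,
    eating = flags$Eating, interacting = flags$Interacting,
    babies = flags$Babies,
    is_blank = is_blank
  )
}

.empty_raw <- function() {
  tibble::tibble(
    capture_event_id = character(), classification_id = character(),
    user_id = character(), species = character(),
    count = count_bin(character()),
    standing = logical(), resting = logical(), moving = logical(),
    eating = logical(), interacting = logical(), babies = logical(),
    is_blank = logical()
  )
}

#' Write a raw classification table
#'
#' Inverse of [read_raw_classifications()]. Behaviour flags are written as
#' 0/1; blank rows carry `Species = "blank"` and empty payload fields.
#'
#' @param raw Tibble in the format returned by [read_raw_classifications()].
#' @param path Output CSV path.
#' @param provenance Optional character vector written as `#`-prefixed header
#'   comment lines.
#' @return The path, invisibly.
#' @export
write_raw_classifications <- function(raw, path, provenance = NULL) {
  out <- tibble::tibble(
    CaptureEventID = raw$capture_event_id,
    ClassificationID = raw$classification_id,
    UserID = raw$user_id,
    Species = ifelse(raw$is_blank, "blank", raw$species),
    Count = ifelse(raw$is_blank, "", as.character(raw$count)),
    Standing = .format_flag(raw$standing),
    Resting = .format_flag(raw$resting),
    Moving = .format_flag(raw$moving),
    Eating = .format_flag(raw$eating),
    Interacting = .format_flag(raw$interacting),
    Babies = .format_flag(raw$babies)
  )
  .write_table(out, path, provenance)
}

#' Write a consensus classification table
#'
#' One output row per (capture event, species) in the `consensus_data.csv`
#' schema: capture metadata, `NumSpecies`, the species, its median count bin,
#' six behaviour/young proportions, `NumClassifications`, `NumVotes`,
#' `NumBlanks` and the shared `Evenness`. With `diagnostics = TRUE` two
#' non-schema columns, `Tie` and `PercentSupport`, are appended.
#'
#' @param records Consensus tibble as returned by [aggregate_classifications()].
#' @param path Output CSV path.
#' @param diagnostics Append the tie flag and percent-support columns.
#' @param provenance Optional `#`-prefixed header comment lines.
#' @return The path, invisibly.
#' @export
write_consensus <- function(records, path, diagnostics = FALSE,
                            provenance = NULL) {
  needed <- c("capture_event_id", "num_images", "datetime", "site_id",
              "location_x", "location_y", "num_species", "species", "count",
              .behaviour_flags, "num_classifications", "num_votes",
              "num_blanks", "evenness")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("consensus records missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    CaptureEventID = records$capture_event_id,
    NumImages = records$num_images,
    DateTime = ifelse(is.na(records$datetime), "",
                      format(records$datetime, "%Y-%m-%d %H:%M:%S",
                             tz = .camera_tz)),
    SiteID = records$site_id,
    LocationX = records$location_x,
    LocationY = records$location_y,
    NumSpecies = records$num_species,
    Species = records$species,
    Count = as.character(records$count),
    Standing = records$standing,
    Resting = records$resting,
    Moving = records$moving,
    Eating = records$eating,
    Interacting = records$interacting,
    Babies = records$babies,
    NumClassifications = records$num_classifications,
    NumVotes = records$num_votes,
    NumBlanks = records$num_blanks,
    Evenness = records$evenness
  )
  if (diagnostics) {
    out$Tie <- as.integer(records$tie)
    out$PercentSupport <- records$percent_support
  }
  .write_table(out, path, provenance)
}

#' Read a consensus classification table
#'
#' Inverse of [write_consensus()]. Diagnostic columns (`Tie`,
#' `PercentSupport`), when present, are read back too.
#'
#' @param path Path to a CSV file with the `consensus_data.csv` header.
#' @return Consensus tibble (see [aggregate_classifications()]).
#' @export
read_consensus <- function(path) {
  df0 <- .read_table(path)
  df <- .check_columns(df0, .consensus_cols, "consensus table")
  num <- function(x) suppressWarnings(as.numeric(ifelse(trimws(x) == "", NA, x)))
  int <- function(x) suppressWarnings(as.integer(ifelse(trimws(x) == "", NA, x)))
  out <- tibble::tibble(
    capture_event_id = df$CaptureEventID,
    num_images = int(df$NumImages),
    datetime = as.POSIXct(ifelse(trimws(df$DateTime) == "", NA_character_,
                                 df$DateTime),
                          tz = .camera_tz, format = "%Y-%m-%d %H:%M:%S"),
    site_id = ifelse(trimws(df$SiteID) == "", NA_character_, df$SiteID),
    location_x = num(df$LocationX),
    location_y = num(df$LocationY),
    num_species = int(df$NumSpecies),
    species = normalize_species(df$Species, allow_blank = FALSE),
    count = count_bin(df$Count),
    standing = num(df$Standing), resting = num(df$Resting),
    moving = num(df$Moving), eating = num(df$Eating),
    interacting = num(df$Interacting), babies = num(df$Babies),
    num_classifications = int(df$NumClassifications),
    num_votes = int(df$NumVotes),
    num_blanks = int(df$NumBlanks),
    evenness = num(df$Evenness)
  )
  if (all(c("Tie", "PercentSupport") %in% names(df0))) {
    out$tie <- int(df0$Tie) == 1L
    out$percent_support <- num(df0$PercentSupport)
  }
  out
}

#' Read an expert gold-standard table
#'
#' Parses a `gold_standard_data.csv`-schema file. The reserved species
#' `"impossible"` (the expert panel could not identify the image) is allowed
#' and must be the only record for its capture event.
#'
#' @param path Path to a CSV file with the gold-standard header.
#' @return Tibble with `capture_event_id`, `num_species`, `species` and
#'   `count` (`NA` for impossible records).
#' @export
read_gold <- function(path) {
  df <- .check_columns(.read_table(path), .gold_cols, "gold-standard table")
  species <- normalize_species(df$Species, allow_blank = FALSE,
                               allow_impossible = TRUE)
  imp <- species == "impossible"
  out <- tibble::tibble(
    capture_event_id = df$CaptureEventID,
    num_species = suppressWarnings(as.integer(df$NumSpecies)),
    species = species,
    count = count_bin(ifelse(imp | trimws(df$Count) == "", NA_character_,
                             df$Count))
  )
  n_rows <- table(out$capture_event_id)
  imp_ids <- unique(out$capture_event_id[imp])
  bad <- imp_ids[n_rows[imp_ids] > 1L]
  if (length(bad)) {
    stop("gold-standard table: 'impossible' must be the only record for a ",
         "capture event; violated by: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write an expert gold-standard table
#'
#' @param gold Tibble as returned by [read_gold()].
#' @param path Output CSV path.
#' @param provenance Optional `#`-prefixed header comment lines.
#' @return The path, invisibly.
#' @export
write_gold <- function(gold, path, provenance = NULL) {
  out <- tibble::tibble(
    CaptureEventID = gold$capture_event_id,
    NumSpecies = gold$num_species,
    Species = gold$species,
    Count = ifelse(is.na(gold$count), "", as.character(gold$count))
  )
  .write_table(out, path, provenance)
}

#' Read a camera operation-date table
#'
#' Parses a `search_effort.csv`-schema file: one row per SD card with the
#' first and last dates of valid photographs. Headers with or without spaces
#' (`Site ID` / `SiteID`) are accepted. An end date before its start date is
#' an error.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `site_id`, `start_date`, `end_date` (`Date` columns).
#' @export
read_effort <- function(path) {
  aliases <- c("site id" = "Site ID", "siteid" = "Site ID",
               "start date" = "Start date", "startdate" = "Start date",
               "end date" = "End date", "enddate" = "End date")
  df <- .check_columns(.read_table(path), .effort_cols,
                       "search-effort table", aliases = aliases)
  out <- tibble::tibble(
    site_id = df[["Site ID"]],
    start_date = as.Date(df[["Start date"]]),
    end_date = as.Date(df[["End date"]])
  )
  bad <- which(!is.na(out$start_date) & !is.na(out$end_date) &
                 out$end_date < out$start_date)
  if (length(bad)) {
    stop(sprintf(
      "search-effort table: end date before start date at data row %d (%s)",
      bad[1], out$site_id[bad[1]]), call. = FALSE)
  }
  out
}

#' Write a camera operation-date table
#'
#' @param effort Tibble as returned by [read_effort()].
#' @param path Output CSV path.
#' @param provenance Optional `#`-prefixed header comment lines.
#' @return The path, invisibly.
#' @export
write_effort <- function(effort, path, provenance = NULL) {
  out <- tibble::tibble(
    `Site ID` = effort$site_id,
    `Start date` = format(effort$start_date, "%Y-%m-%d"),
    `End date` = format(effort$end_date, "%Y-%m-%d")
  )
  .write_table(out, path, provenance)
}

#' Read an image URL index
#'
#' Parses an `all_images.csv`-schema file. The URL suffix is stored verbatim
#' for later appending to a configured base URL.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `capture_event_id` and `url_info`.
#' @export
read_image_index <- function(path) {
  df <- .check_columns(.read_table(path), .images_cols, "image index")
  tibble::tibble(capture_event_id = df$CaptureEventID, url_info = df$URL_Info)
}

#' Write an image URL index
#'
#' @param images Tibble as returned by [read_image_index()].
#' @param path Output CSV path.
#' @param provenance Optional `#`-prefixed header comment lines.
#' @return The path, invisibly.
#' @export
write_image_index <- function(images, path, provenance = NULL) {
  out <- tibble::tibble(CaptureEventID = images$capture_event_id,
                        URL_Info = images$url_info)
  .write_table(out, path, provenance)
}

#' Read capture-event metadata
#'
#' Reads the metadata columns of the consensus schema (`CaptureEventID`,
#' `NumImages`, `DateTime`, `SiteID`, `LocationX`, `LocationY`) from a CSV
#' file, for joining onto aggregated records.
#'
#' @param path Path to a CSV file carrying at least those columns.
#' @return Tibble with `capture_event_id`, `num_images`, `datetime`,
#'   `site_id`, `location_x`, `location_y`.
#' @export
read_capture_metadata <- function(path) {
  cols <- c("CaptureEventID", "NumImages", "DateTime", "SiteID",
            "LocationX", "LocationY")
  df <- .check_columns(.read_table(path), cols, "capture metadata")
  tibble::tibble(
    capture_event_id = df$CaptureEventID,
    num_images = suppressWarnings(as.integer(df$NumImages)),
    datetime = as.POSIXct(df$DateTime, tz = .camera_tz,
                          format = "%Y-%m-%d %H:%M:%S"),
    site_id = df$SiteID,
    location_x = suppressWarnings(as.numeric(df$LocationX)),
    location_y = suppressWarnings(as.numeric(df$LocationY))
  )
}
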