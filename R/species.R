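# Controlled species vocabulary of the Serengeti camera-trap survey: 48
# species / species-group options available to volunteers, plus the reserved
# answers "blank" (nothing here) and "impossible" (experts only).

.species_vocab <- c(
  "aardvark", "aardwolf", "baboon", "bat eared fox", "buffalo", "bushbuck",
  "caracal", "cheetah", "civet", "dik dik", "eland", "elephant", "genet",
  "giraffe", "Grant's gazelle", "guinea fowl", "hare", "hartebeest",
  "hippopotamus", "honey badger", "human", "impala", "jackal", "kori bustard",
  "leopard", "lion female&cub", "lion male", "mongoose", "ostrich",
  "other bird", "porcupine", "reedbuck", "reptiles", "rhinoceros", "rodents",
  "secretary bird", "serval", "spotted hyena", "striped hyena",
  "Thomson's gazelle", "topi", "vervet monkey", "warthog", "waterbuck",
  "wildcat", "wildebeest", "zebra", "zorilla"
)

# Variant spellings that occur in published material for the same categories.
.species_aliases <- c(
  "g. gazelle"          = "Grant's gazelle",
  "grants gazelle"      = "Grant's gazelle",
  "t. gazelle"          = "Thomson's gazelle",
  "thomsons gazelle"    = "Thomson's gazelle",
  "rodent"              = "rodents",
  "reptile"             = "reptiles",
  "bird (other)"        = "other bird",
  "lion (male)"         = "lion male",
  "lion (female&cubs)"  = "lion female&cub",
  "lion female&cubs"    = "lion female&cub",
  "lion (female & cubs)" = "lion female&cub",
  "batearedfox"         = "bat eared fox",
  "dikdik"              = "dik dik"
)

# Total capture events per species in the original 2010-2013 deployment,
# as published with the consensus dataset. Used as the simulator's default
# relative prevalence.
.species_event_totals <- c(
  aardvark = 386, aardwolf = 162, baboon = 1556, `bat eared fox` = 291,
  buffalo = 13672, bushbuck = 252, caracal = 79, cheetah = 1272, civet = 37,
  `dik dik` = 1483, eland = 2689, elephant = 10178, genet = 27, giraffe = 8386,
  `Grant's gazelle` = 7723, `guinea fowl` = 7793, hare = 398,
  hartebeest = 12431, hippopotamus = 2611, `honey badger` = 35, human = 9851,
  impala = 8286, jackal = 561, `kori bustard` = 688, leopard = 228,
  `lion female&cub` = 3343, `lion male` = 923, mongoose = 246, ostrich = 673,
  `other bird` = 5549, porcupine = 288, reedbuck = 2875, reptiles = 131,
  rhinoceros = 30, rodents = 48, `secretary bird` = 434, serval = 458,
  `spotted hyena` = 5303, `striped hyena` = 115, `Thomson's gazelle` = 41420,
  topi = 2299, `vervet monkey` = 314, warthog = 7493, waterbuck = 353,
  wildcat = 47, wildebeest = 100660, zebra = 70577, zorilla = 17
)

# Case-fold, trim, collapse whitespace, normalize typographic punctuation.
.norm_key <- function(x) {
  x <- gsub("’", "'", x)
  x <- gsub("–|—", "-", x)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(trimws(x))
}

.species_lookup <- function(allow_blank = TRUE, allow_impossible = FALSE) {
  lut <- stats::setNames(.species_vocab, .norm_key(.species_vocab))
  lut <- c(lut, stats::setNames(unname(.species_aliases),
                                .norm_key(names(.species_aliases))))
  if (allow_blank) lut <- c(lut, blank = "blank")
  if (allow_impossible) lut <- c(lut, impossible = "impossible")
  lut
}

#' Species vocabulary of the volunteer interface
#'
#' The 48 species and species-group options volunteers can choose from,
#' including the four group categories (human, other bird, reptiles, rodents)
#' and the two lion categories. The reserved answers `"blank"` (nothing here)
#' and `"impossible"` (expert gold standard only) are not part of the
#' vocabulary and are handled separately by the parsers.
#'
#' @return Character vector of 48 canonical species labels.
#' @export
#' @examples
#' length(species_vocabulary())
species_vocabulary <- function() .species_vocab

#' Published capture-event totals per species
#'
#' Total number of capture events attributed to each species by the consensus
#' algorithm in the original 2010-2013 Serengeti deployment. These totals are
#' the default relative prevalence of [generate_scenes()].
#'
#' @return Named numeric vector over [species_vocabulary()].
#' @export
species_event_totals <- function() .species_event_totals

#' Normalize species labels against the controlled vocabulary
#'
#' Labels are matched case-insensitively after trimming, whitespace collapse
#' and punctuation normalization (curly apostrophes). A small set of published
#' variant spellings (e.g. `"G. gazelle"`, `"rodent"`, `"lion (male)"`) maps
#' to the canonical label. Unknown labels are an error naming the offending
#' values and their positions.
#'
#' @param x Character vector of raw labels.
#' @param allow_blank Accept the reserved `"blank"` answer (volunteer tables).
#' @param allow_impossible Accept the reserved `"impossible"` answer
#'   (gold-standard tables only).
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_species(c(" Zebra", "G. gazelle"))
normalize_species <- function(x, allow_blank = TRUE, allow_impossible = FALSE) {
  lut <- .species_lookup(allow_blank, allow_impossible)
  out <- unname(lut[.norm_key(as.character(x))])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    shown <- utils::head(bad, 5L)
    stop("unknown species label(s): ",
         paste0(sprintf("'%s' (position %d)", x[shown], shown), collapse = ", "),
         if (length(bad) > 5L) sprintf(" and %d more", length(bad) - 5L),
         call. = FALSE)
  }
  out
}
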