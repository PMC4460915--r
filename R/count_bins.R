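# The 12-level ordinal count scale used for both raw and consensus counts:
# 1, 2, ..., 10, 11-50, 51+. Represented as an ordered factor.

.count_bin_labels <- c(as.character(1:10), "11-50", "51+")

#' Labels of the ordinal count scale
#'
#' Group sizes are recorded on a 12-level ordinal scale: exact counts 1-10,
#' then the bins `11-50` and `51+`.
#'
#' @return Character vector of the 12 bin labels in increasing order.
#' @export
count_bin_labels <- function() .count_bin_labels

.bin_from_level <- function(level) {
  factor(.count_bin_labels[level], levels = .count_bin_labels, ordered = TRUE)
}

#' Coerce to a count bin
#'
#' Character input must use the bin labels (the en-dash variant `11–50`
#' is accepted). Numeric input is interpreted as a raw number of individuals
#' and binned: 1-10 map to their own bin, 11-50 to `11-50`, 51 and above to
#' `51+`.
#'
#' @param x Character labels, raw numeric counts, or an existing factor.
#' @return Ordered factor on the 12-level scale ([count_bin_labels()]).
#' @export
#' @examples
#' count_bin(c(1, 12, 60))
count_bin <- function(x) {
  if (is.factor(x) && identical(levels(x), .count_bin_labels) && is.ordered(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & (x < 1 | x != floor(x)))
    if (length(bad)) {
      stop("counts must be positive integers; offending values: ",
           paste(utils::head(x[bad], 5L), collapse = ", "), call. = FALSE)
    }
    level <- ifelse(is.na(x), NA_integer_,
                    ifelse(x <= 10, x, ifelse(x <= 50, 11L, 12L)))
    return(.bin_from_level(as.integer(level)))
  }
  key <- .norm_key(as.character(x))
  key[!is.na(key) & key == ""] <- NA_character_
  m <- match(key, .norm_key(.count_bin_labels))
  bad <- which(is.na(m) & !is.na(key))
  if (length(bad)) {
    stop("invalid count bin label(s): ",
         paste0(sprintf("'%s' (position %d)", as.character(x)[utils::head(bad, 5L)],
                        utils::head(bad, 5L)), collapse = ", "),
         call. = FALSE)
  }
  .bin_from_level(m)
}

# Lower-bound arithmetic with saturation on bin levels (integers 1..12).
.combine_levels <- function(a, b) {
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  if (a == 12L || b == 12L) return(12L)
  lower <- function(l) if (l == 11L) 11L else l
  s <- lower(a) + lower(b)
  if (s <= 10L) s else if (s <= 50L) 11L else 12L
}

#' Combine two count bins
#'
#' When one volunteer lists the same species twice in a classification (e.g.
#' "1 zebra standing" plus "1 zebra moving"), the counts are combined on the
#' ordinal scale using lower-bound arithmetic with saturation: exact bins sum
#' numerically (1 + 1 = 2), a sum landing in 11-50 gives `11-50`
#' (10 + 1 = `11-50`), and `51+` absorbs everything. `11-50` combined with any
#' exact bin or with itself stays `11-50`: summing the bins' lower bounds never
#' proves the total exceeds 50, so saturation is the unique order-preserving
#' rule.
#'
#' The operation is commutative and monotone non-decreasing in each argument.
#'
#' @param a,b Count bins (anything [count_bin()] accepts); vectors recycle.
#' @return Ordered factor of combined bins.
#' @export
#' @examples
#' combine_counts("1", "1")     # "2"
#' combine_counts("10", "1")    # "11-50"
#' combine_counts("11-50", "51+") # "51+"
combine_counts <- function(a, b) {
  la <- as.integer(count_bin(a))
  lb <- as.integer(count_bin(b))
  n <- max(length(la), length(lb))
  la <- rep_len(la, n)
  lb <- rep_len(lb, n)
  .bin_from_level(vapply(seq_len(n), function(i) {
    as.integer(.combine_levels(la[i], lb[i]))
  }, integer(1)))
}

#' Ordinal median of count bins
#'
#' Median on the 12-level ordinal scale. For an even number of values the
#' lower of the two middle bins is returned, keeping the result on the bin
#' scale (the schema stores a bin, not a fraction).
#'
#' @param x Count bins; `NA`s are dropped.
#' @return A single count bin.
#' @export
#' @examples
#' median_count_bin(c("2", "3", "4"))      # "3"
#' median_count_bin(c("10", "11-50"))      # "10" (lower middle)
median_count_bin <- function(x) {
  lv <- as.integer(count_bin(x))
  lv <- lv[!is.na(lv)]
  if (!length(lv)) stop("no counts to take a median of", call. = FALSE)
  lv <- sort(lv)
  .bin_from_level(lv[floor((length(lv) + 1L) / 2L)])
}

#' Ordinal distance between count bins
#'
#' Number of steps separating two bins on the 12-level scale; `10` and
#' `11-50` are adjacent (distance 1).
#'
#' @param a,b Count bins; vectors recycle.
#' @return Integer vector of ordinal distances.
#' @export
count_bin_distance <- function(a, b) {
  abs(as.integer(count_bin(a)) - as.integer(count_bin(b)))
}
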