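#' Scale definitions for PSS-10, GAD-7 and PHQ-9
#'
#' A scale definition names the instrument, its item count and coded
#' response range, the 1-based indices of reverse-scored items, and (for
#' GAD-7 and PHQ-9) the cut-off marking moderate severity. The PSS-10
#' follows the instrument's published convention of reverse-scoring its
#' four positively stated items (items 4, 5, 7 and 8); it carries no
#' moderate cut-off. GAD-7 and PHQ-9 flag moderate anxiety/depressive mood
#' at a total score of 10 or more.
#'
#' @param name One of \code{"PSS"}, \code{"GAD7"}, \code{"PHQ9"}.
#' @return An object of class \code{scale_definition}: a list with fields
#'   \code{name}, \code{item_count}, \code{response_range} (length-2
#'   integer), \code{reverse_items}, \code{moderate_cutoff} (or \code{NA}),
#'   and \code{prefix} (cohort column prefix).
#' @examples
#' scale_definition("PSS")$reverse_items   # 4 5 7 8
#' scale_definition("PHQ9")$moderate_cutoff  # 10
#' @export
scale_definition <- function(name = c("PSS", "GAD7", "PHQ9")) {
  name <- match.arg(name)
  def <- switch(name,
    PSS = list(name = "PSS", item_count = 10L, response_range = c(0L, 4L),
               reverse_items = c(4L, 5L, 7L, 8L), moderate_cutoff = NA_integer_,
               prefix = "pss"),
    GAD7 = list(name = "GAD7", item_count = 7L, response_range = c(0L, 3L),
                reverse_items = integer(0), moderate_cutoff = 10L,
                prefix = "gad"),
    PHQ9 = list(name = "PHQ9", item_count = 9L, response_range = c(0L, 3L),
                reverse_items = integer(0), moderate_cutoff = 10L,
                prefix = "phq")
  )
  stopifnot(all(def$reverse_items >= 1L),
            all(def$reverse_items <= def$item_count))
  max_total <- def$item_count * def$response_range[2]
  if (!is.na(def$moderate_cutoff)) {
    stopifnot(def$moderate_cutoff >= 0, def$moderate_cutoff <= max_total)
  }
  structure(def, class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items coded %d..%d\n", x$name,
              x$item_count, x$response_range[1], x$response_range[2]))
  if (length(x$reverse_items)) {
    cat("  reverse-scored items:", paste(x$reverse_items, collapse = ", "),
        "\n")
  }
  if (!is.na(x$moderate_cutoff)) {
    cat("  moderate cut-off: total >=", x$moderate_cutoff, "\n")
  }
  invisible(x)
}

#' Score a scale from raw item responses
#'
#' Sums the item responses, with each reverse-scored item \code{i}
#' contributing \code{max - raw[i]} (where \code{max} is the top of the
#' response range), the standard reverse-coding rule for instruments whose
#' positively stated items run against the construct.
#'
#' @param responses Integer vector of raw item responses, in item order.
#' @param scale A [scale_definition()].
#' @param id Optional respondent identifier used in error messages.
#' @return Integer total score.
#' @examples
#' score_scale(rep(1, 9), scale_definition("PHQ9"))   # 9
#' score_scale(rep(0, 10), scale_definition("PSS"))   # 16
#' @export
score_scale <- function(responses, scale, id = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  who <- if (is.null(id)) "" else paste0(" (respondent ", id, ")")
  if (length(responses) != scale$item_count) {
    stop(scale$name, who, ": expected ", scale$item_count,
         " responses, got ", length(responses))
  }
  bad <- which(is.na(responses) | responses < scale$response_range[1] |
                 responses > scale$response_range[2] |
                 responses != round(responses))
  if (length(bad)) {
    stop(scale$name, who, ": missing or out-of-range response at item(s) ",
         paste(bad, collapse = ", "))
  }
  contrib <- responses
  if (length(scale$reverse_items)) {
    contrib[scale$reverse_items] <-
      scale$response_range[2] - responses[scale$reverse_items]
  }
  as.integer(sum(contrib))
}

#' Classify a scale total against the moderate-severity cut-off
#'
#' @param total Integer total score within the scale's achievable range.
#' @param scale A [scale_definition()] carrying a moderate cut-off (GAD-7 or
#'   PHQ-9). Calling this on the PSS, which has no conventional moderate
#'   cut-off, is an error.
#' @return Logical: \code{TRUE} iff \code{total >= cutoff}.
#' @examples
#' classify_moderate(10, scale_definition("PHQ9"))  # TRUE
#' classify_moderate(9, scale_definition("PHQ9"))   # FALSE
#' @export
classify_moderate <- function(total, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (is.na(scale$moderate_cutoff)) {
    stop("scale ", scale$name, " has no moderate-severity cut-off")
  }
  max_total <- scale$item_count * scale$response_range[2]
  min_total <- scale$item_count * scale$response_range[1]
  if (is.na(total) || total < min_total || total > max_total) {
    stop(scale$name, ": total ", total, " outside achievable range [",
         min_total, ", ", max_total, "]")
  }
  total >= scale$moderate_cutoff
}

#' Binarize a multiple-choice answer over a fixed option universe
#'
#' Multiple-choice survey questions (spare-time activities, online-class
#' difficulties) are transformed into one binary indicator per option:
#' 1 where the option was selected, 0 elsewhere.
#'
#' @param selected Character vector of selected option labels (possibly
#'   empty).
#' @param option_universe Ordered character vector of all options.
#' @return Named integer vector of 0/1 flags, one per option, in universe
#'   order.
#' @examples
#' binarize_multichoice(c("sleep", "study"), spare_time_options())
#' @export
binarize_multichoice <- function(selected, option_universe) {
  stopifnot(is.character(option_universe), length(option_universe) >= 1,
            !anyDuplicated(option_universe))
  selected <- as.character(selected)
  unknown <- setdiff(selected, option_universe)
  if (length(unknown)) {
    stop("unknown option label(s): ", paste(unknown, collapse = ", "))
  }
  out <- as.integer(option_universe %in% selected)
  names(out) <- option_universe
  out
}

#' Score the three mental-health scales for every cohort respondent
#'
#' @param cohort Validated cohort data frame.
#' @return Data frame with columns \code{id}, \code{grade}, \code{pss_total}
#'   (0..40), \code{gad7_total} (0..21), \code{phq9_total} (0..27),
#'   \code{moderate_anxiety} and \code{moderate_depression} (0/1 flags at
#'   the GAD-7/PHQ-9 cut-off of 10).
#' @export
score_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort, drop_incomplete = FALSE)
  scales <- lapply(c("PSS", "GAD7", "PHQ9"), scale_definition)
  totals <- lapply(scales, function(sc) {
    mat <- as.matrix(cohort[, paste0(sc$prefix, seq_len(sc$item_count))])
    vapply(seq_len(nrow(mat)), function(r) {
      score_scale(mat[r, ], sc, id = cohort$id[r])
    }, integer(1))
  })
  names(totals) <- c("pss", "gad7", "phq9")
  gad <- scale_definition("GAD7")
  phq <- scale_definition("PHQ9")
  data.frame(
    id = cohort$id,
    grade = cohort$grade,
    pss_total = totals$pss,
    gad7_total = totals$gad7,
    phq9_total = totals$phq9,
    moderate_anxiety = as.integer(vapply(totals$gad7, classify_moderate,
                                         logical(1), scale = gad)),
    moderate_depression = as.integer(vapply(totals$phq9, classify_moderate,
                                            logical(1), scale = phq)),
    stringsAsFactors = FALSE
  )
}
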