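#' Analysis-item schema for the 43 survey variables
#'
#' The cohort analysed by this package carries, per respondent, 43 coded
#' analysis variables grouped into seven blocks: 7 attitude items toward the
#' pandemic on a 5-point agreement scale coded -2..+2, 1 binary school
#' dropout-intention item, the 10 PSS items (0..4), the 7 GAD-7 items
#' (0..3), the 9 PHQ-9 items (0..3), 6 binary spare-time activity flags and
#' 3 binary online-class-difficulty flags.
#'
#' @return A data frame with one row per analysis item and columns
#'   \code{item} (column name in the cohort CSV), \code{block},
#'   \code{min}, \code{max} (inclusive coded range) and \code{nlevels}.
#' @examples
#' nrow(item_schema())  # 43
#' @export
item_schema <- function() {
  blocks <- list(
    attitude = list(items = paste0("att", 1:7), min = -2L, max = 2L),
    dropout = list(items = "dropout", min = 0L, max = 1L),
    pss = list(items = paste0("pss", 1:10), min = 0L, max = 4L),
    gad7 = list(items = paste0("gad", 1:7), min = 0L, max = 3L),
    phq9 = list(items = paste0("phq", 1:9), min = 0L, max = 3L),
    spare_time = list(items = paste0("st_", spare_time_options()),
                      min = 0L, max = 1L),
    online_difficulty = list(items = paste0("od_", online_difficulty_options()),
                             min = 0L, max = 1L)
  )
  out <- do.call(rbind, lapply(names(blocks), function(b) {
    x <- blocks[[b]]
    data.frame(item = x$items, block = b, min = x$min, max = x$max,
               stringsAsFactors = FALSE)
  }))
  out$nlevels <- out$max - out$min + 1L
  rownames(out) <- NULL
  out
}

#' @rdname item_schema
#' @export
spare_time_options <- function() {
  c("sleep", "game", "read", "study", "exercise", "friends")
}

#' @rdname item_schema
#' @export
online_difficulty_options <- function() {
  c("routine", "interact", "social")
}

#' Expected column order of the cohort CSV
#' @return Character vector: \code{id}, \code{grade}, \code{sex}, then the
#'   43 analysis items in schema order.
#' @export
cohort_columns <- function() {
  c("id", "grade", "sex", item_schema()$item)
}

#' Validate a cohort data frame against the item schema
#'
#' Checks column presence and order-independence, coded ranges, grade and
#' sex levels, and respondent-id uniqueness. Rows failing validation are
#' reported with their row numbers and the offending item.
#'
#' @param cohort A data frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param drop_incomplete Drop (with a message) rows containing any missing
#'   analysis variable, mirroring a complete-case analysis policy; when
#'   \code{FALSE}, missingness is an error.
#' @return The validated (possibly row-filtered) data frame, invisibly
#'   classed as before; attribute \code{n_dropped} records exclusions.
#' @export
validate_cohort <- function(cohort, drop_incomplete = TRUE) {
  stopifnot(is.data.frame(cohort))
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cohort <- cohort[, cols]
  if (anyDuplicated(cohort$id)) {
    dup <- unique(cohort$id[duplicated(cohort$id)])
    stop("duplicated respondent_id: ", paste(dup, collapse = ", "))
  }
  schema <- item_schema()
  n_dropped <- 0L
  incomplete <- !stats::complete.cases(cohort[, schema$item])
  if (any(incomplete)) {
    if (!drop_incomplete) {
      stop("missing analysis values in rows: ",
           paste(which(incomplete), collapse = ", "))
    }
    message("dropping ", sum(incomplete),
            " record(s) with missing analysis values")
    n_dropped <- sum(incomplete)
    cohort <- cohort[!incomplete, , drop = FALSE]
  }
  if (!all(cohort$grade %in% 1:4)) {
    bad <- which(!cohort$grade %in% 1:4)
    stop("grade outside 1..4 in rows: ", paste(bad, collapse = ", "))
  }
  if (!all(cohort$sex %in% c("men", "women"))) {
    bad <- which(!cohort$sex %in% c("men", "women"))
    stop("sex must be 'men' or 'women'; bad rows: ",
         paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(schema))) {
    v <- cohort[[schema$item[i]]]
    ok <- v >= schema$min[i] & v <= schema$max[i] & v == round(v)
    if (!all(ok)) {
      stop("item ", schema$item[i], " out of range [", schema$min[i], ", ",
           schema$max[i], "] for respondent(s) ",
           paste(cohort$id[!ok], collapse = ", "))
    }
  }
  rownames(cohort) <- NULL
  attr(cohort, "n_dropped") <- n_dropped
  cohort
}

#' Read and write cohort CSV files
#'
#' The cohort format is a UTF-8 comma-separated file with a header row and
#' the columns listed by [cohort_columns()]. `read_cohort()` validates the
#' rows against the item schema; `write_cohort()` writes a file that
#' round-trips through `read_cohort()` unchanged.
#'
#' @param path Path to a CSV file.
#' @param drop_incomplete Passed to [validate_cohort()].
#' @return `read_cohort()` returns the validated data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, drop_incomplete = TRUE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
  validate_cohort(cohort, drop_incomplete = drop_incomplete)
}

#' @rdname read_cohort
#' @param cohort Validated cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort, drop_incomplete = FALSE)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
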