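#' Configuration for the synthetic survey cohort generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: ordinal symptom items driven by a general distress factor plus
#' block factors (stress, anxiety, depression, attitude) and thresholded
#' into their coded levels; grade-dependent latent shifts so junior grades
#' show more distress; and binary lifestyle/difficulty/dropout items drawn
#' at per-grade prevalences. Default per-grade sample sizes are the four
#' grade strata of the study cohort (123/110/121/100) and default binary
#' prevalences follow the observed per-grade frequencies of the printed
#' contingency rows.
#'
#' @param n_per_grade Integer vector of length 4: respondents in grades
#'   1..4.
#' @param factor_loadings 43 x 5 numeric matrix (rows = analysis items in
#'   schema order, columns \code{general}, \code{stress}, \code{anxiety},
#'   \code{depression}, \code{attitude}). Defaults to
#'   [default_factor_loadings()].
#' @param grade_shift Numeric length 4: mean offset of the latent general
#'   distress factor per grade; it reaches each item through the item's
#'   general-factor loading (so reverse-keyed items shift coherently).
#' @param binary_prevalence 10 x 4 numeric matrix in \[0,1\] (rows = the 6
#'   spare-time flags, 3 difficulty flags and dropout; columns = grades).
#' @param ordinal_thresholds Named list of strictly increasing cut-point
#'   vectors per ordinal block (\code{attitude}, \code{pss}, \code{gad7},
#'   \code{phq9}); an item's coded level is the number of cut-points its
#'   latent score exceeds, offset to the block's coded minimum.
#' @param item_difficulty Named numeric vector (one entry per ordinal
#'   analysis item): additive latent offset controlling how readily the
#'   item is endorsed. Real survey items differ widely in endorsement
#'   rates; spreading difficulties staggers the quantized z-score grids of
#'   the items, which is what gives respondent deviation profiles their
#'   quasi-continuous spread. Defaults to [default_item_difficulty()],
#'   an even spread within each block.
#' @param noise_sd Positive item-level noise standard deviation.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_per_grade = c(123L, 110L, 121L, 100L),
                              factor_loadings = default_factor_loadings(),
                              grade_shift = c(0.4, 0.15, -0.15, -0.4),
                              binary_prevalence = default_binary_prevalence(),
                              ordinal_thresholds = default_ordinal_thresholds(),
                              item_difficulty = default_item_difficulty(),
                              noise_sd = 0.5,
                              seed = 1L) {
  schema <- item_schema()
  ordinal_items <- schema$item[schema$block %in%
                                 c("attitude", "pss", "gad7", "phq9")]
  binary_items <- schema$item[schema$block %in%
                                c("spare_time", "online_difficulty", "dropout")]
  stopifnot(length(n_per_grade) == 4, all(n_per_grade >= 1),
            all(n_per_grade == round(n_per_grade)))
  stopifnot(is.matrix(factor_loadings),
            nrow(factor_loadings) == nrow(schema),
            ncol(factor_loadings) == length(factor_names()))
  if (is.null(rownames(factor_loadings))) {
    rownames(factor_loadings) <- schema$item
  }
  stopifnot(identical(rownames(factor_loadings), schema$item))
  stopifnot(length(grade_shift) == 4, is.numeric(grade_shift))
  stopifnot(is.matrix(binary_prevalence),
            nrow(binary_prevalence) == length(binary_items),
            ncol(binary_prevalence) == 4,
            all(binary_prevalence >= 0), all(binary_prevalence <= 1))
  if (is.null(rownames(binary_prevalence))) {
    rownames(binary_prevalence) <- binary_items
  }
  stopifnot(identical(rownames(binary_prevalence), binary_items))
  stopifnot(setequal(names(ordinal_thresholds),
                     c("attitude", "pss", "gad7", "phq9")))
  for (b in names(ordinal_thresholds)) {
    th <- ordinal_thresholds[[b]]
    nlev <- schema$nlevels[schema$block == b][1]
    if (length(th) != nlev - 1 || any(diff(th) <= 0)) {
      stop("ordinal_thresholds$", b, " must be ", nlev - 1,
           " strictly increasing cut-points")
    }
  }
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0)
  if (is.null(names(item_difficulty))) {
    names(item_difficulty) <- ordinal_items
  }
  stopifnot(setequal(names(item_difficulty), ordinal_items),
            is.numeric(item_difficulty))
  structure(list(
    n_per_grade = as.integer(n_per_grade),
    factor_loadings = factor_loadings,
    grade_shift = as.numeric(grade_shift),
    binary_prevalence = binary_prevalence,
    ordinal_thresholds = ordinal_thresholds,
    item_difficulty = item_difficulty[ordinal_items],
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

factor_names <- function() {
  c("general", "stress", "anxiety", "depression", "attitude")
}

#' @rdname simulation_config
#' @export
default_factor_loadings <- function() {
  schema <- item_schema()
  L <- matrix(0, nrow(schema), length(factor_names()),
              dimnames = list(schema$item, factor_names()))
  L[schema$block == "pss", c("general", "stress")] <-
    rep(c(0.7, 0.5), each = sum(schema$block == "pss"))
  L[schema$block == "gad7", c("general", "anxiety")] <-
    rep(c(0.7, 0.5), each = sum(schema$block == "gad7"))
  L[schema$block == "phq9", c("general", "depression")] <-
    rep(c(0.7, 0.5), each = sum(schema$block == "phq9"))
  L[schema$block == "attitude", c("general", "attitude")] <-
    rep(c(0.2, 0.6), each = sum(schema$block == "attitude"))
  # positively stated PSS items run against distress; their raw responses
  # load negatively so that reverse scoring restores coherence
  rev_items <- paste0("pss", scale_definition("PSS")$reverse_items)
  L[rev_items, ] <- -L[rev_items, ]
  L
}

#' @rdname simulation_config
#' @export
default_binary_prevalence <- function() {
  n <- c(123, 110, 121, 100)
  yes <- rbind(
    st_sleep    = c(63, 60, 82, 46),
    st_game     = c(20, 33, 31, 25),
    st_read     = c(9, 13, 14, 9),
    st_study    = c(81, 46, 58, 34),
    st_exercise = c(26, 42, 49, 28),
    st_friends  = c(40, 38, 53, 35),
    od_routine  = c(40, 32, 21, 19),
    od_interact = c(31, 15, 23, 28),
    od_social   = c(65, 62, 60, 46),
    dropout     = c(65, 51, 33, 14)
  )
  p <- sweep(yes, 2, n, "/")
  schema <- item_schema()
  binary_items <- schema$item[schema$block %in%
                                c("spare_time", "online_difficulty", "dropout")]
  p[binary_items, , drop = FALSE]
}

#' @rdname simulation_config
#' @export
default_item_difficulty <- function() {
  schema <- item_schema()
  ordinal_blocks <- c("attitude", "pss", "gad7", "phq9")
  out <- unlist(lapply(ordinal_blocks, function(b) {
    items <- schema$item[schema$block == b]
    stats::setNames(seq(-0.7, 0.7, length.out = length(items)), items)
  }))
  out
}

#' @rdname simulation_config
#' @export
default_ordinal_thresholds <- function() {
  list(
    attitude = c(-1.15, -0.40, 0.40, 1.15),
    pss = c(-1.15, -0.40, 0.40, 1.15),
    gad7 = c(0.35, 1.10, 1.80),
    phq9 = c(0.35, 1.10, 1.80)
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  n per grade:", paste(x$n_per_grade, collapse = "/"),
      " (total", sum(x$n_per_grade), ")\n")
  cat("  grade shift:", paste(format(x$grade_shift), collapse = ", "), "\n")
  cat("  noise sd:", x$noise_sd, "  seed:", x$seed, "\n")
  hub <- attr(x, "planted_hubs")
  if (!is.null(hub)) {
    cat("  planted hub(s):", paste(hub, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a synthetic survey cohort
#'
#' Draws per-respondent latent factors (general distress plus four block
#' factors), builds each ordinal item as
#' \code{loadings \%*\% factors + grade_shift + noise} thresholded into its
#' coded levels, and draws each binary item by thresholding its own latent
#' score at the per-grade prevalence quantile (reducing to an independent
#' Bernoulli draw when the item has no factor loadings, the default).
#'
#' @param config A [simulation_config()].
#' @return A validated cohort data frame (one row per respondent, columns
#'   per [cohort_columns()]).
#' @examples
#' cfg <- simulation_config(n_per_grade = c(10, 10, 10, 10), seed = 7)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort)  # 40
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  schema <- item_schema()
  set.seed(config$seed)
  n <- sum(config$n_per_grade)
  grade <- rep(1:4, times = config$n_per_grade)
  # sex frequencies follow the cohort's per-grade men/women split
  p_men <- c(80, 70, 75, 64) / c(123, 110, 121, 100)
  sex <- ifelse(stats::runif(n) < p_men[grade], "men", "women")
  factors <- matrix(stats::rnorm(n * length(factor_names())), nrow = n,
                    dimnames = list(NULL, factor_names()))
  # grade effects enter as a mean offset of the general distress factor,
  # reaching each item through its (signed) general loading
  factors[, "general"] <- factors[, "general"] + config$grade_shift[grade]
  out <- data.frame(id = sprintf("S%04d", seq_len(n)), grade = grade,
                    sex = sex, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(schema))) {
    item <- schema$item[i]
    block <- schema$block[i]
    lam <- config$factor_loadings[item, ]
    latent <- as.numeric(factors %*% lam) +
      stats::rnorm(n, 0, config$noise_sd)
    if (block %in% names(config$ordinal_thresholds)) {
      th <- config$ordinal_thresholds[[block]]
      out[[item]] <- findInterval(latent + config$item_difficulty[item],
                                  th) + schema$min[i]
    } else {
      p <- config$binary_prevalence[item, grade]
      sd_total <- sqrt(sum(lam^2) + config$noise_sd^2)
      if (sd_total == 0) {
        out[[item]] <- as.integer(p >= 1)
      } else {
        out[[item]] <- as.integer(latent > stats::qnorm(1 - p) * sd_total)
      }
    }
  }
  validate_cohort(out[, cohort_columns()], drop_incomplete = FALSE)
}

#' Block-structured configuration for ICN hub experiments
#'
#' A simulation configuration in which each ordinal scale forms a tight
#' single-factor block (loading 0.9, no shared general factor), item
#' difficulties are flat, all binary items sit at 50\% prevalence, the
#' grade shift is off and the item noise is small. Under these conditions
#' each block occupies a narrow band of the respondent's z-deviation line,
#' which is the regime in which planted-hub experiments
#' ([plant_hub_item()]) are interpretable.
#'
#' @param n_per_grade,noise_sd,seed Passed to [simulation_config()].
#' @return A \code{simulation_config}.
#' @export
icn_block_config <- function(n_per_grade = rep(50L, 4), noise_sd = 0.15,
                             seed = 1L) {
  schema <- item_schema()
  L <- default_factor_loadings()
  L[, ] <- 0
  L[schema$block == "pss", "stress"] <- 0.9
  L[schema$block == "gad7", "anxiety"] <- 0.9
  L[schema$block == "phq9", "depression"] <- 0.9
  L[schema$block == "attitude", "attitude"] <- 0.9
  bp <- default_binary_prevalence()
  bp[, ] <- 0.5
  # the default within-block difficulty spread is kept: it staggers the
  # blocks' quantized z-grids, which keeps the thresholded-edge budget
  # from being monopolized by co-located same-code pairs
  simulation_config(n_per_grade = n_per_grade, factor_loadings = L,
                    grade_shift = rep(0, 4), binary_prevalence = bp,
                    noise_sd = noise_sd, seed = seed)
}

block_factor_map <- function() {
  c(pss = "stress", gad7 = "anxiety", phq9 = "depression",
    attitude = "attitude")
}

#' Plant a hub item into a simulation configuration
#'
#' Restructures the latent model so that one item persistently occupies
#' the bridging position between two item blocks in the thresholded
#' intra-individual covariance network. The two bridge blocks are placed
#' on a shared latent factor with opposite difficulty offsets
#' (\code{separation} apart), so their z-deviation bands sit a controlled
#' distance apart in every respondent, and the hub item is given the
#' shared factor with zero offset, landing midway between the bands. Its
#' betweenness centrality is then systematically enriched relative to the
#' exchangeable null.
#'
#' The offset geometry matters: if the bands are too far apart the hub's
#' bridging edges fall outside the proportional-threshold budget, and if
#' they are too close the blocks connect directly and no bottleneck
#' forms. The default separation targets the window between those
#' regimes. All planted quantities are blended with the original
#' configuration, so \code{strength} near 0 leaves it essentially
#' unchanged and \code{strength = 1} imposes the full construction.
#'
#' @param config A [simulation_config()]; [icn_block_config()] is the
#'   intended base.
#' @param hub_item Name of one of the 43 analysis items; should belong to
#'   one of the two bridge blocks.
#' @param strength Blend weight in (0, 1].
#' @param bridge_blocks Character length 2: the ordinal item blocks
#'   (\code{"pss"}, \code{"gad7"}, \code{"phq9"}, \code{"attitude"}) whose
#'   communities the hub will straddle.
#' @param separation Difficulty offset between the two bridge blocks at
#'   full strength, in latent SD units.
#' @return A new \code{simulation_config}; planted items are recorded in
#'   attribute \code{planted_hubs}.
#' @export
plant_hub_item <- function(config, hub_item, strength,
                           bridge_blocks = c("pss", "phq9"),
                           separation = 0.45) {
  stopifnot(inherits(config, "simulation_config"))
  schema <- item_schema()
  if (!hub_item %in% schema$item) {
    stop("hub_item must be one of the 43 analysis items; got ", hub_item)
  }
  if (!is.numeric(strength) || length(strength) != 1 ||
      strength <= 0 || strength > 1) {
    stop("strength must lie in (0, 1]")
  }
  fmap <- block_factor_map()
  stopifnot(length(bridge_blocks) == 2,
            all(bridge_blocks %in% names(fmap)))
  shared <- fmap[[bridge_blocks[1]]]
  L <- config$factor_loadings
  d <- config$item_difficulty
  blend <- function(old, target) (1 - strength) * old + strength * target
  for (k in 1:2) {
    items <- setdiff(schema$item[schema$block == bridge_blocks[k]], hub_item)
    target <- matrix(0, length(items), ncol(L),
                     dimnames = list(items, colnames(L)))
    target[, shared] <- 0.9
    L[items, ] <- blend(L[items, , drop = FALSE], target)
    offset <- (if (k == 1) -1 else 1) * separation / 2
    d[items] <- blend(d[items], offset)
  }
  hub_target <- stats::setNames(numeric(ncol(L)), colnames(L))
  hub_target[shared] <- 0.9
  L[hub_item, ] <- blend(L[hub_item, ], hub_target)
  d[hub_item] <- blend(d[hub_item], 0)
  out <- config
  out$factor_loadings <- L
  out$item_difficulty <- d
  attr(out, "planted_hubs") <- unique(c(attr(config, "planted_hubs"),
                                        hub_item))
  class(out) <- "simulation_config"
  out
}
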