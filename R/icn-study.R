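#' Fit the intra-individual covariance network analysis to a cohort
#'
#' One-stop front end for the ICN stage: standardizes the 43 analysis
#' items into per-respondent z-deviation profiles, selects the working
#' sparsity over a K grid by the connectedness / small-worldness /
#' modularity screen (or accepts a fixed K), computes rank-transformed
#' betweenness profiles at that sparsity, identifies hub items, and
#' correlates item centrality with the PSS / GAD-7 / PHQ-9 totals.
#'
#' @param cohort Validated cohort data frame.
#' @param K Fixed sparsity fraction; when \code{NULL} (default) the
#'   sparsity is selected from \code{k_grid} via [select_sparsity()].
#' @param criteria A [hub_criteria()].
#' @inheritParams select_sparsity
#' @return Object of class \code{icn_study} with components \code{K},
#'   \code{pass_rates} (NULL for fixed K), \code{z}, \code{profiles}
#'   (betweenness and rank matrices), \code{hubs}, \code{associations},
#'   \code{scores}, \code{criteria}, \code{seed}.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(simulation_config(n_per_grade = rep(20L, 4)))
#' fit <- icn_study(cohort, K = 0.14)
#' print(fit)
#' }
#' @export
icn_study <- function(cohort, K = NULL, k_grid = seq(0.05, 0.20, by = 0.01),
                      participant_fraction = 0.95, criteria = hub_criteria(),
                      n_null = 20L, seed = 1L) {
  cohort <- validate_cohort(cohort, drop_incomplete = FALSE)
  z <- zscore_items(cohort)
  pass_rates <- NULL
  if (is.null(K)) {
    sel <- select_sparsity(z, k_grid = k_grid,
                           participant_fraction = participant_fraction,
                           n_null = n_null, seed = seed)
    K <- sel$K
    pass_rates <- sel$pass_rates
  }
  profiles <- icn_profiles(z, K)
  hubs <- identify_hubs(profiles$rank, criteria)
  scores <- score_cohort(cohort)
  assoc <- centrality_association(
    profiles$rank, scores[, c("pss_total", "gad7_total", "phq9_total")])
  structure(list(K = K, pass_rates = pass_rates, z = z,
                 profiles = profiles, hubs = hubs, associations = assoc,
                 scores = scores, criteria = criteria, seed = seed),
            class = "icn_study")
}

#' @export
print.icn_study <- function(x, ...) {
  cat(sprintf("<icn_study> %d respondents, %d items, K = %.2f\n",
              nrow(x$z), ncol(x$z), x$K))
  hubs <- x$hubs[x$hubs$hub, , drop = FALSE]
  cat(sprintf("  hubs (rank <= %d in > %.0f%% of respondents): %s\n",
              x$criteria$rank_threshold,
              100 * x$criteria$prevalence_threshold,
              if (nrow(hubs)) paste(hubs$item, collapse = ", ") else "none"))
  flagged <- x$associations[x$associations$flagged %in% TRUE, , drop = FALSE]
  cat("  flagged centrality-symptom associations:", nrow(flagged), "\n")
  invisible(x)
}

#' @export
summary.icn_study <- function(object, ...) {
  print(object)
  if (!is.null(object$pass_rates)) {
    cat("screening pass rates by sparsity:\n")
    print(object$pass_rates, row.names = FALSE)
  }
  cat("top items by hub prevalence:\n")
  print(utils::head(object$hubs, 8), row.names = FALSE)
  flagged <- object$associations[object$associations$flagged %in% TRUE, ,
                                 drop = FALSE]
  if (nrow(flagged)) {
    cat("flagged associations (|rho| > 0.3, p < 0.001):\n")
    print(flagged, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.icn_study <- function(x, respondent = 1, ...) {
  z <- x$z[respondent, ]
  adj <- proportional_threshold(icn_weights(z), x$K)
  g <- adj_to_graph(adj)
  igraph::V(g)$name <- colnames(x$z)
  hubs <- x$hubs$item[x$hubs$hub]
  igraph::plot.igraph(
    g, vertex.size = 6, vertex.label.cex = 0.6,
    vertex.color = ifelse(igraph::V(g)$name %in% hubs, "tomato", "grey80"),
    ...)
  invisible(x)
}
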