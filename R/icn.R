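#' Standardize cohort items into per-respondent z-deviation profiles
#'
#' Each item is centred on its cohort mean and scaled by its cohort
#' standard deviation (denominator n - 1), so a respondent's profile
#' records how far each of their 43 coded responses deviates from the
#' group average in SD units. These deviations are the raw material of the
#' intra-individual covariance network.
#'
#' @param x Validated cohort data frame (the 43 analysis items are used)
#'   or a numeric respondents-by-items matrix.
#' @return Numeric matrix of z-scores, respondents by items, with
#'   respondent ids as row names where available.
#' @export
zscore_items <- function(x) {
  if (is.data.frame(x) && all(item_schema()$item %in% names(x))) {
    x <- validate_cohort(x, drop_incomplete = FALSE)
    m <- as.matrix(x[, item_schema()$item])
    rownames(m) <- x$id
  } else {
    m <- as.matrix(x)
    stopifnot(is.numeric(m))
  }
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("constant item(s) with zero SD: ",
         paste(colnames(m)[sdv == 0], collapse = ", "))
  }
  scale(m, center = mu, scale = sdv)[, , drop = FALSE]
}

#' Intra-individual covariance weights of one respondent
#'
#' For a z-deviation profile \eqn{z}, the similarity between items a and b
#' is \eqn{w_{ab} = \exp(-(z_a - z_b)^2)}: 1 when the two items deviate
#' from their group averages identically, and decaying toward 0 (never
#' reaching it) as the deviations diverge.
#'
#' @param z Numeric vector: one respondent's z-deviation profile.
#' @return Symmetric numeric matrix with unit diagonal, entries in (0, 1].
#' @examples
#' w <- icn_weights(c(0, 1, -1))
#' w[1, 2]  # exp(-1)
#' @export
icn_weights <- function(z) {
  labels <- names(z)
  z <- as.numeric(z)
  stopifnot(length(z) >= 2, !anyNA(z))
  d <- outer(z, z, "-")
  w <- exp(-d^2)
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  w
}

# Precompute the unordered pair index of a p-item network once.
pair_index <- function(p) {
  ij <- utils::combn(p, 2)
  list(i = ij[1, ], j = ij[2, ], m = ncol(ij))
}

# Indices (into the pair list) of the edges retained at sparsity K, for a
# respondent's z profile. Larger weight = smaller squared z-gap, so the
# top-K weights are the bottom-K squared gaps; ties at the cut break by
# lexicographic pair order.
threshold_pairs <- function(z, K, pairs) {
  n_edges <- round(K * pairs$m)
  if (n_edges < 1) {
    stop("K = ", K, " retains zero edges on ", pairs$m, " candidate pairs")
  }
  gap <- (z[pairs$i] - z[pairs$j])^2
  ord <- order(gap, pairs$i, pairs$j)
  ord[seq_len(min(n_edges, pairs$m))]
}

#' Proportional thresholding of an ICN weight matrix
#'
#' Retains exactly \code{round(K * p(p-1)/2)} of the largest off-diagonal
#' weights as binary undirected edges (for the 43-item network,
#' K = 0.14 keeps 126 of 903 pairs). Ties at the cut are resolved by
#' lexicographic node-pair order.
#'
#' @param w Symmetric weight matrix from [icn_weights()].
#' @param K Sparsity fraction in (0, 1\].
#' @return Binary symmetric adjacency matrix (0/1, zero diagonal) with
#'   attributes \code{K} and \code{n_edges}.
#' @export
proportional_threshold <- function(w, K) {
  w <- as.matrix(w)
  p <- ncol(w)
  stopifnot(nrow(w) == p, p >= 2, is.numeric(K), length(K) == 1,
            K > 0, K <= 1)
  pairs <- pair_index(p)
  gap <- -w[cbind(pairs$i, pairs$j)]   # descending weight order
  n_edges <- round(K * pairs$m)
  if (n_edges < 1) {
    stop("K = ", K, " retains zero edges on ", pairs$m, " candidate pairs")
  }
  keep <- order(gap, pairs$i, pairs$j)[seq_len(min(n_edges, pairs$m))]
  adj <- matrix(0L, p, p, dimnames = dimnames(w))
  adj[cbind(pairs$i[keep], pairs$j[keep])] <- 1L
  adj[cbind(pairs$j[keep], pairs$i[keep])] <- 1L
  attr(adj, "K") <- K
  attr(adj, "n_edges") <- as.integer(length(keep))
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

#' Connectedness, small-worldness and modularity of a thresholded graph
#'
#' Screens one binarized network against the three organization criteria
#' used to pick the working sparsity: the fraction of nodes in the largest
#' connected component; small-worldness
#' \eqn{\sigma = (C/\bar C_{null}) / (L/\bar L_{null})} against an
#' ensemble of degree-preserving rewired null graphs (C = mean local
#' clustering with degree-<2 nodes counted as 0; L = characteristic path
#' length on the largest component); and modularity Q of the best
#' partition found by seeded Louvain restarts.
#'
#' @param adj Binary symmetric adjacency matrix with at least one edge.
#' @param n_null Number of rewired null graphs (each with 10x the edge
#'   count of swap attempts).
#' @param seed Integer seed for rewiring and Louvain restarts.
#' @param louvain_restarts Restarts for modularity maximization; the best
#'   Q is reported.
#' @return List with \code{connectedness}, \code{sigma} (NA, with
#'   \code{sigma_defined = FALSE}, when the null ensemble has no
#'   triangles), \code{Q}, and the underlying \code{C}, \code{L},
#'   \code{C_null}, \code{L_null}.
#' @export
graph_screen <- function(adj, n_null = 20L, seed = 1L,
                         louvain_restarts = 5L) {
  g <- adj_to_graph(adj)
  if (igraph::ecount(g) < 1) stop("graph has no edges")
  comp <- igraph::components(g)
  connectedness <- max(comp$csize) / igraph::vcount(g)
  cl <- clustering_and_length(g, comp)
  set.seed(seed)
  null_C <- numeric(n_null)
  null_L <- numeric(n_null)
  for (r in seq_len(n_null)) {
    gn <- igraph::rewire(g, igraph::keeping_degseq(
      niter = 10 * igraph::ecount(g)))
    nl <- clustering_and_length(gn, igraph::components(gn))
    null_C[r] <- nl$C
    null_L[r] <- nl$L
  }
  sigma_defined <- mean(null_C) > 0 && cl$L > 0 && mean(null_L) > 0
  sigma <- if (sigma_defined) {
    (cl$C / mean(null_C)) / (cl$L / mean(null_L))
  } else {
    NA_real_
  }
  best_q <- -Inf
  for (r in seq_len(louvain_restarts)) {
    set.seed(seed + r)
    q <- max(igraph::cluster_louvain(g)$modularity)
    if (q > best_q) best_q <- q
  }
  list(connectedness = connectedness, sigma = sigma,
       sigma_defined = sigma_defined, Q = best_q,
       C = cl$C, L = cl$L, C_null = mean(null_C), L_null = mean(null_L))
}

clustering_and_length <- function(g, comp) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  C <- mean(cc)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  L <- if (igraph::vcount(giant) > 1) {
    igraph::mean_distance(giant, directed = FALSE)
  } else {
    0
  }
  list(C = C, L = L)
}

#' Select the working sparsity over a K grid
#'
#' Evaluates the three screening criteria (connectedness > 0.8, sigma > 1,
#' Q > 0.3) for every respondent's thresholded network at every grid
#' sparsity, and returns the sparsest (smallest) K at which more than
#' \code{participant_fraction} of respondents satisfy all three.
#'
#' @param z Z-profile matrix from [zscore_items()].
#' @param k_grid Increasing sparsity grid (default 0.05..0.20 by 0.01).
#' @param participant_fraction Required fraction of passing respondents
#'   (strictly exceeded; default 0.95).
#' @param connectedness_min,sigma_min,q_min Screening thresholds.
#' @inheritParams graph_screen
#' @return List with \code{K} (selected sparsity) and \code{pass_rates}
#'   (per-K data frame). If no grid K qualifies, an error carrying the
#'   pass-rate table is raised.
#' @export
select_sparsity <- function(z, k_grid = seq(0.05, 0.20, by = 0.01),
                            participant_fraction = 0.95,
                            connectedness_min = 0.8, sigma_min = 1,
                            q_min = 0.3, n_null = 20L, seed = 1L) {
  z <- as.matrix(z)
  stopifnot(all(k_grid > 0), all(k_grid <= 1), !is.unsorted(k_grid))
  p <- ncol(z)
  pairs <- pair_index(p)
  pass <- matrix(NA, nrow(z), length(k_grid))
  for (r in seq_len(nrow(z))) {
    for (ki in seq_along(k_grid)) {
      keep <- threshold_pairs(z[r, ], k_grid[ki], pairs)
      adj <- matrix(0L, p, p)
      adj[cbind(pairs$i[keep], pairs$j[keep])] <- 1L
      adj[cbind(pairs$j[keep], pairs$i[keep])] <- 1L
      sc <- graph_screen(adj, n_null = n_null, seed = seed + r)
      pass[r, ki] <- sc$connectedness > connectedness_min &&
        sc$sigma_defined && sc$sigma > sigma_min && sc$Q > q_min
    }
  }
  rates <- colMeans(pass)
  tab <- data.frame(K = k_grid, pass_rate = rates)
  ok <- which(rates > participant_fraction)
  if (!length(ok)) {
    stop("no grid sparsity satisfies the screening criteria for > ",
         participant_fraction * 100, "% of respondents\n",
         paste(utils::capture.output(print(tab, row.names = FALSE)),
               collapse = "\n"))
  }
  list(K = k_grid[min(ok)], pass_rates = tab)
}

#' Betweenness centrality with within-respondent ranks
#'
#' Unweighted shortest-path betweenness of every node of a thresholded
#' graph, rank-transformed in descending order (rank 1 = most central);
#' tied values share the minimum rank, so "rank <= r" keeps its top-share
#' interpretation under ties.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with numeric \code{betweenness} and integer \code{rank},
#'   both named by node.
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
#' rank_betweenness(star)$betweenness[1]  # 6 shortest paths via the centre
#' @export
rank_betweenness <- function(adj) {
  g <- adj_to_graph(adj)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (!is.null(colnames(adj))) names(btw) <- colnames(adj)
  list(betweenness = btw,
       rank = rank_descending_min(btw))
}

rank_descending_min <- function(x) {
  r <- as.integer(rank(-x, ties.method = "min"))
  names(r) <- names(x)
  r
}

#' Per-respondent centrality profiles at a fixed sparsity
#'
#' @param z Z-profile matrix from [zscore_items()].
#' @param K Sparsity fraction.
#' @return List of matrices (respondents x items): \code{betweenness} and
#'   integer \code{rank}.
#' @export
icn_profiles <- function(z, K) {
  z <- as.matrix(z)
  p <- ncol(z)
  pairs <- pair_index(p)
  btw <- matrix(NA_real_, nrow(z), p, dimnames = dimnames(z))
  for (r in seq_len(nrow(z))) {
    keep <- threshold_pairs(z[r, ], K, pairs)
    el <- cbind(pairs$i[keep], pairs$j[keep])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, p - igraph::vcount(g)))
    btw[r, ] <- igraph::betweenness(g, directed = FALSE)
  }
  ranks <- t(apply(btw, 1, function(row) as.integer(rank(-row,
                                                         ties.method = "min"))))
  dimnames(ranks) <- dimnames(btw)
  list(betweenness = btw, rank = ranks)
}

#' Hub-detection criteria
#'
#' Two published presets: \code{"results"} declares an item a hub when its
#' rank-transformed betweenness is within the top 10% (rank <= 4 of 43) in
#' more than 40% of respondents; \code{"figure"} is the looser top-12%
#' (rank <= 5) in at least 25% variant.
#'
#' @param preset \code{"results"} (default) or \code{"figure"}; ignored
#'   when both thresholds are given explicitly.
#' @param rank_threshold Integer rank cut (1..items).
#' @param prevalence_threshold Required respondent fraction in (0, 1\].
#' @return List with the two thresholds, class \code{hub_criteria}.
#' @export
hub_criteria <- function(preset = c("results", "figure"),
                         rank_threshold = NULL,
                         prevalence_threshold = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
                results = list(rank_threshold = 4L,
                               prevalence_threshold = 0.40),
                figure = list(rank_threshold = 5L,
                              prevalence_threshold = 0.25))
  if (!is.null(rank_threshold)) def$rank_threshold <- as.integer(rank_threshold)
  if (!is.null(prevalence_threshold)) {
    def$prevalence_threshold <- prevalence_threshold
  }
  stopifnot(def$rank_threshold >= 1,
            def$prevalence_threshold > 0, def$prevalence_threshold <= 1)
  structure(c(def, list(preset = preset)), class = "hub_criteria")
}

#' Identify hub items across respondents
#'
#' An item is a hub when its within-respondent betweenness rank is at or
#' above the rank threshold in more than the prevalence threshold of
#' respondents.
#'
#' @param ranks Respondents-by-items integer rank matrix (from
#'   [icn_profiles()]).
#' @param criteria A [hub_criteria()].
#' @return Data frame of all items with their top-rank \code{prevalence}
#'   and logical \code{hub}, sorted by prevalence (descending); hubs
#'   first. An empty hub set is legitimate.
#' @export
identify_hubs <- function(ranks, criteria = hub_criteria()) {
  ranks <- as.matrix(ranks)
  stopifnot(inherits(criteria, "hub_criteria"),
            criteria$rank_threshold <= ncol(ranks), nrow(ranks) >= 1)
  prevalence <- colMeans(ranks <= criteria$rank_threshold)
  out <- data.frame(
    item = colnames(ranks) %||% paste0("item", seq_len(ncol(ranks))),
    prevalence = as.numeric(prevalence),
    hub = as.numeric(prevalence) > criteria$prevalence_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$prevalence, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman association between item centrality and scale totals
#'
#' Correlates each item's rank-transformed betweenness (across
#' respondents) with each mental-health scale total, flagging pairs that
#' pass the reporting threshold |rho| > 0.3 with p < 0.001.
#'
#' @param ranks Respondents-by-items rank matrix, rows aligned with
#'   \code{totals}.
#' @param totals Data frame (or named matrix) of scale totals per
#'   respondent (e.g. columns \code{pss_total}, \code{gad7_total},
#'   \code{phq9_total}).
#' @param items,scales Optional subsets of item / total names to test
#'   (default: all).
#' @param rho_min,p_max Reporting thresholds.
#' @return Data frame with \code{item}, \code{scale}, \code{rho}, \code{p},
#'   \code{defined} (FALSE where a zero-variance vector leaves the
#'   correlation undefined) and \code{flagged}.
#' @export
centrality_association <- function(ranks, totals, items = NULL,
                                   scales = NULL, rho_min = 0.3,
                                   p_max = 0.001) {
  ranks <- as.matrix(ranks)
  totals <- as.data.frame(totals)
  num <- vapply(totals, is.numeric, logical(1))
  totals <- totals[, num, drop = FALSE]
  stopifnot(nrow(ranks) == nrow(totals))
  items <- items %||% colnames(ranks)
  scales <- scales %||% colnames(totals)
  grid <- expand.grid(item = items, scale = scales,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- ranks[, grid$item[k]]
    y <- totals[[grid$scale[k]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(grid[k, ], rho = NA_real_, p = NA_real_,
                        defined = FALSE, flagged = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(grid[k, ], rho = unname(ct$estimate),
               p = unname(ct$p.value), defined = TRUE,
               flagged = abs(unname(ct$estimate)) > rho_min &
                 unname(ct$p.value) < p_max)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
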