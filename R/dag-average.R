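#' Bootstrap model averaging of hill-climbed network structures
#'
#' Learns a DAG on each of \code{B} nonparametric bootstrap resamples
#' (rows drawn with replacement, variable level sets held fixed) and
#' tabulates, for every unordered variable pair, the fraction of resamples
#' in which the pair is connected (presence strength) and, among those,
#' the fraction oriented each way (direction strength). The final averaged
#' graph keeps pairs whose presence strength reaches \code{threshold},
#' orients each by majority direction (ties toward the lower-indexed
#' source), and — should the majority orientations ever combine into a
#' cycle — drops the lowest-presence edge of each cycle until the result
#' is acyclic, recording what was dropped.
#'
#' @inheritParams hill_climb
#' @param B Number of bootstrap resamples (the reference analysis uses
#'   10,000; a few hundred is adequate for testing).
#' @param seed Integer seed driving the resamples.
#' @param threshold Presence-strength cut for keeping an edge.
#' @param progress Print a dot every 50 resamples.
#' @return Object of class \code{averaged_dag}; see
#'   [as.data.frame.averaged_dag()] for the pair table.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_per_grade = rep(25L, 4), seed = 3)
#' ds <- discrete_dataset(generate_cohort(cfg))
#' avg <- bootstrap_average(ds, B = 20, seed = 1)
#' }
#' @export
bootstrap_average <- function(ds, B = 200L, seed = 1L, threshold = 0.5,
                              max_params = 1e5, progress = FALSE) {
  stopifnot(inherits(ds, "discrete_dataset"))
  B <- as.integer(B)
  stopifnot(B >= 1)
  if (B > 5000L) {
    warning("B = ", B, " bootstrap resamples may take very long to run")
  }
  p <- length(ds$items)
  n <- nrow(ds$codes)
  dir_counts <- matrix(0L, p, p, dimnames = list(ds$items, ds$items))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- structure(list(codes = ds$codes[idx, , drop = FALSE],
                           nlevels = ds$nlevels, items = ds$items),
                      class = "discrete_dataset")
    dag <- hill_climb(boot, max_params = max_params)
    e <- dag_edges(dag)
    if (nrow(e)) {
      ij <- cbind(match(e[, 1], ds$items), match(e[, 2], ds$items))
      dir_counts[ij] <- dir_counts[ij] + 1L
    }
    if (progress && b %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  pairs <- utils::combn(p, 2)
  pair_tab <- data.frame(
    from = ds$items[pairs[1, ]],
    to = ds$items[pairs[2, ]],
    n_forward = dir_counts[t(pairs)],
    n_backward = dir_counts[t(pairs[2:1, ])],
    stringsAsFactors = FALSE
  )
  pair_tab$presence_strength <- (pair_tab$n_forward + pair_tab$n_backward) / B
  pair_tab$direction_strength <- ifelse(
    pair_tab$presence_strength > 0,
    pair_tab$n_forward / (pair_tab$n_forward + pair_tab$n_backward),
    NA_real_)
  keep <- pair_tab[pair_tab$presence_strength >= threshold, , drop = FALSE]
  edges <- if (nrow(keep)) {
    flip <- keep$direction_strength < 0.5   # ties (0.5) stay lower-index first
    data.frame(
      from = ifelse(flip, keep$to, keep$from),
      to = ifelse(flip, keep$from, keep$to),
      presence_strength = keep$presence_strength,
      direction_strength = ifelse(flip, 1 - keep$direction_strength,
                                  keep$direction_strength),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from = character(0), to = character(0),
               presence_strength = numeric(0),
               direction_strength = numeric(0), stringsAsFactors = FALSE)
  }
  res <- enforce_acyclic(ds$items, edges)
  structure(list(nodes = ds$items, pairs = pair_tab, edges = res$edges,
                 dropped_edges = res$dropped, B = B, threshold = threshold,
                 seed = seed),
            class = "averaged_dag")
}

# Drop the weakest edge of each directed cycle until the edge set is
# acyclic; deterministic (ties broken by lexicographic from/to).
enforce_acyclic <- function(nodes, edges) {
  dropped <- edges[0, , drop = FALSE]
  repeat {
    cyc <- find_cycle(nodes, edges)
    if (is.null(cyc)) break
    on_cycle <- which(paste(edges$from, edges$to) %in%
                        paste(cyc$from, cyc$to))
    ord <- on_cycle[order(edges$presence_strength[on_cycle],
                          edges$from[on_cycle], edges$to[on_cycle])]
    victim <- ord[1]
    message("averaged graph contained a cycle; dropping edge ",
            edges$from[victim], " -> ", edges$to[victim],
            " (presence ", edges$presence_strength[victim], ")")
    dropped <- rbind(dropped, edges[victim, , drop = FALSE])
    edges <- edges[-victim, , drop = FALSE]
  }
  rownames(edges) <- NULL
  list(edges = edges, dropped = dropped)
}

# Return the edges of one directed cycle, or NULL if acyclic.
find_cycle <- function(nodes, edges) {
  p <- length(nodes)
  adj <- rep(list(integer(0)), p)
  for (k in seq_len(nrow(edges))) {
    a <- match(edges$from[k], nodes)
    adj[[a]] <- c(adj[[a]], match(edges$to[k], nodes))
  }
  color <- integer(p)  # 0 unvisited, 1 on stack, 2 done
  parent <- integer(p)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (!is.null(cycle)) return()
      if (color[w] == 0L) {
        parent[w] <<- v
        visit(w)
      } else if (color[w] == 1L) {
        path <- v
        while (path[1] != w) path <- c(parent[path[1]], path)
        cycle <<- data.frame(from = nodes[path],
                             to = nodes[c(path[-1], w)],
                             stringsAsFactors = FALSE)
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L && is.null(cycle)) visit(v)
  }
  cycle
}

#' @export
print.averaged_dag <- function(x, ...) {
  cat(sprintf(
    "<averaged_dag> %d nodes; %d edges at presence >= %.2f (B = %d)\n",
    length(x$nodes), nrow(x$edges), x$threshold, x$B))
  if (nrow(x$dropped_edges)) {
    cat("  ", nrow(x$dropped_edges), "edge(s) dropped to restore acyclicity\n")
  }
  invisible(x)
}

#' @export
summary.averaged_dag <- function(object, n_show = 15, ...) {
  cat(sprintf("Bootstrap-averaged DAG (B = %d, threshold = %.2f, seed = %d)\n",
              object$B, object$threshold, object$seed))
  e <- object$edges[order(-object$edges$presence_strength), , drop = FALSE]
  cat(sprintf("%d of %d pairs retained as edges\n", nrow(e),
              nrow(object$pairs)))
  print(utils::head(e, n_show), row.names = FALSE)
  invisible(object)
}

#' Pair table of an averaged DAG
#'
#' @param x An \code{averaged_dag}.
#' @param what \code{"edges"} (the thresholded, acyclic edge list) or
#'   \code{"pairs"} (presence/direction strengths for every unordered
#'   pair).
#' @param ... Unused.
#' @return Data frame.
#' @export
as.data.frame.averaged_dag <- function(x, what = c("edges", "pairs"), ...) {
  switch(match.arg(what), edges = x$edges, pairs = x$pairs)
}

#' @export
plot.averaged_dag <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = x$nodes))
  igraph::plot.igraph(g, edge.width = 1 + 3 * x$edges$presence_strength,
                      vertex.size = 8, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Export an averaged DAG
#'
#' `write_dag_csv()` writes the edge list (source, target,
#' presence_strength, direction_strength); `write_dag_dot()` writes a DOT
#' file for rendering with graphviz.
#'
#' @param x An \code{averaged_dag}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dag_csv <- function(x, path) {
  stopifnot(inherits(x, "averaged_dag"))
  utils::write.csv(x$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dag_csv
#' @export
write_dag_dot <- function(x, path) {
  stopifnot(inherits(x, "averaged_dag"))
  lines <- c("digraph averaged_dag {",
             paste0("  \"", x$nodes, "\";"),
             if (nrow(x$edges)) {
               sprintf("  \"%s\" -> \"%s\" [weight=%.3f];",
                       x$edges$from, x$edges$to, x$edges$presence_strength)
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}
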