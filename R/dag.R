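#' Discrete dataset for Bayesian-network structure learning
#'
#' Encodes a data frame of categorical variables as an integer code matrix
#' with a fixed number of levels per variable. Level sets are fixed up
#' front (for survey cohorts, from the item schema: attitude 5 levels, PSS
#' 5, GAD-7 and PHQ-9 4, binary items 2) so that bootstrap resamples are
#' scored against the same state spaces regardless of which levels they
#' happen to contain.
#'
#' @param x A validated cohort data frame (the 43 analysis items are
#'   taken), or any data frame of factors/integer codes.
#' @param levels Optional named integer vector giving the number of levels
#'   per column when \code{x} is not a cohort; integer columns are assumed
#'   coded \code{0..levels-1} unless they are factors.
#' @return Object of class \code{discrete_dataset}: list with integer
#'   matrix \code{codes} (values 1..L per column), \code{nlevels}, and
#'   \code{items}.
#' @export
discrete_dataset <- function(x, levels = NULL) {
  stopifnot(is.data.frame(x))
  schema <- item_schema()
  if (all(schema$item %in% names(x))) {
    x <- validate_cohort(x, drop_incomplete = FALSE)
    codes <- vapply(seq_len(nrow(schema)), function(i) {
      as.integer(x[[schema$item[i]]] - schema$min[i] + 1L)
    }, integer(nrow(x)))
    colnames(codes) <- schema$item
    nlev <- stats::setNames(schema$nlevels, schema$item)
  } else {
    codes <- vapply(names(x), function(v) {
      col <- x[[v]]
      if (is.factor(col)) {
        as.integer(col)
      } else {
        as.integer(col) + 1L
      }
    }, integer(nrow(x)))
    colnames(codes) <- names(x)
    nlev <- vapply(names(x), function(v) {
      col <- x[[v]]
      if (is.factor(col)) {
        nlevels(col)
      } else if (!is.null(levels)) {
        as.integer(levels[[v]])
      } else {
        as.integer(max(col) + 1L)
      }
    }, integer(1))
  }
  if (anyNA(codes)) stop("discrete dataset must not contain missing cells")
  for (j in seq_len(ncol(codes))) {
    if (any(codes[, j] < 1L | codes[, j] > nlev[j])) {
      stop("values of '", colnames(codes)[j],
           "' fall outside its declared level set")
    }
  }
  structure(list(codes = codes, nlevels = nlev, items = colnames(codes)),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("<discrete_dataset> %d respondents x %d variables (%s levels)\n",
              nrow(x$codes), length(x$items),
              paste(range(x$nlevels), collapse = "-")))
  invisible(x)
}

#' Directed acyclic graph over a variable set
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data frame of directed edges
#'   (from, to); may be empty.
#' @return Object of class \code{dag_structure}: \code{nodes} plus a named
#'   \code{parents} list of character vectors.
#' @export
dag_structure <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    stopifnot(ncol(edges) == 2)
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
      stop("duplicate edges")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (!all(edges %in% nodes)) stop("edge endpoints must be nodes")
    for (k in seq_len(nrow(edges))) {
      parents[[edges[k, 2]]] <- c(parents[[edges[k, 2]]], edges[k, 1])
    }
  }
  out <- structure(list(nodes = nodes, parents = parents),
                   class = "dag_structure")
  if (!is_acyclic(out)) stop("edge set contains a cycle")
  out
}

#' @rdname dag_structure
#' @param dag A \code{dag_structure}.
#' @return `is_acyclic()` returns TRUE iff a topological order exists.
#' @export
is_acyclic <- function(dag) {
  parents <- lapply(dag$parents, function(p) match(p, dag$nodes))
  n <- length(dag$nodes)
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (b in seq_len(n)) {
    for (a in parents[[b]]) children[[a]] <- c(children[[a]], b)
  }
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  seen == n
}

#' @rdname dag_structure
#' @return `dag_edges()` returns the edge list as a two-column character
#'   matrix.
#' @export
dag_edges <- function(dag) {
  stopifnot(inherits(dag, "dag_structure"))
  out <- do.call(rbind, lapply(dag$nodes, function(b) {
    if (length(dag$parents[[b]])) cbind(from = dag$parents[[b]], to = b)
  }))
  if (is.null(out)) out <- matrix(character(0), 0, 2,
                                  dimnames = list(NULL, c("from", "to")))
  out
}

#' @export
print.dag_structure <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<dag_structure> %d nodes, %d edges\n", length(x$nodes),
              nrow(e)))
  if (nrow(e)) {
    show <- utils::head(seq_len(nrow(e)), 10)
    cat(paste0("  ", e[show, 1], " -> ", e[show, 2], collapse = "\n"), "\n")
    if (nrow(e) > 10) cat("  ...\n")
  }
  invisible(x)
}

# multinomial log-likelihood and free-parameter count of one node family;
# zero-count cells and empty parent configurations contribute zero
family_fit <- function(ds, node_idx, parent_idx) {
  x <- ds$codes[, node_idx]
  L <- ds$nlevels[node_idx]
  if (!length(parent_idx)) {
    counts <- tabulate(x, nbins = L)
    n <- length(x)
    nz <- counts > 0
    ll <- sum(counts[nz] * log(counts[nz] / n))
    return(list(loglik = ll, nparams = L - 1))
  }
  pl <- ds$nlevels[parent_idx]
  pid <- ds$codes[, parent_idx[1]] - 1L
  if (length(parent_idx) > 1) {
    for (k in 2:length(parent_idx)) {
      pid <- pid * pl[k] + (ds$codes[, parent_idx[k]] - 1L)
    }
  }
  ncfg <- prod(pl)
  joint <- tabulate(pid * L + x, nbins = ncfg * L)
  cfg <- tabulate(pid + 1L, nbins = ncfg)
  nz <- joint > 0
  ll <- sum(joint[nz] * log(joint[nz] / rep(cfg, each = L)[nz]))
  list(loglik = ll, nparams = (L - 1) * ncfg)
}

family_bic <- function(ds, node_idx, parent_idx, max_params) {
  fit <- family_fit(ds, node_idx, parent_idx)
  if (fit$nparams > max_params) {
    return(NA_real_)
  }
  fit$loglik - log(nrow(ds$codes)) / 2 * fit$nparams
}

#' BIC network score of a DAG on a discrete dataset
#'
#' Decomposable score: the sum over nodes of the family's multinomial
#' log-likelihood given each parent configuration, penalized by
#' \eqn{(\ln n / 2)} times the family's free-parameter count
#' \eqn{(L-1)\prod L_{parents}}.
#'
#' @param ds A [discrete_dataset()].
#' @param dag A [dag_structure()] on the dataset's variables.
#' @param max_params Guard against parent-configuration explosion: scoring
#'   a family whose free-parameter count exceeds this cap is an error.
#' @return Numeric score (larger is better).
#' @export
bic_score <- function(ds, dag, max_params = 1e6) {
  stopifnot(inherits(ds, "discrete_dataset"), inherits(dag, "dag_structure"))
  stopifnot(setequal(dag$nodes, ds$items))
  total <- 0
  for (b in dag$nodes) {
    s <- family_bic(ds, match(b, ds$items),
                    match(dag$parents[[b]], ds$items), max_params)
    if (is.na(s)) {
      stop("family of '", b, "' exceeds the parameter cap (", max_params,
           "); reduce parents or raise max_params")
    }
    total <- total + unname(s)
  }
  total
}

#' Greedy hill-climbing search for a high-scoring DAG
#'
#' Starts from the empty graph and repeatedly applies the single-edge
#' add/delete/reverse move with the largest strictly positive score gain,
#' skipping moves that would create a cycle or exceed the family parameter
#' cap. Among equal-gain moves the lexicographically smallest
#' (operation, source, target) is chosen, with operations ordered
#' add < delete < reverse, so the search is fully deterministic.
#'
#' @inheritParams bic_score
#' @param max_params Families whose free-parameter count would exceed this
#'   cap are not considered as moves.
#' @param max_iter Safety bound on accepted moves.
#' @param seed Accepted for interface uniformity; the search itself is
#'   deterministic and does not consume randomness.
#' @return A [dag_structure()] with attributes \code{score} (its BIC) and
#'   \code{trajectory} (score after each accepted move, strictly
#'   increasing).
#' @export
hill_climb <- function(ds, max_params = 1e5, max_iter = 1000L, seed = NULL) {
  stopifnot(inherits(ds, "discrete_dataset"))
  p <- length(ds$items)
  n <- nrow(ds$codes)
  penalty <- log(n) / 2
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  fam <- function(b, pa) {
    key <- paste0(b, "|", paste(sort(pa), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- family_bic(ds, b, pa, max_params)
    cache[[key]] <- val
    val
  }
  parents <- rep(list(integer(0)), p)
  children <- rep(list(integer(0)), p)
  fam_score <- vapply(seq_len(p), function(b) fam(b, integer(0)), numeric(1))
  score <- sum(fam_score)
  trajectory <- numeric(0)
  tol <- 1e-8

  reachable_from <- function(start) {
    # nodes reachable from `start` via directed edges (excluding start
    # unless on a cycle)
    seen <- logical(p)
    stack <- children[[start]]
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, children[[v]])
      }
    }
    seen
  }

  op_rank <- c(add = 1, delete = 2, reverse = 3)
  for (iter in seq_len(max_iter)) {
    # descendants[b, ] = which nodes are reachable from b
    desc <- t(vapply(seq_len(p), reachable_from, logical(p)))
    best <- list(gain = tol, op = NULL)
    consider <- function(gain, op, a, b, cand) {
      if (is.na(gain)) return()
      if (gain > best$gain + tol) {
        best <<- list(gain = gain, op = op, a = a, b = b, cand = cand)
      } else if (gain > best$gain - tol && !is.null(best$op)) {
        old <- c(op_rank[best$op], best$a, best$b)
        new <- c(op_rank[op], a, b)
        if (new[1] < old[1] ||
            (new[1] == old[1] && (new[2] < old[2] ||
                                  (new[2] == old[2] && new[3] < old[3])))) {
          best <<- list(gain = gain, op = op, a = a, b = b, cand = cand)
        }
      }
    }
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        if (a == b) next
        pa <- parents[[b]]
        has_edge <- a %in% pa
        if (!has_edge) {
          if (desc[b, a]) next  # a is reachable from b: adding a->b cycles
          s_new <- fam(b, c(pa, a))
          consider(s_new - fam_score[b], "add", a, b, list(new_b = s_new))
        } else {
          s_del <- fam(b, setdiff(pa, a))
          consider(s_del - fam_score[b], "delete", a, b, list(new_b = s_del))
          # reverse a->b: forbidden if another a~>b path exists
          other_path <- FALSE
          for (w in setdiff(children[[a]], b)) {
            if (w == b || desc[w, b]) {
              other_path <- TRUE
              break
            }
          }
          if (!other_path) {
            s_b <- fam(b, setdiff(pa, a))
            s_a <- fam(a, c(parents[[a]], b))
            consider((s_b - fam_score[b]) + (s_a - fam_score[a]),
                     "reverse", a, b, list(new_b = s_b, new_a = s_a))
          }
        }
      }
    }
    if (is.null(best$op)) break
    a <- best$a
    b <- best$b
    if (best$op == "add") {
      parents[[b]] <- c(parents[[b]], a)
      children[[a]] <- c(children[[a]], b)
      fam_score[b] <- best$cand$new_b
    } else if (best$op == "delete") {
      parents[[b]] <- setdiff(parents[[b]], a)
      children[[a]] <- setdiff(children[[a]], b)
      fam_score[b] <- best$cand$new_b
    } else {
      parents[[b]] <- setdiff(parents[[b]], a)
      children[[a]] <- setdiff(children[[a]], b)
      parents[[a]] <- c(parents[[a]], b)
      children[[b]] <- c(children[[b]], a)
      fam_score[b] <- best$cand$new_b
      fam_score[a] <- best$cand$new_a
    }
    score <- score + best$gain
    trajectory <- c(trajectory, score)
  }
  edges <- do.call(rbind, lapply(seq_len(p), function(b) {
    if (length(parents[[b]])) {
      cbind(from = ds$items[parents[[b]]], to = ds$items[b])
    }
  }))
  out <- dag_structure(ds$items, edges)
  attr(out, "score") <- score
  attr(out, "trajectory") <- trajectory
  out
}
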