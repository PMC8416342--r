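# Independent brute-force oracles and fixture builders used across the
# suite. Oracles deliberately avoid the code paths (and where possible the
# libraries) they are used to check.

# Pearson chi-square by direct evaluation of sum (O - E)^2 / E.
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}

# Kruskal-Wallis H with tie correction, from first principles.
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- as.factor(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# One-way ANOVA F from raw data, summed squares written out.
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# KMO via explicit inverse and anti-image partial correlations.
oracle_kmo <- function(R) {
  A <- solve(R)
  p <- ncol(R)
  Q <- matrix(0, p, p)
  for (i in 1:p) {
    for (j in 1:p) {
      Q[i, j] <- -A[i, j] / sqrt(A[i, i] * A[j, j])
    }
  }
  r2 <- q2 <- 0
  for (i in 1:p) {
    for (j in 1:p) {
      if (i != j) {
        r2 <- r2 + R[i, j]^2
        q2 <- q2 + Q[i, j]^2
      }
    }
  }
  r2 / (r2 + q2)
}

# Spearman rho as Pearson correlation of ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Unnormalized shortest-path betweenness by explicit enumeration of every
# shortest path (DFS over the BFS predecessor structure). Exponential in
# the worst case; fine for the small graphs used in tests.
oracle_betweenness <- function(adj) {
  p <- nrow(adj)
  btw <- numeric(p)
  neighbors <- lapply(seq_len(p), function(i) which(adj[i, ] != 0))
  bfs_dist <- function(s) {
    d <- rep(Inf, p)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in neighbors[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          q <- c(q, w)
        }
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, d) {
    # enumerate backwards from t along predecessors
    walk <- function(v) {
      if (v == s) return(list(v))
      preds <- Filter(function(u) d[u] == d[v] - 1, neighbors[[v]])
      out <- list()
      for (u in preds) {
        for (pp in walk(u)) out <- c(out, list(c(pp, v)))
      }
      out
    }
    walk(t)
  }
  for (s in 1:(p - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):p) {
      if (is.infinite(d[t])) next
      paths <- all_shortest_paths(s, t, d)
      npath <- length(paths)
      for (pp in paths) {
        inner <- setdiff(pp, c(s, t))
        btw[inner] <- btw[inner] + 1 / npath
      }
    }
  }
  btw
}

# Newman modularity of a given partition, from the definition.
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  p <- nrow(adj)
  for (i in 1:p) {
    for (j in 1:p) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# All 25 DAGs over 3 labelled nodes: each unordered pair independently
# absent, forward or backward, minus the two directed 3-cycles.
enumerate_dags3 <- function(nodes = c("A", "B", "C")) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    states <- c(s1, s2, s3)
    edges <- NULL
    for (k in 1:3) {
      if (states[k] == 1) {
        edges <- rbind(edges, nodes[pairs[[k]]])
      } else if (states[k] == 2) {
        edges <- rbind(edges, rev(nodes[pairs[[k]]]))
      }
    }
    dag <- tryCatch(dag_structure(nodes, edges), error = function(e) NULL)
    if (!is.null(dag)) out <- c(out, list(dag))
  }
  out
}

# Data matrix whose *sample* correlation matrix equals `target` exactly
# (whiten the sample, then recolour with the target's Cholesky factor).
exact_corr_data <- function(n, target, seed = 1) {
  set.seed(seed)
  p <- ncol(target)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(X) / (n - 1)
  X <- X %*% solve(chol(S)) %*% chol(target)
  scale(X, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

# Random positive-definite correlation matrix.
random_corr <- function(p, seed) {
  set.seed(seed)
  X <- matrix(rnorm((p + 5) * p), p + 5, p)
  R <- cor(X)
  R
}

# Small valid cohort for IO and scoring tests.
small_cohort <- function(n_per_grade = rep(5L, 4), seed = 11) {
  generate_cohort(simulation_config(n_per_grade = n_per_grade, seed = seed))
}

# Random binary-symmetric adjacency matrix with at least one edge.
random_adjacency <- function(p, prob, seed) {
  set.seed(seed)
  adj <- matrix(0L, p, p)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < prob]
  if (!length(on)) on <- up[1]
  adj[on] <- 1L
  adj + t(adj)
}

# Exchangeable-null z-profile cohort (iid standard normal deviations).
null_z_cohort <- function(n, p = 43, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(NULL, item_schema()$item[seq_len(p)]))
}

# z-profile matrix whose order statistics are stable (Gaussian quantile
# spread plus small jitter); such profiles satisfy the ICN screening
# criteria at sparse K.
quantile_spread_z <- function(n, p = 43, jitter = 0.05, seed = 1) {
  set.seed(seed)
  base <- qnorm((seq_len(p) - 0.5) / p)
  z <- t(vapply(seq_len(n), function(i) {
    sample(base) + rnorm(p, 0, jitter)
  }, numeric(p)))
  colnames(z) <- item_schema()$item[seq_len(p)]
  z
}

# Chain-structured discrete data A -> B -> C with given flip probability.
chain_data <- function(n, flip = 0.2, seed = 1) {
  set.seed(seed)
  a <- sample(0:1, n, replace = TRUE)
  b <- ifelse(runif(n) < 1 - flip, a, 1L - a)
  c_ <- ifelse(runif(n) < 1 - flip, b, 1L - b)
  discrete_dataset(data.frame(A = a, B = b, C = c_),
                   levels = c(A = 2L, B = 2L, C = 2L))
}
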