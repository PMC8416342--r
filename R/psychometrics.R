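as_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-10 &&
      all(abs(diag(x) - 1) < 1e-10)) {
    return(x)
  }
  stats::cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-item KMO from the anti-image of the correlation matrix:
#' with \eqn{A = R^{-1}}, the partial correlation of items i and j given
#' the rest is \eqn{q_{ij} = -a_{ij}/\sqrt{a_{ii}a_{jj}}}, and KMO is the
#' ratio of summed squared correlations to summed squared correlations
#' plus summed squared partials. Values near 1 indicate that compact
#' factors can account for the correlations; the conventional floor for
#' factoring is 0.5.
#'
#' @param x Correlation matrix, or a numeric data matrix from which one is
#'   computed.
#' @return List with \code{kmo_overall} and named \code{kmo_per_item},
#'   class \code{kmo}.
#' @export
kmo <- function(x) {
  R <- as_correlation(x)
  p <- ncol(R)
  stopifnot(p >= 2)
  Ri <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; check for collinear items (",
         conditionMessage(e), ")")
  })
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * tcrossprod(d)       # partial correlations, diagonal = -1
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_item) <- colnames(R)
  structure(list(kmo_overall = overall, kmo_per_item = per_item),
            class = "kmo")
}

#' @export
print.kmo <- function(x, ...) {
  cat(sprintf("<kmo> overall = %.3f (per-item range %.3f-%.3f)\n",
              x$kmo_overall, min(x$kmo_per_item), max(x$kmo_per_item)))
  invisible(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' \eqn{\chi^2 = -(n - 1 - (2p + 5)/6)\,\ln\det R} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @inheritParams kmo
#' @param n Number of observations behind the correlations (must exceed the
#'   number of items).
#' @return List with \code{bartlett_chi2}, \code{bartlett_df},
#'   \code{bartlett_p}.
#' @export
bartlett_sphericity <- function(x, n) {
  R <- as_correlation(x)
  p <- ncol(R)
  stopifnot(n > p)
  detR <- det(R)
  if (detR <= 0) {
    stop("correlation matrix is not positive definite (det = ", detR, ")")
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(bartlett_chi2 = chi2, bartlett_df = as.integer(df),
       bartlett_p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal components with Kaiser retention and varimax rotation
#'
#' Eigendecomposition of the item correlation matrix; components with
#' eigenvalue strictly greater than 1 are retained (Kaiser criterion) and
#' their loadings varimax-rotated (Kaiser-normalized, tolerance 1e-6).
#' Column signs are flipped so each component's largest-magnitude loading
#' is positive, a reproducible orientation convention. Items are treated as
#' numeric, i.e. Pearson correlations on the coded Likert levels.
#'
#' @inheritParams kmo
#' @return Object of class \code{pca_varimax}: \code{eigenvalues} (all p,
#'   descending), \code{retained_components}, \code{rotated_loadings}
#'   (p x m), \code{cumulative_explained_variance} (percent, retained set),
#'   \code{communalities} (per item, retained set).
#' @export
pca_varimax <- function(x) {
  R <- as_correlation(x)
  p <- ncol(R)
  stopifnot(p >= 2)
  if (is.null(colnames(R))) {
    colnames(R) <- rownames(R) <- paste0("item", seq_len(p))
  }
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  m <- sum(ev > 1)
  if (m == 0) {
    warning("no component has eigenvalue > 1; nothing retained")
    out <- list(eigenvalues = ev, retained_components = 0L,
                rotated_loadings = matrix(numeric(0), p, 0,
                                          dimnames = list(colnames(R), NULL)),
                cumulative_explained_variance = 0,
                communalities = stats::setNames(rep(0, p), colnames(R)))
    return(structure(out, class = "pca_varimax"))
  }
  load <- eig$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m)
  rot <- if (m > 1) {
    unclass(stats::varimax(load, normalize = TRUE, eps = 1e-6)$loadings)
  } else {
    load
  }
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  rot <- sweep(rot, 2, ifelse(flip == 0, 1, flip), "*")
  dimnames(rot) <- list(colnames(R), paste0("RC", seq_len(m)))
  structure(list(
    eigenvalues = ev,
    retained_components = as.integer(m),
    rotated_loadings = rot,
    cumulative_explained_variance = 100 * sum(ev[seq_len(m)]) / p,
    communalities = stats::setNames(rowSums(rot^2), colnames(R))
  ), class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<pca_varimax> %d component(s) retained (eigenvalue > 1), %.2f%% of variance\n",
    x$retained_components, x$cumulative_explained_variance))
  if (x$retained_components > 0) {
    print(round(x$rotated_loadings, digits))
  }
  invisible(x)
}

#' Cronbach's alpha internal-consistency reliability
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2}
#' are item variances and \eqn{s_T^2} the variance of the item total.
#'
#' @param items Numeric matrix or data frame, respondents x items (at
#'   least 2 of each).
#' @return Numeric alpha (can be negative for incoherent item sets).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  stopifnot(ncol(items) >= 2, nrow(items) >= 2, !anyNA(items))
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    stop("total score has zero variance; alpha undefined")
  }
  (k / (k - 1)) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}
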