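#' Normalize a population snapshot into mutational-step units
#'
#' Elementwise \eqn{p_n(i,t) = (p(i,t) - p(i,0)) / \sigma_p} where
#' \eqn{p(i,0)} is the population's common initialization value of the
#' parameter (every cell starts from the same origin) and \eqn{\sigma_p} its
#' mutational step size, so coordinates measure distance from the origin in
#' units of mutation steps. A never-mutated population maps to the all-zeros
#' matrix.
#'
#' @param snapshot Data frame with the ten phenotype columns (e.g., from
#'   \code{\link{population_snapshot}}), or a numeric matrix with columns in
#'   \code{\link{phenotype_names}} order.
#' @param spec A \code{\link{mutation_spec}} supplying origins and step
#'   sizes.
#' @return Numeric matrix (cells x 10) of class \code{phenotype_matrix}.
#' @export
normalize_phenotypes <- function(snapshot, spec = mutation_spec()) {
  cols <- phenotype_names()
  if (is.data.frame(snapshot)) {
    missing_cols <- setdiff(cols, names(snapshot))
    if (length(missing_cols)) {
      stop("normalize_phenotypes(): missing parameter column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    m <- as.matrix(snapshot[cols])
  } else {
    m <- as.matrix(snapshot)
    if (ncol(m) != length(cols)) {
      stop("normalize_phenotypes(): expected ", length(cols), " columns")
    }
    colnames(m) <- cols
  }
  if (any(spec$step <= 0)) stop("normalize_phenotypes(): step sizes must be > 0")
  out <- sweep(sweep(m, 2, spec$init, "-"), 2, spec$step, "/")
  class(out) <- c("phenotype_matrix", class(out))
  out
}

#' Principal axes of the normalized phenotype cloud
#'
#' Principal component analysis (via singular value decomposition of the
#' centered cloud) of the cells-by-10 normalized phenotype matrix. Returns
#' the leading three axes, their weights (variances normalized over all ten
#' components, summing to one), and the per-parameter loadings describing
#' the composition of each axis.
#'
#' @param x A matrix from \code{\link{normalize_phenotypes}} (>= 2 distinct
#'   rows).
#' @param n_axes Number of leading axes to report (default 3).
#' @return List with \code{axes} (10 x n_axes orthonormal matrix),
#'   \code{weights} (length n_axes, leading shares of total variance),
#'   \code{all_weights} (all 10, summing to 1), and \code{loadings}
#'   (alias of \code{axes}, rows named by parameter).
#' @export
principal_axes <- function(x, n_axes = 3) {
  x <- unclass(x)
  if (nrow(x) < 2 || nrow(unique(x)) < 2) {
    stop("principal_axes(): need at least 2 distinct points")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  # pad: prcomp drops trailing zero-variance components when n < p
  ev <- c(ev, rep(0, ncol(x) - length(ev)))
  w <- ev / sum(ev)
  k <- min(n_axes, ncol(pc$rotation))
  axes <- pc$rotation[, seq_len(k), drop = FALSE]
  rownames(axes) <- colnames(x)
  list(axes = axes, weights = w[seq_len(n_axes)], all_weights = w,
       loadings = axes)
}

#' Hierarchical clusters in phenotype space and their summary statistics
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances,
#' cut at a cophenetic distance (default 100, in mutational-step units).
#' For each flat cluster: member count, displacement (10-D Euclidean
#' distance of its center of mass from the origin), spread (mean member
#' distance from the center of mass), and density (spread divided by member
#' count).
#'
#' @param x A matrix from \code{\link{normalize_phenotypes}} (>= 1 row).
#' @param cutoff Cophenetic cutting height.
#' @return Data frame with one row per cluster: \code{cluster}, \code{n},
#'   \code{displacement}, \code{spread}, \code{density}, ordered by cluster
#'   label.
#' @export
cluster_metrics <- function(x, cutoff = 100) {
  x <- unclass(x)
  if (nrow(x) == 0) stop("cluster_metrics(): need at least one point")
  if (nrow(x) == 1) {
    member <- 1L
  } else {
    hc <- hclust(dist(x), method = "ward.D2")
    member <- cutree(hc, h = cutoff)
  }
  out <- lapply(sort(unique(member)), function(k) {
    pts <- x[member == k, , drop = FALSE]
    com <- colMeans(pts)
    spread <- mean(sqrt(rowSums(sweep(pts, 2, com)^2)))
    data.frame(cluster = k, n = nrow(pts),
               displacement = sqrt(sum(com^2)),
               spread = spread, density = spread / nrow(pts))
  })
  do.call(rbind, out)
}

#' Combined chemotaxis parameter
#'
#' \eqn{\chi' = \chi_g + \chi_{O_2} - \chi_l}: net nutrient-seeking drive
#' (attraction to glucose and oxygen, repulsion from lactate counts
#' positively).
#'
#' @param chi_g,chi_o2,chi_l Chemotaxis coefficients (vectorized).
#' @return Numeric vector.
#' @examples
#' combined_chemotaxis(2, 1, -1) # 4
#' @export
combined_chemotaxis <- function(chi_g, chi_o2, chi_l) {
  chi_g + chi_o2 - chi_l
}
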