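#' Reflect values into an interval
#'
#' Iterated reflection across the violated bound, applied until the value
#' lies inside \code{[lo, hi]}. Iterating (rather than clamping) keeps the
#' stationary distribution of a reflected Gaussian walk uniform even for
#' steps larger than the range.
#'
#' @param x Numeric vector of raw proposals.
#' @param lo,hi Interval bounds (\code{lo < hi}).
#' @return Numeric vector inside \code{[lo, hi]}.
#' @examples
#' reflect_bounds(-0.05, 0, 1) # 0.05
#' @export
reflect_bounds <- function(x, lo, hi) {
  if (any(hi <= lo)) stop("reflect_bounds(): need lo < hi")
  span <- hi - lo
  # fold onto [0, 2*span) then mirror the upper half
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Mutate a phenotype vector
#'
#' Each of the ten parameters independently mutates with probability
#' \code{rate(spec)}; a mutation adds a Gaussian step of standard deviation
#' equal to the parameter's characteristic step size and reflects the result
#' back into the allowed range. Both daughters of a division undergo this
#' pass independently; at initialization every cell undergoes exactly one
#' pass to seed heterogeneity.
#'
#' @param phenotype Named numeric vector in \code{\link{phenotype_names}}
#'   order.
#' @param spec A \code{\link{mutation_spec}}.
#' @return Mutated phenotype vector (always within bounds).
#' @examples
#' set.seed(1)
#' mutate_phenotype(initial_phenotype(), mutation_spec(rate = 1))
#' @export
mutate_phenotype <- function(phenotype, spec = mutation_spec()) {
  rate <- attr(spec, "rate")
  hit <- runif(nrow(spec)) < rate
  if (any(hit)) {
    raw <- phenotype[hit] + rnorm(sum(hit), 0, spec$step[hit])
    phenotype[hit] <- reflect_bounds(raw, spec$min[hit], spec$max[hit])
  }
  phenotype
}

# Mutate many phenotypes at once (rows of a matrix); used by the engine at
# initialization and by tests. Same trial/step semantics as
# mutate_phenotype() applied row-wise, vectorized column-by-column.
mutate_phenotype_matrix <- function(pheno, spec = mutation_spec()) {
  rate <- attr(spec, "rate")
  if (rate <= 0 || nrow(pheno) == 0) return(pheno)
  for (j in seq_len(ncol(pheno))) {
    hit <- runif(nrow(pheno)) < rate
    if (any(hit)) {
      raw <- pheno[hit, j] + rnorm(sum(hit), 0, spec$step[j])
      pheno[hit, j] <- reflect_bounds(raw, spec$min[j], spec$max[j])
    }
  }
  pheno
}
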