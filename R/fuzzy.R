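#' Triangular fuzzy partition of an input domain
#'
#' Builds 2 or 3 triangular membership functions with apexes uniformly
#' spaced over `[domain_min, domain_max]` (at the endpoints for density 2,
#' plus the midpoint for density 3). These are order-2 B-splines on uniform
#' knots, so the memberships form a partition of unity on the domain and
#' double as the regression basis of the spline submodels.
#'
#' @param domain_min,domain_max Domain endpoints (typically the empirical
#'   min/max of an ion over the training runs), `domain_min < domain_max`.
#' @param density Number of fuzzy sets, 2 or 3.
#' @return Object of class `fuzzy_partition`: apex positions and labels
#'   (`Low`/`High` or `Low`/`Mid`/`High`).
#' @export
fuzzy_partition <- function(domain_min, domain_max, density = 2) {
  if (!density %in% c(2L, 3L)) stop("density must be 2 or 3")
  if (!(domain_min < domain_max)) stop("domain_min must be < domain_max")
  apexes <- seq(domain_min, domain_max, length.out = density)
  labels <- if (density == 2) c("Low", "High") else c("Low", "Mid", "High")
  structure(list(min = domain_min, max = domain_max,
                 density = as.integer(density),
                 apexes = apexes, labels = labels),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %d sets on [%g, %g]\n",
              x$density, x$min, x$max))
  invisible(x)
}

#' Membership degrees
#'
#' @param partition A [fuzzy_partition()].
#' @param x Numeric vector of input values; values outside the domain are
#'   clamped (prediction-mode behavior).
#' @param warn_clamp Warn when clamping occurs.
#' @return Matrix `length(x)` x `density` of memberships; rows sum to 1.
#' @export
membership <- function(partition, x, warn_clamp = FALSE) {
  if (warn_clamp && any(x < partition$min - 1e-12 | x > partition$max + 1e-12)) {
    warning("input outside fuzzification domain; clamped")
  }
  x <- pmin(pmax(x, partition$min), partition$max)
  a <- partition$apexes
  k <- partition$density
  M <- matrix(0, length(x), k, dimnames = list(NULL, partition$labels))
  # hat functions: boundary sets are pure ramps, interior sets the min of
  # the up- and down-ramp around their apex
  M[, 1] <- pmax(0, pmin(1, (a[2] - x) / (a[2] - a[1])))
  M[, k] <- pmax(0, pmin(1, (x - a[k - 1]) / (a[k] - a[k - 1])))
  if (k == 3) {
    M[, 2] <- pmax(0, pmin((x - a[1]) / (a[2] - a[1]),
                           (a[3] - x) / (a[3] - a[2])))
  }
  M
}

#' Dominance ranges of a partition
#'
#' The interval where each label's membership is at least every other
#' label's: the "low/mid/high" concentration ranges read off fuzzified
#' rules. In closed form the boundaries sit at `min + range/2` (density 2)
#' and `min + range/4`, `min + 3 range/4` (density 3).
#'
#' @param partition A [fuzzy_partition()].
#' @return Data frame with columns `level`, `lo`, `hi`; the intervals tile
#'   the domain.
#' @export
dominance <- function(partition) {
  r <- partition$max - partition$min
  b <- if (partition$density == 2) {
    partition$min + r / 2
  } else {
    partition$min + r * c(1, 3) / 4
  }
  edges <- c(partition$min, b, partition$max)
  data.frame(level = partition$labels,
             lo = edges[-length(edges)],
             hi = edges[-1])
}
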