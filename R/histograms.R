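#' Descriptor histograms for desirability fitting
#'
#' Frequency histograms of one descriptor over one compound class feed the
#' curve fit in [fit_desirability()]. Continuous descriptors (MW, LogP) use
#' an optimised common bin width; integer-valued descriptors (HBA, HBD, RB,
#' arR) use unit bins centred on each integer.
#'
#' @name histograms
NULL

new_histogram <- function(bin_edges, counts, descriptor, type) {
  structure(
    list(bin_edges = bin_edges, counts = as.integer(counts),
         centers = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
         width = bin_edges[2] - bin_edges[1],
         n_total = sum(counts), descriptor = descriptor, type = type),
    class = "desc_histogram"
  )
}

#' @export
print.desc_histogram <- function(x, ...) {
  cat(sprintf("%s histogram of %s: %d bins of width %.6g, n = %d\n",
              x$type, x$descriptor %||% "?", length(x$counts), x$width,
              x$n_total))
  invisible(x)
}

#' @export
as.data.frame.desc_histogram <- function(x, ...) {
  data.frame(lower = x$bin_edges[-length(x$bin_edges)],
             upper = x$bin_edges[-1], center = x$centers,
             count = x$counts)
}

# Shimazaki-Shinomoto cost at one width: C = (2*kbar - v) / width^2 with
# kbar/v the mean and biased variance of the bin counts.
ss_cost <- function(values, width) {
  counts <- bin_counts(values, width)
  kbar <- mean(counts)
  v <- mean((counts - kbar)^2)
  (2 * kbar - v) / width^2
}

bin_counts <- function(values, width, anchor = min(values)) {
  rng <- max(values) - anchor
  m <- max(1L, ceiling(rng / width))
  edges <- anchor + width * (0:m)
  # guard: last edge must cover max(values) despite rounding
  if (edges[m + 1L] < max(values)) edges <- c(edges, edges[m + 1L] + width)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Optimal histogram bin width (Shimazaki-Shinomoto)
#'
#' Selects, from a candidate grid, the bin width minimising the
#' Shimazaki-Shinomoto (2007) cost \eqn{C(\Delta) = (2\bar k - v)/\Delta^2},
#' where \eqn{\bar k} and \eqn{v} are the mean and biased variance of the
#' bin counts at width \eqn{\Delta}. Ties are broken toward the smaller
#' width.
#'
#' @param values Numeric vector, at least 10 values with non-zero range.
#' @param candidate_widths Positive widths to evaluate; default 100 widths
#'   log-spaced between range/100 and range/2.
#' @return A list of class `"bin_width_cost"` with `width` (the minimiser),
#'   `cost`, and the full `grid` (width, cost per candidate).
#' @examples
#' set.seed(1)
#' optimal_bin_width(rnorm(500))$width
#' @export
optimal_bin_width <- function(values, candidate_widths = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) stop("need at least 10 values")
  rng <- max(values) - min(values)
  if (rng <= 0) stop("all values identical; no bin width selectable")
  if (is.null(candidate_widths))
    candidate_widths <- exp(seq(log(rng / 100), log(rng / 2),
                                length.out = 100))
  if (length(candidate_widths) == 0L) stop("empty candidate width set")
  if (any(candidate_widths <= 0)) stop("candidate widths must be positive")
  costs <- vapply(candidate_widths, function(w) ss_cost(values, w),
                  numeric(1))
  ord <- order(costs, candidate_widths)  # ties -> smaller width
  structure(list(width = candidate_widths[ord[1L]], cost = costs[ord[1L]],
                 grid = data.frame(width = candidate_widths, cost = costs)),
            class = "bin_width_cost")
}

#' Histogram of a continuous descriptor
#'
#' Bins are half-open `[edge_i, edge_{i+1})`, anchored at the data minimum,
#' with the last bin closed so that the maximum is counted.
#'
#' @param values Non-empty numeric vector.
#' @param width Positive bin width.
#' @param descriptor Optional descriptor label.
#' @return A `"desc_histogram"` object.
#' @export
histogram_continuous <- function(values, width, descriptor = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no values")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a single positive number")
  anchor <- min(values)
  rng <- max(values) - anchor
  m <- max(1L, ceiling(rng / width))
  edges <- anchor + width * (0:m)
  if (edges[m + 1L] < max(values)) edges <- c(edges, edges[m + 1L] + width)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  new_histogram(edges, counts, descriptor, "continuous")
}

#' Histogram of an integer descriptor with unit bins
#'
#' One bin per integer from the observed minimum to maximum (inclusive),
#' centred on the integers.
#'
#' @param values Non-empty vector of non-negative integers.
#' @param descriptor Optional descriptor label.
#' @return A `"desc_histogram"` object.
#' @export
histogram_discrete <- function(values, descriptor = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no values")
  iv <- as.integer(round(values))
  if (any(abs(values - iv) > 1e-8))
    stop("values must be integers for a discrete histogram")
  if (any(iv < 0)) stop("values must be non-negative")
  lo <- min(iv); hi <- max(iv)
  counts <- tabulate(iv - lo + 1L, nbins = hi - lo + 1L)
  edges <- seq(lo - 0.5, hi + 0.5, by = 1)
  new_histogram(edges, counts, descriptor, "discrete")
}
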