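#' Locate the extreme points of a smoothed distance curve
#'
#' Both local maxima and local minima are candidate functional nucleotides.
#' Runs of exactly equal values (plateaus) are collapsed first: an interior
#' plateau is an extremum iff its left and right neighbouring values are both
#' strictly smaller (max) or both strictly larger (min), and it is
#' represented by its midpoint (the lower of the two middle indices for
#' even-length runs). With `include_endpoints = TRUE` (the default) position
#' 1 (resp. n) is an extremum when the first non-equal neighbour makes it a
#' one-sided maximum or minimum; curve ends must be eligible for the
#' predictor to ever report a site at the very 5' or 3' terminus.
#'
#' @param curve A smoothed [distance_curve()] (or numeric vector; feeding an
#'   unsmoothed curve is then the caller's explicit choice).
#' @param include_endpoints Are positions 1 and n eligible?
#' @return Integer vector of extremum positions, increasing.
#' @export
#' @examples
#' find_extrema(distance_curve(c(1, 2, 3, 2, 1), smoothed = TRUE))  # 1 3 5
find_extrema <- function(curve, include_endpoints = TRUE) {
  v <- if (inherits(curve, "distance_curve")) curve$values else as.numeric(curve)
  n <- length(v)
  if (n < 3L && !include_endpoints) return(integer(0))
  r <- rle(v)
  nb <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  if (nb == 1L) return(integer(0))  # constant curve: no extrema anywhere
  for (b in seq_len(nb)) {
    val <- r$values[b]
    if (b == 1L || b == nb) {
      if (!include_endpoints) next
      nbr <- if (b == 1L) r$values[2L] else r$values[nb - 1L]
      if (nbr != val) out <- c(out, if (b == 1L) 1L else n)
    } else {
      left <- r$values[b - 1L]; right <- r$values[b + 1L]
      if ((left < val && right < val) || (left > val && right > val)) {
        len <- r$lengths[b]
        out <- c(out, starts[b] + (len - 1L) %/% 2L)
      }
    }
  }
  sort(out)
}

#' Predicted-site container
#'
#' Sites are 1-based inclusive intervals, sorted and pairwise separated by
#' more than `merge_gap` positions.
#'
#' @param sites data.frame with columns start, end, peak_position, peak_value.
#' @param molecule_id Text id.
#' @param merge_gap The gap used to build the set.
#' @export
site_set <- function(sites, molecule_id = "rna", merge_gap = 2L) {
  need <- c("start", "end", "peak_position", "peak_value")
  if (!all(need %in% names(sites)))
    stop_input("site table must have columns %s", paste(need, collapse = ", "))
  sites <- sites[order(sites$start), need, drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites) > 1L) {
    sep <- sites$start[-1L] - sites$end[-nrow(sites)]
    if (any(sep <= merge_gap))
      stop_input("sites closer than merge_gap = %d remain unmerged", merge_gap)
  }
  structure(list(molecule_id = molecule_id, sites = sites,
                 merge_gap = as.integer(merge_gap)),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> %s: %d site(s), merge_gap %d\n",
              x$molecule_id, nrow(x$sites), x$merge_gap))
  if (nrow(x$sites)) print(x$sites, ...)
  invisible(x)
}

#' Merge nearby extremum positions into predicted sites
#'
#' Greedy left-to-right chaining: a position joins the current site when its
#' distance to the previous position is at most `merge_gap` (default 2
#' nucleotides, applied pairwise so chains of close points form one site,
#' regardless of the RNA's length). The site interval spans the min..max of
#' its member positions. The site's peak is the member whose smoothed value
#' deviates most from the curve mean (tie broken toward the smaller index).
#'
#' @param positions Strictly increasing integer positions in `[1, n]`.
#' @param n Curve length (upper bound for positions).
#' @param merge_gap Maximum pairwise distance merged into one site.
#' @param values Optional smoothed curve values (length n) used to pick peaks.
#' @param molecule_id Text id.
#' @return A [site_set()].
#' @export
#' @examples
#' merge_points(c(10, 12, 14), n = 20)$sites  # one site 10-14
merge_points <- function(positions, n, merge_gap = 2L, values = NULL,
                         molecule_id = "rna") {
  if (!is_count(merge_gap)) stop_config("merge_gap must be a non-negative integer")
  positions <- as.integer(positions)
  if (length(positions)) {
    if (any(diff(positions) <= 0L))
      stop_input("positions must be strictly increasing")
    if (positions[1L] < 1L || positions[length(positions)] > n)
      stop_input("positions outside [1, %d]", n)
  }
  if (!is.null(values) && length(values) != n)
    stop_input("values must have length n")
  dev <- if (is.null(values)) NULL else abs(values - mean(values))
  rows <- list()
  i <- 1L
  while (i <= length(positions)) {
    j <- i
    while (j < length(positions) &&
           positions[j + 1L] - positions[j] <= merge_gap) j <- j + 1L
    members <- positions[i:j]
    if (is.null(dev)) {
      peak <- members[1L]; pv <- NA_real_
    } else {
      best <- which.max(dev[members])  # first index on ties -> smaller pos
      peak <- members[best]; pv <- values[peak]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = members[1L], end = members[length(members)],
      peak_position = peak, peak_value = pv)
    i <- j + 1L
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               peak_position = integer(0), peak_value = numeric(0))
  site_set(sites, molecule_id, merge_gap)
}

#' Predict functional sites from a structure, layout or curve
#'
#' The full pipeline: (structure -> radiate layout ->) location metric ->
#' Gaussian smoothing -> extreme points -> merge into sites. Entirely
#' deterministic: identical input and configuration give identical sites.
#'
#' @param x An [rna_structure()], an n x 2/3 coordinate matrix, or a raw
#'   [distance_curve()].
#' @param metric `"ndc"` (default) or `"nds"`; ignored when `x` is already a
#'   curve.
#' @param sigma,truncation,boundary Smoothing parameters, see
#'   [gaussian_smooth()].
#' @param merge_gap Site merge distance in nucleotides (default 2).
#' @param include_endpoints Are curve ends eligible extrema?
#' @param backbone_spacing,pair_span Layout parameters, used only when `x`
#'   is a structure.
#' @return A [site_set()]; the smoothed curve is attached as attribute
#'   `"curve"` and the raw curve as `"raw_curve"`.
#' @export
predict_sites <- function(x, metric = c("ndc", "nds"), sigma = 2.0,
                          truncation = 4.0, boundary = "reflect",
                          merge_gap = 2L, include_endpoints = TRUE,
                          backbone_spacing = 1.0, pair_span = 2.0) {
  metric <- match.arg(metric)
  if (inherits(x, "rna_structure")) {
    id <- x$sequence$id
    pts <- layout_radiate(strip_pseudoknots(x, warn = TRUE),
                          backbone_spacing, pair_span)
    raw <- location_curve(pts, metric, id)
  } else if (inherits(x, "distance_curve")) {
    raw <- x
  } else {
    raw <- location_curve(as_points(x), metric)
  }
  sm <- if (raw$smoothed) raw else
    gaussian_smooth(raw, sigma, truncation, boundary)
  pos <- find_extrema(sm, include_endpoints)
  out <- merge_points(pos, n = length(sm$values), merge_gap = merge_gap,
                      values = sm$values, molecule_id = raw$molecule_id)
  attr(out, "curve") <- sm
  attr(out, "raw_curve") <- if (raw$smoothed) NULL else raw
  out
}
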