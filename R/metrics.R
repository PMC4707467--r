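#' Centroid of a point set
#'
#' Coordinate-wise arithmetic mean; nucleotides are treated as bare points,
#' with no mass or identity weighting.
#'
#' @param points n x d numeric matrix (d = 2 or 3).
#' @return Numeric vector of length d.
#' @export
centroid <- function(points) {
  points <- as_points(points)
  colMeans(points)
}

as_points <- function(points) {
  if (inherits(points, "structure3d")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop_input("point set is empty")
  if (!ncol(points) %in% c(2L, 3L))
    stop_input("points must be 2D or 3D, got %d columns", ncol(points))
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop_input("non-finite coordinates")
  points
}

#' Distance curve container
#'
#' The per-nucleotide location signal D(1..n): D(i) quantifies where the
#' i-th nucleotide sits in the molecule. Outermost nucleotides have the
#' largest values, innermost the smallest.
#'
#' @param values Numeric vector of finite, non-negative values.
#' @param metric `"ndc"` or `"nds"`.
#' @param molecule_id Text id.
#' @param smoothed Has a Gaussian filter already been applied?
#' @return Object of class `distance_curve`.
#' @export
distance_curve <- function(values, metric = c("ndc", "nds"),
                           molecule_id = "rna", smoothed = FALSE) {
  metric <- match.arg(metric)
  values <- as.numeric(values)
  if (length(values) < 1L) stop_input("distance curve is empty")
  if (!all(is.finite(values))) stop_input("distance curve has non-finite values")
  if (any(values < 0)) stop_input("distance values must be >= 0")
  structure(list(molecule_id = molecule_id, values = values,
                 metric = metric, smoothed = smoothed),
            class = "distance_curve")
}

#' @export
print.distance_curve <- function(x, ...) {
  cat(sprintf("<distance_curve> %s: %s, n = %d, %s\n", x$molecule_id,
              toupper(x$metric), length(x$values),
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

#' Nucleotide distance to centroid (NDC)
#'
#' D(i) is the Euclidean distance from point i to the molecular centroid.
#' This is the default location metric of the predictor.
#'
#' @param points n x 2 or n x 3 coordinate matrix (or a `structure3d`).
#' @param molecule_id Text id carried into the curve.
#' @return A [distance_curve()] with `metric = "ndc"`.
#' @export
ndc_curve <- function(points, molecule_id = "rna") {
  points <- as_points(points)
  ctr <- colMeans(points)
  d <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  distance_curve(d, "ndc", molecule_id, smoothed = FALSE)
}

#' Nucleotide distance sum (NDS)
#'
#' D(i) is the sum of Euclidean distances from point i to every other
#' nucleotide. Undefined for a single point (the molecule-length filter
#' removes such degenerate inputs upstream anyway).
#'
#' @inheritParams ndc_curve
#' @return A [distance_curve()] with `metric = "nds"`.
#' @export
nds_curve <- function(points, molecule_id = "rna") {
  points <- as_points(points)
  if (nrow(points) < 2L)
    stop_input("NDS needs at least 2 points")
  d <- rowSums(as.matrix(stats::dist(points)))
  distance_curve(d, "nds", molecule_id, smoothed = FALSE)
}

#' Compute a distance curve by metric name
#'
#' @inheritParams ndc_curve
#' @param metric `"ndc"` (default) or `"nds"`.
#' @export
location_curve <- function(points, metric = c("ndc", "nds"),
                           molecule_id = "rna") {
  metric <- match.arg(metric)
  if (metric == "ndc") ndc_curve(points, molecule_id)
  else nds_curve(points, molecule_id)
}
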