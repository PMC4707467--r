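#' Gaussian smoothing of a distance curve
#'
#' Discrete convolution with a truncated, normalized Gaussian kernel.
#' `sigma` is in nucleotides; the kernel extends `truncation` sigmas to each
#' side (half-width `ceiling(truncation * sigma)`). Boundaries are handled by
#' index reflection with the edge value repeated (`"reflect"`, as in
#' scipy-style filters) or by edge replication (`"nearest"`). `sigma = 0`
#' leaves the values untouched but still marks the curve smoothed, so the
#' unfiltered curve can be fed to the extremum detector by explicit choice.
#'
#' @param curve A raw [distance_curve()].
#' @param sigma Gaussian standard deviation in nucleotides, >= 0 (default 2).
#' @param truncation Kernel half-width in sigmas, > 0 (default 4).
#' @param boundary `"reflect"` or `"nearest"`.
#' @return The smoothed [distance_curve()].
#' @export
gaussian_smooth <- function(curve, sigma = 2.0, truncation = 4.0,
                            boundary = c("reflect", "nearest")) {
  boundary <- match.arg(boundary)
  if (!inherits(curve, "distance_curve")) stop_input("expected a distance_curve")
  if (curve$smoothed) stop_input("curve is already smoothed")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop_config("sigma must be a single number >= 0")
  if (!is.numeric(truncation) || truncation <= 0)
    stop_config("truncation must be > 0")
  v <- curve$values
  n <- length(v)
  if (sigma == 0) {
    out <- v
  } else {
    h <- as.integer(ceiling(truncation * sigma))
    k <- (-h):h
    w <- exp(-(k^2) / (2 * sigma^2))
    w <- w / sum(w)
    idx <- vapply((1L - h):(n + h), pad_index, integer(1L),
                  n = n, boundary = boundary)
    padded <- v[idx]
    out <- as.numeric(stats::filter(padded, w, sides = 2L))[(h + 1L):(h + n)]
  }
  distance_curve(out, curve$metric, curve$molecule_id, smoothed = TRUE)
}

# Map an out-of-range index into [1, n]. "reflect" repeats the edge sample
# (… 2 1 | 1 2 … n | n n-1 …) and folds with period 2n so any half-width
# works; "nearest" clamps.
pad_index <- function(i, n, boundary) {
  if (boundary == "nearest") return(max(1L, min(n, i)))
  j <- (i - 1L) %% (2L * n)
  if (j < n) j + 1L else 2L * n - j
}
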