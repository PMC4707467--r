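#' Molecule filters for the 2D-3D correlation analysis
#'
#' A molecule is excluded when it has multiple RNA chains, is no longer than
#' 20 nt (so exactly 20 nt is excluded), has incomplete coordinates (at
#' least one residue without a usable representative point), or its residue
#' composition does not cover all four bases A, C, G, U.
#'
#' @param structure3d A `structure3d` from [read_pdb_nucleotides()].
#' @param sequence Optional [rna_sequence()]; defaults to the one read from
#'   the PDB residue names.
#' @return List with `molecule_id`, `excluded` and `reasons` (subset of
#'   `multi_chain`, `too_short`, `incomplete_coords`, `missing_bases`).
#' @export
filter_molecule <- function(structure3d, sequence = NULL) {
  if (is.null(sequence)) sequence <- structure3d$sequence
  reasons <- character(0)
  if (structure3d$chain_count > 1L) reasons <- c(reasons, "multi_chain")
  if (seq_length(sequence) <= 20L) reasons <- c(reasons, "too_short")
  if (length(structure3d$incomplete) > 0L)
    reasons <- c(reasons, "incomplete_coords")
  present <- strsplit(sequence$residues, "", fixed = TRUE)[[1L]]
  if (!all(c("A", "C", "G", "U") %in% present))
    reasons <- c(reasons, "missing_bases")
  list(molecule_id = sequence$id,
       excluded = length(reasons) > 0L,
       reasons = reasons)
}

#' Spearman rank correlation with a large-sample p-value
#'
#' rho is the Pearson correlation of the average ranks (midranks on ties).
#' The p-value uses the t approximation t = rho * sqrt((n-2)/(1-rho^2)) with
#' n-2 degrees of freedom, two-sided; for |rho| = 1 the statistic diverges
#' and the p-value is floored at the smallest positive double rather than
#' reported as a literal zero. A constant input vector makes rho undefined,
#' which is flagged instead of silently returning a number.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `n`, `defined`.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_input("x and y lengths differ (%d vs %d)", n, length(y))
  if (n < 3L) stop_input("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- max(min(p, 1), .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Estimate false-discovery-rate q-values
#'
#' `method = "storey"` estimates the null proportion pi0 on the lambda grid
#' 0.05, 0.10, ..., 0.95 (pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))),
#' stabilized with a smoothing spline evaluated at the largest lambda and
#' clipped into `[1/m, 1]`; q_i = min over p_j >= p_i of pi0 m p_j / rank(p_j).
#' For small batches (m < 100) the pi0 estimate is too noisy and the method
#' silently falls back to `"bh"` (pi0 = 1), which is also available directly.
#' q-values are clipped to `[0, 1]` and are monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1]")
  pi0 <- 1
  if (method == "storey" && m >= 100L) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' Per-molecule and pooled 2D-3D distance-curve correlation
#'
#' For each molecule the location curve is computed from the 2D layout and
#' from the 3D coordinates with the same metric, and the two are compared by
#' Spearman correlation; q-values are estimated jointly across the batch.
#' The pooled coefficient concatenates the raw per-nucleotide (2D, 3D)
#' distance pairs of all molecules into one vector pair — it is NOT a
#' weighted mean of the per-molecule coefficients. `zscore = TRUE` optionally
#' standardizes each molecule's curves before pooling, for users worried
#' about mixing molecules of very different size/units.
#'
#' @param molecules List; each element a list with `id`, `layout2d` (n x 2
#'   matrix) and `points3d` (n x 3 matrix or `structure3d`).
#' @param metric `"ndc"` (default) or `"nds"`.
#' @param qmethod Passed to [qvalues()].
#' @param zscore Standardize per molecule before pooling?
#' @return List with `records` (data.frame: molecule_id, n, rho, p, q),
#'   `pooled` (list rho/p/n), `skipped` (ids with a reason, e.g. 2D/3D
#'   length mismatch).
#' @export
run_correlation_batch <- function(molecules, metric = c("ndc", "nds"),
                                  qmethod = c("storey", "bh"),
                                  zscore = FALSE) {
  metric <- match.arg(metric)
  qmethod <- match.arg(qmethod)
  recs <- list(); skipped <- list()
  all2 <- numeric(0); all3 <- numeric(0)
  for (mol in molecules) {
    p3 <- if (inherits(mol$points3d, "structure3d")) mol$points3d$points
          else mol$points3d
    if (nrow(mol$layout2d) != nrow(p3)) {
      skipped[[length(skipped) + 1L]] <-
        list(molecule_id = mol$id,
             reason = sprintf("2D/3D length mismatch (%d vs %d)",
                              nrow(mol$layout2d), nrow(p3)))
      next
    }
    c2 <- location_curve(mol$layout2d, metric, mol$id)$values
    c3 <- location_curve(p3, metric, mol$id)$values
    sp <- spearman_rho(c2, c3)
    recs[[length(recs) + 1L]] <- data.frame(
      molecule_id = mol$id, n = sp$n,
      rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
    if (zscore) {
      c2 <- (c2 - mean(c2)) / stats::sd(c2)
      c3 <- (c3 - mean(c3)) / stats::sd(c3)
    }
    all2 <- c(all2, c2); all3 <- c(all3, c3)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(molecule_id = character(0), n = integer(0),
               rho = numeric(0), p = numeric(0))
  ok <- !is.na(records$p)
  records$q <- NA_real_
  if (any(ok)) records$q[ok] <- qvalues(records$p[ok], qmethod)
  pooled <- if (length(all2) >= 3L) spearman_rho(all2, all3) else
    list(rho = NA_real_, p = NA_real_, n = length(all2), defined = FALSE)
  list(records = records, pooled = pooled, skipped = skipped)
}
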