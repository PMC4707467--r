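#' Score predicted sites against known functional-site intervals
#'
#' A predicted site HITS a known interval iff their position ranges share at
#' least one nucleotide after the known interval is extended by `tolerance`
#' on both sides. A known interval counts as hit when at least one predicted
#' site hits it (several hits still count once); a predicted site counts as
#' hitting when it hits at least one known interval. Sensitivity is the
#' fraction of known intervals hit; PPV the fraction of predicted sites that
#' hit. With zero predictions PPV is undefined (flagged, not reported as 0),
#' and likewise sensitivity with zero known intervals.
#'
#' @param pred A [site_set()] or a data.frame with `start`/`end` columns.
#' @param known data.frame with `start`/`end` (and optionally `label`)
#'   columns of known functional-site intervals.
#' @param tolerance Non-negative integer slack added to each known interval
#'   before overlap testing (default 0; footprint-style evaluations may want
#'   more).
#' @return Object of class `evaluation_result`: counts, `sensitivity`,
#'   `ppv`, definedness flags and `hit_map` (for each known interval, the
#'   indices of the predicted sites hitting it).
#' @export
evaluate_sites <- function(pred, known, tolerance = 0L) {
  if (!is_count(tolerance)) stop_config("tolerance must be a non-negative integer")
  ps <- if (inherits(pred, "site_set")) pred$sites else as.data.frame(pred)
  if (nrow(ps) && !all(c("start", "end") %in% names(ps)))
    stop_input("predictions need start/end columns")
  if (nrow(known) && !all(c("start", "end") %in% names(known)))
    stop_input("known sites need start/end columns")
  n_pred <- nrow(ps); n_known <- nrow(known)
  hit_map <- vector("list", n_known)
  pred_hit <- logical(n_pred)
  for (k in seq_len(n_known)) {
    lo <- known$start[k] - tolerance
    hi <- known$end[k] + tolerance
    hits <- which(ps$start <= hi & ps$end >= lo)
    hit_map[[k]] <- hits
    pred_hit[hits] <- TRUE
  }
  n_known_hit <- sum(lengths(hit_map) > 0L)
  n_pred_hit <- sum(pred_hit)
  structure(list(
    n_known = n_known, n_known_hit = n_known_hit,
    n_pred = n_pred, n_pred_hit = n_pred_hit,
    sensitivity = if (n_known > 0L) n_known_hit / n_known else NA_real_,
    sensitivity_defined = n_known > 0L,
    ppv = if (n_pred > 0L) n_pred_hit / n_pred else NA_real_,
    ppv_defined = n_pred > 0L,
    tolerance = as.integer(tolerance),
    hit_map = hit_map), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> known hit %d/%d, predicted hitting %d/%d\n",
              x$n_known_hit, x$n_known, x$n_pred_hit, x$n_pred))
  if (x$sensitivity_defined)
    cat(sprintf("  sensitivity %.3f", x$sensitivity))
  else cat("  sensitivity undefined")
  if (x$ppv_defined) cat(sprintf(", PPV %.3f\n", x$ppv))
  else cat(", PPV undefined\n")
  invisible(x)
}

# round half up: 6/7 -> 86, 13/17 -> 76, 13/25 -> 52
round_half_up <- function(x) floor(x + 0.5)

#' Integer-percent summary of an evaluation
#'
#' Percentages are rounded half up to the nearest integer, the convention of
#' published sensitivity/PPV tables (6/7 -> 86, 13/17 -> 76).
#'
#' @param result An [evaluate_sites()] result.
#' @return Named numeric: `sensitivity_pct`, `ppv_pct` (NA when undefined).
#' @export
summarize_percent <- function(result) {
  if (!inherits(result, "evaluation_result"))
    stop_input("expected an evaluation_result")
  c(sensitivity_pct = if (result$sensitivity_defined)
      round_half_up(100 * result$sensitivity) else NA_real_,
    ppv_pct = if (result$ppv_defined)
      round_half_up(100 * result$ppv) else NA_real_)
}

#' Pool evaluation results across molecules
#'
#' Aggregates by summing counts, not by averaging percentages: the overall
#' PPV of a cohort is sum(n_pred_hit) / sum(n_pred). Undefined components
#' (no predictions / no known sites for a molecule) contribute zero counts.
#'
#' @param results List of [evaluate_sites()] results.
#' @return An `evaluation_result` over the pooled counts.
#' @export
pool_evaluations <- function(results) {
  stopifnot(length(results) > 0L)
  tot <- function(f) sum(vapply(results, function(r) r[[f]], numeric(1L)))
  n_known <- tot("n_known"); n_pred <- tot("n_pred")
  structure(list(
    n_known = n_known, n_known_hit = tot("n_known_hit"),
    n_pred = n_pred, n_pred_hit = tot("n_pred_hit"),
    sensitivity = if (n_known > 0L) tot("n_known_hit") / n_known else NA_real_,
    sensitivity_defined = n_known > 0L,
    ppv = if (n_pred > 0L) tot("n_pred_hit") / n_pred else NA_real_,
    ppv_defined = n_pred > 0L,
    tolerance = results[[1L]]$tolerance,
    hit_map = NULL), class = "evaluation_result")
}
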