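#' Write predicted sites as TSV
#'
#' Columns: molecule_id, start, end, peak_position, peak_value; rows ordered
#' by start. Lines starting with `#` (provenance headers) are permitted and
#' skipped on read.
#'
#' @param sites A [site_set()].
#' @param path Output file path (or connection).
#' @param header Optional character vector of comment lines written first,
#'   each prefixed with `#`.
#' @export
write_sites <- function(sites, path, header = NULL) {
  if (!inherits(sites, "site_set")) stop_input("expected a site_set")
  df <- sites$sites
  df <- data.frame(molecule_id = rep(sites$molecule_id, nrow(df)), df)
  con <- if (is.character(path)) file(path, "w") else path
  if (is.character(path)) on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("molecule_id", "start", "end", "peak_position",
                     "peak_value"), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a predicted-site TSV
#'
#' @param path File written by [write_sites()] (or hand-made with the same
#'   columns).
#' @return data.frame with columns molecule_id, start, end, peak_position,
#'   peak_value.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "start", "end")
  if (!all(need %in% names(df)))
    stop_input("site TSV %s lacks columns %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read a known-functional-site TSV
#'
#' Columns molecule_id, start, end and optional label; single-position sites
#' have start == end. Comment lines start with `#`.
#'
#' @param path TSV path.
#' @return data.frame of intervals.
#' @export
read_known_sites <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "start", "end")
  if (!all(need %in% names(df)))
    stop_input("known-site TSV %s lacks columns %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$start > df$end)) stop_input("known interval with start > end")
  df
}

#' Write a distance curve (raw and smoothed) as TSV
#'
#' @param raw,smoothed [distance_curve()] objects of equal length; either may
#'   be NULL.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_curve <- function(raw, smoothed, path, header = NULL) {
  a <- if (is.null(raw)) NULL else raw$values
  b <- if (is.null(smoothed)) NULL else smoothed$values
  n <- length(if (is.null(a)) b else a)
  df <- data.frame(position = seq_len(n))
  if (!is.null(a)) df$raw <- a
  if (!is.null(b)) df$smoothed <- b
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
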