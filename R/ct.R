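#' Parse a connectivity-table (CT) secondary structure
#'
#' Standard CT layout: a header line whose first token is the sequence length,
#' then one row per nucleotide with columns index, base, previous index, next
#' index, pairing partner (0 = unpaired) and natural numbering. The sequence
#' is reconstructed from the base column. Reciprocal pairing is enforced: if
#' row i names partner j, row j must name i.
#'
#' @param x Path to a CT file, or the CT text itself (character vector of
#'   lines or a single string with newlines).
#' @param id Molecule id; defaults to the remainder of the header line.
#' @return An [rna_structure()].
#' @export
parse_ct <- function(x, id = NULL) {
  lines <- read_text_lines(x, "CT")
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) < 2L) stop_input("CT input has no data rows")
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(head_tok[1L]))
  if (is.na(n) || n < 1L)
    stop_input("CT header does not start with a positive length")
  if (length(lines) < n + 1L)
    stop_input("CT declares %d rows but only %d present", n, length(lines) - 1L)
  if (is.null(id))
    id <- if (length(head_tok) > 1L)
      paste(head_tok[-1L], collapse = " ") else "ct"
  bases <- character(n)
  pair <- integer(n)
  for (r in seq_len(n)) {
    tok <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1L]]
    if (length(tok) < 5L)
      stop_input("CT row %d has %d columns; at least 5 required", r, length(tok))
    idx <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(idx) || idx != r)
      stop_input("CT row %d is numbered '%s'", r, tok[1L])
    bases[r] <- tok[2L]
    p <- suppressWarnings(as.integer(tok[5L]))
    if (is.na(p) || p < 0L || p > n)
      stop_input("CT row %d: pairing column '%s' out of range", r, tok[5L])
    pair[r] <- p
  }
  for (r in seq_len(n)) {
    p <- pair[r]
    if (p != 0L && pair[p] != r)
      stop_input("CT inconsistent pairing: row %d pairs to %d but row %d pairs to %d",
                 r, p, p, pair[p])
  }
  keep <- which(pair > seq_len(n))
  pairs <- cbind(keep, pair[keep])
  rna_structure(rna_sequence(paste(bases, collapse = ""), id = id),
                pairs, logical(length(keep)))
}

# Accept either a file path or raw text for the plain-text readers.
read_text_lines <- function(x, what) {
  if (!is.character(x)) stop_input("%s input must be text or a path", what)
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}
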