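BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Construct a secondary structure
#'
#' A secondary structure is a sequence plus a set of base pairs (i, j),
#' 1-based with i < j. Pairs from non-round bracket families are flagged as
#' pseudoknot pairs: they are retained for bookkeeping but the planar layout
#' engine refuses them (crossing pairs cannot be drawn without overlap).
#'
#' @param sequence An [rna_sequence()].
#' @param pairs Two-column integer matrix of (i, j) pairs; may have 0 rows.
#' @param pseudoknot Logical vector, one flag per pair.
#' @return Object of class `rna_structure` with fields `sequence`, `pairs`
#'   (matrix, columns `i`, `j`) and `pseudoknot`.
#' @export
rna_structure <- function(sequence, pairs = matrix(integer(0), 0, 2),
                          pseudoknot = logical(nrow(pairs))) {
  if (!inherits(sequence, "rna_sequence"))
    stop_input("sequence must be an rna_sequence")
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  n <- seq_length(sequence)
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] >= pairs[, 2L]))
      stop_input("pairs must satisfy i < j")
    if (any(pairs < 1L) || any(pairs > n))
      stop_input("pair index outside [1, %d]", n)
    if (anyDuplicated(c(pairs)))
      stop_input("an index occurs in more than one pair")
    if (any(pairs[, 2L] - pairs[, 1L] < 2L))
      stop_input("adjacent residues cannot pair (j - i >= 2 required)")
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    pseudoknot <- pseudoknot[ord]
  }
  structure(list(sequence = sequence, pairs = pairs,
                 pseudoknot = as.logical(pseudoknot)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s: %d nt, %d pairs (%d pseudoknot)\n",
              x$sequence$id, seq_length(x$sequence), nrow(x$pairs),
              sum(x$pseudoknot)))
  invisible(x)
}

#' Parse a dot-bracket string
#'
#' Round brackets `()` define canonical (nested) pairs; the `[] {} <>`
#' families are parsed too but their pairs are flagged as pseudoknots.
#'
#' @param text Dot-bracket string over `.()[]{}<>`.
#' @param sequence Optional [rna_sequence()] of matching length; an all-N
#'   sequence is fabricated when omitted (the metrics are geometry-only).
#' @return An [rna_structure()].
#' @export
#' @examples
#' parse_dotbracket("((..))")$pairs   # (1,6) and (2,5)
parse_dotbracket <- function(text, sequence = NULL) {
  if (!is.character(text) || length(text) != 1L)
    stop_input("dot-bracket text must be a single string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 1L) stop_input("dot-bracket string is empty")
  bad <- which(!chars %in% c(".", BRACKET_OPEN, BRACKET_CLOSE))
  if (length(bad))
    stop_input("invalid dot-bracket character '%s' at position %d",
               chars[bad[1L]], bad[1L])
  if (is.null(sequence)) {
    sequence <- rna_sequence(strrep("N", n))
  } else if (seq_length(sequence) != n) {
    stop_input("structure length %d does not match sequence length %d",
               n, seq_length(sequence))
  }
  stacks <- vector("list", length(BRACKET_OPEN))
  pi <- pj <- integer(0)
  pk <- logical(0)
  for (pos in seq_len(n)) {
    ch <- chars[pos]
    f <- match(ch, BRACKET_OPEN)
    if (!is.na(f)) {
      stacks[[f]] <- c(stacks[[f]], pos)
      next
    }
    f <- match(ch, BRACKET_CLOSE)
    if (!is.na(f)) {
      if (length(stacks[[f]]) == 0L)
        stop_input("unbalanced brackets: unmatched '%s' at position %d",
                   ch, pos)
      opener <- stacks[[f]][length(stacks[[f]])]
      stacks[[f]] <- stacks[[f]][-length(stacks[[f]])]
      pi <- c(pi, opener); pj <- c(pj, pos)
      pk <- c(pk, f != 1L)
    }
  }
  left <- unlist(stacks)
  if (length(left))
    stop_input("unbalanced brackets: unmatched '%s' at position %d",
               chars[max(left)], max(left))
  rna_structure(sequence, cbind(pi, pj), pk)
}

#' Render a structure back to dot-bracket
#'
#' Canonical pairs become `()`. Pseudoknot pairs are greedily assigned to the
#' `[] {} <>` families so that pairs within one family never cross; if more
#' than three mutually crossing pseudoknot layers occur the render fails.
#'
#' @param structure An [rna_structure()].
#' @return Dot-bracket string.
#' @export
render_dotbracket <- function(structure) {
  n <- seq_length(structure$sequence)
  out <- rep(".", n)
  pr <- structure$pairs
  fam <- integer(nrow(pr))
  fam[!structure$pseudoknot] <- 1L
  crossing <- function(a, b) {
    (a[1L] < b[1L] & b[1L] < a[2L] & a[2L] < b[2L]) ||
      (b[1L] < a[1L] & a[1L] < b[2L] & b[2L] < a[2L])
  }
  for (k in which(structure$pseudoknot)) {
    for (f in 2:4) {
      clash <- FALSE
      for (m in which(fam == f))
        if (crossing(pr[k, ], pr[m, ])) { clash <- TRUE; break }
      if (!clash) { fam[k] <- f; break }
    }
    if (fam[k] == 0L)
      stop_input("structure needs more than four bracket families to render")
  }
  for (k in seq_len(nrow(pr))) {
    out[pr[k, 1L]] <- BRACKET_OPEN[fam[k]]
    out[pr[k, 2L]] <- BRACKET_CLOSE[fam[k]]
  }
  paste(out, collapse = "")
}

#' Drop pseudoknot pairs before planar layout
#'
#' @param structure An [rna_structure()].
#' @param warn Emit a warning when pairs are removed.
#' @return The structure with only canonical (nested) pairs.
#' @export
strip_pseudoknots <- function(structure, warn = TRUE) {
  drop <- structure$pseudoknot
  if (any(drop) && warn)
    warning(sprintf("stripping %d pseudoknot pair(s) before layout",
                    sum(drop)))
  rna_structure(structure$sequence,
                structure$pairs[!drop, , drop = FALSE],
                logical(sum(!drop)))
}

# Partner vector: pt[i] = j if (i,j) paired, else 0. Canonical pairs only;
# errors if crossing pairs remain (the layout engine needs a nested tree).
partner_vector <- function(structure, require_nested = TRUE) {
  n <- seq_length(structure$sequence)
  pt <- integer(n)
  pr <- structure$pairs
  if (any(structure$pseudoknot))
    stop_input("pseudoknot pairs present; strip_pseudoknots() first")
  for (k in seq_len(nrow(pr))) {
    pt[pr[k, 1L]] <- pr[k, 2L]
    pt[pr[k, 2L]] <- pr[k, 1L]
  }
  if (require_nested && nrow(pr) > 1L) {
    i <- pr[, 1L]; j <- pr[, 2L]
    for (k in seq_len(nrow(pr) - 1L)) {
      a <- k + seq_len(nrow(pr) - k)
      if (any(i[a] < j[k] & j[k] < j[a] & i[k] < i[a]))
        stop_input("crossing canonical pairs; structure is not nested")
    }
  }
  pt
}
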