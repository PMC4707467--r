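#' Read per-nucleotide 2D coordinates from structure-plot PostScript
#'
#' Primary dialect: the RNAfold/RNAplot coordinate array, a block of the form
#' `/coor [ [x y] [x y] ... ] def`. Fallback dialect (RNA STRAND style):
#' per-nucleotide drawing lines where a coordinate pair precedes a drawing
#' command, e.g. `(G) 12.5 40.0 a` or `12.5 40.0 lineto`. Any other dialect
#' is reported as unsupported rather than guessed at.
#'
#' @param x Path to a PostScript file, or its text.
#' @return Numeric n x 2 matrix of (x, y), one row per nucleotide in 5'->3'
#'   file order.
#' @export
read_ps_coordinates <- function(x) {
  lines <- read_text_lines(x, "PostScript")
  txt <- paste(lines, collapse = "\n")
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  coor_at <- regexpr("/coor\\b", txt)
  if (coor_at > 0L) {
    rest <- substr(txt, coor_at, nchar(txt))
    end <- regexpr("\\]\\s*def", rest)
    if (end < 0L) stop_input("'/coor' block is not closed by '] def'")
    block <- substr(rest, 1L, end)
    pat <- sprintf("\\[\\s*(%s)\\s+(%s)\\s*\\]", num, num)
    m <- gregexpr(pat, block, perl = TRUE)
    if (m[[1L]][1L] < 0L) stop_input("'/coor' block contains no [x y] rows")
    rows <- regmatches(block, m)[[1L]]
    xy <- t(vapply(rows, function(r) {
      as.numeric(strsplit(gsub("[][]", "", r), "\\s+")[[1L]])
    }, numeric(2L), USE.NAMES = FALSE))
    return(validate_layout2d(xy))
  }
  # fallback: "(B) x y cmd" or "x y cmd" drawing lines
  pat <- sprintf("^\\s*(\\([A-Za-z]\\)\\s+)?(%s)\\s+(%s)\\s+(a|n|t|lineto|moveto)\\s*$",
                 num, num)
  hit <- grepl(pat, lines, perl = TRUE)
  if (!any(hit))
    stop_input("no coordinate array found: unsupported PostScript dialect")
  xy <- t(vapply(lines[hit], function(l) {
    g <- regmatches(l, regexec(pat, l, perl = TRUE))[[1L]]
    as.numeric(g[c(3L, 4L)])
  }, numeric(2L), USE.NAMES = FALSE))
  validate_layout2d(xy)
}

validate_layout2d <- function(xy) {
  xy <- matrix(as.numeric(xy), ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (nrow(xy) == 0L) stop_input("coordinate block is empty")
  if (!all(is.finite(xy))) stop_input("non-finite 2D coordinate encountered")
  xy
}

#' Write a minimal coordinate-block PostScript file
#'
#' Emits only the `/coor` array (plus a comment header); enough for
#' [read_ps_coordinates()] to round-trip the layout exactly.
#'
#' @param points n x 2 coordinate matrix.
#' @param path Output file.
#' @param id Molecule id written into the header comment.
#' @export
write_ps_coordinates <- function(points, path, id = "rna") {
  points <- validate_layout2d(points)
  rows <- sprintf("[%.17g %.17g]", points[, 1L], points[, 2L])
  writeLines(c("%!PS-Adobe-3.0 EPSF-3.0",
               sprintf("%%%% molecule: %s", id),
               "/coor [", rows, "] def"),
             path)
  invisible(path)
}
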