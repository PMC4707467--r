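#' Construct a normalized RNA sequence
#'
#' Uppercases the residues, maps T to U (DNA-alphabet input is accepted) and
#' maps any other letter outside \{A, C, G, U\} to N. The distance metrics are
#' geometry-only, so unknown residues are tolerated rather than rejected.
#'
#' @param residues Single character string of residues, length >= 1.
#' @param id Text identifier for the molecule.
#' @return An object of class `rna_sequence` with fields `id` and `residues`.
#' @export
#' @examples
#' rna_sequence("acgt")$residues  # "ACGU"
rna_sequence <- function(residues, id = "rna") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop_input("residues must be a single character string")
  res <- chartr("T", "U", toupper(residues))
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L)
    stop_input("sequence '%s' is empty", id)
  chars[!chars %in% c("A", "C", "G", "U", "N")] <- "N"
  structure(list(id = as.character(id),
                 residues = paste(chars, collapse = "")),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Sequence length in nucleotides
#' @param x An `rna_sequence`.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Read RNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that normalizes each
#' record through [rna_sequence()] (T mapped to U, unknown letters to N).
#'
#' @param path FASTA file path.
#' @return List of `rna_sequence` objects, named by record id.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_input("FASTA file %s contains no records", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  out <- lapply(seq_along(set),
                function(k) rna_sequence(as.character(set[[k]]), id = ids[k]))
  names(out) <- ids
  out
}
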