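RNA_RESNAMES <- c("A", "C", "G", "U", "N",
                  "RA", "RC", "RG", "RU", "RN",
                  "ADE", "CYT", "GUA", "URA", "URI")

#' Read one representative 3D point per nucleotide from a PDB file
#'
#' Scans ATOM/HETATM records with standard ribonucleotide residue names
#' (A, C, G, U and common aliases). Only the first MODEL of multi-model files
#' is used, and alternate locations other than blank/"A" are skipped.
#'
#' Representative-point policy: `"mean"` (default) averages all non-hydrogen
#' atoms of the residue; `"c1prime"` takes the C1' atom. A residue with no
#' usable atom under the chosen policy is NOT dropped: its row is NA and its
#' index is recorded in the `incomplete` field, which the correlation-stage
#' filter consumes as "incomplete coordinates".
#'
#' @param x Path to a PDB file, or its text.
#' @param representative `"mean"` or `"c1prime"`.
#' @return Object of class `structure3d`: list with `points` (n x 3 matrix,
#'   angstroms), `chain_count`, `incomplete` (integer residue indices),
#'   `sequence` (an [rna_sequence()] read off the residue names).
#' @export
read_pdb_nucleotides <- function(x, representative = c("mean", "c1prime")) {
  representative <- match.arg(representative)
  lines <- read_text_lines(x, "PDB")
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    mend <- grep("^ENDMDL", lines)
    last <- if (length(mend)) mend[1L] else length(lines)
    lines <- lines[(mstart[1L] + 1L):(last - 1L)]
  }
  atom <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(atom)) stop_input("no ATOM/HETATM records found")
  fld <- function(s, a, b) trimws(substr(s, a, b))
  resname <- fld(atom, 18, 20)
  keep <- resname %in% RNA_RESNAMES
  altloc <- substr(atom, 17, 17)
  keep <- keep & altloc %in% c(" ", "", "A")
  atom <- atom[keep]; resname <- resname[keep]
  if (!length(atom)) stop_input("no ribonucleotide residues found")
  name <- fld(atom, 13, 16)
  chain <- substr(atom, 22, 22)
  resid <- paste0(chain, ":", fld(atom, 23, 27))  # resseq + insertion code
  xyz <- cbind(as.numeric(substr(atom, 31, 38)),
               as.numeric(substr(atom, 39, 46)),
               as.numeric(substr(atom, 47, 54)))
  if (!all(is.finite(xyz))) stop_input("malformed coordinate field in PDB")
  elem <- toupper(fld(atom, 77, 78))
  is_h <- elem %in% c("H", "D") |
    (!nzchar(elem) & grepl("^[0-9]*[HD]", name))
  res_order <- unique(resid)
  n <- length(res_order)
  pts <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  bases <- character(n)
  incomplete <- integer(0)
  for (r in seq_len(n)) {
    sel <- resid == res_order[r]
    bases[r] <- base_letter(resname[sel][1L])
    use <- if (representative == "c1prime") {
      sel & name %in% c("C1'", "C1*")
    } else {
      sel & !is_h
    }
    if (!any(use)) {
      incomplete <- c(incomplete, r)
    } else {
      pts[r, ] <- colMeans(xyz[use, , drop = FALSE])
    }
  }
  structure(list(points = pts,
                 chain_count = length(unique(chain)),
                 incomplete = incomplete,
                 sequence = rna_sequence(paste(bases, collapse = ""),
                                         id = "pdb")),
            class = "structure3d")
}

base_letter <- function(resname) {
  map <- c(ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
           RA = "A", RC = "C", RG = "G", RU = "U", RN = "N")
  if (resname %in% names(map)) unname(map[resname])
  else if (resname %in% c("A", "C", "G", "U", "N")) resname
  else "N"
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d residues, %d chain(s), %d incomplete\n",
              nrow(x$points), x$chain_count, length(x$incomplete)))
  invisible(x)
}
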