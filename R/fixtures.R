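#' Synthetic secondary structures for testing and demos
#'
#' Deterministic generators: `hairpin` is `(^s .^l )^s`; `cloverleaf` is a
#' tRNA-like topology (acceptor stem, three hairpin arms on a central
#' multiloop, single-stranded tail); `unpaired` is all dots.
#'
#' @param kind `"hairpin"`, `"cloverleaf"` or `"unpaired"`.
#' @param n Length for `unpaired`.
#' @param stem,loop Stem and loop lengths for `hairpin`.
#' @param acc_stem Acceptor-stem length for `cloverleaf`.
#' @param arm_stem,arm_loop Arm stem/loop lengths for `cloverleaf` (each a
#'   single value or one per arm).
#' @param tail 3' single-stranded tail length for `cloverleaf`.
#' @param id Molecule id.
#' @return An [rna_structure()] (random filler sequence is not generated;
#'   residues are all N since the geometry alone drives the method).
#' @export
#' @examples
#' render_dotbracket(make_structure("hairpin", stem = 3, loop = 4))
make_structure <- function(kind = c("hairpin", "cloverleaf", "unpaired"),
                           n = 10L, stem = 3L, loop = 4L,
                           acc_stem = 7L, arm_stem = c(4L, 5L, 5L),
                           arm_loop = c(8L, 7L, 7L), tail = 4L,
                           id = kind) {
  kind <- match.arg(kind)
  db <- switch(kind,
    unpaired = {
      if (n < 1L) stop_input("unpaired structure needs n >= 1")
      strrep(".", n)
    },
    hairpin = {
      if (stem < 1L || loop < 3L)
        stop_input("hairpin needs stem >= 1 and loop >= 3")
      paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
    },
    cloverleaf = {
      arm_stem <- rep_len(arm_stem, 3L)
      arm_loop <- rep_len(arm_loop, 3L)
      if (acc_stem < 1L || any(arm_stem < 1L) || any(arm_loop < 3L))
        stop_input("cloverleaf arms need stem >= 1 and loop >= 3")
      arm <- function(k) paste0(strrep("(", arm_stem[k]),
                                strrep(".", arm_loop[k]),
                                strrep(")", arm_stem[k]))
      # 7 + 2 + 16 + 1 + 17 + 5 + 17 + 7 + 4 = 76 nt with the defaults,
      # the canonical tRNA length (variable loop of 5 between arms 2 and 3)
      paste0(strrep("(", acc_stem), "..",
             arm(1L), ".", arm(2L), ".....",
             arm(3L), strrep(")", acc_stem), strrep(".", tail))
    })
  parse_dotbracket(db, rna_sequence(strrep("N", nchar(db)), id = id))
}

#' Planted-extremum distance curves with known ground truth
#'
#' A constant baseline plus Gaussian lobes (bumps for positive amplitudes,
#' dips for negative) centred at the given positions. Between two lobes of
#' opposite sign the curve is strictly monotone, so the planted positions
#' are exactly the interior extrema; two same-sign neighbours would induce
#' an extra extremum between them, so lobes are required to alternate in
#' sign. Lobes must be separated by more than `min_separation` and stay
#' `min_separation` clear of the curve ends.
#'
#' @param n Curve length.
#' @param positions Integer lobe centres, strictly increasing.
#' @param amplitudes Lobe heights; sign gives bump/dip, must alternate.
#' @param width Lobe standard deviation in nucleotides.
#' @param baseline Constant offset; must exceed `sum(abs(amplitudes))` so the
#'   curve stays non-negative.
#' @param min_separation Minimum centre separation and edge clearance
#'   (default `8 * width`, i.e. lobes essentially disjoint).
#' @param id Molecule id.
#' @return List with `curve` (a raw [distance_curve()]) and `truth`
#'   (the planted interior extremum positions).
#' @export
make_planted_curve <- function(n, positions, amplitudes, width = 3,
                               baseline = 10, min_separation = 8 * width,
                               id = "planted") {
  positions <- as.integer(positions)
  if (length(positions) != length(amplitudes))
    stop_input("positions and amplitudes must have equal length")
  if (length(positions)) {
    if (any(diff(positions) <= min_separation))
      stop_input("overlapping lobes: centres closer than %g", min_separation)
    if (positions[1L] <= min_separation ||
        positions[length(positions)] > n - min_separation)
      stop_input("lobes too close to the curve ends")
    if (any(amplitudes == 0)) stop_input("zero-amplitude lobe")
    if (length(amplitudes) > 1L && any(diff(sign(amplitudes)) == 0))
      stop_input("lobe signs must alternate (same-sign neighbours plant an extra extremum)")
  }
  if (baseline <= sum(abs(amplitudes)))
    stop_input("baseline must exceed total lobe amplitude")
  i <- seq_len(n)
  v <- rep(baseline, n)
  for (k in seq_along(positions))
    v <- v + amplitudes[k] * exp(-((i - positions[k])^2) / (2 * width^2))
  list(curve = distance_curve(v, "ndc", id, smoothed = FALSE),
       truth = positions)
}

#' Synthetic PDB text for an RNA helix
#'
#' Writes one C1' atom per residue along a circular helix (radius 9.4 A,
#' twist 32.7 degrees, rise 2.8 A — A-form-like numbers), cycling the bases
#' A, C, G, U. Options add a translated second chain (for the multi-chain
#' filter) or replace chosen residues' atoms with a lone hydrogen, which no
#' heavy-atom representative policy can use, so [read_pdb_nucleotides()]
#' reports those residues as incomplete (for the incomplete-coordinates
#' filter).
#'
#' @param n Residues per chain.
#' @param chains 1 or 2.
#' @param drop_atoms_of Residue indices (chain A) whose atoms are replaced by
#'   a lone hydrogen, making them unusable under any heavy-atom policy and
#'   hence reported as incomplete.
#' @param id Molecule id for the header.
#' @return Character scalar of PDB text.
#' @export
make_toy_pdb <- function(n, chains = 1L, drop_atoms_of = integer(0),
                         id = "toyrna") {
  if (!is_count(n) || n < 1L) stop_input("n must be a positive integer")
  if (!chains %in% c(1L, 2L)) stop_input("chains must be 1 or 2")
  bases <- rep_len(c("A", "C", "G", "U"), n)
  twist <- 32.7 * pi / 180
  lines <- c(sprintf("HEADER    SYNTHETIC RNA %s", toupper(id)))
  serial <- 0L
  for (ch in c("A", "B")[seq_len(chains)]) {
    off <- if (ch == "A") 0 else 30  # translate the copy away from chain A
    for (r in seq_len(n)) {
      serial <- serial + 1L
      x <- 9.4 * cos(twist * r) + off
      y <- 9.4 * sin(twist * r)
      z <- 2.8 * r
      if (ch == "A" && r %in% drop_atoms_of) {
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
          serial, "H1'", bases[r], ch, r, x, y, z))
      } else {
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, "C1'", bases[r], ch, r, x, y, z))
      }
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END"), collapse = "\n")
}
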