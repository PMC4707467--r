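#' Radiate 2D layout of a nested secondary structure
#'
#' Deterministic drawing engine used when no PostScript coordinates are
#' supplied. The exterior loop runs along the +x axis from the origin;
#' helices are parallel ladders with partners `pair_span` apart and
#' consecutive pairs `backbone_spacing` apart; each internal loop is placed
#' on a circle sized so that backbone steps and pair chords fit at their
#' nominal lengths (solved numerically from the inscribed-polygon angle
#' equation, with a proportional-angle fallback for loops too tight to
#' close). Child helices leave a loop radially, continuing the bisector of
#' their two anchor points.
#'
#' The engine makes no attempt to match any external drawing program
#' coordinate-for-coordinate: the downstream distance metrics depend only on
#' relative geometry, and rank-based comparison is scale-free.
#'
#' @param structure An [rna_structure()] with nested canonical pairs only;
#'   refuses structures still carrying pseudoknot pairs
#'   (see [strip_pseudoknots()]).
#' @param backbone_spacing Distance between consecutive backbone neighbours
#'   on straight segments and between loop members; default 1.
#' @param pair_span Distance between the two partners of a base pair;
#'   default 2.
#' @return n x 2 coordinate matrix (a Layout2D).
#' @export
#' @examples
#' s <- parse_dotbracket("(((...)))")
#' layout_radiate(s)
layout_radiate <- function(structure, backbone_spacing = 1.0, pair_span = 2.0) {
  if (!is.numeric(backbone_spacing) || backbone_spacing <= 0)
    stop_config("backbone_spacing must be > 0")
  if (!is.numeric(pair_span) || pair_span <= 0)
    stop_config("pair_span must be > 0")
  if (any(structure$pseudoknot))
    stop_input("layout_radiate: pseudoknot pairs present; strip them first")
  pt <- partner_vector(structure)
  n <- length(pt)
  s <- backbone_spacing; p <- pair_span
  coords <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))

  chord_angle <- function(c, r) 2 * asin(pmin(1, c / (2 * r)))

  # Solve the loop circle radius: m points on a circle, consecutive chords of
  # given lengths, angles must sum to 2*pi. Monotone in r -> uniroot.
  loop_radius <- function(n_bb, n_pc) {
    rmin <- max(s, p) / 2
    f <- function(r) n_bb * chord_angle(s, r) + n_pc * chord_angle(p, r) - 2 * pi
    if (f(rmin) < 0) return(list(r = rmin, exact = FALSE))
    rmax <- (n_bb * s + n_pc * p)  # angles ~ chord/r, safely past the root
    while (f(rmax) > 0) rmax <- rmax * 2
    r <- stats::uniroot(f, c(rmin, rmax), tol = 1e-12)$root
    list(r = r, exact = TRUE)
  }

  place_loop <- function(i, j, A, B, u) {
    # elements strictly inside (i, j): unpaired singles and child helices
    elems <- list()
    k <- i + 1L
    while (k < j) {
      if (pt[k] == 0L) {
        elems[[length(elems) + 1L]] <- k
        k <- k + 1L
      } else {
        elems[[length(elems) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      }
    }
    n_child <- sum(lengths(elems) == 2L)
    n_single <- sum(lengths(elems) == 1L)
    m <- 2L + n_single + 2L * n_child            # points on the circle
    n_pc <- 1L + n_child                         # pair chords (incl. closing)
    n_bb <- m - n_pc                             # backbone chords
    sol <- loop_radius(n_bb, n_pc)
    r <- sol$r
    h <- sqrt(max(r^2 - (p / 2)^2, 0))
    M <- (A + B) / 2
    C <- M + u * h
    ang <- function(P) atan2(P[2L] - C[2L], P[1L] - C[1L])
    th5 <- ang(A); th3 <- ang(B)
    closing <- chord_angle(p, r)
    interior <- 2 * pi - closing
    # walk direction: th5 + d * interior must land on th3 (mod 2pi)
    d <- if (abs((th3 - th5 - interior) %% (2 * pi)) < 1e-6 ||
             abs((th3 - th5 - interior) %% (2 * pi) - 2 * pi) < 1e-6) 1 else -1
    gap <- function(c) {
      if (sol$exact) chord_angle(c, r)
      else interior * c / (n_bb * s + (n_pc - 1L) * p)  # proportional fallback
    }
    on_circle <- function(theta) C + r * c(cos(theta), sin(theta))
    theta <- th5
    for (e in elems) {
      theta <- theta + d * gap(s)
      if (length(e) == 1L) {
        coords[e, ] <<- on_circle(theta)
      } else {
        Ae <- on_circle(theta)
        theta <- theta + d * gap(p)
        Be <- on_circle(theta)
        mid <- (Ae + Be) / 2
        uc <- mid - C
        uc <- uc / sqrt(sum(uc^2))
        place_helix(e[1L], e[2L], Ae, Be, uc)
      }
    }
  }

  place_helix <- function(i, j, A, B, u) {
    repeat {
      coords[i, ] <<- A
      coords[j, ] <<- B
      if (i + 1L < j - 1L && pt[i + 1L] == j - 1L) {
        i <- i + 1L; j <- j - 1L
        A <- A + u * s; B <- B + u * s
      } else break
    }
    place_loop(i, j, A, B, u)
  }

  # exterior loop: straight line along +x from the origin
  x <- 0
  k <- 1L
  while (k <= n) {
    if (pt[k] == 0L) {
      coords[k, ] <- c(x, 0)
      x <- x + s
      k <- k + 1L
    } else {
      j <- pt[k]
      place_helix(k, j, c(x, 0), c(x + p, 0), c(0, 1))
      x <- x + p + s
      k <- j + 1L
    }
  }
  coords
}
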