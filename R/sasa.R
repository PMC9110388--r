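# Solvent-accessible surface area by the Shrake-Rupley rolling-probe method
# with a deterministic Fibonacci-spiral point set, and buried interface area
# between two selections.

# Deterministic quasi-uniform points on the unit sphere (golden-angle spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(s, radii_set) {
  if (identical(radii_set, "bead")) {
    if (is.null(s$radius)) stop("radii_set 'bead' needs a radius column",
                                call. = FALSE)
    return(s$radius)
  }
  if (is.numeric(radii_set)) return(rep_len(radii_set, nrow(s)))
  if (!is.null(s$radius) && all(is.finite(s$radius))) return(s$radius)
  .element_lookup(s$element, "radius")
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure: each atom is inflated by the
#' probe radius and sampled with a fixed quasi-uniform point set; points not
#' buried inside any neighbouring inflated sphere are accessible.  The point
#' set is deterministic, so results are exactly reproducible.
#'
#' @param s structure; per-atom radii are taken from a `radius` column if
#'   present, else from the element radii set
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water)
#' @param n_points sphere sample points per atom (default 960)
#' @param radii_set `"element"` (Bondi van der Waals radii by element, the
#'   default), `"bead"` (require the structure's own radius column), or a
#'   numeric radius applied to all atoms
#' @return numeric vector of per-atom accessible areas (Angstrom^2); the
#'   total SASA is their sum
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960,
                 radii_set = "element") {
  n <- nrow(s)
  r <- .atom_radii(s, radii_set) + probe_radius
  xyz <- coords(s)
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  # cell list for neighbour search
  cell <- 2 * max(r)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  keystr <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(n), keystr)
  keymat <- unique(key)
  rownames(keymat) <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cellmap <- new.env(hash = TRUE)
  for (nm in names(cells)) assign(nm, cells[[nm]], envir = cellmap)
  for (i in seq_len(n)) {
    k <- key[i, ]
    nb <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nm <- paste(k[1] + offs[o, 1], k[2] + offs[o, 2], k[3] + offs[o, 3])
      if (exists(nm, envir = cellmap, inherits = FALSE))
        nb <- c(nb, get(nm, envir = cellmap, inherits = FALSE))
    }
    nb <- nb[nb != i]
    if (length(nb)) {
      d2 <- rowSums(sweep(xyz[nb, , drop = FALSE], 2, xyz[i, ])^2)
      nb <- nb[d2 < (r[i] + r[nb])^2]
    }
    if (!length(nb)) { out[i] <- 4 * pi * r[i]^2; next }
    sp <- sweep(pts * r[i], 2, xyz[i, ], `+`)   # n_points x 3
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- d2 > r[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  out
}

#' Buried interface area between two selections
#'
#' `SASA(A alone) + SASA(B alone) - SASA(A and B together)`: the surface
#' area occluded by bringing the two selections into contact.  Symmetric in
#' its arguments and non-negative up to quadrature error.
#'
#' @param s structure containing both selections
#' @param selA,selB length-2 residue intervals `c(first, last)` (disjoint)
#' @inheritParams sasa
#' @return buried area in Angstrom^2
#' @export
buried_interface_area <- function(s, selA, selB, probe_radius = 1.4,
                                  n_points = 960, radii_set = "element") {
  if (max(selA[1], selB[1]) <= min(selA[2], selB[2]))
    stop("selections overlap", call. = FALSE)
  a <- select_domain(s, selA)
  b <- select_domain(s, selB)
  ab <- rbind(a, b)
  class(ab) <- class(a)
  sum(sasa(a, probe_radius, n_points, radii_set)) +
    sum(sasa(b, probe_radius, n_points, radii_set)) -
    sum(sasa(ab, probe_radius, n_points, radii_set))
}
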