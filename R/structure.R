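#' @useDynLib pincerflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rmultinom approx sd median quantile lm coef fitted residuals predict optimize setNames
#' @importFrom utils head tail read.table write.table combn
NULL

# Atomic masses (Da) and electron counts for the elements seen in protein
# crystal structures and coarse-grained bead models.  Beads carry their own
# mass/radius, so this table only needs the common heavy atoms plus H.
.element_data <- data.frame(
  element   = c("H",  "C",   "N",   "O",   "S",   "P",   "SE",  "FE",  "ZN",  "MG",  "CA",  "NA",  "CL",  "K"),
  mass      = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971, 55.845, 65.38, 24.305, 40.078, 22.990, 35.45, 39.098),
  electrons = c(1,    6,     7,     8,     16,    15,    34,    26,    30,    12,    20,    11,    17,    19),
  # van der Waals radii (Bondi 1964), the default element radii set for SASA
  radius    = c(1.20, 1.70,  1.55,  1.52,  1.80,  1.80,  1.90,  2.00,  2.10,  1.73,  2.00,  2.27,  1.75,  2.75),
  stringsAsFactors = FALSE
)

.element_lookup <- function(elements, what) {
  idx <- match(toupper(elements), .element_data$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .element_data[[what]][idx]
}

#' Construct a structure object
#'
#' A structure is an ordered table of atoms (or coarse-grained beads) with
#' coordinates in Angstrom, masses in Dalton and author residue numbering.
#' It is the common currency of the geometry, elastic-network, sampling and
#' SAXS layers.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` (Angstrom) and
#'   optionally `serial`, `name`, `element`, `mass` (Da), `resno`, `chain`,
#'   `occ`, `radius` (Angstrom).  Missing columns are filled with sensible
#'   defaults (element "C", one residue per atom, occupancy 1); a missing
#'   `mass` is inferred from `element`.
#' @return An object of class `pincer_structure` (a data.frame).
#' @export
new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns x, y, z", call. = FALSE)
  n <- nrow(atoms)
  if (n == 0L) stop("empty structure: no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, need])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(atoms$serial))  atoms$serial  <- seq_len(n)
  if (is.null(atoms$element)) atoms$element <- "C"
  if (is.null(atoms$name))    atoms$name    <- atoms$element
  if (is.null(atoms$resno))   atoms$resno   <- seq_len(n)
  if (is.null(atoms$chain))   atoms$chain   <- "A"
  if (is.null(atoms$occ))     atoms$occ     <- 1
  if (is.null(atoms$mass))    atoms$mass    <- .element_lookup(atoms$element, "mass")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("masses must be positive and finite", call. = FALSE)
  structure(as.data.frame(atoms), class = c("pincer_structure", "data.frame"))
}

#' @export
print.pincer_structure <- function(x, ...) {
  cat(sprintf("<pincer_structure> %d atoms, %d residue(s), chain(s): %s\n",
              nrow(x), length(unique(x$resno)),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s a `pincer_structure`
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(s) {
  as.matrix(s[, c("x", "y", "z"), drop = FALSE])
}

`coords<-` <- function(s, value) {
  s$x <- value[, 1]; s$y <- value[, 2]; s$z <- value[, 3]
  s
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, resolves alternate locations
#' and infers element and mass.  Parsing proper is delegated to
#' [bio3d::read.pdb]; a pre-scan enforces the fixed-column coordinate fields
#' so that a malformed record is reported with its line number.
#'
#' @param path path to a PDB-format text file
#' @param altloc_policy how alternate locations are resolved:
#'   `"occupancy"` (default) keeps the highest-occupancy conformer of each
#'   atom, ties broken in favour of the first listed; `"first"` keeps the
#'   first listed conformer unconditionally.
#' @param het keep HETATM records (ligands, waters)?  Default `FALSE`:
#'   protein atoms only.
#' @param model model number to read from multi-MODEL files (default 1)
#' @return a [new_structure()] object
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first"),
                           het = FALSE, model = 1L) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (any(is_atom)) {
    idx <- which(is_atom)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[idx], fld[1], fld[2])))
      if (anyNA(v)) {
        bad <- idx[which(is.na(v))[1]]
        stop(sprintf("malformed ATOM/HETATM record at line %d of %s: %s",
                     bad, path, trimws(lines[bad])), call. = FALSE)
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = (model > 1L), rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (model > 1L) {
    if (nrow(pdb$xyz) < model) stop("model ", model, " not present", call. = FALSE)
    m <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  }
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty structure: no ", if (het) "atoms" else "protein (ATOM) records",
         " in ", path, call. = FALSE)
  # altloc resolution: group by chain/residue/insert/atom name
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    if (altloc_policy == "occupancy") {
      occ <- at$o
      occ[is.na(occ)] <- 1
      ord <- order(key, -occ, seq_len(nrow(at)))
    } else {
      ord <- order(key, seq_len(nrow(at)))
    }
    keep_first <- !duplicated(key[ord])
    keep <- sort(ord[keep_first])
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) elem[blank] <- bio3d::atom2ele(at$elety[blank])
  elem <- toupper(trimws(elem))
  new_structure(data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    resno = at$resno, chain = at$chain,
    occ = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Define an ordered domain partition
#'
#' Domains are named, closed residue intervals in author numbering, e.g. the
#' four AbnA domains 1-441, 442-550, 551-639, 640-848.
#'
#' @param first,last integer vectors of first/last residues (closed intervals)
#' @param names domain names; default `Domain1..DomainN`
#' @return object of class `domain_partition`
#' @export
domain_partition <- function(first, last, names = NULL) {
  stopifnot(length(first) == length(last), all(last >= first))
  if (is.null(names)) names <- paste0("Domain", seq_along(first))
  ord <- order(first)
  first <- first[ord]; last <- last[ord]; names <- names[ord]
  if (length(first) > 1 && any(first[-1] <= last[-length(last)]))
    stop("domain intervals overlap", call. = FALSE)
  structure(data.frame(name = names, first = first, last = last,
                       stringsAsFactors = FALSE),
            class = c("domain_partition", "data.frame"))
}

#' The default AbnA domain partition (residues 1-441 / 442-550 / 551-639 /
#' 640-848)
#' @return a [domain_partition()]
#' @export
abna_partition <- function() {
  domain_partition(c(1, 442, 551, 640), c(441, 550, 639, 848))
}

#' Select the atoms of one domain (or residue interval)
#' @param s structure
#' @param domain either a row index / name into `partition`, or a length-2
#'   vector `c(first, last)` when `partition` is NULL
#' @param partition a [domain_partition()]
#' @return a `pincer_structure` subset
#' @export
select_domain <- function(s, domain, partition = NULL) {
  if (!is.null(partition)) {
    if (is.character(domain)) domain <- match(domain, partition$name)
    iv <- c(partition$first[domain], partition$last[domain])
  } else iv <- domain
  sel <- s$resno >= iv[1] & s$resno <= iv[2]
  if (!any(sel)) stop("empty selection: residues ", iv[1], "-", iv[2],
                      " not present", call. = FALSE)
  out <- s[sel, , drop = FALSE]
  class(out) <- class(s)
  out
}

#' Center of mass of a structure or selection
#'
#' @param s structure
#' @param selection optional length-2 residue interval `c(first, last)`
#' @param mass_weighted mass-weighted (default) or geometric mean
#' @return length-3 numeric (x, y, z) in Angstrom
#' @export
center_of_mass <- function(s, selection = NULL, mass_weighted = TRUE) {
  if (!is.null(selection)) s <- select_domain(s, selection)
  w <- if (mass_weighted) s$mass else rep(1, nrow(s))
  unname(drop(crossprod(coords(s), w) / sum(w))[1:3])
}

# Interior angle and IUPAC torsion of point sequences ------------------------

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  v <- c(b2[2] * b3[3] - b2[3] * b3[2],
         b2[3] * b3[1] - b2[1] * b3[3],
         b2[1] * b3[2] - b2[2] * b3[1])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2)); nb2 <- sqrt(sum(b2^2))
  if (nu < 1e-10 || nv < 1e-10 || nb2 < 1e-10)
    stop("degenerate geometry: torsion undefined for collinear points",
         call. = FALSE)
  y <- sum((c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])) * b2) / nb2
  x <- sum(u * v)
  atan2(y, x)
}

#' Collective-variable pair of a four-domain structure
#'
#' CV1 is the distance (Angstrom) between the centers of mass of the first
#' and fourth domains; CV2 is the torsion (degrees, IUPAC convention, in
#' (-180, 180]) of the four domain centers of mass.  These are the two
#' coordinates along which the pincer opens ("opening-up", CV1) and swings
#' ("sideways", CV2).
#'
#' @param s structure
#' @param partition a [domain_partition()] with at least 4 domains
#' @param mass_weighted mass-weighted centers of mass (default) or geometric
#' @param verbose if TRUE, also print the geometric-COM variant
#' @return list with elements `d` (Angstrom) and `phi` (degrees)
#' @export
cv_pair <- function(s, partition = abna_partition(), mass_weighted = TRUE,
                    verbose = FALSE) {
  if (nrow(partition) < 4) stop("partition must have >= 4 domains", call. = FALSE)
  coms <- lapply(1:4, function(k)
    center_of_mass(select_domain(s, k, partition), mass_weighted = mass_weighted))
  d <- sqrt(sum((coms[[1]] - coms[[4]])^2))
  phi <- .torsion(coms[[1]], coms[[2]], coms[[3]], coms[[4]]) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  if (verbose) {
    alt <- cv_pair(s, partition, mass_weighted = !mass_weighted)
    cat(sprintf("CV pair (%s): d = %.2f A, phi = %.2f deg; (%s): d = %.2f, phi = %.2f\n",
                if (mass_weighted) "mass-weighted" else "geometric", d, phi,
                if (mass_weighted) "geometric" else "mass-weighted", alt$d, alt$phi))
  }
  list(d = d, phi = phi)
}

#' Radius of gyration
#'
#' `sqrt(sum(m_i |r_i - COM|^2) / sum(m_i))` over the (heavy) atoms present.
#'
#' @inheritParams center_of_mass
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(s, mass_weighted = TRUE) {
  if (nrow(s) < 2) stop("radius of gyration needs >= 2 atoms", call. = FALSE)
  w <- if (mass_weighted) s$mass else rep(1, nrow(s))
  xyz <- coords(s)
  com <- drop(crossprod(xyz, w) / sum(w))
  dx <- sweep(xyz, 2, com)
  sqrt(sum(w * rowSums(dx^2)) / sum(w))
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atoms of two structures, and applies it to `mobile`.
#'
#' @param mobile,reference structures (or n x 3 coordinate matrices)
#' @param pairing two-column integer matrix of (mobile, reference) atom
#'   indices; default pairs atoms in order (requires equal atom counts)
#' @param weights optional per-pair weights (e.g. masses)
#' @return list with `rotation` (3 x 3, det +1), `translation` (applied as
#'   `x %*% t(R) + t`), `rmsd` (Angstrom over the paired atoms) and
#'   `mobile_fitted` (all mobile coordinates transformed)
#' @export
superpose <- function(mobile, reference, pairing = NULL, weights = NULL) {
  xm_all <- if (is.matrix(mobile)) mobile else coords(mobile)
  xr_all <- if (is.matrix(reference)) reference else coords(reference)
  if (is.null(pairing)) {
    if (nrow(xm_all) != nrow(xr_all))
      stop("atom counts differ; supply an explicit pairing", call. = FALSE)
    pairing <- cbind(seq_len(nrow(xm_all)), seq_len(nrow(xr_all)))
  }
  xm <- xm_all[pairing[, 1], , drop = FALSE]
  xr <- xr_all[pairing[, 2], , drop = FALSE]
  n <- nrow(xm)
  if (n < 3) stop("need >= 3 paired atoms", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  cm <- drop(crossprod(xm, w)); cr <- drop(crossprod(xr, w))
  am <- sweep(xm, 2, cm); ar <- sweep(xr, 2, cr)
  # guard against degenerate (collinear) pairings
  if (any(svd(am * sqrt(w))$d[1:2] < 1e-8))
    stop("degenerate pairing: paired atoms are collinear", call. = FALSE)
  H <- crossprod(am * w, ar)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile -> reference
  tr <- cr - drop(R %*% cm)
  fit_pairs <- am %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fit_pairs - ar)^2)))
  list(rotation = R, translation = tr,
       rmsd = rmsd,
       mobile_fitted = sweep(xm_all %*% t(R), 2, tr, `+`))
}

#' Rotation angle (degrees) of a 3 x 3 rotation matrix
#' @param R rotation matrix
#' @return angle in degrees in [0, 180]
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid-body transform to a structure
#' @param s structure
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector
#' @return transformed structure
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  coords(s) <- xyz
  s
}

#' Write a (possibly multi-model) PDB file
#'
#' Minimal fixed-column writer used for coarse-grained conformers and
#' trajectory frames; crystal structures read with [read_structure()] can be
#' round-tripped at coordinate precision 1e-3 Angstrom.
#'
#' @param s structure (template for atom fields)
#' @param path output file
#' @param frames optional list of n x 3 coordinate matrices; if supplied each
#'   becomes one MODEL record
#' @return invisibly, `path`
#' @export
write_structure <- function(s, path, frames = NULL) {
  fmt_line <- function(i, xyz) {
    sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            s$serial[i] %% 100000, substr(s$name[i], 1, 4), "BEA",
            substr(s$chain[i], 1, 1), s$resno[i] %% 10000,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], s$occ[i], 0,
            substr(s$element[i], 1, 2))
  }
  con <- file(path, "w"); on.exit(close(con))
  if (is.null(frames)) frames <- list(coords(s))
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    writeLines(vapply(seq_len(nrow(s)), fmt_line, "", xyz = frames[[m]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
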