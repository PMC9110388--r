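# Anisotropic elastic-network model (ANM): Hessian assembly, normal modes,
# overlap with observed displacements, and classification of inter-domain
# motions as "opening" (along the domain1-domain4 distance) or "sideways"
# (along the four-domain torsion).

#' Select one node per residue (C-alpha, or bead)
#'
#' @param s structure
#' @param atom_name node atom name, default `"CA"`; if no atom of that name
#'   exists (coarse-grained models) the first atom of each residue is used
#' @return a `pincer_structure` of nodes
#' @export
enm_nodes <- function(s, atom_name = "CA") {
  ca <- s[s$name == atom_name, , drop = FALSE]
  if (nrow(ca) == 0) {
    keep <- !duplicated(paste(s$chain, s$resno))
    ca <- s[keep, , drop = FALSE]
  }
  class(ca) <- class(s)
  ca
}

#' Build the anisotropic-network-model Hessian
#'
#' For each pair of nodes within `cutoff`, the 3 x 3 off-diagonal block is
#' `-gamma * (r_ij r_ij^T) / |r_ij|^2`; diagonal blocks are minus the row
#' sums, so rigid translations are exact null vectors.
#'
#' @param s structure of network nodes (e.g. [enm_nodes()] output)
#' @param cutoff interaction cutoff in Angstrom (default 15)
#' @param gamma uniform spring constant (default 1, arbitrary units)
#' @return symmetric 3N x 3N matrix with attribute `"n_components"` (number
#'   of connected components; a warning is issued if the network is
#'   disconnected, which adds 6 extra zero modes per extra component at most)
#' @export
build_hessian <- function(s, cutoff = 15, gamma = 1) {
  xyz <- coords(s)
  n <- nrow(xyz)
  d2 <- as.matrix(dist(xyz))^2
  adj <- d2 <= cutoff^2 & d2 > 0
  # connected components by BFS
  comp <- integer(n); cc <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cc <- cc + 1L
    q <- start
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (comp[v]) next
      comp[v] <- cc
      q <- c(q, which(adj[v, ] & comp == 0L))
    }
  }
  if (cc > 1L)
    warning("elastic network is disconnected at cutoff ", cutoff, " A (",
            cc, " components); expect extra zero modes", call. = FALSE)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    js <- which(adj[i, ] & seq_len(n) > i)
    for (j in js) {
      rij <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(rij) / sum(rij^2)
      ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  attr(H, "n_components") <- cc
  H
}

#' Normal modes of an elastic-network Hessian
#'
#' Dense eigendecomposition (intended for networks of up to ~1000 nodes).
#' Eigenvalues are returned ascending; modes with eigenvalue below
#' `zero_tol * max(eigenvalue)` are flagged as rigid-body (trivial) modes,
#' and `nontrivial` indexes the remaining modes from slowest up.
#'
#' @param H Hessian from [build_hessian()]
#' @param n_modes number of nontrivial modes wanted (default all)
#' @param zero_tol relative threshold for the zero (rigid-body) eigenspace
#' @return object of class `mode_set`: list with `values` (ascending),
#'   `vectors` (orthonormal columns), `trivial` (logical), `nontrivial`
#'   (column indices of the first `n_modes` nontrivial modes)
#' @export
normal_modes <- function(H, n_modes = NULL, zero_tol = 1e-8) {
  if (!isTRUE(all.equal(H, t(H), tolerance = 1e-8)))
    stop("Hessian must be symmetric", call. = FALSE)
  n3 <- nrow(H)
  if (!is.null(n_modes) && n_modes > n3)
    stop("n_modes exceeds matrix dimension", call. = FALSE)
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  trivial <- values < zero_tol * max(abs(values))
  nontrivial <- which(!trivial)
  if (!is.null(n_modes)) nontrivial <- head(nontrivial, n_modes)
  structure(list(values = values, vectors = vectors, trivial = trivial,
                 nontrivial = nontrivial),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes (%d rigid-body); slowest nontrivial eigenvalues: %s\n",
              length(x$values), sum(x$trivial),
              paste(signif(x$values[head(x$nontrivial, 5)], 3), collapse = ", ")))
  invisible(x)
}

#' Overlap of a mode with an observed displacement
#'
#' `|v . d| / (|v| |d|)`, in [0, 1].
#'
#' @param mode,displacement 3N vectors
#' @return scalar overlap
#' @export
mode_overlap <- function(mode, displacement) {
  if (length(mode) != length(displacement))
    stop("dimension mismatch", call. = FALSE)
  nv <- sqrt(sum(mode^2)); nd <- sqrt(sum(displacement^2))
  if (nv < 1e-300 || nd < 1e-300) stop("zero-norm input", call. = FALSE)
  abs(sum(mode * displacement)) / (nv * nd)
}

#' Cumulative overlap of the first k nontrivial modes with a displacement
#' @param modes a `mode_set`
#' @param displacement 3N vector
#' @param k number of nontrivial modes (default all)
#' @return `sqrt(sum(overlap_i^2))` over the k slowest nontrivial modes
#' @export
cumulative_overlap <- function(modes, displacement, k = NULL) {
  idx <- modes$nontrivial
  if (!is.null(k)) idx <- head(idx, k)
  ov <- vapply(idx, function(i) mode_overlap(modes$vectors[, i], displacement),
               0.0)
  sqrt(sum(ov^2))
}

# Analytic gradients of the two collective variables with respect to node
# coordinates, used both for motion classification and (in C++) for biased
# sampling.  Returns a 3N-vector for each CV.
.cv_gradients <- function(s, partition) {
  n <- nrow(s)
  dom <- integer(n)
  for (k in seq_len(nrow(partition)))
    dom[s$resno >= partition$first[k] & s$resno <= partition$last[k]] <- k
  coms <- lapply(1:4, function(k) {
    sel <- dom == k
    if (!any(sel)) stop("domain ", k, " unresolvable in structure", call. = FALSE)
    drop(crossprod(coords(s)[sel, , drop = FALSE], s$mass[sel]) / sum(s$mass[sel]))
  })
  mfrac <- lapply(1:4, function(k) {
    sel <- dom == k
    w <- numeric(n); w[sel] <- s$mass[sel] / sum(s$mass[sel]); w
  })
  # CV1 gradient
  u <- coms[[1]] - coms[[4]]
  d <- sqrt(sum(u^2)); u <- u / d
  g1 <- matrix(0, n, 3)
  g1 <- g1 + outer(mfrac[[1]], u) - outer(mfrac[[4]], u)
  # CV2 gradient: torsion derivative w.r.t. the four COM points
  b1 <- coms[[2]] - coms[[1]]; b2 <- coms[[3]] - coms[[2]]; b3 <- coms[[4]] - coms[[3]]
  cp <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  u2 <- cp(b1, b2); v2 <- cp(b2, b3); nb2 <- sqrt(sum(b2^2))
  gp1 <- -nb2 / sum(u2^2) * u2
  gp4 <-  nb2 / sum(v2^2) * v2
  s1 <- -sum(b1 * b2) / sum(b2^2); s2 <- -sum(b3 * b2) / sum(b2^2)
  gp2 <- (s1 - 1) * gp1 - s2 * gp4
  gp3 <- (s2 - 1) * gp4 - s1 * gp1
  gp <- list(gp1, gp2, gp3, gp4)
  g2 <- matrix(0, n, 3)
  for (k in 1:4) g2 <- g2 + outer(mfrac[[k]], gp[[k]])
  list(d = as.vector(t(g1)), phi = as.vector(t(g2)), domain = dom)
}

#' Classify a normal mode as "opening", "sideways" or "mixed"
#'
#' Projects the Domain4 sub-vector of the mode onto the Domain4 sub-vectors
#' of the analytic CV gradients: a mode dominated by the inter-domain
#' distance gradient is an "opening" motion of the pincer, one dominated by
#' the four-domain torsion gradient is a "sideways" swing.
#'
#' @param mode 3N vector over the network nodes
#' @param s node structure the mode belongs to
#' @param partition a [domain_partition()] (>= 4 domains)
#' @param ratio dominance threshold: label assigned when one |projection|
#'   exceeds `ratio` times the other (default 1.5), otherwise "mixed"
#' @return character label with attribute `"projections"`
#' @export
classify_motion <- function(mode, s, partition = abna_partition(), ratio = 1.5) {
  g <- .cv_gradients(s, partition)
  idx4 <- which(g$domain == 4)
  sel <- as.vector(rbind(3 * (idx4 - 1) + 1, 3 * (idx4 - 1) + 2, 3 * idx4))
  m4 <- mode[sel]
  gd <- g$d[sel]; gp <- g$phi[sel]
  gd <- gd / sqrt(sum(gd^2)); gp <- gp / sqrt(sum(gp^2))
  pd <- abs(sum(m4 * gd)); pp <- abs(sum(m4 * gp))
  lab <- if (pd > ratio * pp) "opening" else if (pp > ratio * pd) "sideways" else "mixed"
  attr(lab, "projections") <- c(opening = pd, sideways = pp)
  lab
}

#' Randomization test for mode/displacement agreement
#'
#' Compares the cumulative overlap of the k slowest nontrivial modes with an
#' observed displacement against the null distribution of cumulative
#' overlaps with random unit vectors (uniform on the sphere in 3N
#' dimensions).
#'
#' @param modes a `mode_set`
#' @param displacement 3N vector (superposed-pair difference)
#' @param k number of modes (default 10)
#' @param n_random null-sample size (default 200)
#' @param seed RNG seed
#' @return list with `overlap`, `null` (vector), `quantile95`, `p_value`
#' @export
overlap_randomization_test <- function(modes, displacement, k = 10,
                                       n_random = 200, seed = 1) {
  ov <- cumulative_overlap(modes, displacement, k)
  n3 <- length(displacement)
  set.seed(seed)
  null <- vapply(seq_len(n_random), function(i) {
    v <- rnorm(n3)
    cumulative_overlap(modes, v, k)
  }, 0.0)
  list(overlap = ov, null = null,
       quantile95 = unname(quantile(null, 0.95)),
       p_value = mean(null >= ov))
}
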