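# Coarse-grained pincer protein generator: a four-domain bead model whose
# free-energy landscape over the two collective variables (domain1-domain4
# COM distance d, four-domain torsion phi) is imposed as a sum of Gaussian
# wells.  The inter-domain linker chain contributes a configurational
# entropy of its own in (d, phi); the model compensates it by quadrature so
# that the marginal free energy of the dynamical system equals the
# configured well landscape exactly (up to bonded-term fluctuations).

.kB <- 0.0019872041  # kcal/mol/K

# wrap an angle difference (radians) into (-pi, pi]
.wrap <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# Deterministic quasi-uniform bead cloud: one center bead, an inner and an
# outer golden-spiral shell.  Centered so the cloud COM is exactly 0.
.domain_cloud <- function(n_beads, radius) {
  n_out <- max(1L, round(n_beads * 0.6))
  n_in <- n_beads - 1L - n_out
  pts <- rbind(matrix(0, 1, 3),
               if (n_in > 0) .sphere_points(n_in) * radius * 0.55,
               .sphere_points(n_out) * radius)
  pts <- pts[seq_len(n_beads), , drop = FALSE]
  sweep(pts, 2, colMeans(pts))
}

# Place the four domain COMs for a symmetric-bend conformation with the
# requested collective variables: linker arms of length r, equal interior
# angles at the two hinges, torsion phi about the central arm.
.chain_coms <- function(arm, d, phi_rad) {
  k <- 2 - 2 * cos(phi_rad)
  t <- (d / arm)^2
  # (4 - k) c^2 - 4 c + (1 + k) - t = 0 with c = cos(interior angle)
  a <- 4 - k; b <- -4; cc <- 1 + k - t
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("requested d = ", d, " unreachable at phi = ",
                     round(phi_rad * 180 / pi, 1), " deg with arm ", arm,
                     call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots > -1 & roots < 1]
  if (!length(roots)) stop("no valid hinge angle for d = ", d, call. = FALSE)
  cth <- min(roots)      # most extended admissible bend
  sth <- sqrt(1 - cth^2)
  p2 <- c(0, 0, 0); p3 <- c(arm, 0, 0)
  p1 <- c(arm * cth, arm * sth, 0)
  p4 <- c(arm - arm * cth, arm * sth * cos(phi_rad), arm * sth * sin(phi_rad))
  rbind(p1, p2, p3, p4)
}

#' Build a coarse-grained pincer model
#'
#' Four quasi-rigid bead domains on a three-arm linker chain, with a
#' CV-space potential
#' `U(d, phi) = sum_k -A_k exp(-(d-d_k)^2/(2 s_dk^2) - wrap(phi-phi_k)^2/(2 s_pk^2))`
#' plus harmonic intra-domain networks, harmonic COM-COM linker bonds, and
#' one-sided polynomial restraining walls on d.  The `"abna-landscape"`
#' preset places the wells at the four free-energy minima of the pincer
#' landscape, (55 A, -63 deg), (50, 27), (67, -63), (74, 45), with relative
#' depths 0 / 1.2 / 2.5 / 8.2 kcal/mol below a common baseline, and walls at
#' 41 and 75 A (force constant 0.36 kcal/mol/A^2, power 2).
#'
#' A configurational-entropy compensation term (computed by quadrature over
#' the linker-chain measure and stored as a lookup table) is part of the
#' model potential, so that the marginal free energy over (d, phi) equals
#' the configured wells exactly; see the methods vignette.
#'
#' @param preset `"abna-landscape"` (only preset)
#' @param beads_per_domain beads per domain (default 20)
#' @param bead_mass bead mass in Da (default 25; light beads speed up CV
#'   diffusion at fixed friction)
#' @param bead_radius bead radius in Angstrom (default 3)
#' @param domain_radius domain cloud radius in Angstrom (default 10)
#' @param arm linker arm length (consecutive-domain COM distance), Angstrom
#'   (default 46, sized so the preset's 3-state mixture scatters like the
#'   ~36 A protein it emulates)
#' @param base_depth depth of the deepest well below the flat baseline,
#'   kcal/mol (default 9); well k has amplitude `base_depth - ddg_k`
#' @param wells data.frame with columns `d`, `phi` (degrees), `ddg`
#'   (kcal/mol relative depth), `sigma_d` (A), `sigma_phi` (degrees);
#'   default: the preset's four wells
#' @param walls list `(lower, upper, k, power)` for the one-sided walls on d
#' @param temperature Kelvin (default 300; kT = 0.5925 kcal/mol)
#' @param k_intra,intra_cutoff intra-domain elastic network stiffness
#'   (kcal/mol/A^2) and cutoff (A)
#' @param k_link linker COM-COM bond stiffness (kcal/mol/A^2)
#' @param compensate include the chain-entropy compensation term (default
#'   TRUE)
#' @return object of class `pincer_model`; its `$reference` element is the
#'   bead structure at the deepest well's CV values
#' @export
build_pincer <- function(preset = "abna-landscape",
                         beads_per_domain = 20, bead_mass = 25,
                         bead_radius = 3, domain_radius = 10, arm = 46,
                         base_depth = 9, wells = NULL,
                         walls = list(lower = 41, upper = 75, k = 0.36, power = 2),
                         temperature = 300,
                         k_intra = 10, intra_cutoff = 12, k_link = 5,
                         compensate = TRUE) {
  stopifnot(preset == "abna-landscape")
  if (is.null(wells))
    wells <- data.frame(
      name = c("EM1", "EM2", "EM3", "EM4"),
      d = c(55, 50, 67, 74),
      phi = c(-63, 27, -63, 45),
      ddg = c(0, 1.2, 2.5, 8.2),
      sigma_d = 2.5, sigma_phi = 18,
      stringsAsFactors = FALSE)
  wells$A <- base_depth - wells$ddg
  if (any(wells$A <= 0))
    stop("base_depth must exceed the largest relative depth", call. = FALSE)
  wells <- wells[order(-wells$A), , drop = FALSE]   # deepest first
  rownames(wells) <- NULL
  if (any(wells$d < walls$lower | wells$d > walls$upper))
    warning("well center(s) outside the wall bounds", call. = FALSE)
  kT <- .kB * temperature
  n_dom <- 4L
  cloud <- .domain_cloud(beads_per_domain, domain_radius)
  # reference conformation at the deepest well
  coms <- .chain_coms(arm, wells$d[1], wells$phi[1] * pi / 180)
  beads <- do.call(rbind, lapply(seq_len(n_dom), function(k)
    data.frame(name = "BB", element = "C", mass = bead_mass,
               resno = (k - 1) * beads_per_domain + seq_len(beads_per_domain),
               chain = "A", occ = 1,
               x = cloud[, 1] + coms[k, 1],
               y = cloud[, 2] + coms[k, 2],
               z = cloud[, 3] + coms[k, 3],
               radius = bead_radius, stringsAsFactors = FALSE)))
  reference <- new_structure(beads)
  partition <- domain_partition(
    first = (seq_len(n_dom) - 1) * beads_per_domain + 1,
    last = seq_len(n_dom) * beads_per_domain)
  # intra-domain elastic network from the cloud template
  d2 <- as.matrix(dist(cloud))
  pr <- which(upper.tri(d2) & d2 > 0 & d2 <= intra_cutoff, arr.ind = TRUE)
  bonds <- do.call(rbind, lapply(seq_len(n_dom), function(k) {
    off <- (k - 1) * beads_per_domain
    cbind(i = pr[, 1] + off, j = pr[, 2] + off,
          r0 = d2[pr], k = k_intra)
  }))
  comp <- if (compensate) .chain_entropy_table(arm, kT) else NULL
  structure(list(
    preset = preset, n_domains = n_dom, beads_per_domain = beads_per_domain,
    bead_mass = bead_mass, bead_radius = bead_radius,
    domain_radius = domain_radius, arm = arm,
    wells = wells, base_depth = base_depth, walls = walls,
    temperature = temperature, kT = kT,
    k_intra = k_intra, k_link = k_link,
    bonds = bonds, reference = reference, partition = partition,
    comp = comp), class = "pincer_model")
}

#' @export
print.pincer_model <- function(x, ...) {
  cat(sprintf("<pincer_model> %d domains x %d beads, arm %.0f A, kT = %.4f kcal/mol\n",
              x$n_domains, x$beads_per_domain, x$arm, x$kT))
  cat("wells (deepest first):\n")
  print(x$wells[, c("name", "d", "phi", "ddg", "A", "sigma_d", "sigma_phi")])
  invisible(x)
}

# Configurational entropy of the three-arm linker chain over (d, phi).
# The chain's internal measure is flat in (cos th1, cos th2, phi); phi is
# itself the second collective variable, so the entropy depends on d only
# through the conditional density of d given phi.  Tabulated by quadrature
# on a (d, phi) grid; the compensation potential is +kT log P0(d | phi).
.chain_entropy_table <- function(arm, kT, d_range = c(36, 86),
                                 nd = 101, nphi = 61, ngrid = 481) {
  cth <- seq(-1 + 1e-6, 1 - 1e-6, length.out = ngrid)
  s <- sqrt(1 - cth^2)
  d_grid <- seq(d_range[1], d_range[2], length.out = nd)
  dd <- d_grid[2] - d_grid[1]
  phi_grid <- seq(-pi, pi, length.out = nphi)
  V <- matrix(NA_real_, nd, nphi)
  c1 <- matrix(cth, ngrid, ngrid)
  c2 <- t(c1)
  s1 <- matrix(s, ngrid, ngrid)
  s2 <- t(s1)
  for (j in seq_len(nphi)) {
    cp <- cos(phi_grid[j])
    D <- arm * sqrt((c1 + c2 - 1)^2 + s1^2 + s2^2 - 2 * s1 * s2 * cp)
    idx <- findInterval(D, d_grid - dd / 2)
    idx[D > d_grid[nd] + dd / 2] <- 0L    # beyond the tabulated range
    h <- tabulate(idx, nbins = nd)
    # light smoothing against quadrature graininess
    hs <- stats::filter(h, rep(1 / 5, 5), sides = 2)
    hs[is.na(hs)] <- h[is.na(hs)]
    V[, j] <- ifelse(hs > 0, kT * log(hs), NA)
  }
  # unreachable (d, phi) cells: repulsive shelf above the largest finite value
  shelf <- max(V, na.rm = TRUE) + 4 * kT
  V[is.na(V)] <- shelf
  V <- V - min(V)
  dVd <- V * 0; dVp <- V * 0
  dVd[2:(nd - 1), ] <- (V[3:nd, ] - V[1:(nd - 2), ]) / (2 * dd)
  dp <- phi_grid[2] - phi_grid[1]
  dVp[, 2:(nphi - 1)] <- (V[, 3:nphi] - V[, 1:(nphi - 2)]) / (2 * dp)
  list(d_grid = d_grid, phi_grid = phi_grid, V = V, dVd = dVd, dVphi = dVp)
}

# Bilinear lookup into a compensation/bias-style table (phi periodic).
.table_lookup <- function(tab, d, phi, what = "V") {
  M <- tab[[what]]
  nd <- length(tab$d_grid); np <- length(tab$phi_grid)
  fd <- (d - tab$d_grid[1]) / (tab$d_grid[2] - tab$d_grid[1])
  fd <- pmin(pmax(fd, 0), nd - 1 - 1e-9)
  id <- floor(fd); wd <- fd - id
  fp <- (.wrap(phi) - tab$phi_grid[1]) / (tab$phi_grid[2] - tab$phi_grid[1])
  fp <- pmin(pmax(fp, 0), np - 1 - 1e-9)
  ip <- floor(fp); wp <- fp - ip
  i1 <- cbind(id + 1, ip + 1); i2 <- cbind(id + 2, ip + 1)
  i3 <- cbind(id + 1, ip + 2); i4 <- cbind(id + 2, ip + 2)
  (1 - wd) * (1 - wp) * M[i1] + wd * (1 - wp) * M[i2] +
    (1 - wd) * wp * M[i3] + wd * wp * M[i4]
}

#' Evaluate the model's CV-space potential and gradient
#'
#' Components: the Gaussian wells (analytic), the one-sided restraining
#' walls on d (analytic), and the chain-entropy compensation (tabulated).
#' Vectorised over (d, phi).
#'
#' @param model a [build_pincer()] model
#' @param d,phi collective variables (Angstrom, degrees)
#' @param terms character subset of `c("wells", "walls", "comp")`
#' @return list with `energy` (kcal/mol) and `dU_dd`, `dU_dphi`
#'   (kcal/mol/A, kcal/mol/degree) vectors
#' @export
pincer_cv_potential <- function(model, d, phi,
                                terms = c("wells", "walls", "comp")) {
  phi_rad <- phi * pi / 180
  U <- numeric(length(d)); gd <- numeric(length(d)); gp <- numeric(length(d))
  if ("wells" %in% terms) {
    w <- model$wells
    for (k in seq_len(nrow(w))) {
      sp <- w$sigma_phi[k] * pi / 180
      dd <- d - w$d[k]
      dp <- .wrap(phi_rad - w$phi[k] * pi / 180)
      e <- -w$A[k] * exp(-dd^2 / (2 * w$sigma_d[k]^2) - dp^2 / (2 * sp^2))
      U <- U + e
      gd <- gd + e * (-dd / w$sigma_d[k]^2)
      gp <- gp + e * (-dp / sp^2)
    }
  }
  if ("walls" %in% terms && !is.null(model$walls)) {
    wl <- model$walls
    lo <- pmax(0, wl$lower - d)
    hi <- pmax(0, d - wl$upper)
    U <- U + wl$k * (lo^wl$power + hi^wl$power)
    gd <- gd - wl$k * wl$power * lo^(wl$power - 1) +
      wl$k * wl$power * hi^(wl$power - 1)
  }
  if ("comp" %in% terms && !is.null(model$comp)) {
    U <- U + .table_lookup(model$comp, d, phi_rad, "V")
    gd <- gd + .table_lookup(model$comp, d, phi_rad, "dVd")
    gp <- gp + .table_lookup(model$comp, d, phi_rad, "dVphi")
  }
  list(energy = U, dU_dd = gd, dU_dphi = gp * pi / 180)
}

#' Build a bead structure at given collective-variable values
#'
#' Domain clouds are rigidly placed on the symmetric-bend linker chain that
#' realises (d, phi); the returned structure satisfies
#' `cv_pair(s, model$partition) == (d, phi)` up to numerical precision.
#'
#' @param model a [build_pincer()] model
#' @param d,phi target collective variables (Angstrom, degrees)
#' @return a `pincer_structure`
#' @export
conformer_structure <- function(model, d, phi) {
  coms <- .chain_coms(model$arm, d, phi * pi / 180)
  s <- model$reference
  npb <- model$beads_per_domain
  xyz <- coords(s)
  ref_coms <- vapply(seq_len(model$n_domains), function(k) {
    colMeans(xyz[(k - 1) * npb + seq_len(npb), , drop = FALSE])
  }, numeric(3))
  for (k in seq_len(model$n_domains)) {
    ii <- (k - 1) * npb + seq_len(npb)
    xyz[ii, ] <- sweep(xyz[ii, , drop = FALSE], 2, ref_coms[, k]) |>
      sweep(2, coms[k, ], `+`)
  }
  coords(s) <- xyz
  s
}

#' Generate a labelled conformational ensemble
#'
#' Draws states multinomially from the model's wells with the given
#' population weights, builds each drawn conformer at its well's CV values
#' and perturbs bead coordinates with isotropic Gaussian jitter.
#'
#' @param model a [build_pincer()] model
#' @param state_weights population weights over the wells (simplex)
#' @param n ensemble size
#' @param seed RNG seed (all randomness flows from it)
#' @param jitter per-coordinate Gaussian jitter, Angstrom (default 0.5)
#' @return list with `structures` (length n), `labels` (well row indices),
#'   `weights`
#' @export
generate_ensemble <- function(model, state_weights, n, seed, jitter = 0.5) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(state_weights < 0) || abs(sum(state_weights) - 1) > 1e-9)
    stop("state weights must lie on the simplex", call. = FALSE)
  set.seed(seed)
  labels <- sample.int(length(state_weights), n, replace = TRUE,
                       prob = state_weights)
  templates <- lapply(seq_len(nrow(model$wells)), function(k)
    conformer_structure(model, model$wells$d[k], model$wells$phi[k]))
  structures <- lapply(labels, function(l) {
    s <- templates[[l]]
    xyz <- coords(s) + matrix(rnorm(3 * nrow(s), sd = jitter), ncol = 3)
    coords(s) <- xyz
    s
  })
  list(structures = structures, labels = labels, weights = state_weights)
}

#' Define a conformer mixture with a noise model
#'
#' @param structures list of conformer structures
#' @param weights population weights (simplex)
#' @param noise_a,noise_b noise model `sigma(q) = a * I(q) + b` (default 1%
#'   relative, no floor)
#' @return object of class `mixture_spec`
#' @export
mixture_spec <- function(structures, weights, noise_a = 0.01, noise_b = 0) {
  if (length(structures) != length(weights)) stop("length mismatch", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must lie on the simplex", call. = FALSE)
  structure(list(structures = structures, weights = weights,
                 noise_a = noise_a, noise_b = noise_b),
            class = "mixture_spec")
}

#' Synthesise a noisy SAXS experiment from a conformer mixture
#'
#' Computes each conformer's Debye profile, mixes them with the population
#' weights, adds Gaussian noise `N(0, sigma(q))` with
#' `sigma(q) = a I(q) + b`, and records the sigma column, emulating an
#' azimuthally averaged, buffer-subtracted synchrotron measurement.
#'
#' @param mix a [mixture_spec()]
#' @param q_grid scattering vectors
#' @param seed RNG seed
#' @param bead_radius,hydration_pad passed to [debye_profile()]
#' @return a [saxs_profile()] with sigma, plus attribute
#'   `"component_profiles"` (the noiseless per-state profiles)
#' @export
synthetic_saxs_experiment <- function(mix, q_grid = default_q_grid(), seed = 1,
                                      bead_radius = NULL, hydration_pad = 0) {
  stopifnot(inherits(mix, "mixture_spec"))
  comps <- lapply(mix$structures, debye_profile, q_grid = q_grid,
                  bead_radius = bead_radius, hydration_pad = hydration_pad)
  I <- Reduce(`+`, Map(function(p, w) w * p$I, comps, mix$weights))
  sigma <- mix$noise_a * I + mix$noise_b
  set.seed(seed)
  noisy <- I + if (all(sigma == 0)) 0 else rnorm(length(I), sd = sigma)
  out <- saxs_profile(q_grid, noisy,
                      sigma = if (all(sigma == 0)) NULL else sigma)
  attr(out, "component_profiles") <- comps
  out
}
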