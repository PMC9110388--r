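# Langevin dynamics and metadynamics on the coarse-grained pincer model:
# BAOAB integration (C++ core), Gaussian bias deposition on the two
# collective variables with restraining walls, free-energy-surface
# reconstruction from the deposited bias, convergence diagnostics, and
# microstate binning of the sampled CV space.

.model_sim_args <- function(model, include_cv = TRUE) {
  s <- model$reference
  dom <- integer(nrow(s))
  for (k in seq_len(nrow(model$partition)))
    dom[s$resno >= model$partition$first[k] &
          s$resno <= model$partition$last[k]] <- k
  wells <- if (include_cv) {
    w <- model$wells
    cbind(w$d, w$phi * pi / 180, w$A, w$sigma_d, w$sigma_phi * pi / 180)
  } else matrix(0, 0, 5)
  list(x0 = coords(s), mass = s$mass, dom = dom,
       bonds = model$bonds, arm = model$arm, k_link = model$k_link,
       wells = wells,
       walls = if (include_cv && !is.null(model$walls)) model$walls else list(),
       comp = if (include_cv && !is.null(model$comp)) model$comp else list())
}

.check_dt <- function(model, dt) {
  kmax <- max(c(model$bonds[, 4], model$k_link))
  period <- 2 * pi * sqrt(min(model$reference$mass) / (2 * kmax))
  if (dt > period / 10)
    warning(sprintf("dt = %.3g exceeds 1/10 of the stiffest bond period (%.3g); integration may be unstable",
                    dt, period), call. = FALSE)
}

.new_traj <- function(res, model, dt, seed) {
  cv <- res$cv
  structure(list(
    time = cv[, 1], d = cv[, 2], phi = cv[, 3] * 180 / pi,
    frames = if (nrow(res$frames) > 0) res$frames else NULL,
    frame_step = res$frame_step,
    x_final = res$x_final, v_final = res$v_final,
    n_steps = res$n_steps, dt = dt, seed = seed, model = model),
    class = "pincer_traj")
}

#' @export
print.pincer_traj <- function(x, ...) {
  cat(sprintf("<pincer_traj> %d steps (dt = %.3g), %d CV samples, %d stored frames\n",
              x$n_steps, x$dt, length(x$time),
              if (is.null(x$frames)) 0L else nrow(x$frames)))
  cat(sprintf("  d in [%.1f, %.1f] A, phi in [%.1f, %.1f] deg\n",
              min(x$d), max(x$d), min(x$phi), max(x$phi)))
  invisible(x)
}

#' @export
plot.pincer_traj <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$d, type = "l", xlab = "time", ylab = "d (A)", ...)
  plot(x$time, x$phi, type = "l", xlab = "time", ylab = "phi (deg)", ...)
  invisible(x)
}

#' Unbiased Langevin dynamics on a pincer model
#'
#' BAOAB-split Langevin integration of the bead model under its full
#' potential (intra-domain network, linker bonds, CV-space wells, walls and
#' entropy compensation).  Deterministic for a fixed seed.
#'
#' @param model a [build_pincer()] model
#' @param n_steps number of steps
#' @param dt time step in internal units (sqrt(Da A^2 / kcal/mol) ~ 48.9 fs;
#'   default 0.5, roughly a 25 fs-equivalent coarse-grained step)
#' @param temperature Kelvin (default: the model's)
#' @param friction Langevin friction, 1/time-unit (default 0.02, weak
#'   coupling so inter-domain diffusion is fast)
#' @param seed integer seed; all stochastic force realisations flow from it
#' @param cv_stride record the collective variables every this many steps
#' @param frame_stride record full coordinates every this many steps
#'   (0 = never)
#' @param start optional structure to start from (default: the model
#'   reference)
#' @param include_cv include the CV-space potential terms (wells, walls,
#'   compensation); set FALSE for a plain elastic chain
#' @return object of class `pincer_traj`
#' @export
langevin_run <- function(model, n_steps, dt = 0.5, temperature = model$temperature,
                         friction = 0.02, seed = 1, cv_stride = 50,
                         frame_stride = 0, start = NULL, include_cv = TRUE) {
  .check_dt(model, dt)
  a <- .model_sim_args(model, include_cv)
  if (!is.null(start)) a$x0 <- if (is.matrix(start)) start else coords(start)
  res <- .run_cg_dynamics(a$x0, a$mass, a$dom, a$bonds, a$arm, a$k_link,
                          a$wells, a$walls, a$comp,
                          list(enabled = FALSE), as.integer(n_steps), dt,
                          .kB * temperature, friction, as.numeric(seed),
                          as.integer(cv_stride), as.integer(frame_stride))
  .new_traj(res, model, dt, seed)
}

#' Metadynamics bias parameters
#'
#' Gaussian hills of fixed height deposited along (d, phi) at a fixed
#' stride, accumulated on a grid.  The all-atom reference protocol for this
#' landscape used hills of height 0.289 kcal/mol and widths 0.2 A / 0.07 rad
#' every 20 ps; the defaults here keep that height but widen the hills and
#' shorten the stride to match the coarse-grained model's diffusion scale
#' (see the methods vignette).
#'
#' @param height hill height, kcal/mol (default 0.289)
#' @param sigma_d hill width along d, Angstrom (default 1.2)
#' @param sigma_phi hill width along phi, radians (default 0.15)
#' @param stride deposition stride in steps (default 100)
#' @param grid_dmin,grid_dmax,grid_nd,grid_nphi bias-grid extent and
#'   resolution
#' @return list of bias parameters
#' @export
bias_params <- function(height = 0.289, sigma_d = 1.2, sigma_phi = 0.15,
                        stride = 100, grid_dmin = 33, grid_dmax = 88,
                        grid_nd = 276, grid_nphi = 180) {
  stopifnot(height >= 0, sigma_d > 0, sigma_phi > 0, stride >= 1)
  list(height = height, sigma_d = sigma_d, sigma_phi = sigma_phi,
       stride = as.integer(stride), grid_dmin = grid_dmin,
       grid_dmax = grid_dmax, grid_nd = as.integer(grid_nd),
       grid_nphi = as.integer(grid_nphi))
}

#' Metadynamics run on a pincer model
#'
#' Langevin dynamics with a history-dependent repulsive bias: every
#' `stride` steps a Gaussian hill is deposited at the current (d, phi) and
#' its force is added to the physical force; phi hills are periodic;
#' restraining walls act as one-sided polynomial potentials
#' `k (x - x0)^p` beyond the bounds.
#'
#' @inheritParams langevin_run
#' @param bias a [bias_params()] list
#' @return list with elements `traj` (a `pincer_traj`) and `bias` (a
#'   `bias_state`: the deposited hills, the walls and the accumulated bias
#'   grid)
#' @export
metad_run <- function(model, n_steps, bias = bias_params(), dt = 0.5,
                      temperature = model$temperature, friction = 0.02,
                      seed = 1, cv_stride = 50, frame_stride = 0,
                      start = NULL) {
  .check_dt(model, dt)
  a <- .model_sim_args(model, include_cv = TRUE)
  if (!is.null(start)) a$x0 <- if (is.matrix(start)) start else coords(start)
  metad <- c(list(enabled = TRUE), bias)
  res <- .run_cg_dynamics(a$x0, a$mass, a$dom, a$bonds, a$arm, a$k_link,
                          a$wells, a$walls, a$comp, metad,
                          as.integer(n_steps), dt, .kB * temperature,
                          friction, as.numeric(seed),
                          as.integer(cv_stride), as.integer(frame_stride))
  traj <- .new_traj(res, model, dt, seed)
  hills <- as.data.frame(res$hills)
  names(hills) <- c("t", "d", "phi", "sigma_d", "sigma_phi", "height")
  bias_state <- structure(list(hills = hills, params = bias,
                               walls = model$walls, grid = res$bias_grid),
                          class = "bias_state")
  # warn if the CVs strayed far outside the grid+walls region
  if (nrow(hills) && (max(traj$d) > bias$grid_dmax + 3 * bias$sigma_d ||
                      min(traj$d) < bias$grid_dmin - 3 * bias$sigma_d))
    warning("CV1 left the bias grid by more than 3 hill widths", call. = FALSE)
  list(traj = traj, bias = bias_state)
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("<bias_state> %d hills (height %.3f kcal/mol, widths %.2f A / %.3f rad)\n",
              nrow(x$hills), x$params$height, x$params$sigma_d, x$params$sigma_phi))
  if (!is.null(x$walls))
    cat(sprintf("  walls on d at [%.0f, %.0f] A (k = %.2f, p = %d)\n",
                x$walls$lower, x$walls$upper, x$walls$k, x$walls$power))
  invisible(x)
}

#' Write / read a deposited-hills table (5+1 column text)
#' @param bias a `bias_state` (or its hills data.frame)
#' @param path file path
#' @return invisibly, `path`
#' @export
write_hills <- function(bias, path) {
  hills <- if (inherits(bias, "bias_state")) bias$hills else bias
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# t  d(A)  phi(rad)  sigma_d  sigma_phi  height", con)
  write.table(format(hills, digits = 9), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  tab <- read.table(path, comment.char = "#")
  names(tab) <- c("t", "d", "phi", "sigma_d", "sigma_phi", "height")
  tab
}

# Sum of deposited Gaussians on a (d, phi) grid, exploiting separability:
# V = (Ed scaled by heights) %*% t(Ephi).
.bias_on_grid <- function(hills, d_centers, phi_centers_rad) {
  if (!nrow(hills)) return(matrix(0, length(d_centers), length(phi_centers_rad)))
  Ed <- exp(-outer(d_centers, hills$d, `-`)^2 /
              matrix(2 * hills$sigma_d^2, length(d_centers), nrow(hills),
                     byrow = TRUE))
  dphi <- .wrap(outer(phi_centers_rad, hills$phi, `-`))
  Ep <- exp(-dphi^2 / matrix(2 * hills$sigma_phi^2, length(phi_centers_rad),
                             nrow(hills), byrow = TRUE))
  (Ed * matrix(hills$height, length(d_centers), nrow(hills), byrow = TRUE)) %*%
    t(Ep)
}

#' Free-energy surface from the deposited metadynamics bias
#'
#' In standard (fixed-height) metadynamics the negative of the accumulated
#' bias estimates the free energy up to a constant.  To damp the
#' late-stage oscillation of the estimator, the surface is averaged over
#' several checkpoints spanning the final fraction of the deposition
#' history, then shifted so its minimum is 0.  Bins that received
#' essentially no bias (more than ~3 hill widths from every hill) are
#' flagged unset (NA), not zero.
#'
#' @param bias a `bias_state` from [metad_run()] (or a hills data.frame)
#' @param n_bins_d,n_bins_phi grid resolution (default 96 x 72 for plotting;
#'   use 20 x 20 for microstate-style tables)
#' @param d_range range of d covered (default: the bias grid extent)
#' @param time_average_fraction average the estimator over checkpoints in
#'   this final fraction of the deposition history (default 0.6; 0 disables
#'   averaging and uses the final bias only)
#' @param n_checkpoints number of checkpoints in the averaging window
#' @return object of class `pincer_fes`: list with `d` (bin centers),
#'   `phi` (bin centers, degrees), `F` (kcal/mol matrix, min 0, NA where
#'   unset), `visited`, `counts` (hill counts per bin), `checkpoints`
#' @export
fes_from_bias <- function(bias, n_bins_d = 96, n_bins_phi = 72,
                          d_range = NULL, time_average_fraction = 0.6,
                          n_checkpoints = 25) {
  hills <- if (inherits(bias, "bias_state")) bias$hills else bias
  if (!nrow(hills)) stop("empty bias: no deposited hills", call. = FALSE)
  if (is.null(d_range)) {
    d_range <- if (inherits(bias, "bias_state"))
      c(bias$params$grid_dmin, bias$params$grid_dmax)
    else range(hills$d) + c(-3, 3) * hills$sigma_d[1]
  }
  dc <- seq(d_range[1], d_range[2], length.out = n_bins_d + 1)
  dc <- (dc[-1] + dc[-length(dc)]) / 2
  pc <- seq(-pi, pi, length.out = n_bins_phi + 1)
  pc <- (pc[-1] + pc[-length(pc)]) / 2
  m <- nrow(hills)
  if (time_average_fraction <= 0) {
    cps <- m
  } else {
    cps <- unique(round(seq(m * (1 - time_average_fraction), m,
                            length.out = n_checkpoints)))
    cps <- cps[cps >= 1]
  }
  Vsum <- matrix(0, length(dc), length(pc))
  prev <- 0
  Vcur <- matrix(0, length(dc), length(pc))
  Facc <- matrix(0, length(dc), length(pc))
  for (cp in sort(cps)) {
    if (cp > prev)
      Vcur <- Vcur + .bias_on_grid(hills[(prev + 1):cp, , drop = FALSE], dc, pc)
    prev <- cp
    Facc <- Facc + (-Vcur)
  }
  FF <- Facc / length(cps)
  Vfull <- if (prev == m) Vcur else
    Vcur + .bias_on_grid(hills[(prev + 1):m, , drop = FALSE], dc, pc)
  visited <- Vfull > max(hills$height) / 2
  FF[!visited] <- NA
  FF <- FF - min(FF, na.rm = TRUE)
  # hill counts per bin (occupancy of the deposition trajectory)
  di <- findInterval(hills$d, seq(d_range[1], d_range[2],
                                  length.out = n_bins_d + 1),
                     rightmost.closed = TRUE)
  pi_ <- findInterval(hills$phi, seq(-pi, pi, length.out = n_bins_phi + 1),
                      rightmost.closed = TRUE)
  counts <- matrix(0L, length(dc), length(pc))
  ok <- di >= 1 & di <= n_bins_d
  for (r in which(ok)) counts[di[r], pi_[r]] <- counts[di[r], pi_[r]] + 1L
  structure(list(d = dc, phi = pc * 180 / pi, F = FF, visited = visited,
                 counts = counts, checkpoints = cps,
                 n_hills = m),
            class = "pincer_fes")
}

#' @export
print.pincer_fes <- function(x, ...) {
  cat(sprintf("<pincer_fes> %d x %d bins over d [%.1f, %.1f] A, phi (deg); %d/%d bins set\n",
              length(x$d), length(x$phi), min(x$d), max(x$d),
              sum(x$visited), length(x$visited)))
  cat(sprintf("  F range 0 - %.2f kcal/mol (from %d hills, %d checkpoints)\n",
              max(x$F, na.rm = TRUE), x$n_hills, length(x$checkpoints)))
  invisible(x)
}

#' @export
plot.pincer_fes <- function(x, levels = seq(0, 15, by = 1.4), ...) {
  FF <- x$F
  FF[is.na(FF)] <- max(FF, na.rm = TRUE)
  graphics::image(x$d, x$phi, FF, col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "d (A)", ylab = "phi (deg)",
                  main = "Free energy (kcal/mol)", ...)
  graphics::contour(x$d, x$phi, FF, levels = levels, add = TRUE,
                    drawlabels = FALSE)
  invisible(x)
}

#' Free energy at given CV points (bilinear off the FES grid)
#' @param fes a `pincer_fes`
#' @param d,phi query points (Angstrom, degrees)
#' @return kcal/mol (NA outside the set region)
#' @export
fes_lookup <- function(fes, d, phi) {
  tab <- list(d_grid = fes$d, phi_grid = fes$phi * pi / 180, V = fes$F)
  .table_lookup(tab, d, phi * pi / 180, "V")
}

#' Relative free energies of the landscape wells from a FES
#'
#' The free energy of a well is the minimum of the surface within `n_sigma`
#' well widths of the well center (`method = "min"`, the default; this is
#' the value a microstate table reports for the well bottom), or the basin
#' free energy `F_k = -kT log sum(exp(-F/kT))` over that neighbourhood
#' (`method = "basin"`, smoother under bin-level noise but biased low for
#' shallow wells by the basin-entropy term).  Values are reported relative
#' to the deepest well.
#'
#' @param fes a `pincer_fes`
#' @param wells data.frame with `d`, `phi` (deg) and widths `sigma_d`,
#'   `sigma_phi` (deg); e.g. `model$wells`
#' @param method `"min"` or `"basin"`
#' @param n_sigma neighbourhood half-width in units of the well widths
#' @param kT thermal energy for the basin integral (kcal/mol)
#' @return numeric vector of ddG values (kcal/mol), one per well row
#' @export
fes_well_ddg <- function(fes, wells, method = c("min", "basin"),
                         n_sigma = 1.5, kT = 0.5925) {
  method <- match.arg(method)
  vals <- vapply(seq_len(nrow(wells)), function(k) {
    seld <- abs(fes$d - wells$d[k]) <= max(n_sigma * wells$sigma_d[k],
                                           diff(fes$d[1:2]))
    selp <- abs(.wrap((fes$phi - wells$phi[k]) * pi / 180)) <=
      max(n_sigma * wells$sigma_phi[k] * pi / 180,
          diff(fes$phi[1:2]) * pi / 180)
    sub <- fes$F[seld, selp]
    if (all(is.na(sub))) return(NA_real_)
    if (method == "min") return(min(sub, na.rm = TRUE))
    -kT * log(sum(exp(-sub[!is.na(sub)] / kT)))
  }, 0.0)
  vals - min(vals, na.rm = TRUE)
}

#' Convergence diagnostics for a metadynamics run
#'
#' Reports (i) the CV range covered in consecutive quarters of the
#' trajectory and (ii) the maximum absolute change of the free-energy
#' estimate between successive late checkpoints of the deposition history,
#' compared against the requested tolerances (the reference protocol used
#' 5 kcal/mol, then 1.8 kcal/mol).
#'
#' @param traj a `pincer_traj`
#' @param bias the matching `bias_state`
#' @param equilibration_time discard CV samples (and hills) before this time
#' @param tolerances kcal/mol thresholds to flag convergence against
#' @param n_checkpoints number of late FES checkpoints (over the final half
#'   of the post-equilibration deposition history)
#' @param n_bins_d,n_bins_phi FES grid used for the diagnostic
#' @return object of class `metad_convergence`: list with `coverage`
#'   (per-quarter CV ranges), `delta_f` (successive checkpoint max |dF|),
#'   `max_delta_f`, `converged` (named logical per tolerance)
#' @export
convergence_report <- function(traj, bias, equilibration_time = 0,
                               tolerances = c(5, 1.8), n_checkpoints = 6,
                               n_bins_d = 48, n_bins_phi = 36) {
  if (equilibration_time >= max(traj$time))
    stop("equilibration time is not shorter than the run", call. = FALSE)
  keep <- traj$time > equilibration_time
  qs <- cut(traj$time[keep], 4, labels = FALSE)
  coverage <- do.call(rbind, lapply(1:4, function(qq) {
    sel <- qs == qq
    data.frame(quarter = qq,
               d_min = min(traj$d[keep][sel]), d_max = max(traj$d[keep][sel]),
               phi_min = min(traj$phi[keep][sel]),
               phi_max = max(traj$phi[keep][sel]))
  }))
  hills <- bias$hills
  late <- hills[hills$t > equilibration_time, , drop = FALSE]
  m <- nrow(late)
  dmn <- if (inherits(bias, "bias_state")) bias$params$grid_dmin else min(hills$d)
  dmx <- if (inherits(bias, "bias_state")) bias$params$grid_dmax else max(hills$d)
  dc <- seq(dmn, dmx, length.out = n_bins_d)
  pc <- seq(-pi, pi, length.out = n_bins_phi + 1)[-1] - pi / n_bins_phi
  delta <- numeric(0)
  if (m >= 1) {
    cps <- unique(round(seq(max(1, m / 2), m, length.out = n_checkpoints)))
    Vprev <- NULL
    Vcur <- matrix(0, length(dc), length(pc))
    prev <- 0
    # |dF| is compared on bins set in both checkpoints
    Vfull <- .bias_on_grid(late, dc, pc)
    mask <- Vfull > max(late$height) / 2
    for (cp in cps) {
      if (cp > prev)
        Vcur <- Vcur + .bias_on_grid(late[(prev + 1):cp, , drop = FALSE], dc, pc)
      prev <- cp
      Fcur <- -Vcur
      Fcur <- Fcur - min(Fcur[mask])
      if (!is.null(Vprev)) delta <- c(delta, max(abs(Fcur - Vprev)[mask]))
      Vprev <- Fcur
    }
  }
  mx <- if (length(delta)) max(delta) else 0
  structure(list(coverage = coverage, delta_f = delta, max_delta_f = mx,
                 converged = setNames(mx <= tolerances,
                                      paste0("tol_", tolerances)),
                 equilibration_time = equilibration_time),
            class = "metad_convergence")
}

#' @export
print.metad_convergence <- function(x, ...) {
  cat(sprintf("Metadynamics convergence (equilibration %.0f):\n", x$equilibration_time))
  cat(sprintf("  max |dF| between late checkpoints: %.3f kcal/mol\n", x$max_delta_f))
  for (nm in names(x$converged))
    cat(sprintf("  %s kcal/mol: %s\n", sub("tol_", "", nm),
                if (x$converged[[nm]]) "converged" else "NOT converged"))
  invisible(x)
}

#' Microstate table from a metadynamics trajectory
#'
#' Discretises the sampled CV space into `n_bins_per_cv` bins per CV; each
#' visited bin is a microstate with a relative free energy taken from the
#' FES at the bin center, a member list of post-equilibration CV samples,
#' and a representative frame (the member nearest the bin center in
#' bin-width-scaled CV units, among samples for which full coordinates were
#' stored).  A contiguity filter marks the 4-neighbour connected component
#' that contains the free-energy global minimum; relative free energies are
#' reported for that component.
#'
#' @param traj a `pincer_traj`
#' @param fes a `pincer_fes` for the same run
#' @param n_bins_per_cv bins per CV (default 20)
#' @param equilibration discard samples before this time
#' @return object of class `microstate_table`: data.frame with columns
#'   `id`, `d`, `phi`, `ddg`, `n_members`, `contiguous`,
#'   `representative` (row of the stored frame matrix, NA if none), plus
#'   attributes `members` (list of CV-sample indices) and `bins`
#' @export
bin_microstates <- function(traj, fes, n_bins_per_cv = 20, equilibration = 0) {
  keep <- which(traj$time > equilibration)
  if (!length(keep)) stop("no frames after equilibration", call. = FALSE)
  d <- traj$d[keep]; phi <- traj$phi[keep]
  # discretise over the FES extent (samples outside clamp to edge bins)
  db <- seq(min(fes$d), max(fes$d), length.out = n_bins_per_cv + 1)
  pb <- seq(-180, 180, length.out = n_bins_per_cv + 1)
  di <- pmin(pmax(findInterval(d, db, rightmost.closed = TRUE), 1), n_bins_per_cv)
  pi_ <- pmin(pmax(findInterval(phi, pb, rightmost.closed = TRUE), 1), n_bins_per_cv)
  bin <- (pi_ - 1) * n_bins_per_cv + di
  occupied <- sort(unique(bin))
  dc <- (db[-1] + db[-length(db)]) / 2
  pc <- (pb[-1] + pb[-length(pb)]) / 2
  id_d <- (occupied - 1) %% n_bins_per_cv + 1
  id_p <- (occupied - 1) %/% n_bins_per_cv + 1
  ddg_raw <- fes_lookup(fes, dc[id_d], pc[id_p])
  # map stored frames to CV samples via the step index
  frame_of_sample <- rep(NA_integer_, length(traj$time))
  if (!is.null(traj$frames)) {
    steps_cv <- round(traj$time / traj$dt)
    frame_of_sample[match(traj$frame_step, steps_cv)] <- seq_along(traj$frame_step)
  }
  members <- split(seq_along(bin), factor(bin, levels = occupied))
  dwidth <- diff(dc[1:2]); pwidth <- diff(pc[1:2])
  rep_frame <- vapply(seq_along(occupied), function(k) {
    mm <- members[[k]]
    fr <- frame_of_sample[keep[mm]]
    has <- !is.na(fr)
    if (!any(has)) return(NA_integer_)
    mm <- mm[has]
    dist2 <- ((d[mm] - dc[id_d[k]]) / dwidth)^2 +
      ((phi[mm] - pc[id_p[k]]) / pwidth)^2
    fr[has][which.min(dist2)]
  }, 0L)
  # contiguity: 4-neighbour component containing the global minimum
  grid_id <- matrix(0L, n_bins_per_cv, n_bins_per_cv)
  grid_id[cbind(id_d, id_p)] <- seq_along(occupied)
  start <- which.min(ddg_raw)
  in_comp <- logical(length(occupied))
  if (length(start) && is.finite(ddg_raw[start])) {
    qq <- start
    while (length(qq)) {
      k <- qq[1]; qq <- qq[-1]
      if (in_comp[k]) next
      in_comp[k] <- TRUE
      for (nb in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- id_d[k] + nb[1]; jj <- id_p[k] + nb[2]
        if (ii >= 1 && ii <= n_bins_per_cv && jj >= 1 && jj <= n_bins_per_cv &&
            grid_id[ii, jj] > 0 && !in_comp[grid_id[ii, jj]])
          qq <- c(qq, grid_id[ii, jj])
      }
    }
  }
  ddg <- ddg_raw
  ddg[in_comp] <- ddg_raw[in_comp] - min(ddg_raw[in_comp], na.rm = TRUE)
  tab <- data.frame(id = seq_along(occupied), d = dc[id_d], phi = pc[id_p],
                    ddg = ddg, n_members = lengths(members),
                    contiguous = in_comp, representative = rep_frame)
  structure(tab, class = c("microstate_table", "data.frame"),
            members = members, bins = list(d = db, phi = pb),
            n_frames = length(keep))
}

#' @export
print.microstate_table <- function(x, ...) {
  cat(sprintf("<microstate_table> %d microstates (%d in the contiguous component), %d frames\n",
              nrow(x), sum(x$contiguous), attr(x, "n_frames")))
  best <- x[order(x$ddg), ]
  print(utils::head(as.data.frame(best), 5))
  invisible(x)
}

#' Bead structure of a stored trajectory frame
#' @param traj a `pincer_traj` recorded with `frame_stride > 0`
#' @param frame frame row index (e.g. a microstate's `representative`)
#' @return a `pincer_structure`
#' @export
frame_structure <- function(traj, frame) {
  if (is.null(traj$frames)) stop("trajectory has no stored frames", call. = FALSE)
  s <- traj$model$reference
  xyz <- matrix(traj$frames[frame, ], ncol = 3, byrow = TRUE)
  coords(s) <- xyz
  s
}

#' Write a free-energy surface as a gridded text table
#'
#' One row per bin: d (Angstrom), phi (degrees), F (kcal/mol, NA for unset
#' bins), visited flag.
#'
#' @param fes a `pincer_fes`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fes <- function(fes, path) {
  grid <- expand.grid(d = fes$d, phi = fes$phi)
  grid$F <- as.vector(fes$F)
  grid$visited <- as.vector(fes$visited)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# d(A)  phi(deg)  F(kcal/mol)  visited", con)
  write.table(format(grid, digits = 7), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
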