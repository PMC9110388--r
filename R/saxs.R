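# Small-angle X-ray scattering: Debye profile computation, Guinier analysis,
# pair-distance distribution, Porod-Debye flexibility, chi fitting of a
# computed profile to an experimental one, and multi-state ensemble fitting
# with non-negative population weights.

#' Construct a SAXS profile
#'
#' @param q scattering vector, 1/Angstrom, strictly ascending
#' @param I intensity (arbitrary units)
#' @param sigma optional per-point uncertainty (> 0); present for
#'   experimental profiles, absent for computed ones
#' @return object of class `saxs_profile` (a data.frame)
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  stopifnot(length(q) == length(I))
  if (any(diff(q) <= 0)) stop("q must be strictly ascending", call. = FALSE)
  if (!all(is.finite(I))) stop("non-finite intensities", call. = FALSE)
  df <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
    df$sigma <- sigma
  }
  structure(df, class = c("saxs_profile", "data.frame"))
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, q in [%.4g, %.4g] 1/A%s\n",
              nrow(x), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Default BM29-like q grid: 0.005-0.45 1/Angstrom, 200 points
#' @param n number of points
#' @param qmin,qmax range in 1/Angstrom
#' @return numeric vector
#' @export
default_q_grid <- function(n = 200, qmin = 0.005, qmax = 0.45) {
  seq(qmin, qmax, length.out = n)
}

#' Read / write 3-column profile text (q, I, sigma; `#` comments)
#' @param path file path
#' @return a [saxs_profile()]
#' @export
read_saxs <- function(path) {
  tab <- read.table(path, comment.char = "#")
  saxs_profile(tab[[1]], tab[[2]],
               sigma = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' @rdname read_saxs
#' @param p profile to write
#' @export
write_saxs <- function(p, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# q(1/A)  I  sigma", con)
  tab <- if (is.null(p$sigma)) data.frame(p$q, p$I) else data.frame(p$q, p$I, p$sigma)
  write.table(format(tab, digits = 9, scientific = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-center scattering factors: electron counts by element, a constant, the
# structure's own f column (coarse-grained residue centers), or NULL for
# "f column if present, else constant 1".
.form_factors <- function(s, form_factor_model) {
  if (is.null(form_factor_model)) {
    if (!is.null(s$f)) return(s$f)
    return(rep(1, nrow(s)))
  }
  if (is.numeric(form_factor_model)) return(rep_len(form_factor_model, nrow(s)))
  switch(form_factor_model,
         electrons = .element_lookup(s$element, "electrons"),
         constant  = rep(1, nrow(s)),
         stop("unknown form_factor_model: ", form_factor_model, call. = FALSE))
}

# Normalised sphere form-factor amplitude 3(sin x - x cos x)/x^3.
.sphere_amplitude <- function(x) {
  out <- rep(1, length(x))
  nz <- x > 1e-4
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

#' Theoretical SAXS profile by the Debye formula
#'
#' `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij)/(q r_ij)`, with the q -> 0 limit
#' handled analytically (`I(0) = (sum f)^2`).  Scattering centers are the
#' structure's atoms or beads; structures above `max_centers` centers should
#' be reduced with [coarse_grain_residues()] first.
#'
#' @param s structure
#' @param q_grid scattering vectors (default [default_q_grid()])
#' @param form_factor_model `"electrons"` (per-atom electron counts, for
#'   atomic models), `"constant"`, or a numeric per-center value
#' @param bead_radius if non-NULL, every center is treated as a homogeneous
#'   sphere of this radius (Angstrom) and the profile is multiplied by the
#'   squared sphere form-factor amplitude; used for coarse-grained beads
#' @param hydration_pad added to `bead_radius` to mimic the ordered water
#'   layer (2-3 Angstrom) when comparing to experimental-scale sizes;
#'   default 0 (off)
#' @param max_centers guard against accidental all-atom Debye sums
#' @return a [saxs_profile()] (no sigma column)
#' @export
debye_profile <- function(s, q_grid = default_q_grid(),
                          form_factor_model = NULL,
                          bead_radius = NULL, hydration_pad = 0,
                          max_centers = 5000) {
  n <- nrow(s)
  if (n == 0) stop("empty structure", call. = FALSE)
  if (n > max_centers)
    stop(n, " centers exceeds max_centers = ", max_centers,
         "; coarse-grain per residue first", call. = FALSE)
  f <- .form_factors(s, form_factor_model)
  xyz <- coords(s)
  I <- numeric(length(q_grid))
  if (n == 1) {
    I[] <- f^2
  } else {
    d <- as.vector(dist(xyz))
    fw <- tcrossprod(f)
    w2 <- fw[lower.tri(fw)]
    sumf2 <- sum(f^2)
    for (k in seq_along(q_grid)) {
      x <- q_grid[k] * d
      sinc <- ifelse(x < 1e-8, 1, sin(x) / x)
      I[k] <- sumf2 + 2 * sum(w2 * sinc)
    }
  }
  if (!is.null(bead_radius)) {
    a <- bead_radius + hydration_pad
    I <- I * .sphere_amplitude(q_grid * a)^2
  }
  saxs_profile(q_grid, I)
}

#' Reduce an atomic structure to one scattering center per residue
#'
#' Each residue becomes a single center at its mass-weighted center of mass
#' with scattering factor equal to the residue's summed electron count.
#'
#' @param s atomic structure
#' @return a `pincer_structure` of residue centers with an `f` column
#' @export
coarse_grain_residues <- function(s) {
  key <- paste(s$chain, s$resno)
  idx <- split(seq_len(nrow(s)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(ii) {
    m <- s$mass[ii]
    el <- .element_lookup(s$element[ii], "electrons")
    data.frame(name = "RES", element = "C",
               mass = sum(m), resno = s$resno[ii[1]], chain = s$chain[ii[1]],
               occ = 1,
               x = sum(s$x[ii] * m) / sum(m),
               y = sum(s$y[ii] * m) / sum(m),
               z = sum(s$z[ii] * m) / sum(m),
               f = sum(el), stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows))
}

#' Guinier analysis of a SAXS profile
#'
#' Linear fit of `ln I` against `q^2` at low q, iterating the upper limit of
#' the fit window to the fixed point `q_max * Rg <= 1.3`; reports the radius
#' of gyration, the forward scattering, the adjusted R-squared of the fit
#' and a quality flag against the usual `adj R^2 > 0.995` rule.
#'
#' @param p a [saxs_profile()]
#' @param qrg_max Guinier validity limit (default 1.3)
#' @param r2_min adjusted R-squared acceptance threshold (default 0.995)
#' @param max_iter maximum range iterations
#' @return object of class `guinier_fit` with elements `Rg`, `I0`,
#'   `adj_r_squared`, `q_range`, `n_points`, `pass`, `iterations`
#' @export
guinier_fit <- function(p, qrg_max = 1.3, r2_min = 0.995, max_iter = 50) {
  stopifnot(inherits(p, "saxs_profile"))
  pos <- p$I > 0
  q <- p$q[pos]; I <- p$I[pos]
  if (length(q) < 5) stop("need >= 5 positive-intensity points", call. = FALSE)
  fit_window <- function(qmax) {
    sel <- q <= qmax
    if (sum(sel) < 5) sel <- seq_len(5)
    fm <- lm(log(I[sel]) ~ I(q[sel]^2))
    b <- coef(fm)
    # noiseless synthetic profiles fit exactly; silence lm's warning
    r2 <- suppressWarnings(summary(fm)$adj.r.squared)
    list(Rg = sqrt(max(0, -3 * b[2])), I0 = exp(b[1]),
         r2 = r2, n = sum(sel), qmax = max(q[sel]))
  }
  res <- fit_window(q[min(10, length(q))])
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (res$Rg <= 0) stop("Guinier iteration collapsed (non-positive Rg); ",
                          "trace: ", paste(signif(trace, 4), collapse = " "),
                          call. = FALSE)
    qmax_new <- qrg_max / res$Rg
    trace <- c(trace, res$Rg)
    res_new <- fit_window(qmax_new)
    if (abs(res_new$Rg - res$Rg) < 1e-6) { res <- res_new; break }
    res <- res_new
    if (it == max_iter)
      stop("Guinier range iteration did not converge; Rg trace: ",
           paste(signif(trace, 5), collapse = " "), call. = FALSE)
  }
  structure(list(Rg = unname(res$Rg), I0 = unname(res$I0),
                 adj_r_squared = res$r2,
                 q_range = c(min(q), res$qmax), n_points = res$n,
                 pass = res$r2 > r2_min, iterations = it),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I(0) = %.4g (%d pts, q <= %.4g, qRg <= %.2f)\n",
              x$Rg, x$I0, x$n_points, x$q_range[2], x$q_range[2] * x$Rg))
  cat(sprintf("  adj R^2 = %.4f (%s the > 0.995 aggregation/quality rule)\n",
              x$adj_r_squared, if (x$pass) "passes" else "FAILS"))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) c(Rg = object$Rg, I0 = object$I0)

#' @export
plot.guinier_fit <- function(x, p = NULL, ...) {
  if (is.null(p)) stop("supply the profile the fit was made from", call. = FALSE)
  sel <- p$q <= 1.5 * x$q_range[2] & p$I > 0
  plot(p$q[sel]^2, log(p$I[sel]), xlab = expression(q^2), ylab = "ln I",
       main = "Guinier plot", ...)
  abline(log(x$I0), -x$Rg^2 / 3, col = 2)
  abline(v = x$q_range[2]^2, lty = 2)
  invisible(x)
}

#' Pair-distance distribution from a structure
#'
#' Scattering-weighted histogram of intramolecular distances, normalised to
#' unit area.  This is the real-space P(r) of the model, not a regularised
#' inverse transform of experimental data.
#'
#' @param s structure
#' @param bin_width histogram bin width in Angstrom
#' @param form_factor_model as in [debye_profile()]
#' @return object of class `pr_dist`: data.frame (`r`, `p`) with attributes
#'   `Dmax` (maximum distance) and `mode` (bin center of the maximum)
#' @export
pr_from_structure <- function(s, bin_width = 1, form_factor_model = NULL) {
  if (nrow(s) < 2) stop("need >= 2 centers", call. = FALSE)
  f <- .form_factors(s, form_factor_model)
  d <- as.vector(dist(coords(s)))
  fw <- tcrossprod(f)
  w <- fw[lower.tri(fw)]
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1),
              function(b) sum(w[bin == b]), 0.0)
  p <- p / (sum(p) * bin_width)
  r <- breaks[-length(breaks)] + bin_width / 2
  structure(data.frame(r = r, p = p),
            class = c("pr_dist", "data.frame"),
            Dmax = dmax, mode = r[which.max(p)])
}

#' @export
print.pr_dist <- function(x, ...) {
  cat(sprintf("P(r): %d bins, Dmax = %.1f A, most probable distance = %.1f A\n",
              nrow(x), attr(x, "Dmax"), attr(x, "mode")))
  invisible(x)
}

#' Porod-Debye flexibility analysis
#'
#' Plots `q^4 I` against `q^4`; a plateau in the high-q tail indicates a
#' compact rigid particle, its absence indicates flexibility.  The plateau
#' index is the magnitude of the relative change of `q^4 I` across the tail
#' (|slope| times the tail's `q^4` span, normalised by the mean `q^4 I`):
#' near 0 for an ideal Porod scatterer, larger for flexible particles.
#'
#' @param p a [saxs_profile()]
#' @param tail_fraction fraction of (ascending-q) points treated as the tail
#'   (default 1/3)
#' @return list with `curve` (data.frame `q4`, `q4I`), `plateau_index`
#' @export
porod_debye <- function(p, tail_fraction = 1 / 3) {
  n <- nrow(p)
  tail_idx <- seq.int(ceiling(n * (1 - tail_fraction)) + 1, n)
  if (length(tail_idx) < 10) stop("tail has < 10 points", call. = FALSE)
  x <- p$q^4
  y <- p$q^4 * p$I
  fm <- lm(y[tail_idx] ~ x[tail_idx])
  slope <- coef(fm)[2]
  idx <- abs(slope) * diff(range(x[tail_idx])) / mean(y[tail_idx])
  list(curve = data.frame(q4 = x, q4I = y),
       plateau_index = unname(idx))
}

#' Chi fit of a computed profile against an experimental one
#'
#' The computed curve is linearly interpolated onto the experimental grid
#' (out-of-range points dropped, never extrapolated), the optimal scale is
#' `c = sum(Ie Ic / s^2) / sum(Ic^2 / s^2)`, and
#' `chi = sqrt(mean(((Ie - c Ic)/s)^2))`.
#'
#' @param exp experimental [saxs_profile()] (with sigma)
#' @param calc computed profile
#' @param min_overlap minimum fraction of experimental points covered
#' @return list with `c` (scale), `chi`, `fitted` (profile on the shared
#'   grid), `n`
#' @export
chi_fit <- function(exp, calc, min_overlap = 0.8) {
  sig <- exp$sigma
  if (is.null(sig)) sig <- rep(1, nrow(exp))
  inside <- exp$q >= min(calc$q) & exp$q <= max(calc$q)
  if (mean(inside) < min_overlap)
    stop("q-grid overlap below ", min_overlap * 100, "%", call. = FALSE)
  Ic <- approx(calc$q, calc$I, xout = exp$q[inside])$y
  Ie <- exp$I[inside]; s <- sig[inside]
  cc <- sum(Ie * Ic / s^2) / sum(Ic^2 / s^2)
  chi <- sqrt(mean(((Ie - cc * Ic) / s)^2))
  list(c = cc, chi = chi,
       fitted = saxs_profile(exp$q[inside], cc * Ic),
       n = sum(inside))
}

#' Multi-state ensemble fit of a SAXS profile
#'
#' For each number of states k up to `k_max`, enumerates candidate subsets
#' and solves, for each, a non-negative least-squares problem for the state
#' populations (the overall scale `c` absorbs the intensity normalisation,
#' and the weights are reported on the simplex).  Models are ranked by chi.
#' This is multi-state modelling in the spirit of ensemble SAXS fitting:
#' one experimental curve, a small pool of rigid conformers, non-negative
#' population weights.
#'
#' @param exp experimental [saxs_profile()] (sigma used if present)
#' @param candidates list of computed [saxs_profile()]s (the conformer pool)
#' @param k_max largest number of states to consider
#' @param max_enum enumeration bound on the number of subsets
#' @return object of class `multistate_fit`: list with `by_k` (best fit per
#'   k: `k`, `states`, `weights`, `c`, `chi`), `best` (lowest chi overall),
#'   `exp`, `candidate_matrix`
#' @export
multistate_fit <- function(exp, candidates, k_max = 3, max_enum = 20000) {
  ncand <- length(candidates)
  if (ncand < 1 || ncand > 20)
    stop("need 1-20 candidates (enumeration bound); pre-cluster larger pools",
         call. = FALSE)
  k_max <- min(k_max, ncand)
  sig <- exp$sigma
  if (is.null(sig)) sig <- rep(1, nrow(exp))
  Imat <- vapply(candidates, function(p) {
    inside <- exp$q >= min(p$q) & exp$q <= max(p$q)
    if (mean(inside) < 0.8) stop("candidate grid overlap below 80%", call. = FALSE)
    approx(p$q, p$I, xout = exp$q, rule = 1)$y
  }, numeric(nrow(exp)))
  keep <- rowSums(is.na(Imat)) == 0
  A_all <- Imat[keep, , drop = FALSE] / sig[keep]
  b <- exp$I[keep] / sig[keep]
  M <- sum(keep)
  by_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    subsets <- combn(ncand, k)
    if (ncol(subsets) > max_enum)
      stop("subset enumeration exceeds ", max_enum, call. = FALSE)
    best <- NULL
    for (j in seq_len(ncol(subsets))) {
      states <- subsets[, j]
      A <- A_all[, states, drop = FALSE]
      x <- if (k == 1) {
        max(0, sum(A * b) / sum(A * A))
      } else {
        pracma::lsqnonneg(A, b)$x
      }
      resid <- b - A %*% as.matrix(x)
      chi <- sqrt(sum(resid^2) / M)
      if (is.null(best) || chi < best$chi) {
        cs <- sum(x)
        best <- list(k = k, states = states,
                     weights = if (cs > 0) as.numeric(x) / cs else rep(NA_real_, k),
                     c = cs, chi = chi)
      }
    }
    by_k[[k]] <- best
  }
  chis <- vapply(by_k, `[[`, 0.0, "chi")
  structure(list(by_k = by_k, best = by_k[[which.min(chis)]],
                 exp = exp, candidate_matrix = Imat, sigma = sig),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat("Multi-state SAXS fit (non-negative weights, optimal scale):\n")
  for (f in x$by_k)
    cat(sprintf("  k = %d: states {%s}, weights %s, chi = %.4g\n",
                f$k, paste(f$states, collapse = ","),
                paste(sprintf("%.1f%%", 100 * f$weights), collapse = "/"),
                f$chi))
  cat(sprintf("Best: k = %d (chi = %.4g)\n", x$best$k, x$best$chi))
  invisible(x)
}

#' @export
summary.multistate_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$by_k, function(f)
    data.frame(k = f$k, states = paste(f$states, collapse = ","),
               weights = paste(sprintf("%.3f", f$weights), collapse = "/"),
               scale = f$c, chi = f$chi)))
  tab
}

#' @export
coef.multistate_fit <- function(object, ...) {
  setNames(object$best$weights, paste0("state", object$best$states))
}

#' @export
fitted.multistate_fit <- function(object, ...) {
  b <- object$best
  I <- object$candidate_matrix[, b$states, drop = FALSE] %*%
    (b$c * b$weights)
  saxs_profile(object$exp$q, as.numeric(I))
}

#' @export
residuals.multistate_fit <- function(object, ...) {
  (object$exp$I - fitted(object)$I) / object$sigma
}

#' @export
predict.multistate_fit <- function(object, k = NULL, ...) {
  b <- if (is.null(k)) object$best else object$by_k[[k]]
  I <- object$candidate_matrix[, b$states, drop = FALSE] %*% (b$c * b$weights)
  saxs_profile(object$exp$q, as.numeric(I))
}

#' @export
plot.multistate_fit <- function(x, ...) {
  plot(x$exp$q, x$exp$I, log = "y", pch = 16, cex = 0.4,
       xlab = "q (1/A)", ylab = "I(q)", main = "Multi-state fit", ...)
  graphics::lines(fitted(x)$q, fitted(x)$I, col = 2, lwd = 2)
  invisible(x)
}

#' Choose the number of states by relative chi improvement
#'
#' The smallest k is selected such that moving to k+1 states improves chi by
#' less than `improvement` (relative); parsimonious model selection for
#' nested multi-state fits whose chi is non-increasing in k.
#'
#' @param fit a [multistate_fit()] object
#' @param improvement relative chi-improvement threshold (default 0.05)
#' @return the selected `by_k` entry
#' @export
select_k <- function(fit, improvement = 0.05) {
  chis <- vapply(fit$by_k, `[[`, 0.0, "chi")
  k <- 1
  while (k < length(chis) && (chis[k] - chis[k + 1]) > improvement * chis[k])
    k <- k + 1
  fit$by_k[[k]]
}

#' Population-weighted mean radius of gyration
#'
#' Arithmetic weighted mean `sum(w_i Rg_i)` of per-state radii of gyration,
#' the number usually quoted when comparing a multi-state model with an
#' experimental Guinier Rg.
#'
#' @param rgs per-state Rg values (Angstrom)
#' @param weights population weights on the simplex (sum 1, non-negative)
#' @return weighted mean Rg (Angstrom)
#' @export
ensemble_rg <- function(rgs, weights) {
  if (length(rgs) != length(weights)) stop("length mismatch", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  sum(weights * rgs)
}
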