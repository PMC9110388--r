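# Langevin / metadynamics engine and free-energy analysis.

single_well_model <- function(...) {
  build_pincer(wells = data.frame(name = "W", d = 55, phi = -63, ddg = 0,
                                  sigma_d = 2.5, sigma_phi = 18),
               compensate = FALSE, ...)
}

test_that("zero-temperature dynamics at a potential minimum is stationary", {
  m <- single_well_model()
  start <- conformer_structure(m, 55, -63)
  tr <- langevin_run(m, 1000, temperature = 0, seed = 1, cv_stride = 100,
                     frame_stride = 1000)
  expect_lt(max(abs(tr$x_final - coords(start))), 1e-10)
  expect_equal(tr$d[length(tr$d)], 55, tolerance = 1e-10)
})

test_that("bonded fluctuations satisfy equipartition", {
  # linker bond length variance ~ kT / k_link for a stiff harmonic bond
  m <- cached_pincer()
  tr <- langevin_run(m, 3e5, seed = 2, frame_stride = 100, include_cv = FALSE)
  npb <- m$beads_per_domain
  r12 <- apply(tr$frames, 1, function(row) {
    x <- matrix(row, ncol = 3, byrow = TRUE)
    c1 <- colMeans(x[1:npb, ]); c2 <- colMeans(x[npb + 1:npb, ])
    sqrt(sum((c1 - c2)^2))
  })
  r12 <- r12[-(1:500)]                      # discard equilibration
  expect_equal(var(r12), m$kT / m$k_link, tolerance = 0.15)
  expect_equal(mean(r12), m$arm, tolerance = 0.02)
})

test_that("fixed seeds reproduce trajectories bit for bit", {
  m <- cached_pincer()
  a <- langevin_run(m, 2e4, seed = 31)
  b <- langevin_run(m, 2e4, seed = 31)
  expect_identical(a$d, b$d)
  expect_identical(a$x_final, b$x_final)
  c_ <- langevin_run(m, 2e4, seed = 32)
  expect_false(identical(a$d, c_$d))
})

test_that("zero-height hills leave the dynamics identical to plain Langevin", {
  m <- cached_pincer()
  plain <- langevin_run(m, 5e4, seed = 8)
  degen <- metad_run(m, 5e4, bias = bias_params(height = 0), seed = 8)
  expect_identical(plain$d, degen$traj$d)
  expect_identical(plain$phi, degen$traj$phi)
})

test_that("restraining walls confine CV1 over long biased runs", {
  m <- cached_pincer()
  # reference-protocol hill widths deposit little bias volume: the walls
  # hold the CV within a few thermal lengths of the bounds
  r <- metad_run(m, 1e6, bias = bias_params(sigma_d = 0.2, sigma_phi = 0.07),
                 seed = 3)
  expect_gt(min(r$traj$d), m$walls$lower - 5)
  expect_lt(max(r$traj$d), m$walls$upper + 5)
  # the wider default hills eventually overfill the landscape; penetration
  # is still bounded by the wall quadratic
  r2 <- metad_run(m, 1e6, seed = 3)
  expect_gt(min(r2$traj$d), m$walls$lower - 8)
  expect_lt(max(r2$traj$d), m$walls$upper + 8)
})

test_that("an unstable time step triggers the stability warning", {
  m <- cached_pincer()
  expect_warning(langevin_run(m, 10, dt = 5, seed = 1), "unstable")
})

test_that("the FES of a single hill is height minus the Gaussian", {
  hills <- data.frame(t = 1, d = 55, phi = -1.1, sigma_d = 2, sigma_phi = 0.2,
                      height = 0.5)
  fes <- fes_from_bias(hills, n_bins_d = 81, n_bins_phi = 72,
                       d_range = c(45, 65), time_average_fraction = 0)
  at <- function(d, phi) fes$F[which.min(abs(fes$d - d)),
                               which.min(abs(fes$phi - phi))]
  expect_equal(at(55, -63), 0, tolerance = 0.01)
  # one sigma out in d: F = h - h exp(-1/2)
  expect_equal(at(57, -63), 0.5 * (1 - exp(-0.5)), tolerance = 0.03)
  expect_true(is.na(at(45, 120)))          # far bins are unset, not zero
  expect_error(fes_from_bias(hills[0, ]), "empty bias")
})

test_that("the FES is invariant under reordering of the hill list", {
  set.seed(12)
  hills <- data.frame(t = 1:200, d = runif(200, 45, 70),
                      phi = runif(200, -pi, pi),
                      sigma_d = 1.2, sigma_phi = 0.12, height = 0.289)
  f1 <- fes_from_bias(hills, n_bins_d = 40, n_bins_phi = 36,
                      d_range = c(40, 76), time_average_fraction = 0)
  f2 <- fes_from_bias(hills[sample(200), ], n_bins_d = 40, n_bins_phi = 36,
                      d_range = c(40, 76), time_average_fraction = 0)
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  expect_equal(min(f1$F, na.rm = TRUE), 0)
})

test_that("a frozen bias reports zero checkpoint drift and convergence", {
  m <- cached_pincer()
  r <- metad_run(m, 2e5, seed = 4)
  # all hills before the 'equilibration' cut: no new hills afterwards
  tmax <- max(r$bias$hills$t)
  traj <- r$traj
  traj$time <- traj$time + tmax            # pretend sampling continued
  rep_ <- convergence_report(traj, r$bias, equilibration_time = tmax)
  expect_equal(rep_$max_delta_f, 0, tolerance = 1e-12)
  expect_true(all(rep_$converged))
  expect_error(convergence_report(r$traj, r$bias,
                                  equilibration_time = max(r$traj$time) + 1),
               "not shorter")
})

fake_traj <- function(d, phi, model, dt = 0.5) {
  structure(list(time = seq_along(d) * dt, d = d, phi = phi,
                 frames = NULL, frame_step = integer(0),
                 n_steps = length(d), dt = dt, seed = 0, model = model),
            class = "pincer_traj")
}

test_that("microstate binning: confinement, contiguity and conservation", {
  m <- cached_pincer()
  hills <- data.frame(t = 1:50, d = rep(c(50, 55), 25),
                      phi = rep(c(0.4, -1.1), 25),
                      sigma_d = 3, sigma_phi = 0.4, height = 0.3)
  fes <- fes_from_bias(hills, n_bins_d = 30, n_bins_phi = 30,
                       d_range = c(44, 62), time_average_fraction = 0)
  # trajectory confined to one tight spot: a single microstate near ddg 0
  tr1 <- fake_traj(rep(50, 100) + rnorm(100, sd = 0.01),
                   rep(22.9, 100), m)
  ms1 <- bin_microstates(tr1, fes, n_bins_per_cv = 20)
  expect_equal(nrow(ms1), 1L)
  expect_lt(ms1$ddg, 0.3)              # bin center vs hill peak offset
  expect_equal(ms1$n_members, 100L)
  # two diagonal clusters: the contiguity filter keeps the minimum's side
  tr2 <- fake_traj(c(rep(50, 60), rep(55, 40)),
                   c(rep(22.9, 60), rep(-63, 40)), m)
  ms2 <- bin_microstates(tr2, fes, n_bins_per_cv = 20)
  expect_equal(nrow(ms2), 2L)
  expect_equal(sum(ms2$contiguous), 1L)
  expect_equal(sum(ms2$n_members), 100L)
  expect_error(bin_microstates(tr2, fes, equilibration = 1e9),
               "no frames")
})

test_that("microstate counts are conserved on a real biased run", {
  m <- cached_pincer()
  r <- metad_run(m, 2e5, seed = 13, frame_stride = 1000, cv_stride = 100)
  fes <- fes_from_bias(r$bias)
  equil <- 0.25 * max(r$traj$time)
  ms <- bin_microstates(r$traj, fes, equilibration = equil)
  expect_equal(sum(ms$n_members), sum(r$traj$time > equil))
  expect_true(all(ms$ddg[ms$contiguous] >= 0, na.rm = TRUE))
  expect_true(any(ms$contiguous))
  # representatives point at stored frames whose CVs sit in the right bin
  k <- which(!is.na(ms$representative))[1]
  s <- frame_structure(r$traj, ms$representative[k])
  cv <- cv_pair(s, m$partition)
  bins <- attr(ms, "bins")
  expect_lt(abs(cv$d - ms$d[k]), 2 * diff(bins$d[1:2]))
})

test_that("hills and FES tables round-trip through their text formats", {
  m <- cached_pincer()
  r <- metad_run(m, 2e4, seed = 2)
  p <- tempfile(fileext = ".txt")
  write_hills(r$bias, p)
  back <- read_hills(p)
  expect_equal(back$d, r$bias$hills$d, tolerance = 1e-6)
  expect_equal(back$height, r$bias$hills$height, tolerance = 1e-9)
  fes <- fes_from_bias(r$bias, n_bins_d = 20, n_bins_phi = 18)
  fp <- tempfile(fileext = ".txt")
  write_fes(fes, fp)
  tab <- read.table(fp, comment.char = "#")
  expect_equal(nrow(tab), 20L * 18L)
  expect_equal(sort(unique(tab[[1]])), fes$d, tolerance = 1e-5)
})
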