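# SAXS computations: Debye profiles, Guinier analysis, P(r), Porod-Debye,
# chi fitting and multi-state ensemble fits.

test_that("Debye profile closed forms: one and two scattering centers", {
  q <- default_q_grid(50)
  one <- debye_profile(toy_structure(c(0, 0, 0)), q, form_factor_model = 2.5)
  expect_equal(one$I, rep(2.5^2, 50))
  dd <- 13.7
  two <- debye_profile(toy_structure(rbind(c(0, 0, 0), c(dd, 0, 0))), q,
                       form_factor_model = 1.5)
  expect_equal(two$I, 2 * 1.5^2 * (1 + sin(q * dd) / (q * dd)), tolerance = 1e-12)
  expect_equal(two$I[1] < 2 * 1.5^2 * 2, TRUE)   # below the q->0 limit
  expect_error(debye_profile(toy_structure(c(0, 0, 0))[0, ]), "empty|atoms")
})

# homogeneous sphere discretised as radial x angular quadrature nodes with
# r^2 weights as per-center scattering factors
quadrature_sphere <- function(R, nr = 24, npt = 120) {
  r <- (seq_len(nr) - 0.5) / nr * R
  i <- seq_len(npt) - 0.5
  ph <- acos(1 - 2 * i / npt); th <- pi * (1 + sqrt(5)) * i
  shell <- cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  pts <- do.call(rbind, lapply(seq_len(nr), function(k) shell * r[k]))
  list(s = toy_structure(pts), f = rep(r^2, each = npt))
}

test_that("a dense bead sphere matches the analytic sphere form factor", {
  R <- 20
  qs <- quadrature_sphere(R)
  q <- seq(0.01, 4 / R, length.out = 40)
  I <- debye_profile(qs$s, q, form_factor_model = qs$f)$I
  shape <- function(x) (3 * (sin(x) - x * cos(x)) / x^3)^2
  ana <- shape(q * R)
  rel <- I / I[1] / (ana / ana[1])
  expect_lt(max(abs(rel - 1)), 0.02)
  # I(0) = (sum f)^2
  s <- toy_structure(matrix(rnorm(60), 20, 3) * 5)
  expect_equal(debye_profile(s, c(1e-4, 1))$I[1], 400, tolerance = 1e-5)
})

test_that("Debye profiles are invariant under rigid transforms", {
  set.seed(2)
  m <- cached_pincer()
  s <- conformer_structure(m, 60, 10)
  q <- default_q_grid(40)
  I0 <- debye_profile(s, q)$I
  s2 <- transform_structure(s, random_rotation(), c(30, -10, 5))
  expect_equal(debye_profile(s2, q)$I, I0, tolerance = 1e-9)
})

test_that("Guinier analysis recovers exact and Debye radii of gyration", {
  q <- default_q_grid(200)
  # exact Gaussian profile, Rg = 30
  p <- saxs_profile(q, 100 * exp(-q^2 * 30^2 / 3))
  g <- guinier_fit(p)
  expect_equal(g$Rg, 30, tolerance = 0.01 / 30)
  expect_equal(g$I0, 100, tolerance = 1e-3)
  expect_true(g$pass)
  expect_lte(g$q_range[2] * g$Rg, 1.3 + 1e-6)
  # Debye profile of a homogeneous sphere: Rg = sqrt(3/5) R
  R <- 25
  qs <- quadrature_sphere(R)
  ps <- debye_profile(qs$s, default_q_grid(150, 0.002, 0.2),
                      form_factor_model = qs$f)
  expect_equal(guinier_fit(ps)$Rg, sqrt(3 / 5) * R, tolerance = 0.02)
})

test_that("Guinier Rg matches coordinate Rg for random bead clouds", {
  set.seed(14)
  for (i in 1:4) {
    pts <- matrix(rnorm(3 * 150, sd = runif(1, 8, 18)), ncol = 3)
    s <- toy_structure(pts)
    rg <- radius_of_gyration(s)
    p <- debye_profile(s, default_q_grid(150, 0.002, min(0.3, 1.3 / rg * 3)))
    expect_equal(guinier_fit(p)$Rg, rg, tolerance = 0.03)
  }
})

test_that("P(r) histograms: two points, normalisation, uniform sphere", {
  pr <- pr_from_structure(toy_structure(rbind(c(0, 0, 0), c(10, 0, 0))),
                          bin_width = 1)
  expect_equal(attr(pr, "Dmax"), 10)
  expect_equal(attr(pr, "mode"), 10.5)     # bin center containing r = 10
  expect_equal(sum(pr$p > 0), 1L)
  expect_equal(sum(pr$p) * 1, 1, tolerance = 1e-9)
  # uniform solid sphere: P(r) = 3 r^2/R^3 (1 - 3r/(4R) + r^3/(16 R^3))
  set.seed(3)
  R <- 15
  pts <- matrix(runif(3 * 3e4, -R, R), ncol = 3)
  pts <- pts[rowSums(pts^2) <= R^2, ][1:6000, ]
  pr2 <- pr_from_structure(toy_structure(pts), bin_width = 1.5)
  x <- pr2$r / R
  ana <- 3 * x^2 / R * (1 - 0.75 * x + x^3 / 16)
  ana[x > 2] <- 0
  expect_lt(max(abs(pr2$p - ana)), 0.006)
  expect_equal(sum(pr2$p) * 1.5, 1, tolerance = 1e-9)
})

test_that("Porod-Debye plateau index separates rigid from flexible decay", {
  q <- default_q_grid(150, 0.02, 0.4)
  ideal <- saxs_profile(q, 7 / q^4)         # ideal Porod: exact plateau
  soft <- saxs_profile(q, 7 / q^3)
  i1 <- porod_debye(ideal)$plateau_index
  i2 <- porod_debye(soft)$plateau_index
  expect_lt(i1, 1e-9)
  expect_gt(i2, i1)
  expect_gt(i2, 0.1)
  # the flexible 3-state pincer mixture lacks the plateau a compact rigid
  # particle shows (the experimental comparison is likewise between a
  # compact truncation construct and the flexible full-length protein);
  # median over 3 noise seeds
  m <- cached_pincer()
  g <- seq(-25, 25, by = 3)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[rowSums(pts^2) <= 625, ]
  compact <- toy_structure(pts)
  states <- lapply(list(c(50, 27), c(67, -63), c(74, 45)),
                   function(cv) conformer_structure(m, cv[1], cv[2]))
  qq <- default_q_grid(200)
  rigid_idx <- flex_idx <- numeric(3)
  for (sd in 1:3) {
    pr <- synthetic_saxs_experiment(mixture_spec(list(compact), 1,
                                                 noise_a = 0.002),
                                    q_grid = qq, seed = sd)
    pf <- synthetic_saxs_experiment(mixture_spec(states, c(0.607, 0.314, 0.079),
                                                 noise_a = 0.002),
                                    q_grid = qq, seed = sd,
                                    bead_radius = m$bead_radius)
    rigid_idx[sd] <- porod_debye(pr)$plateau_index
    flex_idx[sd] <- porod_debye(pf)$plateau_index
  }
  expect_gt(median(flex_idx), median(rigid_idx))
})

test_that("chi fitting recovers scale and is zero on self-fits", {
  q <- default_q_grid(120)
  m <- cached_pincer()
  p <- debye_profile(conformer_structure(m, 55, -63), q)
  exp_p <- saxs_profile(q, p$I, sigma = 0.01 * p$I)
  self <- chi_fit(exp_p, p)
  expect_equal(self$c, 1, tolerance = 1e-10)
  expect_equal(self$chi, 0, tolerance = 1e-10)
  scaled <- saxs_profile(q, 7.3 * p$I)
  fit <- chi_fit(exp_p, scaled)
  expect_equal(fit$c, 1 / 7.3, tolerance = 1e-10)
  expect_equal(fit$chi, 0, tolerance = 1e-8)
  narrow <- saxs_profile(q[q > 0.2], p$I[q > 0.2])
  expect_error(chi_fit(exp_p, narrow), "overlap")
})

test_that("multi-state fitting recovers populations exactly without noise", {
  m <- cached_pincer()
  states <- lapply(list(c(50, 27), c(67, -63), c(74, 45), c(55, -63)),
                   function(cv) conformer_structure(m, cv[1], cv[2]))
  q <- default_q_grid(180)
  profs <- lapply(states, debye_profile, q_grid = q)
  w_true <- c(0.607, 0.314, 0.079)
  exact <- saxs_profile(q, profs[[1]]$I * w_true[1] + profs[[2]]$I * w_true[2] +
                          profs[[3]]$I * w_true[3])
  fit <- multistate_fit(exact, profs, k_max = 3)
  best3 <- fit$by_k[[3]]
  expect_equal(sort(best3$states), 1:3)
  expect_equal(best3$weights[order(best3$states)], w_true, tolerance = 1e-6)
  expect_lt(best3$chi, 1e-6)
  # chi is non-increasing in k on the same pool
  chis <- vapply(fit$by_k, `[[`, 0.0, "chi")
  expect_true(all(diff(chis) <= 1e-12))
  # a single candidate equal to the data: k = 1 is already perfect
  fit1 <- multistate_fit(exact, profs[1:3], k_max = 1)
  expect_gt(fit1$best$chi, 0)
  fit_self <- multistate_fit(exact, list(exact), k_max = 1)
  expect_lt(fit_self$best$chi, 1e-10)
  expect_equal(unname(coef(fit_self)), 1)
})

test_that("multi-state fitting tolerates 1% noise (weight RMSE < 0.05)", {
  m <- cached_pincer()
  states <- lapply(list(c(50, 27), c(67, -63), c(74, 45)),
                   function(cv) conformer_structure(m, cv[1], cv[2]))
  w_true <- c(0.607, 0.314, 0.079)
  profs <- lapply(states, debye_profile, q_grid = default_q_grid())
  rmse <- chis <- numeric(5)
  for (sd in 1:5) {
    noisy <- synthetic_saxs_experiment(mixture_spec(states, w_true,
                                                    noise_a = 0.01),
                                       seed = sd)
    fit <- multistate_fit(noisy, profs, k_max = 3)
    b <- fit$by_k[[3]]
    w <- b$weights[order(b$states)]
    rmse[sd] <- sqrt(mean((w - w_true)^2))
    chis[sd] <- b$chi
  }
  expect_lt(median(rmse), 0.05)
  expect_lt(abs(mean(chis) - 1), 0.15)
})

test_that("NNLS weights agree with a dense grid search on two candidates", {
  m <- cached_pincer()
  q <- default_q_grid(100)
  p1 <- debye_profile(conformer_structure(m, 50, 27), q)
  p2 <- debye_profile(conformer_structure(m, 70, -100), q)
  target <- saxs_profile(q, 0.35 * p1$I + 0.65 * p2$I,
                         sigma = 0.01 * (0.35 * p1$I + 0.65 * p2$I))
  fit <- multistate_fit(target, list(p1, p2), k_max = 2)$by_k[[2]]
  # oracle: scan the weight simplex and the scale on a fine grid
  sig <- target$sigma
  best <- c(Inf, NA)
  for (w1 in seq(0, 1, by = 0.002)) {
    Ic <- w1 * p1$I + (1 - w1) * p2$I
    cc <- sum(target$I * Ic / sig^2) / sum(Ic^2 / sig^2)
    chi <- sqrt(mean(((target$I - cc * Ic) / sig)^2))
    if (chi < best[1]) best <- c(chi, w1)
  }
  expect_equal(fit$weights[1], best[2], tolerance = 0.005)
  expect_lte(fit$chi, best[1] + 1e-9)
})

test_that("profile text files round-trip", {
  q <- default_q_grid(30)
  p <- saxs_profile(q, exp(-q^2 * 300), sigma = 0.01 * exp(-q^2 * 300))
  f <- tempfile(fileext = ".dat")
  write_saxs(p, f)
  b <- read_saxs(f)
  expect_equal(b$q, p$q, tolerance = 1e-8)
  expect_equal(b$I, p$I, tolerance = 1e-6)
  expect_equal(b$sigma, p$sigma, tolerance = 1e-6)
})

test_that("the ensemble-weighted Rg behaves like a weighted mean", {
  expect_equal(round(ensemble_rg(c(32, 37, 38), c(0.607, 0.314, 0.079)), 1),
               34.0)
  expect_equal(ensemble_rg(29.7, 1), 29.7)
  expect_equal(ensemble_rg(c(37, 32, 38), c(0.314, 0.607, 0.079)),
               ensemble_rg(c(32, 37, 38), c(0.607, 0.314, 0.079)))
  expect_error(ensemble_rg(c(30, 40), c(0.6, 0.6)), "sum to 1")
  expect_error(ensemble_rg(c(30, 40), c(1.2, -0.2)), "non-negative|sum")
})
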