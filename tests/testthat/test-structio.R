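# Structure I/O and geometry: PDB parsing, centers of mass, collective
# variables, radius of gyration, superposition.

test_that("a one-atom PDB round-trips through the parser", {
  p <- write_mini_pdb(pdb_atom_line(1, "CA", "ALA", "A", 1, 1.5, -2.25, 3.125))
  s <- read_structure(p)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(unlist(s[1, c("x", "y", "z")])), c(1.5, -2.25, 3.125))
  expect_equal(s$element, "C")
  expect_gt(s$mass, 11)
})

test_that("malformed ATOM records are reported with their line number", {
  bad <- "ATOM      2  CA  ALA A   2    xxxxxxxxyyyyyyyyzzzzzzzz  1.00  0.00"
  p <- write_mini_pdb(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), bad))
  expect_error(read_structure(p), "line 2")
})

test_that("an empty protein selection is an explicit error", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), p)
  expect_error(read_structure(p), "empty structure")
  expect_equal(nrow(read_structure(p, het = TRUE)), 1L)
})

test_that("alternate locations resolve by occupancy with first-listed ties", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 1, 1, 1, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "CB", "ALA", "A", 1, 5, 5, 5, occ = 0.5, alt = "B"))
  p <- write_mini_pdb(lines)
  s <- read_structure(p)
  expect_equal(nrow(s), 2L)
  expect_equal(s$x[s$name == "CA"], 9)     # higher occupancy wins
  expect_equal(s$x[s$name == "CB"], 1)     # tie -> first listed
  s2 <- read_structure(p, altloc_policy = "first")
  expect_equal(s2$x[s2$name == "CA"], 0)
})

test_that("center of mass matches a brute-force summation", {
  expect_equal(center_of_mass(toy_structure(c(1, 2, 3))), c(1, 2, 3))
  expect_equal(center_of_mass(toy_structure(rbind(c(0, 0, 0), c(2, 0, 0)))),
               c(1, 0, 0))
  set.seed(42)
  s <- toy_structure(matrix(rnorm(60, sd = 10), 20, 3),
                     mass = runif(20, 1, 30))
  oracle <- colSums(coords(s) * s$mass) / sum(s$mass)
  expect_equal(center_of_mass(s), unname(oracle), tolerance = 1e-10)
  expect_equal(center_of_mass(s, mass_weighted = FALSE),
               unname(colMeans(coords(s))), tolerance = 1e-10)
  expect_error(select_domain(s, c(100, 110)), "empty selection")
})

test_that("the collective-variable pair matches hand geometry", {
  # right-handed staircase: torsion exactly +90 degrees
  s <- four_domain_structure(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                             c(10, 10, 10))
  cv <- cv_pair(s, four_domain_partition())
  expect_equal(cv$d, sqrt(300), tolerance = 1e-12)
  expect_equal(cv$phi, 90, tolerance = 1e-10)
  # mirror image flips the torsion sign, keeps the magnitude
  sm <- s; sm$z <- -sm$z
  cvm <- cv_pair(sm, four_domain_partition())
  expect_equal(cvm$phi, -90, tolerance = 1e-10)
  expect_equal(cvm$d, cv$d)
})

test_that("collinear domain centers make the torsion an explicit error", {
  s <- four_domain_structure(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(cv_pair(s, four_domain_partition()), "degenerate|collinear")
})

test_that("radius of gyration: closed forms and the solid-sphere limit", {
  expect_equal(radius_of_gyration(toy_structure(rbind(c(-1, 0, 0), c(1, 0, 0)))),
               1.0)
  # uniform solid sphere: Rg -> sqrt(3/5) R
  set.seed(1)
  R <- 10
  n <- 4e4
  pts <- matrix(runif(3 * n * 3, -R, R), ncol = 3)
  pts <- pts[rowSums(pts^2) <= R^2, ][seq_len(n), ]
  s <- toy_structure(pts)
  expect_equal(radius_of_gyration(s), sqrt(3 / 5) * R, tolerance = 0.01)
  expect_error(radius_of_gyration(toy_structure(c(0, 0, 0))), ">= 2")
})

test_that("geometry is invariant under rigid-body transforms", {
  set.seed(7)
  m <- cached_pincer()
  s <- conformer_structure(m, 58, -40)
  cv0 <- cv_pair(s, m$partition)
  rg0 <- radius_of_gyration(s)
  for (i in 1:5) {
    s2 <- transform_structure(s, random_rotation(), rnorm(3, sd = 50))
    cv <- cv_pair(s2, m$partition)
    expect_equal(cv$d, cv0$d, tolerance = 1e-6)
    expect_equal(cv$phi, cv0$phi, tolerance = 1e-6)
    expect_equal(radius_of_gyration(s2), rg0, tolerance = 1e-6)
  }
})

test_that("Kabsch superposition: exact recovery, closed-form rmsd, oracle", {
  set.seed(11)
  x <- matrix(rnorm(30, sd = 5), 10, 3)
  a <- toy_structure(x)
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-10)
  # rotate 90 deg about z and translate; recover exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- transform_structure(a, Rz, c(3, -7, 2))
  fit <- superpose(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, Rz, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # one atom displaced by 1 A among n paired atoms: rmsd = 1/sqrt(n)
  xc <- x; xc[1, ] <- xc[1, ] + c(1, 0, 0) / sqrt(3) * sqrt(3)
  # displacement along the least-squares-neutral direction is not exactly
  # 1/sqrt(n) after refitting; use a far-apart cloud so refit is negligible
  xbig <- matrix(rnorm(300, sd = 100), 100, 3)
  xd <- xbig; xd[1, ] <- xd[1, ] + c(1, 0, 0)
  expect_equal(superpose(toy_structure(xd), toy_structure(xbig))$rmsd,
               1 / sqrt(100), tolerance = 0.01)
  # brute-force rotation-grid oracle on a 5-atom toy
  small <- matrix(rnorm(15, sd = 3), 5, 3)
  target <- transform_structure(toy_structure(small),
                                random_rotation(), c(1, 2, 3))
  target$x <- target$x + rnorm(5, sd = 0.3)  # make the optimum nontrivial
  k_rmsd <- superpose(toy_structure(small), target)$rmsd
  cs <- sweep(small, 2, colMeans(small))
  ct <- sweep(coords(target), 2, colMeans(coords(target)))
  euler_rmsd <- function(a) {
    R1 <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    R2 <- matrix(c(1, 0, 0, 0, cos(a[2]), -sin(a[2]), 0, sin(a[2]), cos(a[2])), 3, 3, byrow = TRUE)
    R3 <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((cs %*% t(R3 %*% R2 %*% R1) - ct)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 25)[-25]
  best <- Inf; best_a <- NULL
  for (a1 in grid) for (a2 in seq(0, pi, length.out = 13)) for (a3 in grid) {
    r <- euler_rmsd(c(a1, a2, a3))
    if (r < best) { best <- r; best_a <- c(a1, a2, a3) }
  }
  polished <- optim(best_a, euler_rmsd)$value   # local polish off the grid
  expect_gte(polished, k_rmsd - 1e-6)      # Kabsch is the true minimum
  expect_lt(polished - k_rmsd, 1e-3)       # and the search converges to it
  expect_error(superpose(toy_structure(rbind(c(0,0,0), c(1,0,0), c(2,0,0))),
                         toy_structure(rbind(c(0,0,0), c(1,0,0), c(2,0,0)))),
               "collinear|degenerate")
})

test_that("multi-model PDB output re-reads frame by frame", {
  m <- cached_pincer()
  s1 <- conformer_structure(m, 50, 27)
  s2 <- conformer_structure(m, 67, -63)
  p <- tempfile(fileext = ".pdb")
  write_structure(s1, p, frames = list(coords(s1), coords(s2)))
  r2 <- read_structure(p, model = 2)
  expect_equal(nrow(r2), nrow(s2))
  expect_equal(coords(r2), coords(s2), tolerance = 1e-3,
               ignore_attr = TRUE)
})
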