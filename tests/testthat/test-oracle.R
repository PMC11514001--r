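test_that("surrogate energy vanishes for undistorted monomers at large separation", {
  ## intramolecular terms are exactly zero at the equilibrium internal
  ## geometry; the residual is the dipole-dipole Coulomb tail (~ r^-3)
  e500 <- oracle_total_energy(hbonded_dimer(500))
  e5000 <- oracle_total_energy(hbonded_dimer(5000))
  expect_lt(abs(e500), 1e-5)
  expect_lt(abs(e5000), 1e-8)
})

test_that("bond distortion follows the harmonic closed form", {
  spec <- oracle_spec()
  delta <- 0.03
  base <- hbonded_dimer(500)          # intermolecular terms negligible
  m <- unclass(base)
  m[2, 1] <- m[2, 1] - delta          # compress O1-H2 along the bond
  e <- oracle_total_energy(dimer_geometry(m), spec) -
    oracle_total_energy(base, spec)
  expect_equal(e, spec$bond_k * delta^2, tolerance = 1e-6)
})

test_that("total energy equals an independent term-by-term summation", {
  spec <- oracle_spec()
  q <- c(spec$q_O, spec$q_H, spec$q_H, spec$q_O, spec$q_H, spec$q_H)
  for (g in random_geometries(10, seed = 21)) {
    m <- unclass(g)
    pd <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
    ang <- function(i, j, k) {
      u <- m[i, ] - m[j, ]; v <- m[k, ] - m[j, ]
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
    e <- 0
    for (b in list(c(1, 2), c(1, 3), c(4, 5), c(4, 6)))
      e <- e + spec$bond_k * (pd(b[1], b[2]) - spec$bond_r0)^2
    e <- e + spec$angle_k * (ang(2, 1, 3) - spec$angle_theta0)^2 +
      spec$angle_k * (ang(5, 4, 6) - spec$angle_theta0)^2
    for (i in 1:3) for (j in 4:6)
      e <- e + spec$coulomb * q[i] * q[j] / pd(i, j)
    sr6 <- (spec$lj_sigma / pd(1, 4))^6
    e <- e + 4 * spec$lj_epsilon * (sr6^2 - sr6)
    expect_equal(oracle_total_energy(g, spec), e, tolerance = 1e-12)
  }
})

test_that("atomic partition sums exactly to the total energy", {
  for (g in random_geometries(1000, seed = 22)) {
    ae <- oracle_atomic_energies(g)
    expect_lt(abs(sum(ae) - oracle_total_energy(g)), 1e-10)
  }
})

test_that("mirror-symmetric dimers have equal oxygen atomic energies", {
  ## two identical monomers facing each other symmetrically
  th <- 104.52 * pi / 180
  A <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96 * cos(th), 0.96 * sin(th), 0))
  B <- A
  B[, 1] <- 3.0 - B[, 1]              # reflect through the x = 1.5 plane
  g <- dimer_geometry(rbind(A, B))
  ae <- oracle_atomic_energies(g)
  expect_equal(ae[["O1"]], ae[["O4"]])
  expect_equal(ae[["H2"]], ae[["H5"]])
})

test_that("the half-half partition rule reproduces per-term bookkeeping for H2", {
  spec <- oracle_spec()
  g <- random_geometries(1, seed = 23)[[1]]
  m <- unclass(g)
  pd <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  q <- c(spec$q_O, spec$q_H, spec$q_H, spec$q_O, spec$q_H, spec$q_H)
  expected <- 0.5 * spec$bond_k * (pd(1, 2) - spec$bond_r0)^2 +
    0.5 * sum(vapply(4:6, function(j)
      spec$coulomb * q[2] * q[j] / pd(2, j), numeric(1)))
  expect_equal(oracle_atomic_energies(g, spec)[["H2"]], expected)
})

test_that("analytic forces match the finite-difference oracle", {
  for (g in random_geometries(100, seed = 24)) {
    Fd <- fd_forces(oracle_spec(), g, h = 1e-3)
    expect_lt(max(abs(oracle_forces(g) - Fd)), 1e-5)
  }
})

test_that("net force and net torque vanish", {
  for (g in random_geometries(20, seed = 25)) {
    F <- oracle_forces(g)
    expect_lt(max(abs(colSums(F))), 1e-10)
    m <- unclass(g)
    cen <- colMeans(m)
    tq <- c(0, 0, 0)
    for (a in 1:6) {
      r <- m[a, ] - cen
      tq <- tq + c(r[2] * F[a, 3] - r[3] * F[a, 2],
                   r[3] * F[a, 1] - r[1] * F[a, 3],
                   r[1] * F[a, 2] - r[2] * F[a, 1])
    }
    expect_lt(max(abs(tq)), 1e-8)
  }
})

test_that("energies are rigid-motion invariant and forces equivariant", {
  set.seed(31)
  g <- random_geometries(1, seed = 26)[[1]]
  e0 <- oracle_total_energy(g)
  F0 <- oracle_forces(g)
  for (k in 1:20) {
    R <- random_rotation_matrix()
    g2 <- transform_geometry(g, R, rnorm(3, sd = 3))
    expect_lt(abs(oracle_total_energy(g2) - e0), 1e-9)
    expect_lt(max(abs(oracle_forces(g2) - F0 %*% t(R))), 1e-9)
  }
})

test_that("the radial profile minimum balances the intermolecular forces", {
  spec <- oracle_spec()
  profile <- function(r) oracle_total_energy(hbonded_dimer(r), spec)
  rstar <- optimize(profile, c(2.2, 4.0), tol = 1e-10)$minimum
  F <- oracle_forces(hbonded_dimer(rstar), spec)
  ## net force on molecule B projected on the approach axis vanishes
  fB <- colSums(F[4:6, ])
  expect_lt(abs(fB[1]), 1e-3)
})

test_that("labelling is deterministic, rigid-motion invariant, and exact", {
  d <- generate_dataset(generator_config(n_geometries = 5, seed = 27))
  lab1 <- label_dataset(d, forces = TRUE)
  lab2 <- label_dataset(d, forces = TRUE)
  expect_identical(lab1$atomic_energies, lab2$atomic_energies)
  expect_equal(rowSums(lab1$atomic_energies), lab1$total_energy)
  ## rigid motion leaves labels unchanged
  set.seed(8)
  R <- random_rotation_matrix()
  moved <- structure(list(
    geometries = lapply(d$geometries, transform_geometry, rotation = R,
                        translation = c(1, -2, 0.5)),
    config = d$config), class = "dimer_dataset")
  lab3 <- label_dataset(moved)
  expect_equal(lab3$atomic_energies, lab1$atomic_energies, tolerance = 1e-9)
  ## empty dataset
  empty <- structure(list(geometries = list(), config = d$config),
                     class = "dimer_dataset")
  expect_length(label_dataset(empty)$total_energy, 0)
})

test_that("labeled datasets survive a CSV round trip", {
  d <- generate_dataset(generator_config(n_geometries = 4, seed = 28))
  lab <- label_dataset(d, forces = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled(lab, path)
  back <- read_labeled(path)
  expect_equal(back$atomic_energies, lab$atomic_energies, tolerance = 1e-12)
  expect_equal(back$total_energy, lab$total_energy, tolerance = 1e-12)
  expect_equal(back$forces[[2]], lab$forces[[2]], tolerance = 1e-12)
  expect_lt(max(abs(unclass(back$geometries[[3]]) -
                    unclass(lab$geometries[[3]]))), 1e-12)
})

test_that("charges must be neutral per molecule", {
  expect_error(oracle_spec(q_O = -0.8, q_H = 0.41), "sum to zero")
})
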